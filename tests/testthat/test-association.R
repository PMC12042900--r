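base_date <- as.Date("2000-01-01")

test_that("endpoint harmonization handles boundaries and serotype dominance", {
  rec <- make_records(4)
  ev <- data.frame(
    sample_id = c("P001", "P001", "P002", "P003"),
    code = c("M06", "M05", "M06", "M05"),
    date = base_date + c(-100, 300, -50, 1),
    stringsAsFactors = FALSE
  )
  cm <- default_code_map()

  # seropositive code anywhere overrides a seronegative label
  st <- assign_serotype(rec, ev, cm)
  expect_equal(st, c("seropositive", "seronegative", "seropositive", "none"))

  ep <- harmonize_endpoints(rec, ev, cm)
  ra <- ep[ep$endpoint == "ra", ]
  expect_equal(ra$prevalent, c(TRUE, TRUE, FALSE, FALSE))
  # code dated 1 day after sampling: incident, not prevalent
  expect_true(ra$incident[3])
  expect_equal(ra$time_to_event[3], 1 / 365.25)
  # no codes at all
  expect_false(ra$prevalent[4] || ra$incident[4])

  # same-day tie counts as prevalent by default; strict flag flips it
  tie <- data.frame(sample_id = "P001", code = "M05", date = base_date)
  ep_tie <- harmonize_endpoints(rec, tie, cm)
  expect_true(ep_tie$prevalent[ep_tie$endpoint == "ra"][1])
  ep_strict <- harmonize_endpoints(rec, tie, cm, strict_prevalent = TRUE)
  expect_false(ep_strict$prevalent[ep_strict$endpoint == "ra"][1])

  # undated events are rejected with a diagnostic
  bad <- ev; bad$date[2] <- NA
  expect_error(harmonize_endpoints(rec, bad, cm), "no date")
})

test_that("logistic model: null calibration, exclusions, invariances", {
  set.seed(21)
  n <- 4000
  d <- data.frame(sample_id = sprintf("X%04d", 1:n),
                  exposure = runif(n) < 0.1,
                  outcome = runif(n) < 0.05,
                  age = runif(n, 25, 74),
                  pc1 = rnorm(n))
  est <- prevalent_logistic(d, "exposure", "outcome", c("age", "pc1"))
  expect_s3_class(est, "effect_estimate")
  expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
  expect_gt(est$p, 0.001)  # null: no tiny p expected here
  expect_equal(est$n, n)

  # exclusion bookkeeping: n equals input minus logged rows
  d2 <- d
  d2$age[1:7] <- NA
  excl <- rep(FALSE, n); excl[8:12] <- TRUE
  est2 <- prevalent_logistic(d2, "exposure", "outcome", c("age", "pc1"),
                             exclude = excl)
  expect_equal(est2$n_excluded, 12L)
  expect_equal(est2$n, n - 12L)
  expect_equal(sort(table(est2$exclusions$reason), decreasing = TRUE),
               sort(table(c(rep("missing age", 7),
                            rep("prevalent hematologic malignancy", 5))),
                    decreasing = TRUE))

  # invariance to row order and affine PC rescaling
  est_perm <- prevalent_logistic(d[sample(n), ], "exposure", "outcome",
                                 c("age", "pc1"))
  expect_equal(est_perm$estimate, est$estimate, tolerance = 1e-8)
  d3 <- d; d3$pc1 <- 10 * d3$pc1 + 3
  est3 <- prevalent_logistic(d3, "exposure", "outcome", c("age", "pc1"))
  expect_equal(est3$estimate, est$estimate, tolerance = 1e-6)

  # complete separation is flagged, not an error
  sep <- data.frame(exposure = c(rep(TRUE, 20), rep(FALSE, 20)),
                    outcome = c(rep(TRUE, 20), rep(FALSE, 20)))
  est_sep <- prevalent_logistic(sep, "exposure", "outcome")
  expect_true(length(est_sep$flags) > 0)
})

test_that("survival construction censors at incident hematologic malignancy", {
  rec <- make_records(3)
  rec$death_date <- base_date + c(round(5 * 365.25), NA, round(8 * 365.25))
  sv <- build_survival(rec)
  expect_equal(sv$status, c(1L, 0L, 1L))
  expect_equal(sv$time, c(5, 20, 8), tolerance = 1e-3)

  # planting an incident malignancy before the first death converts it to
  # a censoring: event count drops by exactly 1
  hem <- as.Date(c(NA, NA, NA)); hem[1] <- base_date + round(3 * 365.25)
  sv2 <- build_survival(rec, hem_date = hem)
  expect_equal(sum(sv$status) - sum(sv2$status), 1L)
  expect_equal(sv2$time[1], 3, tolerance = 1e-3)
})

test_that("Cox model recovers hazard ratios and flags empty strata", {
  d <- simulate_survival_cohort(4000, hr = 2, seed = 8)
  est <- survival_cox(d, "exposure")
  expect_equal(est$measure, "HR")
  expect_equal(est$estimate, 2, tolerance = 0.2)
  expect_lt(est$p, 0.001)

  # two identical groups: HR near 1, p near 1 in expectation
  d0 <- simulate_survival_cohort(4000, hr = 1, seed = 9)
  est0 <- survival_cox(d0, "exposure")
  expect_equal(est0$estimate, 1, tolerance = 0.2)
  expect_gt(est0$p, 0.01)

  dne <- d[1:100, ]; dne$status[dne$exposure == 1] <- 0L
  est_ne <- suppressWarnings(survival_cox(dne, "exposure"))
  expect_true(any(grepl("no events", est_ne$flags)))
})

test_that("Kaplan-Meier identities and hand-computed readout", {
  # hand-computed KM on a 10-record toy table:
  # times 1+ 2 3 4+ 5 5 6+ 7 8 9+  ->  S(5) = 8/9 * 7/8 * 4/6 = 14/27
  time <- c(1, 2, 3, 4, 5, 5, 6, 7, 8, 9)
  status <- c(0, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  km <- km_logrank(time, status, horizon = 5)
  expect_equal(unname(km$horizon_survival), 14 / 27)
  expect_true(is.na(km$logrank_p))  # single group: p undefined

  # time-rescaling: group B = A with doubled times => S_B(t) = S_A(t/2)
  kmA <- km_logrank(time, status, horizon = 5)
  kmB <- km_logrank(2 * time, status, horizon = 10)
  expect_equal(unname(kmB$horizon_survival), unname(kmA$horizon_survival))

  # two clearly different groups give a small log-rank p
  g <- rep(c("a", "b"), each = 10)
  t2 <- c(time, time * 4)
  km2 <- km_logrank(t2, rep(status, 2), g)
  expect_false(is.na(km2$logrank_p))
  expect_lt(km2$logrank_p, 1)
})

test_that("group tests agree with enumeration oracles", {
  # Fisher on (3,7 / 8,2) equals hypergeometric enumeration
  tab <- matrix(c(3, 8, 7, 2), nrow = 2)
  expect_equal(group_test(table = tab, method = "fisher"),
               oracle_fisher_2x2(3, 7, 8, 2), tolerance = 1e-10)
  # identical distributions: Kruskal-Wallis p on the exhaustive tie case
  v <- rep(c(1, 2, 3), 2)
  g <- rep(c("x", "y"), each = 3)
  expect_gt(group_test(values = v, groups = g, method = "kruskal"), 0.99)
  # chi-squared path exists for larger tables
  expect_true(group_test(table = matrix(c(10, 20, 30, 12, 18, 33), 2,
                                        byrow = TRUE),
                         method = "chisq") > 0)
})

test_that("DAS28 AUC is the trapezoidal integral with horizon handling", {
  # irregular 5-visit series against a hand-computed trapezoid sum:
  # (0,5)(3,4)(9,3)(15,3.5)(24,2):
  # 3*4.5 + 6*3.5 + 6*3.25 + 9*2.75 = 13.5+21+19.5+24.75 = 78.75
  expect_equal(das28_auc(c(0, 3, 9, 15, 24), c(5, 4, 3, 3.5, 2)), 78.75)
  # series past the horizon is interpolated at 24 and truncated
  expect_equal(das28_auc(c(0, 36), c(4, 4)), 96)
  # series ending early integrates to its last visit
  expect_equal(das28_auc(c(0, 12), c(4, 4)), 48)
  expect_error(das28_auc(c(0), c(4)), "two visits")
  expect_error(das28_auc(c(1, 5), c(4, 4)), "month 0")
})

test_that("prevalence by age uses Wilson intervals and partitions the cohort", {
  set.seed(77)
  age <- runif(1000, 25, 74)
  carrier <- runif(1000) < 0.05
  tab <- prevalence_by_age(carrier, age)
  expect_equal(sum(tab$n), 1000L)
  expect_equal(sum(tab$n_carriers), sum(carrier))

  # closed-form Wilson check on one cell (78/1000 ~ [6.3%, 9.6%])
  ci <- wilson_ci(78, 1000)
  z <- qnorm(0.975); p <- 0.078; n <- 1000
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  expect_equal(ci, c(ctr - hw, ctr + hw))
  expect_equal(round(ci, 3), c(0.063, 0.096))

  # zero carriers in a bin: prevalence 0 with CI lower bound 0
  tab0 <- prevalence_by_age(rep(FALSE, 50), rep(33, 50))
  row <- tab0[tab0$n > 0, ]
  expect_equal(row$prevalence, 0)
  expect_equal(row$ci_low, 0)
})

test_that("ratio formatting matches printed-results conventions", {
  expect_equal(percentage(121, 10021), "1.2%")
  expect_equal(percentage(126, 573, digits = 0), "22%")
  expect_equal(percentage(758, 4180), "18.1%")
  expect_equal(ratio_percent(78, 1000), 7.8)
  expect_error(percentage(1, 0), "positive")
})
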