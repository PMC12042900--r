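panel <- example_panel("chip")
lymph <- example_panel("lymphoid")

test_that("single-rule verdicts match the published cascade", {
  # population-AF rule, with and without hotspot exemption
  v <- make_variant(gnomad_max_pop_af = 0.002)
  d <- evaluate_chip_rules(v, panel)
  expect_equal(d$verdict, "fail")
  expect_equal(d$failed_rules, "R2")

  hot <- make_variant(gene = "JAK2", protein_change = "V617F",
                      gnomad_max_pop_af = 0.002)
  expect_equal(evaluate_chip_rules(hot, panel)$verdict, "pass")
  # codon-level exemption covers any substitution at DNMT3A codon 882
  r882c <- make_variant(gene = "DNMT3A", protein_change = "R882C",
                        gnomad_max_pop_af = 0.002)
  expect_equal(evaluate_chip_rules(r882c, panel)$verdict, "pass")
  # ...but not a different codon
  r883 <- make_variant(gene = "DNMT3A", protein_change = "R883H",
                       gnomad_max_pop_af = 0.002)
  expect_equal(evaluate_chip_rules(r883, panel)$failed_rules, "R2")

  # strand support on both strands for both alleles
  ss <- make_variant(alt_fwd = 3L, alt_rev = 0L, alt_depth = 3L)
  expect_equal(evaluate_chip_rules(ss, panel)$failed_rules, "R7")

  # all failed rules are reported, not just the first
  multi <- make_variant(caller_label = "LowQual", somatic_quality = 1,
                        total_depth = 8L, alt_depth = 2L,
                        ref_fwd = 3L, ref_rev = 3L,
                        alt_fwd = 1L, alt_rev = 1L)
  expect_setequal(strsplit(evaluate_chip_rules(multi, panel)$failed_rules,
                           ";")[[1]],
                  c("R3", "R4", "R6"))

  # splice distance: beyond 2 bp fails, missing fails conservatively
  far <- make_variant(consequence = "splice", splice_distance_bp = 3L)
  expect_equal(evaluate_chip_rules(far, panel)$failed_rules, "R8")
  near <- make_variant(consequence = "splice", splice_distance_bp = 2L)
  expect_equal(evaluate_chip_rules(near, panel)$verdict, "pass")
  unk <- make_variant(consequence = "splice")
  expect_equal(evaluate_chip_rules(unk, panel)$failed_rules, "R8")
})

test_that("malformed read evidence is rejected with a named diagnostic", {
  v <- make_variant()
  v$alt_fwd <- NA_integer_
  expect_error(evaluate_chip_rules(v, panel), "alt_fwd")
  v2 <- make_variant()
  v2$ref_rev <- -1L
  expect_error(evaluate_chip_rules(v2, panel), "ref_rev")
  v3 <- make_variant()
  v3$alt_fwd <- 5L  # breaks alt_fwd + alt_rev == alt_depth
  expect_error(evaluate_chip_rules(v3, panel), "alt_depth")
})

test_that("frameshift clusters collapse to the highest-VAF member", {
  pair <- rbind(
    make_variant(pos = 100L, consequence = "frameshift", ref = "AT",
                 alt_depth = 12L, total_depth = 100L, alt_fwd = 6L,
                 alt_rev = 6L, ref_fwd = 44L, ref_rev = 44L),
    make_variant(pos = 103L, consequence = "frameshift", ref = "GC",
                 alt_depth = 5L, total_depth = 100L, alt_fwd = 3L,
                 alt_rev = 2L, ref_fwd = 47L, ref_rev = 48L)
  )
  out <- collapse_frameshift_clusters(pair)
  expect_equal(out$pos, 100L)

  single <- make_variant(consequence = "frameshift", ref = "AT")
  expect_equal(nrow(collapse_frameshift_clusters(single)), 1L)

  # transitive chain: 100-104-108 is one cluster though 100 and 108 are 8 apart
  chain <- rbind(
    make_variant(pos = 100L, consequence = "frameshift", alt = "T",
                 alt_depth = 3L, total_depth = 100L, alt_fwd = 2L,
                 alt_rev = 1L, ref_fwd = 48L, ref_rev = 49L),
    make_variant(pos = 104L, consequence = "frameshift", alt = "C",
                 alt_depth = 10L, total_depth = 100L, alt_fwd = 5L,
                 alt_rev = 5L, ref_fwd = 45L, ref_rev = 45L),
    make_variant(pos = 108L, consequence = "frameshift", alt = "G",
                 alt_depth = 4L, total_depth = 100L, alt_fwd = 2L,
                 alt_rev = 2L, ref_fwd = 48L, ref_rev = 48L)
  )
  out <- collapse_frameshift_clusters(chain)
  expect_equal(out$pos, 104L)
  expect_equal(nrow(oracle_collapse(validate_variants(chain))), 1L)
  expect_equal(oracle_collapse(validate_variants(chain))$pos, 104L)

  # non-frameshifts pass through untouched; multi-sample input is refused
  mixed <- rbind(chain, make_variant(pos = 102L, alt = "A", ref = "G"))
  expect_true(102L %in% collapse_frameshift_clusters(mixed)$pos)
  two <- rbind(make_variant(sample_id = "S1"), make_variant(sample_id = "S2"))
  expect_error(collapse_frameshift_clusters(two), "one sample")
})

test_that("cohort frameshift frequency uses the sample denominator", {
  # the same frameshift allele in 6 of 1000 samples (0.6% > 0.05%)
  six <- do.call(rbind, lapply(1:6, function(i) {
    make_variant(sample_id = sprintf("S%03d", i), pos = 500L,
                 ref = "AT", alt = "A", consequence = "frameshift")
  }))
  res <- filter_chip_wes(six, panel, n_samples = 1000)
  expect_true(all(res$decisions$verdict == "fail"))
  expect_true(all(res$decisions$failed_rules == "R9"))
  # same allele in a large cohort (6/20000 = 0.03% <= 0.05%) passes
  res2 <- filter_chip_wes(six, panel, n_samples = 20000)
  expect_true(all(res2$decisions$verdict == "pass"))
  # denominator smaller than the observed sample count is rejected
  expect_error(filter_chip_wes(six, panel, n_samples = 3), "n_samples")
})

test_that("WES cascade on an empty table yields no carriers", {
  res <- filter_chip_wes(make_variant()[0, ], panel, n_samples = 10,
                         samples = c("A", "B"))
  expect_equal(nrow(res$decisions), 0L)
  expect_false(any(res$profiles$carrier))
})

test_that("planted fixture: survivors equal the generator's clean set", {
  cohort <- generate_cohort(sim_config(n_participants = 3000, seed = 7))
  for (mode in c("wes", "lymphoid", "panel")) {
    vt <- generate_variant_table(cohort, mode)
    dec <- switch(mode,
      wes = filter_chip_wes(vt$variants, panel, 3000)$decisions,
      lymphoid = filter_lymphoid_wes(vt$variants, lymph, 3000),
      panel = filter_chip_panel(vt$variants, example_panel("panel"),
                                3000)$decisions)
    clean <- vt$truth[vt$truth$clean, ]
    expect_setequal(decision_keys(dec),
                    paste(clean$sample_id, clean$chrom, clean$pos, clean$alt))
    # every decoy fails the exact rule it was planted to break
    fails <- dec[dec$verdict == "fail", ]
    key <- paste(fails$sample_id, fails$chrom, fails$pos, fails$alt)
    tkey <- paste(vt$truth$sample_id, vt$truth$chrom, vt$truth$pos,
                  vt$truth$alt)
    expect_equal(fails$failed_rules, vt$truth$violates[match(key, tkey)])
  }
})

test_that("lymphoid evidence rules follow the missense-only scope", {
  ok <- make_variant(gene = "STAT3", cosmic_count = 3L, alt_depth = 4L,
                     alt_fwd = 2L, alt_rev = 2L)
  expect_equal(filter_lymphoid_wes(ok, lymph)$verdict, "pass")
  high <- make_variant(gene = "STAT3", cosmic_count = 5L, total_depth = 40L,
                       alt_depth = 16L, alt_fwd = 8L, alt_rev = 8L,
                       ref_fwd = 12L, ref_rev = 12L)  # VAF 0.40
  expect_equal(filter_lymphoid_wes(high, lymph)$failed_rules, "L1")
  # nonsense without any evidence is exempt from L2
  nons <- make_variant(gene = "STAT3", consequence = "nonsense",
                       cosmic_count = 0L, total_depth = 40L, alt_depth = 2L,
                       alt_fwd = 1L, alt_rev = 1L)  # VAF 0.05
  expect_equal(filter_lymphoid_wes(nons, lymph)$verdict, "pass")
  miss <- make_variant(gene = "STAT3", cosmic_count = 0L)
  expect_equal(filter_lymphoid_wes(miss, lymph)$failed_rules, "L2")
  lchip <- make_variant(gene = "STAT3", cosmic_count = 0L,
                        reported_lchip = TRUE)
  expect_equal(filter_lymphoid_wes(lchip, lymph)$verdict, "pass")
})

test_that("panel rules fire at the documented boundaries", {
  tp <- example_panel("panel")
  shallow <- make_variant(total_depth = 99L, alt_depth = 15L, alt_fwd = 8L,
                          alt_rev = 7L, ref_fwd = 42L, ref_rev = 42L)
  d <- filter_chip_panel(shallow, tp, 100)$decisions
  expect_equal(d$failed_rules, "P4")
  germ <- make_variant(total_depth = 200L, alt_depth = 82L, alt_fwd = 41L,
                       alt_rev = 41L, ref_fwd = 59L, ref_rev = 59L)
  expect_equal(filter_chip_panel(germ, tp, 100)$decisions$failed_rules, "P6")
  tiny <- make_variant(total_depth = 1000L, alt_depth = 19L, alt_fwd = 10L,
                       alt_rev = 9L, ref_fwd = 490L, ref_rev = 491L)
  expect_equal(filter_chip_panel(tiny, tp, 100)$decisions$failed_rules, "P8")
  # cohort recurrence counts every allele, not only frameshifts
  rec <- do.call(rbind, lapply(1:3, function(i) {
    make_variant(sample_id = sprintf("S%02d", i), pos = 700L,
                 total_depth = 200L, alt_depth = 30L, alt_fwd = 15L,
                 alt_rev = 15L, ref_fwd = 85L, ref_rev = 85L)
  }))
  d <- filter_chip_panel(rec, tp, 100)$decisions  # 3/100 samples > 1%
  expect_true(all(d$failed_rules == "P3"))
})

test_that("carrier profiles summarize strata, gene groups and counts", {
  tbl <- rbind(
    make_variant(sample_id = "A", gene = "TET2", pos = 10L,
                 alt_depth = 2L, total_depth = 50L, alt_fwd = 1L,
                 alt_rev = 1L, ref_fwd = 24L, ref_rev = 24L),   # VAF 0.04
    make_variant(sample_id = "A", gene = "TET2", pos = 20L,
                 alt_depth = 4L, total_depth = 50L, alt_fwd = 2L,
                 alt_rev = 2L, ref_fwd = 23L, ref_rev = 23L),   # VAF 0.08
    make_variant(sample_id = "B", gene = "TET2", pos = 30L,
                 alt_depth = 2L, total_depth = 40L, alt_fwd = 1L,
                 alt_rev = 1L, ref_fwd = 19L, ref_rev = 19L),   # VAF 0.05
    make_variant(sample_id = "B", gene = "DNMT3A", pos = 40L,
                 alt_depth = 6L, total_depth = 50L, alt_fwd = 3L,
                 alt_rev = 3L, ref_fwd = 22L, ref_rev = 22L)    # VAF 0.12
  )
  res <- filter_chip_wes(tbl, panel, 10, samples = c("A", "B", "C"))
  p <- res$profiles
  expect_equal(p$sample_id, c("A", "B", "C"))
  expect_equal(p$carrier, c(TRUE, TRUE, FALSE))
  expect_equal(p$vaf_stratum, c("lt10", "ge10", NA))
  expect_equal(p$max_vaf[1:2], c(0.08, 0.12))
  # gene-group truth table for sample B: TET2 + DNMT3A
  expect_true(p$DNMT3A[2] && p$TET2[2] && !p$JAK2[2])
  expect_true(p$non_DNMT3A[2] && p$non_DNMT3A_non_JAK2[2])
  # sample A: TET2 only
  expect_true(!p$DNMT3A[1] && p$TET2[1] && p$non_DNMT3A[1])
  # counting identities
  expect_equal(sum(p$carrier), 2L)
  expect_equal(sum(p$n_variants), sum(res$decisions$verdict == "pass"))
  expect_equal(is.na(p$max_vaf), !p$carrier)

  # duplicate passing keys are malformed input
  dup <- rbind(tbl[1, ], tbl[1, ])
  dec <- evaluate_chip_rules(dup, panel)
  expect_error(build_carrier_profiles(dec, "A"), "duplicate")
})

test_that("oracle equivalence, monotonicity, idempotence, order-invariance", {
  tbl <- random_variant_table(300, panel, seed = 11)
  n_samples <- 4000
  res <- filter_chip_wes(tbl, panel, n_samples)
  expect_setequal(decision_keys(res$decisions),
                  oracle_pass_keys(tbl, panel, n_samples, "wes"))

  # relaxing a threshold never shrinks the pass set; tightening never grows it
  relax <- filter_chip_wes(tbl, panel, n_samples,
                           params = chip_rule_params(min_total_depth = 5))
  tight <- filter_chip_wes(tbl, panel, n_samples,
                           params = chip_rule_params(min_total_depth = 20,
                                                     min_somatic_quality = 10))
  base_keys <- decision_keys(res$decisions)
  expect_true(all(base_keys %in% decision_keys(relax$decisions)))
  expect_true(all(decision_keys(tight$decisions) %in% base_keys))

  # idempotence: filtering the survivors changes nothing
  surv <- res$decisions[res$decisions$verdict == "pass",
                        setdiff(names(res$decisions),
                                c("verdict", "failed_rules"))]
  again <- filter_chip_wes(surv, panel, n_samples)
  expect_setequal(decision_keys(again$decisions), base_keys)

  # row order does not change the verdict set
  perm <- tbl[sample(nrow(tbl)), ]
  res_perm <- filter_chip_wes(perm, panel, n_samples)
  expect_setequal(decision_keys(res_perm$decisions), base_keys)
})
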