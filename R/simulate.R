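#' Synthetic cohort configuration
#'
#' Defaults describe the stated world the downstream analyses assume: a
#' population cohort sampled at ages 25-74; CHIP prevalence rising
#' log-linearly with age, calibrated to about 7.8% at ages 60-69 (and
#' roughly 4% overall); a driver-gene spectrum dominated by DNMT3A, TET2
#' and ASXL1; clone sizes (VAFs) from a right-skewed Beta truncated to the
#' detectable range; sequencing depth 48x in exome mode and 1700x in
#' targeted-panel mode; prevalent RA at 1.2% baseline with a true odds
#' ratio of 2.06 for CHIP carriers; and mortality with a true hazard-ratio
#' multiplier of 1.92 for participants with both CHIP and RA.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; fixed seed gives byte-identical output
#'   (Mersenne-Twister, R's default RNG).
#' @param age_range Uniform age-at-sampling range, years.
#' @param chip_intercept,chip_age_slope Age-logistic for CHIP carriage:
#'   `plogis(intercept + slope * age)`.
#' @param gene_spectrum Named non-negative weights summing to 1.
#' @param vaf_shape1,vaf_shape2,vaf_range Truncated-Beta clone-size model.
#' @param multi_variant_prob Probability a carrier has two variants
#'   (most carriers have exactly one).
#' @param coverage_wes,coverage_panel Mean sequencing depth by mode.
#' @param theta_center,theta_sd Array reference-cluster center and noise.
#' @param intensity_meanlog,intensity_sdlog Log-normal total-intensity model.
#' @param or_ra Odds ratio of prevalent RA given CHIP.
#' @param ra_baseline Prevalent-RA probability at the reference covariate
#'   level (roughly the cohort outcome prevalence).
#' @param seropositive_frac Fraction of RA that is seropositive.
#' @param hr_death Mortality hazard multiplier for CHIP-and-RA.
#' @param death_rate Baseline exponential death hazard per year at age 50.
#' @param death_age_slope Log-hazard increase per year of age.
#' @param followup_years Administrative censoring horizon after sampling.
#' @param hem_prevalent_rate,hem_incident_rate Hematologic-malignancy
#'   probabilities (prevalent carriers are enriched threefold for CHIP).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 10000,
                       seed = 1,
                       age_range = c(25, 74),
                       chip_intercept = -6.045,
                       chip_age_slope = 0.055,
                       gene_spectrum = c(DNMT3A = 0.40, TET2 = 0.20,
                                         ASXL1 = 0.10, JAK2 = 0.05,
                                         other = 0.25),
                       vaf_shape1 = 1.5, vaf_shape2 = 8,
                       vaf_range = c(0.02, 0.45),
                       multi_variant_prob = 0.08,
                       coverage_wes = 48, coverage_panel = 1700,
                       theta_center = 0.03, theta_sd = 0.01,
                       intensity_meanlog = log(2000), intensity_sdlog = 0.3,
                       or_ra = 2.06, ra_baseline = 0.012,
                       seropositive_frac = 0.70,
                       hr_death = 1.92, death_rate = 0.005,
                       death_age_slope = 0.08,
                       followup_years = 20,
                       hem_prevalent_rate = 0.005,
                       hem_incident_rate = 0.01) {
  cfg <- as.list(environment())
  if (abs(sum(gene_spectrum)) < .Machine$double.eps || any(gene_spectrum < 0)) {
    stop("gene_spectrum weights must be non-negative with positive sum",
         call. = FALSE)
  }
  cfg$gene_spectrum <- gene_spectrum / sum(gene_spectrum)
  if (cfg$vaf_range[1] <= 0 || cfg$vaf_range[2] > 1 ||
      cfg$vaf_range[1] >= cfg$vaf_range[2]) {
    stop("vaf_range must satisfy 0 < lo < hi <= 1", call. = FALSE)
  }
  if (cfg$or_ra <= 0 || cfg$hr_death <= 0) {
    stop("effect parameters must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.rbeta_trunc <- function(n, s1, s2, lo, hi) {
  # inverse-CDF sampling of a truncated Beta
  plo <- stats::pbeta(lo, s1, s2); phi <- stats::pbeta(hi, s1, s2)
  stats::qbeta(plo + stats::runif(n) * (phi - plo), s1, s2)
}

#' Default endpoint code map for synthetic registries
#'
#' Pseudo-ICD code sets used by the generator and consumed by
#' [harmonize_endpoints()]: seropositive RA (`M05`), seronegative RA
#' (`M06`), their union as `ra`, and hematologic malignancy (`C90`).
#' @return Named list of character code sets.
#' @export
default_code_map <- function() {
  list(ra = c("M05", "M06"),
       ra_seropositive = "M05",
       ra_seronegative = "M06",
       hem_malignancy = "C90")
}

#' Generate a synthetic biobank cohort with known truth
#'
#' Draws participants (age, sex, smoking, 10 standard-normal ancestry PCs),
#' assigns CHIP by the age-logistic, driver genes and clone-size VAFs per
#' carrier, prevalent RA by a logistic model with `log(or_ra)` on CHIP plus
#' mild age/sex effects, serotype, prevalent/incident hematologic
#' malignancy, and exponential survival with the `hr_death` multiplier for
#' participants with both CHIP and RA. Registry events are emitted as a
#' long (sample_id, code, date) table dated consistently with the sampling
#' date; follow-up is administratively censored `followup_years` after
#' sampling.
#'
#' @param config A [sim_config()].
#' @return List of class `"sim_cohort"`: `records` (one row per
#'   participant: covariates, dates, plus convenience flags `chip`,
#'   `ra_prevalent`, `hem_prevalent`), `events` (long registry table),
#'   `truth` (per-participant truth: CHIP status, genes, VAFs as
#'   comma-joined strings plus a per-variant `truth_variants` table), and
#'   the `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  sample_id <- sprintf("S%05d", seq_len(n))
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- ifelse(stats::runif(n) < 0.53, "male", "female")
  smoking_ever <- stats::runif(n) < 0.5
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  sampling_date <- as.Date("2000-01-01")

  chip <- stats::runif(n) < stats::plogis(config$chip_intercept +
                                            config$chip_age_slope * age)
  # variants per carrier: mostly one
  genes <- vector("list", n); vafs <- vector("list", n)
  carriers <- which(chip)
  n_var <- 1L + (stats::runif(length(carriers)) < config$multi_variant_prob)
  spec <- config$gene_spectrum
  for (k in seq_along(carriers)) {
    i <- carriers[k]
    genes[[i]] <- sample(names(spec), n_var[k], replace = TRUE, prob = spec)
    vafs[[i]] <- .rbeta_trunc(n_var[k], config$vaf_shape1, config$vaf_shape2,
                              config$vaf_range[1], config$vaf_range[2])
  }

  # prevalent RA: logistic with log(or_ra) on CHIP and mild covariate effects
  b_age <- 0.02; b_female <- 0.6
  b0 <- stats::qlogis(config$ra_baseline) -
    b_age * mean(config$age_range) - b_female * 0.47
  lp <- b0 + b_age * age + b_female * (sex == "female") +
    log(config$or_ra) * chip
  ra_prev <- stats::runif(n) < stats::plogis(lp)
  seropos <- ra_prev & (stats::runif(n) < config$seropositive_frac)
  ra_date <- sampling_date - round(stats::runif(n, 0.5, 20) * 365.25)

  # hematologic malignancies: prevalent enriched 3x in CHIP; incident later
  hem_prev <- stats::runif(n) <
    config$hem_prevalent_rate * ifelse(chip, 3, 1)
  hem_prev_date <- sampling_date - round(stats::runif(n, 0.5, 15) * 365.25)
  hem_inc <- !hem_prev & stats::runif(n) < config$hem_incident_rate
  hem_inc_date <- sampling_date +
    round(stats::runif(n, 0.5, config$followup_years) * 365.25)

  # exponential survival; hazard multiplied for CHIP-and-RA
  hazard <- config$death_rate *
    exp(config$death_age_slope * (age - 50) +
          log(config$hr_death) * (chip & ra_prev))
  t_death <- stats::rexp(n, rate = hazard)
  censor_date <- sampling_date + round(config$followup_years * 365.25)
  death_date <- sampling_date + round(t_death * 365.25)
  death_date[death_date > censor_date] <- NA

  records <- data.frame(sample_id, age = age, sex = sex,
                        smoking_ever = smoking_ever, pcs,
                        sampling_date = sampling_date,
                        death_date = death_date, censor_date = censor_date,
                        chip = chip, ra_prevalent = ra_prev,
                        hem_prevalent = hem_prev,
                        stringsAsFactors = FALSE)

  ev_block <- function(sel, code, dates) {
    data.frame(sample_id = sample_id[sel], code = rep(code, sum(sel)),
               date = dates[sel], stringsAsFactors = FALSE)
  }
  events <- rbind(
    ev_block(seropos, "M05", ra_date),
    ev_block(ra_prev & !seropos, "M06", ra_date),
    ev_block(hem_prev, "C90", hem_prev_date),
    ev_block(hem_inc, "C90", hem_inc_date)
  )
  events <- events[order(events$sample_id, events$date, events$code), ,
                   drop = FALSE]
  rownames(events) <- NULL

  truth_variants <- do.call(rbind, lapply(carriers, function(i) {
    data.frame(sample_id = sample_id[i], gene = genes[[i]],
               true_vaf = vafs[[i]], stringsAsFactors = FALSE)
  }))
  if (is.null(truth_variants)) {
    truth_variants <- data.frame(sample_id = character(0), gene = character(0),
                                 true_vaf = numeric(0))
  }
  truth <- list(
    participants = data.frame(
      sample_id, chip = chip,
      genes = vapply(genes, function(g) paste(g, collapse = ","), ""),
      max_vaf = vapply(vafs, function(v) if (length(v)) max(v) else NA_real_, 0),
      ra_prevalent = ra_prev, seropositive = seropos,
      stringsAsFactors = FALSE),
    truth_variants = truth_variants
  )
  structure(list(records = records, events = events, truth = truth,
                 config = config), class = "sim_cohort")
}

# one clean read-evidence draw conditioned on passing the read-support
# rules (depth/alt minima, both strands both alleles) and, in panel mode,
# the observed-VAF window; conditioning keeps planted truth recoverable
.draw_reads <- function(true_vaf, coverage, mode, max_tries = 200L) {
  min_depth <- if (mode == "panel") 100L else 10L
  for (t in seq_len(max_tries)) {
    dp <- stats::rpois(1L, coverage)
    if (dp < min_depth) next
    ad <- stats::rbinom(1L, dp, true_vaf)
    if (ad < 2L || dp - ad < 2L) next
    af <- stats::rbinom(1L, ad, 0.5); rf <- stats::rbinom(1L, dp - ad, 0.5)
    if (min(af, ad - af) < 1L || min(rf, dp - ad - rf) < 1L) next
    vaf <- ad / dp
    if (mode == "panel" && (vaf < 0.02 || vaf > 0.40)) next
    if (mode == "lymphoid" && (vaf < 0.02 || vaf > 0.35)) next
    return(list(total_depth = dp, alt_depth = ad, alt_fwd = af,
                alt_rev = ad - af, ref_fwd = rf, ref_rev = dp - ad - rf))
  }
  # extremely unlikely fallback: deterministic balanced counts
  dp <- max(min_depth, 4L); ad <- max(2L, round(dp * true_vaf))
  list(total_depth = dp, alt_depth = ad, alt_fwd = ad %/% 2L,
       alt_rev = ad - ad %/% 2L, ref_fwd = (dp - ad) %/% 2L,
       ref_rev = (dp - ad) - (dp - ad) %/% 2L)
}

.variant_row <- function(sample_id, gene, true_vaf, reads,
                         chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
                         consequence = "missense",
                         protein_change = NA_character_,
                         splice_distance_bp = NA_integer_,
                         caller_label = "PASS", somatic_quality = 20,
                         germline_quality = 1, gnomad = 0,
                         cosmic_count = 0L, reported_lchip = FALSE,
                         reported_all = FALSE) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene,
             protein_change = protein_change, consequence = consequence,
             splice_distance_bp = splice_distance_bp,
             caller_label = caller_label, somatic_quality = somatic_quality,
             germline_quality = germline_quality,
             total_depth = reads$total_depth, alt_depth = reads$alt_depth,
             ref_fwd = reads$ref_fwd, ref_rev = reads$ref_rev,
             alt_fwd = reads$alt_fwd, alt_rev = reads$alt_rev,
             gnomad_max_pop_af = gnomad, cosmic_count = cosmic_count,
             reported_lchip = reported_lchip, reported_all = reported_all,
             true_vaf = true_vaf, stringsAsFactors = FALSE)
}

#' Generate an annotated variant table with planted rule violations
#'
#' Emits one clean, fully passing variant row per true variant in the
#' cohort truth (depth Poisson around the mode's coverage, alternate reads
#' binomial at the true VAF, strand splits binomial 1/2 — redrawn until
#' the read-support rules are met, so planted truth is always detectable),
#' plus, when `plant_decoys` is on, one decoy per enabled rule that
#' violates *exactly that rule* (recorded in the returned truth table).
#' Decoys are assigned to the first cohort samples deterministically.
#'
#' @param cohort A `"sim_cohort"` from [generate_cohort()].
#' @param mode `"wes"`, `"lymphoid"`, or `"panel"`; selects coverage,
#'   clean-VAF window, and the decoy set.
#' @param plant_decoys Logical (default `TRUE`).
#' @param clean Logical (default `TRUE`): emit the clean set; switch off
#'   for a decoys-only fixture.
#' @return List: `variants` (annotated variant table), `truth` (one row
#'   per emitted variant: `sample_id`, `chrom`, `pos`, `alt`, `clean`,
#'   `violates` — the rule id a decoy was planted to break).
#' @export
generate_variant_table <- function(cohort, mode = c("wes", "lymphoid", "panel"),
                                   plant_decoys = TRUE, clean = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  mode <- match.arg(mode)
  config <- cohort$config
  set.seed(config$seed + 1L)
  coverage <- if (mode == "panel") config$coverage_panel else config$coverage_wes
  n_samples <- config$n_participants
  all_ids <- cohort$records$sample_id

  lymphoid_genes <- example_panel("lymphoid")$genes
  rows <- list(); truth <- list()
  add <- function(row, clean_flag, violates = NA_character_) {
    k <- length(rows) + 1L
    rows[[k]] <<- row
    truth[[k]] <<- data.frame(sample_id = row$sample_id, chrom = row$chrom,
                              pos = row$pos, alt = row$alt, clean = clean_flag,
                              violates = violates, stringsAsFactors = FALSE)
  }

  if (clean) {
    tv <- cohort$truth$truth_variants
    pos_counter <- 10000L
    for (i in seq_len(nrow(tv))) {
      v <- tv[i, ]
      true_vaf <- v$true_vaf
      gene <- v$gene
      if (mode == "lymphoid") {
        gene <- lymphoid_genes[1L + (i %% length(lymphoid_genes))]
        true_vaf <- min(true_vaf, 0.33)
      }
      if (mode == "panel") true_vaf <- min(max(true_vaf, 0.035), 0.36)
      if (gene == "other") gene <- "PPM1D"
      pos_counter <- pos_counter + 100L
      reads <- .draw_reads(true_vaf, coverage, mode)
      add(.variant_row(v$sample_id, gene, true_vaf, reads, pos = pos_counter,
                       cosmic_count = if (mode == "lymphoid") 5L else 0L),
          clean_flag = TRUE)
    }
  }

  if (plant_decoys) {
    host <- function(k) all_ids[1L + ((k - 1L) %% length(all_ids))]
    dp_ok <- function(vaf = 0.15) .draw_reads(vaf, coverage, mode)
    base_pos <- 900000L
    if (mode %in% c("wes", "lymphoid")) {
      g <- if (mode == "lymphoid") "STAT3" else "TET2"
      cc <- if (mode == "lymphoid") 5L else 0L
      mk <- function(k, ...) {
        .variant_row(host(k), g, 0.15, dp_ok(), pos = base_pos + 50L * k,
                     cosmic_count = cc, ...)
      }
      r2 <- mk(1); r2$gnomad_max_pop_af <- 0.002; add(r2, FALSE, "R2")
      r3 <- mk(2); r3$caller_label <- "LowQual"; add(r3, FALSE, "R3")
      r4 <- mk(3); r4$somatic_quality <- 2; add(r4, FALSE, "R4")
      r5 <- mk(4); r5$germline_quality <- 15; add(r5, FALSE, "R5")
      r6 <- mk(5)
      r6[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")] <- list(9L, 2L, 3L, 4L, 1L, 1L)
      add(r6, FALSE, "R6")
      r7 <- mk(6)
      r7[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")] <- list(30L, 4L, 13L, 13L, 4L, 0L)
      add(r7, FALSE, "R7")
      r8 <- mk(7); r8$consequence <- "splice"; r8$splice_distance_bp <- 3L
      add(r8, FALSE, "R8")
      # frameshift allele planted in > 0.05% of samples
      n_fs <- max(2L, ceiling(0.002 * n_samples))
      for (j in seq_len(n_fs)) {
        r9 <- .variant_row(all_ids[j], g, 0.12, dp_ok(0.12),
                           pos = base_pos + 1000L, ref = "AT", alt = "A",
                           consequence = "frameshift", cosmic_count = cc)
        add(r9, FALSE, "R9")
      }
      # frameshift cluster: winner (clean) + loser within 5 bp; only planted
      # alongside the clean set, because the loser fails FS5BP only when the
      # winner is present. Fixed read counts so the observed-VAF ordering
      # always matches the plant.
      if (clean) {
      wk <- .variant_row(host(8), g, 0.12, list(total_depth = 50L,
                                                alt_depth = 6L, alt_fwd = 3L,
                                                alt_rev = 3L, ref_fwd = 22L,
                                                ref_rev = 22L),
                         pos = base_pos + 2000L, ref = "GA", alt = "G",
                         consequence = "frameshift", cosmic_count = cc)
      ls <- .variant_row(host(8), g, 0.04, list(total_depth = 50L,
                                                alt_depth = 2L, alt_fwd = 1L,
                                                alt_rev = 1L, ref_fwd = 24L,
                                                ref_rev = 24L),
                         pos = base_pos + 2003L, ref = "TC", alt = "T",
                         consequence = "frameshift", cosmic_count = cc)
      add(wk, TRUE); add(ls, FALSE, "FS5BP")
      }
      if (mode == "lymphoid") {
        l1 <- mk(9)  # fixed counts so the observed VAF (0.40) surely breaks L1
        l1[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
             "alt_fwd", "alt_rev")] <- list(50L, 20L, 15L, 15L, 10L, 10L)
        add(l1, FALSE, "L1")
        l2 <- mk(10); l2$cosmic_count <- 0L
        l2$reported_lchip <- FALSE; l2$reported_all <- FALSE
        add(l2, FALSE, "L2")
      }
    } else { # panel decoys
      mk <- function(k, vaf = 0.15) {
        .variant_row(host(k), "DNMT3A", vaf, dp_ok(vaf),
                     pos = base_pos + 50L * k)
      }
      p1 <- mk(1); p1$caller_label <- "LowQual"; add(p1, FALSE, "P1")
      p2 <- mk(2); p2$gnomad_max_pop_af <- 0.002; add(p2, FALSE, "P2")
      n_rec <- max(2L, ceiling(0.02 * n_samples))
      for (j in seq_len(n_rec)) {
        p3 <- .variant_row(all_ids[j], "DNMT3A", 0.15, dp_ok(0.15),
                           pos = base_pos + 1000L)
        add(p3, FALSE, "P3")
      }
      p4 <- mk(3)
      p4[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")] <- list(99L, 15L, 42L, 42L, 8L, 7L)
      add(p4, FALSE, "P4")
      p6 <- mk(4)
      p6[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")] <- list(200L, 82L, 59L, 59L, 41L, 41L)
      add(p6, FALSE, "P6")  # vaf 0.41
      p7 <- mk(5)
      p7[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")] <- list(200L, 20L, 90L, 90L, 20L, 0L)
      add(p7, FALSE, "P7")
      p8 <- mk(6)
      p8[c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")] <- list(1000L, 19L, 490L, 491L, 10L, 9L)
      add(p8, FALSE, "P8")  # vaf 0.019
    }
  }

  variants <- if (length(rows)) do.call(rbind, rows) else
    .variant_row(character(0), character(0), numeric(0),
                 list(total_depth = integer(0), alt_depth = integer(0),
                      ref_fwd = integer(0), ref_rev = integer(0),
                      alt_fwd = integer(0), alt_rev = integer(0)))[0, ]
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), alt = character(0), clean = logical(0),
               violates = character(0), stringsAsFactors = FALSE)
  rownames(variants) <- rownames(truth) <- NULL
  list(variants = variants, truth = truth)
}

#' Simulate two-channel array intensities at one hotspot locus
#'
#' Non-carriers draw theta from a Gaussian at the reference-cluster center;
#' a carrier with sequencing VAF v (clone fraction 2v, autosomal
#' heterozygous) draws theta from a Gaussian displaced by v, so the
#' relative BAF concentrates near the VAF. Total intensity is log-normal
#' and split into channels as `y = theta * s`, `x = (1 - theta) * s`.
#' Theta is clipped to \[0, 1\].
#'
#' @param n Number of samples at the locus.
#' @param carrier_vaf Numeric vector of true VAFs for the carriers (length
#'   0 for a carrier-free locus); carriers occupy the first
#'   `length(carrier_vaf)` sample slots.
#' @param locus_id Locus label.
#' @param config A [sim_config()] supplying `theta_center`, `theta_sd`,
#'   and the intensity-strength model.
#' @param seed Integer seed.
#' @return data.frame: `sample_id`, `locus_id`, `x_raw`, `y_raw`, `theta`,
#'   `true_carrier`, `true_vaf`.
#' @export
simulate_locus_intensities <- function(n, carrier_vaf = numeric(0),
                                       locus_id = "L1",
                                       config = sim_config(), seed = 1) {
  stopifnot(length(carrier_vaf) <= n, all(carrier_vaf >= 0 & carrier_vaf <= 0.5))
  set.seed(seed)
  k <- length(carrier_vaf)
  mu <- rep(config$theta_center, n)
  if (k > 0) mu[seq_len(k)] <- config$theta_center + carrier_vaf
  theta <- pmin(pmax(stats::rnorm(n, mu, config$theta_sd), 0), 1)
  s <- stats::rlnorm(n, config$intensity_meanlog, config$intensity_sdlog)
  data.frame(sample_id = sprintf("A%05d", seq_len(n)), locus_id = locus_id,
             x_raw = (1 - theta) * s, y_raw = theta * s, theta = theta,
             true_carrier = seq_len(n) <= k,
             true_vaf = c(carrier_vaf, rep(0, n - k)),
             stringsAsFactors = FALSE)
}

#' Simulate array intensities for a cohort across hotspot loci
#'
#' For each locus, cohort participants whose true CHIP gene matches the
#' locus gene are planted as carriers at their true VAF; everyone else is
#' a non-carrier draw.
#'
#' @param cohort A `"sim_cohort"`.
#' @param loci data.frame with `locus_id` and `gene` (plus any reference
#'   columns carried through).
#' @return data.frame of per-sample, per-locus intensities with truth
#'   columns as in [simulate_locus_intensities()].
#' @export
generate_array_intensities <- function(cohort, loci) {
  stopifnot(inherits(cohort, "sim_cohort"))
  config <- cohort$config
  set.seed(config$seed + 2L)
  tv <- cohort$truth$truth_variants
  n <- nrow(cohort$records)
  out <- lapply(seq_len(nrow(loci)), function(j) {
    g <- loci$gene[j]
    car <- tv[tv$gene == g, , drop = FALSE]
    mu <- rep(config$theta_center, n)
    vaf <- numeric(n)
    idx <- match(car$sample_id, cohort$records$sample_id)
    vaf[idx] <- pmax(vaf[idx], car$true_vaf)
    mu <- config$theta_center + vaf
    theta <- pmin(pmax(stats::rnorm(n, mu, config$theta_sd), 0), 1)
    s <- stats::rlnorm(n, config$intensity_meanlog, config$intensity_sdlog)
    data.frame(sample_id = cohort$records$sample_id,
               locus_id = loci$locus_id[j],
               x_raw = (1 - theta) * s, y_raw = theta * s, theta = theta,
               true_carrier = vaf > 0, true_vaf = vaf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate an exponential survival cohort with a known hazard ratio
#'
#' A minimal generator for hazard-ratio parameter-recovery studies:
#' exposure is Bernoulli, survival is exponential with the baseline rate
#' chosen so that the unexposed event probability within the follow-up
#' horizon equals `event_rate`, and follow-up is administratively censored
#' at `followup_years`. Default exposure prevalence 0.22 mirrors the CHIP
#' carrier fraction observed in newly diagnosed RA patients.
#'
#' @param n Cohort size.
#' @param hr True hazard ratio for the exposed.
#' @param exposure_prev Exposure prevalence.
#' @param event_rate Unexposed event probability within follow-up.
#' @param followup_years Administrative censoring horizon.
#' @param seed Integer seed.
#' @return data.frame: `exposure` (0/1), `time` (years), `status`.
#' @export
simulate_survival_cohort <- function(n, hr = 1.92, exposure_prev = 0.22,
                                     event_rate = 0.30, followup_years = 15,
                                     seed = 1) {
  stopifnot(hr > 0, event_rate > 0, event_rate < 1)
  set.seed(seed)
  exposure <- as.integer(stats::runif(n) < exposure_prev)
  lambda0 <- -log(1 - event_rate) / followup_years
  t <- stats::rexp(n, rate = lambda0 * hr^exposure)
  status <- as.integer(t <= followup_years)
  data.frame(exposure = exposure, time = pmin(t, followup_years),
             status = status)
}
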