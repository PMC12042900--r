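#' Threshold parameters for the WES CHIP filtering cascade
#'
#' All numeric thresholds of the exome-mode rule set in one place, so that
#' tests can probe monotonicity and alternative pipelines can tighten or
#' relax individual rules. Defaults are the published cascade:
#' population AF at most 0.1% (hotspots exempt), caller label `"PASS"`,
#' somatic quality at least 3, germline quality below 10, at least 10 reads
#' of which at least 2 support the alternate allele, at least one read per
#' strand per allele, splice variants within 2 bp of the intron-exon
#' boundary, and frameshift alleles carried by at most 0.05% of cohort
#' samples (strictly more fails).
#'
#' No VAF floor is applied in WES mode by default; `vaf_floor` can switch
#' one on (it is always on in panel mode).
#'
#' @param max_gnomad_af Maximum gnomAD population AF (R2).
#' @param min_somatic_quality Minimum somatic quality score (R4).
#' @param max_germline_quality Germline quality must be strictly below this (R5).
#' @param min_total_depth,min_alt_depth Read-support minima (R6).
#' @param min_strand_reads Minimum reads per strand per allele (R7).
#' @param max_splice_distance_bp Maximum distance from the intron-exon
#'   boundary for splice consequences (R8).
#' @param max_frameshift_cohort_freq Frameshift alleles carried by strictly
#'   more than this fraction of samples fail (R9).
#' @param vaf_floor Optional minimum VAF; `NULL` disables (WES default).
#' @return A list of class `"chip_rule_params"`.
#' @export
chip_rule_params <- function(max_gnomad_af = 0.001,
                             min_somatic_quality = 3,
                             max_germline_quality = 10,
                             min_total_depth = 10,
                             min_alt_depth = 2,
                             min_strand_reads = 1,
                             max_splice_distance_bp = 2,
                             max_frameshift_cohort_freq = 0.0005,
                             vaf_floor = NULL) {
  structure(as.list(environment()), class = "chip_rule_params")
}

#' Threshold parameters for the targeted-panel CHIP filter
#'
#' Defaults follow the published deep-panel rules: `"PASS"` label, gnomAD
#' population AF at most 0.1%, cohort allele frequency at most 1% of
#' samples, at least 100 total reads and 2 alternate reads, VAF at most
#' 40% (above is treated as likely germline) and at least 2% (the CHIP
#' definition floor), and the per-strand read-support rule.
#'
#' @param max_gnomad_af Maximum gnomAD population AF (P2).
#' @param max_cohort_freq Alleles in strictly more than this fraction of
#'   cohort samples fail (P3).
#' @param min_total_depth,min_alt_depth Read-support minima (P4, P5).
#' @param max_vaf,min_vaf VAF ceiling (P6) and floor (P8).
#' @param min_strand_reads Minimum reads per strand per allele (P7).
#' @return A list of class `"panel_rule_params"`.
#' @export
panel_rule_params <- function(max_gnomad_af = 0.001,
                              max_cohort_freq = 0.01,
                              min_total_depth = 100,
                              min_alt_depth = 2,
                              max_vaf = 0.40,
                              min_vaf = 0.02,
                              min_strand_reads = 1) {
  structure(as.list(environment()), class = "panel_rule_params")
}

#' Threshold parameters for the lymphoid driver filter
#'
#' Applied on top of the WES cascade: VAF restricted to \[2%, 35%\], and
#' missense variants additionally require prior somatic evidence (reported
#' at least `min_cosmic_count` times in COSMIC, or reported in a lymphoid
#' clonal-hematopoiesis or acute lymphoblastic leukemia driver catalog).
#' Non-missense consequences are exempt from the evidence rule.
#'
#' @param min_vaf,max_vaf VAF window (L1).
#' @param min_cosmic_count COSMIC report count satisfying L2.
#' @return A list of class `"lymphoid_rule_params"`.
#' @export
lymphoid_rule_params <- function(min_vaf = 0.02, max_vaf = 0.35,
                                 min_cosmic_count = 3) {
  structure(as.list(environment()), class = "lymphoid_rule_params")
}

.decision_frame <- function(variants, failed) {
  stopifnot(length(failed) == nrow(variants))
  out <- variants
  class(out) <- "data.frame"
  out$failed_rules <- vapply(failed, paste, "", collapse = ";")
  out$verdict <- ifelse(out$failed_rules == "", "pass", "fail")
  class(out) <- c("filter_decisions", "data.frame")
  out
}

# Per-row list of failed WES rule ids (R1..R9).
.chip_rule_failures <- function(v, panel, fs_freq, params) {
  n <- nrow(v)
  exempt <- is_hotspot_exempt(v$gene, v$protein_change, panel)
  fail <- list(
    R1 = !(v$gene %in% panel$genes),
    R2 = v$gnomad_max_pop_af > params$max_gnomad_af & !exempt,
    R3 = v$caller_label != "PASS",
    R4 = v$somatic_quality < params$min_somatic_quality,
    R5 = v$germline_quality >= params$max_germline_quality,
    R6 = v$total_depth < params$min_total_depth |
      v$alt_depth < params$min_alt_depth,
    R7 = pmin(v$ref_fwd, v$ref_rev) < params$min_strand_reads |
      pmin(v$alt_fwd, v$alt_rev) < params$min_strand_reads,
    # splice variants with unknown boundary distance fail conservatively
    R8 = v$consequence == "splice" &
      (is.na(v$splice_distance_bp) |
         v$splice_distance_bp > params$max_splice_distance_bp),
    R9 = v$consequence == "frameshift" &
      fs_freq > params$max_frameshift_cohort_freq
  )
  if (!is.null(params$vaf_floor)) {
    fail$RV <- v$vaf < params$vaf_floor
  }
  ids <- names(fail)
  m <- do.call(cbind, fail)
  lapply(seq_len(n), function(i) ids[m[i, ]])
}

#' Evaluate the WES CHIP rules on a variant table
#'
#' Applies the exome-mode rule cascade (R1-R9, see [chip_rule_params()]) to
#' every row and reports *all* failed rules per variant, not just the first,
#' so that per-rule behaviour can be audited. Rules are conjunctive: a
#' variant passes iff no rule fails.
#'
#' Rule ids: R1 gene in panel; R2 gnomAD population AF (hotspot-exempt);
#' R3 caller `"PASS"`; R4 somatic quality; R5 germline quality; R6 depth /
#' alt-read support; R7 per-strand support for both alleles; R8 splice
#' distance; R9 cohort frameshift frequency.
#'
#' @param variants Annotated variant table (see [variant-table]); validated
#'   internally.
#' @param panel A [gene_panel()].
#' @param cohort_frameshift_freq Numeric vector (recycled if length 1): for
#'   each row, the fraction of cohort samples carrying that frameshift
#'   allele; 0 for non-frameshifts. [filter_chip_wes()] computes this for you.
#' @param params [chip_rule_params()].
#' @return A `data.frame` of class `"filter_decisions"`: the input rows plus
#'   `verdict` (`"pass"`/`"fail"`) and `failed_rules` (semicolon-joined ids,
#'   empty iff pass).
#' @export
evaluate_chip_rules <- function(variants, panel,
                                cohort_frameshift_freq = 0,
                                params = chip_rule_params()) {
  v <- validate_variants(variants)
  stopifnot(inherits(panel, "gene_panel"))
  fs <- rep_len(cohort_frameshift_freq, nrow(v))
  .decision_frame(v, .chip_rule_failures(v, panel, fs, params))
}

#' Collapse nearby frameshift calls into their highest-VAF representative
#'
#' Frameshift indels called within 5 bp of each other are usually alternate
#' alignments of the same event; within each sample and chromosome,
#' frameshift variants are grouped by transitive closure of the pairwise
#' distance rule (|pos_i - pos_j| <= `max_gap_bp`) and only the member with
#' the highest VAF is retained. Ties are broken by smaller position, then
#' lexicographically smaller alternate allele. Non-frameshift variants pass
#' through untouched.
#'
#' @param variants Variant table restricted to one sample (enforced).
#' @param max_gap_bp Maximum pairwise distance for clustering (default 5).
#' @return The variant table with cluster losers removed, original row
#'   order preserved.
#' @export
collapse_frameshift_clusters <- function(variants, max_gap_bp = 5) {
  v <- validate_variants(variants)
  if (nrow(v) == 0L) return(v)
  if (length(unique(v$sample_id)) > 1L) {
    stop("collapse_frameshift_clusters expects variants from one sample; ",
         "use filter_chip_wes() for multi-sample tables", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(v))
  is_fs <- v$consequence == "frameshift"
  for (ch in unique(v$chrom[is_fs])) {
    idx <- which(is_fs & v$chrom == ch)
    if (length(idx) < 2L) next
    ord <- idx[order(v$pos[idx])]
    # transitive closure on sorted positions = chain on consecutive gaps
    gap_new <- c(TRUE, diff(v$pos[ord]) > max_gap_bp)
    cluster <- cumsum(gap_new)
    for (cl in unique(cluster)) {
      members <- ord[cluster == cl]
      if (length(members) < 2L) next
      o <- members[order(-v$vaf[members], v$pos[members], v$alt[members])]
      keep[o[-1L]] <- FALSE
    }
  }
  v[keep, , drop = FALSE]
}

# Fraction of cohort samples carrying each row's allele. The carrier count
# is over all rows sharing the allele key; `frameshift_only` restricts
# which rows *receive* a frequency (WES R9 applies only to frameshifts;
# panel P3 applies to every allele).
.cohort_allele_freq <- function(v, n_samples, frameshift_only = TRUE) {
  freq <- numeric(nrow(v))
  rows <- if (frameshift_only) which(v$consequence == "frameshift") else seq_len(nrow(v))
  if (length(rows) == 0L) return(freq)
  key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")
  counts <- tapply(v$sample_id, key, function(s) length(unique(s)))
  freq[rows] <- as.numeric(counts[key[rows]]) / n_samples
  freq
}

.check_n_samples <- function(v, n_samples) {
  n_seen <- length(unique(v$sample_id))
  if (n_samples < n_seen) {
    stop("n_samples (", n_samples, ") is smaller than the number of ",
         "distinct sample ids in the table (", n_seen, ")", call. = FALSE)
  }
}

# Mark cluster losers among passing rows with rule id FS5BP.
.apply_cluster_collapse <- function(decisions, max_gap_bp = 5) {
  pass_idx <- which(decisions$verdict == "pass")
  if (length(pass_idx) == 0L) return(decisions)
  survivors <- decisions[pass_idx, , drop = FALSE]
  class(survivors) <- "data.frame"
  kept_keys <- character(0)
  for (s in unique(survivors$sample_id)) {
    sub <- survivors[survivors$sample_id == s, , drop = FALSE]
    kept <- collapse_frameshift_clusters(sub, max_gap_bp = max_gap_bp)
    kept_keys <- c(kept_keys,
                   paste(kept$sample_id, kept$chrom, kept$pos, kept$alt,
                         sep = "\r"))
  }
  key <- paste(decisions$sample_id, decisions$chrom, decisions$pos,
               decisions$alt, sep = "\r")
  lost <- decisions$verdict == "pass" & !(key %in% kept_keys)
  decisions$verdict[lost] <- "fail"
  decisions$failed_rules[lost] <- "FS5BP"
  decisions
}

#' Full WES CHIP filtering cascade
#'
#' Computes cohort frameshift frequencies (numerator: distinct samples
#' carrying the allele; denominator: `n_samples`), applies the R1-R9 rule
#' set via [evaluate_chip_rules()], collapses 5-bp frameshift clusters per
#' sample among the survivors (losers are marked failed with rule id
#' `FS5BP`), and builds per-sample carrier profiles. Deterministic for a
#' fixed input; row order does not affect the verdict set.
#'
#' @inheritParams evaluate_chip_rules
#' @param n_samples Number of samples in the cohort run (must be at least
#'   the number of distinct `sample_id`s in the table); denominates cohort
#'   allele frequencies.
#' @param samples Optional character vector of all cohort sample ids
#'   (including variant-free samples) for which carrier profiles should be
#'   emitted; defaults to the ids present in the table.
#' @param params [chip_rule_params()].
#' @return A list with elements `decisions` (`"filter_decisions"`) and
#'   `profiles` (see [build_carrier_profiles()]).
#' @export
filter_chip_wes <- function(variants, panel, n_samples,
                            samples = NULL,
                            params = chip_rule_params()) {
  v <- validate_variants(variants)
  .check_n_samples(v, n_samples)
  fs <- .cohort_allele_freq(v, n_samples, frameshift_only = TRUE)
  decisions <- evaluate_chip_rules(v, panel, fs, params)
  decisions <- .apply_cluster_collapse(decisions)
  if (is.null(samples)) samples <- sort(unique(v$sample_id))
  profiles <- build_carrier_profiles(decisions, samples)
  list(decisions = decisions, profiles = profiles)
}

#' Lymphoid driver variant filter
#'
#' Applies the full WES cascade (R1-R9 plus the 5-bp frameshift-cluster
#' collapse) and two additional rules: `L1`, VAF within the
#' \[`min_vaf`, `max_vaf`\] window (default 2-35%; higher VAFs in lymphoid
#' genes are likely germline, lower ones undetectable); and `L2`, missense
#' variants must carry prior somatic evidence (COSMIC count at or above the
#' threshold, or reported as a lymphoid clonal-hematopoiesis or ALL
#' driver). Non-missense consequences are exempt from `L2`.
#'
#' @inheritParams filter_chip_wes
#' @param panel The lymphoid candidate [gene_panel()].
#' @param lymphoid_params [lymphoid_rule_params()].
#' @return A `"filter_decisions"` data.frame.
#' @export
filter_lymphoid_wes <- function(variants, panel,
                                n_samples = NULL,
                                params = chip_rule_params(),
                                lymphoid_params = lymphoid_rule_params()) {
  v <- validate_variants(variants)
  if (is.null(n_samples)) n_samples <- length(unique(v$sample_id))
  .check_n_samples(v, n_samples)
  fs <- .cohort_allele_freq(v, n_samples, frameshift_only = TRUE)
  failed <- .chip_rule_failures(v, panel, fs, params)
  lp <- lymphoid_params
  l1 <- v$vaf < lp$min_vaf | v$vaf > lp$max_vaf
  l2 <- v$consequence == "missense" &
    !(v$cosmic_count >= lp$min_cosmic_count | v$reported_lchip | v$reported_all)
  for (i in seq_len(nrow(v))) {
    if (l1[i]) failed[[i]] <- c(failed[[i]], "L1")
    if (l2[i]) failed[[i]] <- c(failed[[i]], "L2")
  }
  decisions <- .decision_frame(v, failed)
  .apply_cluster_collapse(decisions)
}

#' Targeted-panel CHIP filter
#'
#' Deep-coverage panel mode. Rule ids: P1 caller `"PASS"`; P2 gnomAD
#' population AF at most 0.1%; P3 allele carried by at most 1% of cohort
#' samples (counted over *all* variants, not only frameshifts); P4 at least
#' 100 total reads; P5 at least 2 alternate reads; P6 VAF at most 40%;
#' P7 per-strand support for both alleles; P8 VAF at least 2%. No gene or
#' hotspot rule: the assay design restricts variants to the panel.
#'
#' @inheritParams filter_chip_wes
#' @param panel The targeted [gene_panel()] (recorded in the run, not used
#'   as a filter: panel capture already restricts the genes).
#' @param params [panel_rule_params()].
#' @return As [filter_chip_wes()]: list of `decisions` and `profiles`.
#' @export
filter_chip_panel <- function(variants, panel, n_samples,
                              samples = NULL,
                              params = panel_rule_params()) {
  v <- validate_variants(variants)
  .check_n_samples(v, n_samples)
  freq <- .cohort_allele_freq(v, n_samples, frameshift_only = FALSE)
  fail <- list(
    P1 = v$caller_label != "PASS",
    P2 = v$gnomad_max_pop_af > params$max_gnomad_af,
    P3 = freq > params$max_cohort_freq,
    P4 = v$total_depth < params$min_total_depth,
    P5 = v$alt_depth < params$min_alt_depth,
    P6 = v$vaf > params$max_vaf,
    P7 = pmin(v$ref_fwd, v$ref_rev) < params$min_strand_reads |
      pmin(v$alt_fwd, v$alt_rev) < params$min_strand_reads,
    P8 = v$vaf < params$min_vaf
  )
  ids <- names(fail)
  m <- do.call(cbind, fail)
  failed <- lapply(seq_len(nrow(v)), function(i) ids[m[i, ]])
  decisions <- .decision_frame(v, failed)
  if (is.null(samples)) samples <- sort(unique(v$sample_id))
  profiles <- build_carrier_profiles(decisions, samples)
  list(decisions = decisions, profiles = profiles)
}

#' Build per-sample carrier profiles from filter decisions
#'
#' Summarizes passing variants into one row per cohort sample: carrier
#' status, number of variants, maximum VAF, the clone-size stratum used in
#' the association analyses (`"lt10"` when the maximum VAF is below 10%,
#' `"ge10"` otherwise, `NA` for non-carriers), and gene-group flags
#' (`DNMT3A`, `TET2`, `JAK2`, `non_DNMT3A`, `non_DNMT3A_non_JAK2` — the
#' last two true when the sample carries any passing variant outside the
#' named genes).
#'
#' @param decisions A `"filter_decisions"` data.frame.
#' @param samples Character vector of all cohort sample ids, including
#'   non-carriers.
#' @return A `data.frame` of class `"carrier_profiles"`, one row per entry
#'   of `samples`.
#' @export
build_carrier_profiles <- function(decisions, samples) {
  stopifnot(inherits(decisions, "filter_decisions"))
  samples <- as.character(samples)
  pass <- decisions[decisions$verdict == "pass", , drop = FALSE]
  key <- paste(pass$sample_id, pass$chrom, pass$pos, pass$alt, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate passing rows for the same (sample, chrom, pos, alt); ",
         "input is malformed (multi-allelic rows must be decomposed)",
         call. = FALSE)
  }
  unknown <- setdiff(unique(pass$sample_id), samples)
  if (length(unknown) > 0L) {
    stop("passing variants reference sample id(s) absent from `samples`: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    sample_id = samples,
    carrier = FALSE, n_variants = 0L, max_vaf = NA_real_,
    vaf_stratum = NA_character_,
    DNMT3A = FALSE, TET2 = FALSE, JAK2 = FALSE,
    non_DNMT3A = FALSE, non_DNMT3A_non_JAK2 = FALSE,
    stringsAsFactors = FALSE
  )
  if (nrow(pass) > 0L) {
    sp <- split(seq_len(nrow(pass)), pass$sample_id)
    for (s in names(sp)) {
      i <- match(s, out$sample_id)
      rows <- sp[[s]]
      genes <- pass$gene[rows]
      out$carrier[i] <- TRUE
      out$n_variants[i] <- length(rows)
      out$max_vaf[i] <- max(pass$vaf[rows])
      out$vaf_stratum[i] <- if (out$max_vaf[i] < 0.10) "lt10" else "ge10"
      out$DNMT3A[i] <- "DNMT3A" %in% genes
      out$TET2[i] <- "TET2" %in% genes
      out$JAK2[i] <- "JAK2" %in% genes
      out$non_DNMT3A[i] <- any(genes != "DNMT3A")
      out$non_DNMT3A_non_JAK2[i] <- any(!genes %in% c("DNMT3A", "JAK2"))
    }
  }
  class(out) <- c("carrier_profiles", "data.frame")
  out
}
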