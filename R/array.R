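#' SNP-array hotspot CHIP detection
#'
#' Somatic CHIP hotspot variants (e.g. JAK2 V617F, DNMT3A R882H) displace a
#' carrier's B-allele signal away from the homozygous-reference cluster on a
#' genotyping array: a clone of cell fraction c at an autosomal heterozygous
#' somatic variant shifts theta = y/(x+y) by roughly the VAF = c/2. This
#' module automates what has traditionally been manual inspection of
#' intensity plots: it fits a robust reference cluster per locus, calls
#' carriers as robust-z outliers with a relative-BAF floor, screens loci
#' with prevalence/age/malignancy heuristics, and quantifies concordance
#' against sequencing-derived VAFs.
#'
#' @name array-chip
NULL

#' Theta from two-channel intensities
#'
#' `theta = y_raw / (x_raw + y_raw)`, defined only for positive total
#' intensity; zero-intensity samples get `NA` (they are excluded and
#' counted downstream, never imputed).
#'
#' @param x_raw,y_raw Non-negative A- and B-channel intensities.
#' @return Numeric vector of theta values in \[0, 1\].
#' @export
intensity_theta <- function(x_raw, y_raw) {
  if (any(x_raw < 0 | y_raw < 0, na.rm = TRUE)) {
    stop("raw intensities must be non-negative", call. = FALSE)
  }
  tot <- x_raw + y_raw
  ifelse(is.na(tot) | tot <= 0, NA_real_, y_raw / tot)
}

#' Fit the homozygous-reference cluster at a hotspot locus
#'
#' At a somatic hotspot the vast majority of samples are non-carriers
#' forming a single cluster near theta = 0 (after B-allele orientation), so
#' a robust location/scale fit on all samples recovers the reference
#' cluster: center = median(theta), scale = 1.4826 x MAD(theta), followed
#' by one trimming pass that removes points more than `trim_k` scale units
#' from the center and refits. The scale is floored at `scale_floor` so
#' that degenerate (tie-heavy) loci do not produce infinite z-scores.
#'
#' @param theta Numeric theta values for one locus (`NA` = zero-intensity
#'   samples, excluded and counted).
#' @param min_n Minimum usable samples (default 50).
#' @param scale_floor Lower bound on the reported scale (default 0.005).
#' @param trim_k Trimming threshold in scale units (default 4).
#' @return List of class `"reference_cluster"`: `center`, `scale`,
#'   `n_used`, `n_zero_intensity`, `n_trimmed`.
#' @export
fit_reference_cluster <- function(theta, min_n = 50, scale_floor = 0.005,
                                  trim_k = 4) {
  n_zero <- sum(is.na(theta))
  th <- theta[!is.na(theta)]
  if (length(th) < min_n) {
    stop("reference cluster fit needs at least ", min_n,
         " usable samples; got ", length(th), call. = FALSE)
  }
  center <- stats::median(th)
  scale <- max(stats::mad(th), scale_floor)  # mad() uses constant 1.4826
  keep <- abs(th - center) / scale <= trim_k
  n_trimmed <- sum(!keep)
  if (sum(keep) >= min_n) {
    center <- stats::median(th[keep])
    scale <- max(stats::mad(th[keep]), scale_floor)
  }
  structure(list(center = center, scale = scale, n_used = length(th),
                 n_zero_intensity = n_zero, n_trimmed = n_trimmed),
            class = "reference_cluster")
}

#' Call hotspot carriers as robust outliers from the reference cluster
#'
#' For each sample, `robust_z = (theta - center) / scale` and
#' `relative_baf` = theta minus the cluster center, clamped to \[0, 1\].
#' When the heterozygous-germline cluster center is supplied (a germline
#' SNP at the probe), the relative BAF is rescaled so that the heterozygous
#' cluster maps to 0.5; otherwise the raw offset is used (adequate when the
#' reference cluster sits near theta = 0). A sample is a carrier iff
#' `robust_z >= z_min` *and* `relative_baf >= baf_floor`.
#'
#' Defaults (`z_min = 5`, `baf_floor = 0.05`) were chosen a priori for a
#' per-locus false-positive rate well below 1e-3 under Gaussian-like
#' cluster noise while retaining clones at VAF >= 10%.
#'
#' @param records data.frame with `sample_id` and either `theta` or both
#'   `x_raw`/`y_raw`, all from one locus.
#' @param cluster A `"reference_cluster"` fitted on the same locus.
#' @param z_min Minimum robust z (positive).
#' @param baf_floor Minimum relative BAF (positive).
#' @param het_theta Optional heterozygous-germline cluster center used to
#'   rescale the relative BAF.
#' @return data.frame of class `"array_calls"`: `sample_id`, `theta`,
#'   `robust_z`, `relative_baf`, `carrier`. Zero-intensity samples carry
#'   `NA` theta and `carrier = FALSE`.
#' @export
call_hotspot_carriers <- function(records, cluster, z_min = 5,
                                  baf_floor = 0.05, het_theta = NULL) {
  stopifnot(inherits(cluster, "reference_cluster"))
  if (z_min <= 0 || baf_floor <= 0) {
    stop("z_min and baf_floor must be positive", call. = FALSE)
  }
  theta <- if ("theta" %in% names(records)) records$theta else
    intensity_theta(records$x_raw, records$y_raw)
  z <- (theta - cluster$center) / cluster$scale
  baf <- pmin(pmax(theta - cluster$center, 0), 1)
  if (!is.null(het_theta)) {
    span <- het_theta - cluster$center
    if (span <= 0) stop("het_theta must exceed the cluster center", call. = FALSE)
    baf <- pmin(pmax(baf * (0.5 / span), 0), 1)
  }
  out <- data.frame(
    sample_id = records$sample_id,
    locus_id = if ("locus_id" %in% names(records)) records$locus_id else NA_character_,
    theta = theta, robust_z = z, relative_baf = baf,
    carrier = !is.na(z) & z >= z_min & baf >= baf_floor,
    stringsAsFactors = FALSE
  )
  class(out) <- c("array_calls", "data.frame")
  out
}

#' Locus-qualification decision rule
#'
#' The screening heuristic that separates genuine somatic hotspot loci from
#' noisy probes, expressed on pre-computed summaries. A locus is
#' high-confidence iff its cohort prevalence is less than 10-fold the
#' reference (sequencing-derived) prevalence AND either (a) it shows a
#' positive association with age (p < `age_alpha`) and a positive
#' association with hematologic malignancy (p < `hem_alpha`), or (b) the
#' prevalence ratio is below 2-fold and at least one of the two
#' associations holds. "Positive association" means coefficient > 0 with a
#' two-sided p below the cutoff.
#'
#' @param prevalence_ratio Cohort prevalence over reference prevalence.
#' @param age_beta,age_p Univariate logistic age coefficient and two-sided p.
#' @param hem_beta,hem_p Same for the hematologic-malignancy code.
#' @param max_ratio,relaxed_ratio 10-fold hard cap and 2-fold relaxation.
#' @param age_alpha,hem_alpha Significance cutoffs (0.1 and 0.05).
#' @return List: `high_confidence` (logical) and `reasons` (character).
#' @export
locus_confidence_rule <- function(prevalence_ratio, age_beta, age_p,
                                  hem_beta, hem_p,
                                  max_ratio = 10, relaxed_ratio = 2,
                                  age_alpha = 0.1, hem_alpha = 0.05) {
  reasons <- character(0)
  age_ok <- isTRUE(age_beta > 0 && !is.na(age_p) && age_p < age_alpha)
  hem_ok <- isTRUE(hem_beta > 0 && !is.na(hem_p) && hem_p < hem_alpha)
  if (!is.finite(prevalence_ratio)) {
    return(list(high_confidence = FALSE, reasons = "prevalence ratio undefined"))
  }
  if (prevalence_ratio >= max_ratio) {
    reasons <- c(reasons, sprintf("prevalence ratio %.2f >= %g-fold cap",
                                  prevalence_ratio, max_ratio))
  }
  if (!age_ok) reasons <- c(reasons, "no positive age association")
  if (!hem_ok) reasons <- c(reasons, "no positive hematologic-malignancy association")
  hc <- prevalence_ratio < max_ratio &&
    ((age_ok && hem_ok) ||
       (prevalence_ratio < relaxed_ratio && (age_ok || hem_ok)))
  if (hc) reasons <- character(0)
  list(high_confidence = hc, reasons = reasons)
}

#' Qualify a hotspot locus against reference prevalence and phenotypes
#'
#' Computes the cohort carrier prevalence at the locus, its ratio to the
#' reference (sequencing cohort) prevalence shipped with the locus
#' definition, univariate logistic regressions of carrier status on age
#' and on an any-time hematologic-malignancy indicator, and applies
#' [locus_confidence_rule()]. A locus with zero called carriers is flagged
#' as not qualifiable rather than erroring.
#'
#' @param locus List or one-row data.frame with `locus_id`,
#'   `reference_count`, `reference_n` (variant carriers and cohort size in
#'   the reference sequencing data).
#' @param calls `"array_calls"` for this locus.
#' @param phenotypes data.frame with `sample_id`, `age`, and logical
#'   `hem_malignancy`; joined to `calls` on `sample_id`.
#' @param ... Passed to [locus_confidence_rule()].
#' @return One-row data.frame of class `"locus_qualification"` with the
#'   summaries, `high_confidence`, `qualifiable`, and semicolon-joined
#'   `reasons`.
#' @export
qualify_locus <- function(locus, calls, phenotypes, ...) {
  stopifnot(all(c("reference_count", "reference_n") %in% names(locus)))
  if (locus$reference_count < 10) {
    warning("locus ", locus$locus_id, " has fewer than 10 reference variants; ",
            "candidate loci normally require at least 10", call. = FALSE)
  }
  d <- merge(as.data.frame(calls)[, c("sample_id", "carrier")],
             phenotypes[, c("sample_id", "age", "hem_malignancy")],
             by = "sample_id")
  d <- d[order(d$sample_id), , drop = FALSE]  # order-invariance
  n <- nrow(d)
  n_carriers <- sum(d$carrier)
  prev <- n_carriers / n
  ref_prev <- locus$reference_count / locus$reference_n
  ratio <- prev / ref_prev

  res <- data.frame(
    locus_id = as.character(locus$locus_id), n = n, n_carriers = n_carriers,
    cohort_prevalence = prev, prevalence_ratio = ratio,
    age_beta = NA_real_, age_p = NA_real_,
    hem_beta = NA_real_, hem_p = NA_real_,
    qualifiable = n_carriers > 0, high_confidence = FALSE,
    reasons = "", stringsAsFactors = FALSE
  )
  if (n_carriers == 0L) {
    res$reasons <- "no called carriers; locus not qualifiable"
    class(res) <- c("locus_qualification", "data.frame")
    return(res)
  }
  age_fit <- stats::glm(carrier ~ age, family = stats::binomial(), data = d)
  hem_fit <- stats::glm(carrier ~ hem_malignancy, family = stats::binomial(),
                        data = d)
  sa <- summary(age_fit)$coefficients
  res$age_beta <- sa["age", 1]; res$age_p <- sa["age", 4]
  sh <- summary(hem_fit)$coefficients
  if (nrow(sh) >= 2) { res$hem_beta <- sh[2, 1]; res$hem_p <- sh[2, 4] }
  rule <- locus_confidence_rule(ratio, res$age_beta, res$age_p,
                                res$hem_beta, res$hem_p, ...)
  res$high_confidence <- rule$high_confidence
  res$reasons <- paste(rule$reasons, collapse = "; ")
  class(res) <- c("locus_qualification", "data.frame")
  res
}

#' Concordance between array calls and sequencing truth
#'
#' Given array calls and a sequencing truth set of (sample, locus, VAF)
#' carriers, reports per-bin detection sensitivity (default bins: VAF below
#' vs at/above 10%) and, among truth carriers with a usable array signal,
#' an ordinary least-squares regression of the array relative BAF on the
#' sequencing VAF (slope, intercept, Wald two-sided p for the slope).
#'
#' @param array_calls `"array_calls"` (possibly several loci).
#' @param seq_truth data.frame with `sample_id`, `locus_id`, `vaf` in \[0,1\].
#' @param bin_edges VAF bin edges (default `c(0, 0.10, 1)`).
#' @return List of class `"concordance_report"`: `sensitivity` data.frame
#'   (bin, n_truth, n_detected, sensitivity) and `regression` (slope,
#'   intercept, slope_p, r_squared, n) or `NULL` when inestimable; `empty`
#'   flags an empty truth set.
#' @export
concordance_analysis <- function(array_calls, seq_truth,
                                 bin_edges = c(0, 0.10, 1)) {
  if (nrow(seq_truth) == 0L) {
    return(structure(list(sensitivity = NULL, regression = NULL, empty = TRUE),
                     class = "concordance_report"))
  }
  if (any(seq_truth$vaf < 0 | seq_truth$vaf > 1)) {
    stop("truth VAFs must lie in [0, 1]", call. = FALSE)
  }
  key <- function(d) paste(d$sample_id, d$locus_id, sep = "\r")
  calls <- as.data.frame(array_calls)
  m <- match(key(seq_truth), key(calls))
  detected <- !is.na(m) & calls$carrier[m]
  baf <- ifelse(is.na(m), NA_real_, calls$relative_baf[m])

  bins <- cut(seq_truth$vaf, breaks = bin_edges, include.lowest = TRUE,
              right = FALSE)
  sens <- do.call(rbind, lapply(levels(bins), function(b) {
    idx <- which(bins == b)
    data.frame(bin = b, n_truth = length(idx), n_detected = sum(detected[idx]),
               sensitivity = if (length(idx)) mean(detected[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  reg <- NULL
  ok <- !is.na(baf)
  if (sum(ok) >= 3L) {
    fit <- stats::lm(baf[ok] ~ seq_truth$vaf[ok])
    sm <- summary(fit)
    reg <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                slope_p = sm$coefficients[2, 4],
                r_squared = sm$r.squared, n = sum(ok))
  }
  structure(list(sensitivity = sens, regression = reg, empty = FALSE),
            class = "concordance_report")
}
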