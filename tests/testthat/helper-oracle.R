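# Independent brute-force oracles. These deliberately re-derive every rule
# in the plainest possible form, separately from the package code paths.

# failed rule ids for ONE variant row (a one-row data.frame with vaf set)
oracle_wes_rules <- function(row, panel, fs_freq) {
  failed <- character(0)
  exempt <- FALSE
  ex <- panel$hotspot_exemptions
  if (nrow(ex) > 0 && !is.na(row$protein_change)) {
    for (i in seq_len(nrow(ex))) {
      if (row$gene != ex$gene[i]) next
      ch <- ex$change[i]
      if (identical(row$protein_change, ch)) exempt <- TRUE
      if (grepl("^[A-Z]\\d+$", ch) &&
          grepl(paste0("^", ch, "[^0-9]"), row$protein_change)) exempt <- TRUE
    }
  }
  if (!(row$gene %in% panel$genes)) failed <- c(failed, "R1")
  if (row$gnomad_max_pop_af > 0.001 && !exempt) failed <- c(failed, "R2")
  if (row$caller_label != "PASS") failed <- c(failed, "R3")
  if (row$somatic_quality < 3) failed <- c(failed, "R4")
  if (row$germline_quality >= 10) failed <- c(failed, "R5")
  if (row$total_depth < 10 || row$alt_depth < 2) failed <- c(failed, "R6")
  if (min(row$ref_fwd, row$ref_rev) < 1 || min(row$alt_fwd, row$alt_rev) < 1)
    failed <- c(failed, "R7")
  if (row$consequence == "splice" &&
      (is.na(row$splice_distance_bp) || row$splice_distance_bp > 2))
    failed <- c(failed, "R8")
  if (row$consequence == "frameshift" && fs_freq > 0.0005)
    failed <- c(failed, "R9")
  failed
}

oracle_lymphoid_rules <- function(row, panel, fs_freq) {
  failed <- oracle_wes_rules(row, panel, fs_freq)
  if (row$vaf < 0.02 || row$vaf > 0.35) failed <- c(failed, "L1")
  if (row$consequence == "missense" &&
      !(row$cosmic_count >= 3 || row$reported_lchip || row$reported_all))
    failed <- c(failed, "L2")
  failed
}

oracle_panel_rules <- function(row, freq) {
  failed <- character(0)
  if (row$caller_label != "PASS") failed <- c(failed, "P1")
  if (row$gnomad_max_pop_af > 0.001) failed <- c(failed, "P2")
  if (freq > 0.01) failed <- c(failed, "P3")
  if (row$total_depth < 100) failed <- c(failed, "P4")
  if (row$alt_depth < 2) failed <- c(failed, "P5")
  if (row$vaf > 0.40) failed <- c(failed, "P6")
  if (min(row$ref_fwd, row$ref_rev) < 1 || min(row$alt_fwd, row$alt_rev) < 1)
    failed <- c(failed, "P7")
  if (row$vaf < 0.02) failed <- c(failed, "P8")
  failed
}

# fraction of distinct samples carrying each row's allele
oracle_allele_freq <- function(tbl, n_samples, frameshift_only = TRUE) {
  vapply(seq_len(nrow(tbl)), function(i) {
    if (frameshift_only && tbl$consequence[i] != "frameshift") return(0)
    same <- tbl$chrom == tbl$chrom[i] & tbl$pos == tbl$pos[i] &
      tbl$ref == tbl$ref[i] & tbl$alt == tbl$alt[i]
    length(unique(tbl$sample_id[same])) / n_samples
  }, 0)
}

# brute-force transitive clustering of frameshifts within one sample:
# repeated neighbourhood expansion, keep the highest-VAF member
# (ties: smaller pos, then smaller alt)
oracle_collapse <- function(tbl, max_gap = 5) {
  keep <- rep(TRUE, nrow(tbl))
  for (ch in unique(tbl$chrom)) {
    idx <- which(tbl$consequence == "frameshift" & tbl$chrom == ch)
    if (length(idx) < 2) next
    assigned <- rep(NA_integer_, length(idx))
    comp <- 0
    for (k in seq_along(idx)) {
      if (!is.na(assigned[k])) next
      comp <- comp + 1
      members <- k
      repeat {
        grew <- FALSE
        for (j in seq_along(idx)) {
          if (j %in% members) next
          if (any(abs(tbl$pos[idx[j]] - tbl$pos[idx[members]]) <= max_gap)) {
            members <- c(members, j); grew <- TRUE
          }
        }
        if (!grew) break
      }
      assigned[members] <- comp
    }
    for (cmp in unique(assigned)) {
      m <- idx[assigned == cmp]
      if (length(m) < 2) next
      best <- m[order(-tbl$vaf[m], tbl$pos[m], tbl$alt[m])][1]
      keep[setdiff(m, best)] <- FALSE
    }
  }
  tbl[keep, , drop = FALSE]
}

# the full oracle cascade: per-rule intersection then per-sample collapse;
# returns the set of passing keys
oracle_pass_keys <- function(tbl, panel, n_samples,
                             mode = c("wes", "lymphoid", "panel")) {
  mode <- match.arg(mode)
  tbl$vaf <- ifelse(tbl$total_depth > 0, tbl$alt_depth / tbl$total_depth, 0)
  freq <- oracle_allele_freq(tbl, n_samples,
                             frameshift_only = mode != "panel")
  pass <- vapply(seq_len(nrow(tbl)), function(i) {
    f <- switch(mode,
                wes = oracle_wes_rules(tbl[i, ], panel, freq[i]),
                lymphoid = oracle_lymphoid_rules(tbl[i, ], panel, freq[i]),
                panel = oracle_panel_rules(tbl[i, ], freq[i]))
    length(f) == 0
  }, TRUE)
  surv <- tbl[pass, , drop = FALSE]
  if (mode != "panel" && nrow(surv) > 0) {
    surv <- do.call(rbind, lapply(split(surv, surv$sample_id),
                                  oracle_collapse))
  }
  paste(surv$sample_id, surv$chrom, surv$pos, surv$alt)
}

# Fisher two-sided p by hypergeometric enumeration of all tables with the
# observed margins (probability ordering, as in fisher.test)
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

decision_keys <- function(decisions, verdict = "pass") {
  d <- decisions[decisions$verdict == verdict, , drop = FALSE]
  paste(d$sample_id, d$chrom, d$pos, d$alt)
}
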