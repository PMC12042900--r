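# Fixture builders shared across test files.

# a fully passing variant row; override any field
make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 1000L,
                         ref = "A", alt = "G", gene = "TET2",
                         protein_change = NA_character_,
                         consequence = "missense",
                         splice_distance_bp = NA_integer_,
                         caller_label = "PASS", somatic_quality = 20,
                         germline_quality = 1,
                         total_depth = 40L, alt_depth = 8L,
                         ref_fwd = 16L, ref_rev = 16L,
                         alt_fwd = 4L, alt_rev = 4L,
                         gnomad_max_pop_af = 0, cosmic_count = 0L,
                         reported_lchip = FALSE, reported_all = FALSE) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene,
             protein_change = protein_change, consequence = consequence,
             splice_distance_bp = splice_distance_bp,
             caller_label = caller_label, somatic_quality = somatic_quality,
             germline_quality = germline_quality,
             total_depth = as.integer(total_depth),
             alt_depth = as.integer(alt_depth),
             ref_fwd = as.integer(ref_fwd), ref_rev = as.integer(ref_rev),
             alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
             gnomad_max_pop_af = gnomad_max_pop_af,
             cosmic_count = as.integer(cosmic_count),
             reported_lchip = reported_lchip, reported_all = reported_all,
             stringsAsFactors = FALSE)
}

# randomized variant table that straddles every rule boundary; invariants
# (strand sums, count bounds, unique keys per sample) hold by construction
random_variant_table <- function(n, panel, seed, panel_mode = FALSE) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    dp <- sample(if (panel_mode) 60:220 else 5:60, 1)
    ad <- min(dp - 2L, stats::rbinom(1, dp, stats::runif(1, 0.01, 0.6)))
    af <- stats::rbinom(1, ad, 0.5)
    rf <- stats::rbinom(1, dp - ad, 0.5)
    cons <- sample(c("missense", "nonsense", "frameshift", "splice",
                     "synonymous"), 1,
                   prob = c(0.35, 0.1, 0.3, 0.15, 0.1))
    make_variant(
      sample_id = sprintf("S%03d", sample(1:40, 1)),
      pos = sample(1:400, 1) * 3L,  # coarse grid so 5-bp clusters occur
      gene = sample(c(panel$genes[1:10], "NOTAGENE"), 1,
                    prob = c(rep(0.095, 10), 0.05)),
      protein_change = sample(c(NA, "V617F", "R882H", "A123T"), 1),
      consequence = cons,
      splice_distance_bp = if (cons == "splice") sample(0:5, 1) else NA,
      caller_label = sample(c("PASS", "LowQual"), 1, prob = c(0.85, 0.15)),
      somatic_quality = stats::runif(1, 0, 30),
      germline_quality = stats::runif(1, 0, 20),
      total_depth = dp, alt_depth = ad,
      ref_fwd = rf, ref_rev = dp - ad - rf, alt_fwd = af, alt_rev = ad - af,
      gnomad_max_pop_af = sample(c(0, 0.0005, 0.002, 0.01), 1,
                                 prob = c(0.6, 0.2, 0.15, 0.05)),
      cosmic_count = sample(0:5, 1),
      reported_lchip = stats::runif(1) < 0.2,
      reported_all = stats::runif(1) < 0.1
    )
  })
  tbl <- do.call(rbind, rows)
  # de-duplicate (sample, chrom, pos, alt) keys by nudging positions
  key <- paste(tbl$sample_id, tbl$chrom, tbl$pos, tbl$alt)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    tbl$pos[dup] <- tbl$pos[dup] + 1L
    key <- paste(tbl$sample_id, tbl$chrom, tbl$pos, tbl$alt)
  }
  tbl
}

# minimal phenotype records for survival/endpoint tests
make_records <- function(n, seed = 1, base = as.Date("2000-01-01")) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("P%03d", seq_len(n)),
    age = stats::runif(n, 25, 74),
    sex = sample(c("male", "female"), n, replace = TRUE),
    smoking_ever = stats::runif(n) < 0.5,
    sampling_date = base,
    censor_date = base + round(20 * 365.25),
    death_date = as.Date(NA),
    stringsAsFactors = FALSE
  )
}
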