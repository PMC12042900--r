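#' File formats
#'
#' TSV is the canonical interchange dialect: the working unit of the
#' pipeline is the annotated variant row, not the raw VCF record, so every
#' table round-trips through plain TSV with documented headers. VCF v4.2
#' is supported as an optional input path for variant tables (via the
#' VariantAnnotation package when installed). All coordinates are 1-based
#' inclusive. All outputs are plain text.
#'
#' @name formats
NULL

#' Write / read a pipeline TSV
#'
#' Tab-separated, header row, no quoting of numerics, `NA` for missing;
#' logical columns serialize as `TRUE`/`FALSE`. Reading preserves column
#' types well enough that a write-read cycle reproduces the table.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `read_tsv()`: a data.frame.
#' @export
write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(x)) if (inherits(x[[col]], "Date")) {
    x[[col]] <- format(x[[col]], "%Y-%m-%d")
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

.parse_dates <- function(df, cols) {
  for (col in intersect(cols, names(df))) df[[col]] <- as.Date(df[[col]])
  df
}

#' Read an annotated variant table
#'
#' `dialect = "tsv"` expects exactly the [variant-table] columns. `dialect
#' = "vcf"` reads a VCF v4.2 via VariantAnnotation, decomposes
#' multi-allelic records to biallelic rows, takes `total_depth`/`alt_depth`
#' from the `DP` and `AD` FORMAT fields, the four strand counts from the
#' FORMAT field named by `field_map$strand_counts` (four comma-separated
#' values: ref fwd/rev, alt fwd/rev; site-level counts are apportioned to
#' decomposed alleles proportionally so the AD depths are preserved), and
#' the remaining annotations from the INFO fields named in `field_map`. A missing mapped field is a hard
#' error naming the field; a row failing type coercion is rejected with
#' its line number.
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param field_map For VCF input, a named list mapping the logical fields
#'   `gene`, `consequence`, `somatic_quality`, `germline_quality`,
#'   `gnomad_max_pop_af`, and optionally `protein_change`,
#'   `splice_distance_bp`, `cosmic_count` to INFO keys, plus
#'   `strand_counts` to a FORMAT key. Defaults to same-named uppercase
#'   keys (`GENE`, `CONSEQUENCE`, `SQ`, `GQ`, `GNOMAD_AF`, `PCHANGE`,
#'   `SPLICE_DIST`, `COSMIC_CNT`, `SB`).
#' @return A validated [variant-table].
#' @export
read_variants <- function(path, dialect = c("tsv", "vcf"), field_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- read_tsv(path)
    for (col in c("total_depth", "alt_depth", "ref_fwd", "ref_rev",
                  "alt_fwd", "alt_rev", "pos")) {
      if (col %in% names(df) && !is.numeric(df[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
        stop("column '", col, "' fails numeric coercion at data line ",
             bad, call. = FALSE)
      }
    }
    return(validate_variants(df))
  }
  read_variants_vcf(path, field_map)
}

read_variants_vcf <- function(path, field_map = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("VCF input requires the VariantAnnotation package", call. = FALSE)
  }
  fm <- utils::modifyList(
    list(gene = "GENE", consequence = "CONSEQUENCE",
         somatic_quality = "SQ", germline_quality = "GQ",
         gnomad_max_pop_af = "GNOMAD_AF", protein_change = "PCHANGE",
         splice_distance_bp = "SPLICE_DIST", cosmic_count = "COSMIC_CNT",
         strand_counts = "SB"),
    field_map %||% list())
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)  # decompose multi-allelics
  info <- VariantAnnotation::info(vcf)
  need_info <- c("gene", "consequence", "somatic_quality",
                 "germline_quality", "gnomad_max_pop_af")
  for (f in need_info) {
    if (!fm[[f]] %in% names(info)) {
      stop("VCF is missing mapped INFO field '", fm[[f]], "' (", f, ")",
           call. = FALSE)
    }
  }
  geno <- VariantAnnotation::geno(vcf)
  for (f in c("DP", "AD", fm$strand_counts)) {
    if (!f %in% names(geno)) {
      stop("VCF is missing mapped FORMAT field '", f, "'", call. = FALSE)
    }
  }
  samples <- colnames(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  get_info <- function(f, default = NULL) {
    if (fm[[f]] %in% names(info)) unlist(info[[fm[[f]]]]) else default
  }
  rows <- list()
  # site-level strand counts (ref fwd/rev, alt fwd/rev) are apportioned to
  # each decomposed allele proportionally, preserving the AD depths
  split_strand <- function(depth, fwd, rev) {
    tot <- fwd + rev
    f <- ifelse(tot > 0, round(depth * fwd / tot), depth %/% 2L)
    cbind(as.integer(f), as.integer(depth - f))
  }
  for (s in samples) {
    ad <- geno$AD[, s, ]
    if (is.null(dim(ad))) ad <- matrix(ad, ncol = 2)
    sb <- geno[[fm$strand_counts]][, s, ]
    if (is.null(dim(sb))) sb <- matrix(sb, ncol = 4)
    ref_sp <- split_strand(ad[, 1], sb[, 1], sb[, 2])
    alt_sp <- split_strand(ad[, 2], sb[, 3], sb[, 4])
    rows[[s]] <- data.frame(
      sample_id = s,
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(VariantAnnotation::ref(vcf)),
      alt = as.character(VariantAnnotation::alt(vcf)),
      gene = get_info("gene"),
      protein_change = get_info("protein_change", NA_character_),
      consequence = get_info("consequence"),
      splice_distance_bp = get_info("splice_distance_bp", NA_integer_),
      caller_label = vapply(VariantAnnotation::filt(vcf), as.character, ""),
      somatic_quality = as.numeric(get_info("somatic_quality")),
      germline_quality = as.numeric(get_info("germline_quality")),
      total_depth = as.integer(geno$DP[, s]),
      alt_depth = as.integer(ad[, 2]),
      ref_fwd = ref_sp[, 1], ref_rev = ref_sp[, 2],
      alt_fwd = alt_sp[, 1], alt_rev = alt_sp[, 2],
      gnomad_max_pop_af = as.numeric(get_info("gnomad_max_pop_af")),
      cosmic_count = as.integer(get_info("cosmic_count", 0L)),
      stringsAsFactors = FALSE
    )
  }
  validate_variants(do.call(rbind, rows))
}

#' Read a gene panel TSV
#'
#' Two columns: `gene` and optional `change` (empty or `NA` for plain
#' panel membership; a value declares a hotspot exemption at that gene).
#'
#' @param path TSV path.
#' @param name Panel name (default: file stem).
#' @return A [gene_panel()].
#' @export
read_panel <- function(path, name = NULL) {
  df <- read_tsv(path)
  stopifnot("gene" %in% names(df))
  if (!"change" %in% names(df)) df$change <- NA_character_
  ex <- df[!is.na(df$change) & df$change != "", c("gene", "change")]
  gene_panel(name %||% sub("\\.[^.]*$", "", basename(path)),
             unique(df$gene), if (nrow(ex)) ex else NULL)
}

#' Read hotspot locus definitions
#'
#' TSV with columns `locus_id`, `gene`, `protein_change`, `chrom`, `pos`,
#' `ref`, `alt`, `reference_count`, `reference_n`.
#' @param path TSV path.
#' @return data.frame of loci.
#' @export
read_loci <- function(path) {
  df <- read_tsv(path)
  need <- c("locus_id", "gene", "reference_count", "reference_n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("locus file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$reference_n <= df$reference_count)) {
    stop("reference_n must exceed reference_count", call. = FALSE)
  }
  df
}

#' Read per-sample, per-locus array intensities
#'
#' TSV with columns `sample_id`, `locus_id`, `x_raw`, `y_raw`; `theta` is
#' recomputed on read.
#' @param path TSV path.
#' @return data.frame with a `theta` column.
#' @export
read_intensities <- function(path) {
  df <- read_tsv(path)
  need <- c("sample_id", "locus_id", "x_raw", "y_raw")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("intensity file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$theta <- intensity_theta(df$x_raw, df$y_raw)
  df
}

#' Read phenotype and registry-event tables
#'
#' Phenotypes: one row per participant with `sample_id`, `sampling_date`
#' and any covariate/date columns (dates in ISO `YYYY-MM-DD`). Events:
#' long format `sample_id`, `code`, `date`.
#' @param path TSV path.
#' @return data.frame with date columns parsed.
#' @export
read_phenotypes <- function(path) {
  .parse_dates(read_tsv(path),
               c("sampling_date", "death_date", "censor_date"))
}

#' @rdname read_phenotypes
#' @export
read_events <- function(path) {
  df <- .parse_dates(read_tsv(path), "date")
  need <- c("sample_id", "code", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("event file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Read an endpoint code map (JSON)
#'
#' A JSON object mapping endpoint names to arrays of codes.
#' @param path JSON path.
#' @return Named list of character vectors.
#' @export
read_code_map <- function(path) {
  cm <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cm, as.character)
}
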