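#' Annotated somatic variant tables
#'
#' The package's canonical working unit is the *annotated variant table*: a
#' `data.frame` with one row per candidate somatic call per sample, carrying
#' the annotations and read evidence that the filtering cascades consume.
#' Coordinates are 1-based inclusive (VCF convention). Multi-allelic records
#' must be decomposed to one alternate allele per row before they reach the
#' table (the VCF reader does this).
#'
#' Required columns:
#' \describe{
#'   \item{sample_id}{character, participant/sample identifier}
#'   \item{chrom, pos, ref, alt}{locus and alleles; `pos` integer >= 1}
#'   \item{gene}{HGNC symbol}
#'   \item{consequence}{one of `r paste0('"', consequence_levels(), '"', collapse = ", ")`}
#'   \item{caller_label}{caller verdict string, e.g. `"PASS"`}
#'   \item{somatic_quality, germline_quality}{numeric caller quality scores,
#'     treated as opaque thresholds}
#'   \item{total_depth, alt_depth}{integer read counts}
#'   \item{ref_fwd, ref_rev, alt_fwd, alt_rev}{strand-resolved read counts}
#'   \item{gnomad_max_pop_af}{maximum population allele frequency in gnomAD,
#'     fraction in \[0, 1\]}
#' }
#'
#' Optional columns (filled with defaults when absent):
#' `protein_change` (e.g. `"V617F"`, used for hotspot exemptions; default
#' `NA`), `splice_distance_bp` (distance to the nearest intron-exon boundary,
#' required for splice consequences; default `NA`), `cosmic_count` (default
#' 0), `reported_lchip`, `reported_all` (defaults `FALSE`).
#'
#' A `vaf` column (`alt_depth / total_depth`) is computed and attached by
#' [validate_variants()].
#'
#' @name variant-table
NULL

#' Allowed variant consequence categories
#' @return Character vector of consequence levels.
#' @export
consequence_levels <- function() {
  c("missense", "nonsense", "frameshift", "inframe_indel",
    "splice", "synonymous", "other")
}

.required_variant_cols <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
  "caller_label", "somatic_quality", "germline_quality",
  "total_depth", "alt_depth", "ref_fwd", "ref_rev", "alt_fwd", "alt_rev",
  "gnomad_max_pop_af"
)

.count_cols <- c("total_depth", "alt_depth",
                 "ref_fwd", "ref_rev", "alt_fwd", "alt_rev")

#' Validate an annotated variant table
#'
#' Checks the schema described in [variant-table], fills optional columns
#' with defaults, coerces count columns to integer, computes `vaf`, and
#' enforces the structural invariants (strand counts summing to `alt_depth`,
#' read counts bounded by `total_depth`, non-negative counts, `pos >= 1`).
#'
#' @param variants data.frame of candidate variants.
#' @return The validated table with a `vaf` column, invisibly classed
#'   `"variant_table"`.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)

  missing_cols <- setdiff(.required_variant_cols, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"protein_change" %in% names(variants)) variants$protein_change <- NA_character_
  if (!"splice_distance_bp" %in% names(variants)) variants$splice_distance_bp <- NA_integer_
  if (!"cosmic_count" %in% names(variants)) variants$cosmic_count <- 0L
  if (!"reported_lchip" %in% names(variants)) variants$reported_lchip <- FALSE
  if (!"reported_all" %in% names(variants)) variants$reported_all <- FALSE
  # stable types even when a column is all-NA (e.g. after a TSV round trip)
  variants$protein_change <- as.character(variants$protein_change)
  variants$splice_distance_bp <- as.integer(variants$splice_distance_bp)
  variants$cosmic_count <- as.integer(variants$cosmic_count)
  variants$reported_lchip <- as.logical(variants$reported_lchip)
  variants$reported_all <- as.logical(variants$reported_all)

  if (nrow(variants) == 0L) {
    variants$vaf <- numeric(0)
    class(variants) <- c("variant_table", class(variants))
    return(variants)
  }

  for (col in .count_cols) {
    v <- variants[[col]]
    if (any(is.na(v))) {
      stop("missing value in read-count column '", col, "' (row ",
           which(is.na(v))[1L], ")", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative value in read-count column '", col, "' (row ",
           which(v < 0)[1L], ")", call. = FALSE)
    }
    variants[[col]] <- as.integer(round(v))
  }
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("pos must be >= 1 (VCF 1-based)", call. = FALSE)

  bad_cons <- setdiff(unique(variants$consequence), consequence_levels())
  if (length(bad_cons) > 0L) {
    stop("unknown consequence value(s): ", paste(bad_cons, collapse = ", "),
         call. = FALSE)
  }
  if (with(variants, any(alt_fwd + alt_rev != alt_depth))) {
    stop("alt_fwd + alt_rev must equal alt_depth", call. = FALSE)
  }
  if (with(variants, any(ref_fwd + ref_rev + alt_fwd + alt_rev > total_depth))) {
    stop("strand-resolved counts exceed total_depth", call. = FALSE)
  }
  af <- variants$gnomad_max_pop_af
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    stop("gnomad_max_pop_af must be a fraction in [0, 1]", call. = FALSE)
  }

  variants$vaf <- ifelse(variants$total_depth > 0,
                         variants$alt_depth / variants$total_depth, 0)
  if (any(variants$vaf > 1)) stop("vaf must lie in [0, 1]", call. = FALSE)

  if (!inherits(variants, "variant_table")) {
    class(variants) <- c("variant_table", class(variants))
  }
  variants
}

#' Define a gene panel
#'
#' A panel is a named, non-empty set of gene symbols plus an optional table
#' of *hotspot exemptions*: (gene, protein change or codon) pairs that are
#' exempt from the population allele-frequency rule. Well-known exemptions
#' are the JAK2 V617F and DNMT3A R882 CHIP hotspots, which are common enough
#' in population databases to exceed a germline-frequency cutoff despite
#' being somatic.
#'
#' A codon-level exemption is written without the alternate amino acid
#' (`"R882"`) and matches any substitution at that codon (R882H, R882C, ...);
#' an exact exemption (`"V617F"`) matches only that protein change.
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols (non-empty, de-duplicated).
#' @param hotspot_exemptions Optional data.frame with columns `gene` and
#'   `change`; every exempted gene must be in `genes`.
#' @return An object of class `"gene_panel"`.
#' @export
gene_panel <- function(name, genes, hotspot_exemptions = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene panel must be non-empty", call. = FALSE)
  if (is.null(hotspot_exemptions)) {
    hotspot_exemptions <- data.frame(gene = character(0), change = character(0),
                                     stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "change") %in% names(hotspot_exemptions)))
  if (!all(hotspot_exemptions$gene %in% genes)) {
    stop("hotspot exemptions must reference genes in the panel", call. = FALSE)
  }
  structure(list(name = name, genes = genes,
                 hotspot_exemptions = hotspot_exemptions),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("<gene_panel> ", x$name, ": ", length(x$genes), " genes, ",
      nrow(x$hotspot_exemptions), " hotspot exemption(s)\n", sep = "")
  invisible(x)
}

# TRUE where (gene, protein_change) is covered by a panel exemption.
# Codon-style exemptions ("R882") prefix-match; full changes match exactly.
is_hotspot_exempt <- function(gene, protein_change, panel) {
  ex <- panel$hotspot_exemptions
  out <- rep(FALSE, length(gene))
  if (nrow(ex) == 0L) return(out)
  for (i in seq_len(nrow(ex))) {
    codon_style <- grepl("^[A-Za-z*][0-9]+$", ex$change[i])
    hit <- gene == ex$gene[i] & !is.na(protein_change) &
      if (codon_style) {
        startsWith(protein_change, ex$change[i]) &
          !grepl(paste0("^", ex$change[i], "[0-9]"), protein_change)
      } else {
        protein_change == ex$change[i]
      }
    out <- out | hit
  }
  out
}

#' Built-in example gene panels
#'
#' Small, synthetic stand-ins for the real candidate-gene tables, which are
#' supplementary material not shipped here: a myeloid CHIP driver panel
#' (with the JAK2 V617F and DNMT3A R882 hotspot exemptions), a lymphoid
#' driver panel, and a targeted NGS panel. Real analyses should load their
#' own panels with [read_panel()].
#'
#' @param which One of `"chip"`, `"lymphoid"`, `"panel"`.
#' @return A [gene_panel()].
#' @export
example_panel <- function(which = c("chip", "lymphoid", "panel")) {
  which <- match.arg(which)
  chip_genes <- c(
    "DNMT3A", "TET2", "ASXL1", "JAK2", "TP53", "SF3B1", "SRSF2", "PPM1D",
    "GNB1", "GNAS", "CBL", "IDH1", "IDH2", "KRAS", "NRAS", "RUNX1",
    "U2AF1", "ZRSR2", "BCOR", "BCORL1", "STAG2", "CTCF", "EZH2", "KIT",
    "MPL", "CALR", "CSF3R", "SETBP1", "PHF6", "WT1", "NPM1", "FLT3"
  )
  lymphoid_genes <- c(
    "STAT3", "STAT5B", "ATM", "KMT2D", "CARD11", "NOTCH1", "MYD88",
    "CREBBP", "TNFRSF14", "TNFAIP3", "B2M", "CCND3", "ID3", "TCF3",
    "IKZF1", "PAX5", "ETV6", "EP300", "ARID1A", "CXCR4", "PLCG2",
    "BTK", "SETD2", "FBXW7", "PTEN", "NT5C2", "KLHL6", "POT1"
  )
  switch(which,
    chip = gene_panel(
      "chip_example", chip_genes,
      hotspot_exemptions = data.frame(
        gene = c("JAK2", "DNMT3A"),
        change = c("V617F", "R882"),
        stringsAsFactors = FALSE
      )
    ),
    lymphoid = gene_panel("lymphoid_example", lymphoid_genes),
    panel = gene_panel("targeted_example", chip_genes)
  )
}
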