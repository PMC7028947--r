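#' @keywords internal
"_PACKAGE"

# Consequence classes recognised throughout the package.  A variant table is a
# plain data.frame with one row per somatic call; see read_variant_table() for
# the on-disk schema.
consequence_levels <- function() {
  c("missense", "nonsense", "frameshift_indel", "inframe_indel",
    "splice_site", "synonymous", "other")
}

lof_consequences <- function() c("nonsense", "frameshift_indel", "splice_site")

# Consequences counted towards the SNV count (exonic non-synonymous,
# including indels and splice-site changes).
snv_count_consequences <- function() {
  c("missense", "nonsense", "frameshift_indel", "inframe_indel", "splice_site")
}

#' Validate a variant table
#'
#' Checks the column set and the basic invariants of an in-memory variant
#' table (ref != alt, positions >= 1, population allele frequencies in
#' \[0, 1\], trinucleotide contexts of length 3 whose middle base matches the
#' reference base on the pyrimidine strand).
#'
#' @param variants data.frame of variant calls.
#' @return The input, invisibly, after checking.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  required <- c("patient_id", "gene", "consequence")
  missing <- setdiff(required, names(variants))
  if (length(missing) > 0)
    stop("variant table is missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(variants$consequence), consequence_levels())
  if (length(bad) > 0)
    stop("unknown consequence values: ", paste(bad, collapse = ", "))
  if (!is.null(variants$pos) && any(variants$pos < 1, na.rm = TRUE))
    stop("positions must be >= 1")
  if (!is.null(variants$ref) && !is.null(variants$alt)) {
    same <- !is.na(variants$ref) & !is.na(variants$alt) &
      variants$ref == variants$alt
    if (any(same)) stop("ref and alt alleles must differ")
  }
  af <- variants$population_af
  if (!is.null(af) && any(af < 0 | af > 1, na.rm = TRUE))
    stop("population_af must lie in [0, 1]")
  ctx <- variants$trinucleotide_context
  if (!is.null(ctx)) {
    has <- !is.na(ctx) & nzchar(ctx)
    if (any(nchar(ctx[has]) != 3))
      stop("trinucleotide_context must have length 3")
  }
  invisible(variants)
}

#' Remove putative germline variants
#'
#' Variants observed above a population allele-frequency threshold (default
#' 0.1%) in a germline population database are treated as likely germline and
#' removed.  Variants with no frequency annotation are retained: the filter
#' applies only to observed frequencies, and absence of population evidence is
#' not evidence of germline origin.
#'
#' @param variants data.frame of variant calls with an optional
#'   `population_af` column.
#' @param af_threshold exclusion threshold on the population allele fraction,
#'   in (0, 1).  Default `0.001`.
#' @return The retained rows, in input order.
#' @export
filter_putative_germline <- function(variants, af_threshold = 0.001) {
  stopifnot(is.numeric(af_threshold), length(af_threshold) == 1,
            af_threshold > 0, af_threshold < 1)
  af <- variants$population_af
  if (is.null(af)) return(variants)
  keep <- is.na(af) | af <= af_threshold
  variants[keep, , drop = FALSE]
}

#' Loss-of-function call
#'
#' A variant is loss-of-function when its consequence is a nonsense mutation,
#' a frameshift indel, or a splice-site alteration.
#'
#' @param consequence character vector of consequence classes.
#' @return logical vector.
#' @export
is_loss_of_function <- function(consequence) {
  consequence %in% lof_consequences()
}

#' Deleteriousness call
#'
#' All loss-of-function variants are deleterious.  A missense variant is
#' deleterious when called "damaging" by SIFT and/or "probably damaging" by
#' PolyPhen-2 (inclusive OR).
#'
#' @param consequence character vector of consequence classes.
#' @param sift_call character: "damaging", "tolerated" or "unknown".
#' @param polyphen_call character: "probably_damaging", "possibly_damaging",
#'   "benign" or "unknown".
#' @return logical vector.
#' @export
is_deleterious <- function(consequence,
                           sift_call = "unknown",
                           polyphen_call = "unknown") {
  sift_call <- ifelse(is.na(sift_call), "unknown", sift_call)
  polyphen_call <- ifelse(is.na(polyphen_call), "unknown", polyphen_call)
  is_loss_of_function(consequence) |
    (consequence == "missense" &
       (sift_call == "damaging" | polyphen_call == "probably_damaging"))
}

#' DDR alteration calls
#'
#' Two criteria for calling a variant a significant DNA damage repair (DDR)
#' gene alteration.  The inclusive criterion accepts any deleterious variant
#' (loss-of-function, or missense judged significant by SIFT and/or
#' PolyPhen-2) in a DDR gene.  The restrictive criterion accepts
#' loss-of-function variants, missense variants recurrently catalogued
#' (COSMIC count >= 5, OncoKB, or a hotspot catalogue), and any ERCC2
#' missense variant within or near the conserved helicase domains.
#'
#' @param variants data.frame of variant calls (columns `gene`,
#'   `consequence`, and the functional/catalogue annotation columns used by
#'   each criterion; absent columns are treated as all-unknown / all-false).
#' @param annotations gene annotation data.frame from
#'   [read_gene_annotation()] / [default_ddr_genes()], with columns `gene`
#'   and `ddr_pathway`.
#' @return logical vector, one element per variant row.
#' @export
ddr_alteration_inclusive <- function(variants, annotations) {
  ann <- match_annotation(variants$gene, annotations)
  ann$is_ddr & is_deleterious(variants$consequence,
                              col_or(variants, "sift_call", "unknown"),
                              col_or(variants, "polyphen_call", "unknown"))
}

#' @rdname ddr_alteration_inclusive
#' @export
ddr_alteration_restrictive <- function(variants, annotations) {
  ann <- match_annotation(variants$gene, annotations)
  cosmic <- col_or(variants, "cosmic_count", 0L)
  cosmic[is.na(cosmic)] <- 0L
  oncokb <- isTRUE_vec(col_or(variants, "in_oncokb", FALSE))
  hotspot <- isTRUE_vec(col_or(variants, "in_hotspot_catalog", FALSE))
  helicase <- isTRUE_vec(col_or(variants, "in_helicase_domain", FALSE))
  missense <- variants$consequence == "missense"
  catalogued <- missense & (cosmic >= 5 | oncokb | hotspot)
  ercc2_hel <- variants$gene == "ERCC2" & missense & helicase
  ann$is_ddr & (is_loss_of_function(variants$consequence) | catalogued | ercc2_hel)
}

# Vectorised column fetch with a scalar default when the column is absent.
col_or <- function(df, name, default) {
  if (is.null(df[[name]])) rep(default, nrow(df)) else df[[name]]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

match_annotation <- function(genes, annotations) {
  idx <- match(genes, annotations$gene)
  if (anyNA(idx)) {
    orphan <- unique(genes[is.na(idx)])
    stop("no gene annotation for: ", paste(orphan, collapse = ", "))
  }
  data.frame(gene = genes,
             is_ddr = annotations$ddr_pathway[idx] != "none",
             ddr_pathway = annotations$ddr_pathway[idx],
             stringsAsFactors = FALSE)
}

#' SNV count (panel tumour mutational burden)
#'
#' The number of exonic non-synonymous variants for one patient: missense,
#' nonsense, frameshift and in-frame indels, and splice-site alterations.
#' Synonymous and unclassified variants are excluded.  The putative-germline
#' filter is expected to have been applied already.
#'
#' @param variants data.frame of variant calls for a single patient.
#' @return a non-negative integer.
#' @export
snv_count <- function(variants) {
  if (nrow(variants) == 0) return(0L)
  if (length(unique(variants$patient_id)) > 1)
    stop("snv_count expects variants from a single patient; got ",
         length(unique(variants$patient_id)), " patient_ids")
  sum(variants$consequence %in% snv_count_consequences())
}

#' Per-pathway DDR alteration flags
#'
#' For each DDR pathway present in the annotation table, reports whether at
#' least one variant qualifies as a DDR alteration under the selected
#' criterion in a gene of that pathway; an `any_ddr` flag covers all
#' pathways.
#'
#' @param variants data.frame of variant calls (any number of patients; flags
#'   are pooled — group by patient upstream for per-patient flags).
#' @param annotations gene annotation data.frame.
#' @param mode `"inclusive"` or `"restrictive"`.
#' @return named logical vector: one entry per pathway plus `any_ddr`.
#' @export
pathway_flags <- function(variants, annotations,
                          mode = c("inclusive", "restrictive")) {
  mode <- match.arg(mode)
  pathways <- setdiff(unique(annotations$ddr_pathway), "none")
  flags <- stats::setNames(rep(FALSE, length(pathways)), pathways)
  if (nrow(variants) > 0) {
    hit <- if (mode == "inclusive") ddr_alteration_inclusive(variants, annotations)
           else ddr_alteration_restrictive(variants, annotations)
    idx <- match(variants$gene, annotations$gene)
    pw <- annotations$ddr_pathway[idx]
    for (p in pathways) flags[[p]] <- any(hit & pw == p)
  }
  c(flags, any_ddr = any(flags))
}

#' Restrict a variant table to a gene whitelist
#'
#' Optional filter mirroring a panel-intersection gene set (for example the
#' genes common to all versions of a capture panel); applied before counting.
#'
#' @param variants variant data.frame.
#' @param whitelist character vector of HUGO symbols, or `NULL` for no
#'   filtering.
#' @return the retained rows, in input order.
#' @export
apply_gene_whitelist <- function(variants, whitelist = NULL) {
  if (is.null(whitelist)) return(variants)
  variants[variants$gene %in% whitelist, , drop = FALSE]
}
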