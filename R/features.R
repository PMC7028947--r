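#' Dichotomization rule set
#'
#' Thresholds used to turn continuous features into the indicator variables
#' entering association tests and models: NLR >= 5, SNV count >= 10,
#' SNV count >= cohort median (lower median for even cohorts, or pinned),
#' CNV count > 0, ECOG performance status >= 1.
#'
#' @param nlr_cut,snv_cut,cnv_cut,ecog_cut numeric cuts.
#' @param snv_median_cut `NULL` to recompute the cohort median at
#'   dichotomization time, or a pinned value (for example 8).
#' @return a named list of rules.
#' @export
default_ruleset <- function(nlr_cut = 5, snv_cut = 10, snv_median_cut = NULL,
                            cnv_cut = 0, ecog_cut = 1) {
  list(nlr_cut = nlr_cut, snv_cut = snv_cut, snv_median_cut = snv_median_cut,
       cnv_cut = cnv_cut, ecog_cut = ecog_cut)
}

# Lower median: the floor((n+1)/2)-th order statistic, so the cut is an
# achievable data value for even cohorts too.
lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Validate a clinical table
#'
#' @param clinical data.frame with one row per patient; columns
#'   `patient_id`, `arm`, outcome and covariate columns (see
#'   [read_clinical_table()]).
#' @return the input, invisibly.
#' @export
validate_clinical <- function(clinical) {
  stopifnot(is.data.frame(clinical))
  if (!"patient_id" %in% names(clinical))
    stop("clinical table needs a patient_id column")
  if (anyDuplicated(clinical$patient_id))
    stop("duplicated patient_id in clinical table: ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "))
  both <- !is.na(clinical$pfs_months) & !is.na(clinical$os_months)
  if (!is.null(clinical$pfs_months) && !is.null(clinical$os_months) &&
      any(clinical$pfs_months[both] > clinical$os_months[both] + 1e-9))
    stop("pfs_months must not exceed os_months")
  invisible(clinical)
}

#' Assemble the per-patient feature table
#'
#' Combines the clinical table with variant-derived features (SNV count,
#' signature-attributed counts, DDR flags), copy-number features (CNV count,
#' CDKN2A/CDKN2B homozygous-deletion flags) into one row per patient.
#' Patients without genomic rows receive zero counts.  Genomic rows for
#' patients absent from the clinical table are an error.
#'
#' @param clinical clinical data.frame (one row per patient).
#' @param variants variant data.frame (may cover many patients); the
#'   putative-germline filter and optional whitelist are applied here.
#' @param cnv_calls copy-number call data.frame.
#' @param annotations gene annotation (default [default_gene_annotation()]).
#' @param catalog signature catalogue (default
#'   [synthetic_signature_catalog()]).
#' @param af_threshold population-frequency threshold for the germline
#'   filter.
#' @param whitelist optional gene whitelist applied before counting.
#' @return data.frame of features, one row per clinical patient, with a
#'   `"manifest"` attribute recording thresholds and input provenance.
#' @export
build_feature_table <- function(clinical, variants, cnv_calls,
                                annotations = default_gene_annotation(),
                                catalog = synthetic_signature_catalog(),
                                af_threshold = 0.001, whitelist = NULL) {
  validate_clinical(clinical)
  validate_variants(variants)
  validate_cnv_calls(cnv_calls)
  ids <- clinical$patient_id
  orphans <- union(setdiff(unique(variants$patient_id), ids),
                   setdiff(unique(cnv_calls$patient_id), ids))
  if (length(orphans) > 0)
    stop("genomic rows for patients absent from the clinical table: ",
         paste(orphans, collapse = ", "))

  n_before <- nrow(variants)
  variants <- filter_putative_germline(variants, af_threshold)
  n_germline <- n_before - nrow(variants)
  variants <- apply_gene_whitelist(variants, whitelist)

  one_patient <- function(pid) {
    v <- variants[variants$patient_id == pid, , drop = FALSE]
    cn <- cnv_calls[cnv_calls$patient_id == pid, , drop = FALSE]
    proj <- project_signatures(build_spectrum(v), catalog)
    data.frame(
      patient_id = pid,
      snv_count = snv_count(v),
      cnv_count = cnv_count(cn, annotations),
      sig_apobec = unname(proj[["APOBEC"]]),
      sig_ercc2 = unname(proj[["ERCC2"]]),
      sig_ct_cpg = unname(proj[["C_T_CpG"]]),
      cdkn2a_del = gene_homdel_flag(cn, "CDKN2A"),
      cdkn2b_del = gene_homdel_flag(cn, "CDKN2B"),
      ddr_inclusive = nrow(v) > 0 && any(ddr_alteration_inclusive(v, annotations)),
      ddr_restrictive = nrow(v) > 0 && any(ddr_alteration_restrictive(v, annotations)),
      stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, lapply(ids, one_patient))
  out <- merge(clinical, feats, by = "patient_id", sort = FALSE)
  out <- out[match(ids, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "manifest") <- list(
    af_threshold = af_threshold,
    whitelist = whitelist,
    n_variants_in = n_before,
    n_germline_filtered = n_germline,
    signatures = colnames(catalog$profiles),
    n_annotation_genes = nrow(annotations),
    package_version = as.character(utils::packageVersion("icipredict")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  out
}

#' Fill indicator flags on a feature table
#'
#' Adds `nlr_ge5`, `snv_ge10`, `snv_ge_median`, `cnv_gt0` and `ecog_ge1`
#' indicators per the rule set.  All ">= cut" comparisons are inclusive;
#' CNV-high is strictly positive.  Missing source values give missing flags
#' (listwise exclusion is then applied per analysis, not per cohort).
#' Idempotent, and never alters non-flag columns.
#'
#' @param features feature table from [build_feature_table()] (or any
#'   data.frame with the source columns).
#' @param rules rule set from [default_ruleset()].
#' @return the feature table with indicator columns filled.
#' @export
dichotomize <- function(features, rules = default_ruleset()) {
  med <- rules$snv_median_cut
  if (is.null(med)) med <- lower_median(features$snv_count)
  features$nlr_ge5 <- features$nlr >= rules$nlr_cut
  features$snv_ge10 <- features$snv_count >= rules$snv_cut
  features$snv_ge_median <- features$snv_count >= med
  features$cnv_gt0 <- features$cnv_count > rules$cnv_cut
  if (!is.null(features$ecog)) {
    ecog_num <- suppressWarnings(as.numeric(sub("plus$", "", features$ecog)))
    features$ecog_ge1 <- ecog_num >= rules$ecog_cut
  }
  attr(features, "snv_median_cut") <- med
  features
}

#' SNV/CNV joint subset
#'
#' Partitions patients into four subsets by SNV count (high: >= median,
#' default 8) and CNV count (high: > 0).
#'
#' @param snv_count,cnv_count integer vectors.
#' @param snv_median SNV-high cut (inclusive).
#' @return factor with levels `highSNV_lowCNV`, `highSNV_highCNV`,
#'   `lowSNV_lowCNV`, `lowSNV_highCNV`.
#' @export
snv_cnv_subset <- function(snv_count, cnv_count, snv_median = 8) {
  stopifnot(!anyNA(snv_count), !anyNA(cnv_count))
  hi_snv <- snv_count >= snv_median
  hi_cnv <- cnv_count > 0
  lab <- paste0(ifelse(hi_snv, "highSNV", "lowSNV"), "_",
                ifelse(hi_cnv, "highCNV", "lowCNV"))
  factor(lab, levels = c("highSNV_lowCNV", "highSNV_highCNV",
                         "lowSNV_lowCNV", "lowSNV_highCNV"))
}
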