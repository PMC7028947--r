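#' Validate a copy-number call table
#'
#' Gene-level copy-number calls: one row per (patient, gene, call).  Calls
#' are `homozygous_deletion`, `amplification` (copy number > 6) or `other`.
#'
#' @param calls data.frame with columns `patient_id`, `gene`, `call` and
#'   optional `copy_number`.
#' @return the input, invisibly.
#' @export
validate_cnv_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  required <- c("patient_id", "gene", "call")
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0)
    stop("CNV table is missing columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(calls$call),
                 c("homozygous_deletion", "amplification", "other"))
  if (length(bad) > 0)
    stop("unknown CNV call values: ", paste(bad, collapse = ", "))
  cn <- calls$copy_number
  if (!is.null(cn)) {
    amp <- calls$call == "amplification" & !is.na(cn)
    if (any(cn[amp] <= 6))
      stop("amplification calls must have copy_number > 6 when present")
    del <- calls$call == "homozygous_deletion" & !is.na(cn)
    if (any(cn[del] >= 0.5))
      stop("homozygous_deletion calls must have copy_number < 0.5 when present")
  }
  invisible(calls)
}

#' CNV count for one patient
#'
#' The number of gene-level copy-number events, counting only homozygous
#' deletions in tumour-suppressor genes and amplifications (> 6 copies) in
#' proto-oncogenes.  Genes annotated `both` qualify through either event
#' type; genes with role `unknown` never qualify (skipped events raise a
#' warning).  Repeated calls of the same (gene, call) pair count once: the
#' statistic counts gene-level events, not reported segments.
#'
#' @param calls data.frame of copy-number calls for a single patient.
#' @param annotations gene annotation data.frame with columns `gene`,
#'   `role`.
#' @return a non-negative integer.
#' @export
cnv_count <- function(calls, annotations) {
  if (nrow(calls) == 0) return(0L)
  if (length(unique(calls$patient_id)) > 1)
    stop("cnv_count expects calls from a single patient")
  idx <- match(calls$gene, annotations$gene)
  if (anyNA(idx)) {
    orphan <- unique(calls$gene[is.na(idx)])
    stop("no gene annotation for: ", paste(orphan, collapse = ", "))
  }
  role <- annotations$role[idx]
  qualifies <-
    (calls$call == "homozygous_deletion" & role %in% c("tumour_suppressor", "both")) |
    (calls$call == "amplification" & role %in% c("oncogene", "both"))
  skipped <- role == "unknown" & calls$call != "other"
  if (any(skipped))
    warning("skipping ", sum(skipped),
            " CNV event(s) in genes with unknown role: ",
            paste(unique(calls$gene[skipped]), collapse = ", "))
  keep <- calls[qualifies, c("gene", "call"), drop = FALSE]
  nrow(unique(keep))
}

#' Homozygous-deletion flag for a gene
#'
#' @param calls data.frame of copy-number calls for a single patient.
#' @param gene HUGO symbol.
#' @return `TRUE` iff any call for the gene is a homozygous deletion.
#' @export
gene_homdel_flag <- function(calls, gene) {
  if (nrow(calls) == 0) return(FALSE)
  if (length(unique(calls$patient_id)) > 1)
    stop("gene_homdel_flag expects calls from a single patient")
  any(calls$gene == gene & calls$call == "homozygous_deletion")
}
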