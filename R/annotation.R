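#' Read a gene annotation table
#'
#' A gene annotation table assigns each HUGO symbol a role
#' (`tumour_suppressor`, `oncogene`, `both`, `unknown`) and a DNA damage
#' repair pathway (`HR`, `NER`, `MMR`, `BER`, `FA`, `checkpoint`, `other`,
#' or `none` for non-DDR genes).  The copy-number count uses the role; the
#' DDR alteration calls use the pathway.
#'
#' @param path TSV file with columns `gene`, `role`, `ddr_pathway`.
#' @return data.frame with those three columns.
#' @export
read_gene_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "role", "ddr_pathway")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0)
    stop("gene annotation is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(ann$gene))
    stop("duplicated genes in annotation: ",
         paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "))
  bad_role <- setdiff(ann$role, c("tumour_suppressor", "oncogene", "both", "unknown"))
  if (length(bad_role) > 0)
    stop("unknown role values: ", paste(bad_role, collapse = ", "))
  bad_pw <- setdiff(ann$ddr_pathway,
                    c("HR", "NER", "MMR", "BER", "FA", "checkpoint", "other", "none"))
  if (length(bad_pw) > 0)
    stop("unknown ddr_pathway values: ", paste(bad_pw, collapse = ", "))
  ann[required]
}

#' Default gene annotation
#'
#' The package ships an editable default annotation covering 30 DDR genes
#' (with pathway assignments) and common urothelial-carcinoma panel genes
#' with tumour-suppressor / oncogene roles.  This is a documented default
#' drawn from the DDR-gene literature, not a reconstruction of any specific
#' panel's supplementary table; analyses of real cohorts should supply the
#' panel's own table via [read_gene_annotation()].
#'
#' @return data.frame with columns `gene`, `role`, `ddr_pathway`.
#' @export
default_gene_annotation <- function() {
  read_gene_annotation(system.file("extdata", "gene_annotation_default.tsv",
                                   package = "icipredict", mustWork = TRUE))
}

#' @rdname default_gene_annotation
#' @export
default_ddr_genes <- function() {
  ann <- default_gene_annotation()
  ann[ann$ddr_pathway != "none", , drop = FALSE]
}
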