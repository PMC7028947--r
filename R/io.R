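# Readers/writers for the pipeline's table schemas, and the end-to-end
# orchestration (features -> univariable screen -> ALASSO -> multivariable
# with stay criterion -> point score).

maf_class_map <- function() {
  c(Missense_Mutation = "missense", Nonsense_Mutation = "nonsense",
    Frame_Shift_Del = "frameshift_indel", Frame_Shift_Ins = "frameshift_indel",
    In_Frame_Del = "inframe_indel", In_Frame_Ins = "inframe_indel",
    Splice_Site = "splice_site", Silent = "synonymous",
    missense = "missense", nonsense = "nonsense",
    frameshift_indel = "frameshift_indel", inframe_indel = "inframe_indel",
    splice_site = "splice_site", synonymous = "synonymous", other = "other")
}

#' Read a MAF-dialect variant table
#'
#' Required columns: `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Variant_Classification`.  Optional: `ExAC_AF`, `SIFT`, `PolyPhen`,
#' `COSMIC_Count`, `OncoKB`, `Hotspot`, `Context3`, `Helicase_Domain`.
#' Classification synonyms (`Missense_Mutation`, `Silent`, ...) are mapped
#' to the internal consequence classes; unknown strings map to `other`
#' with a warning naming the offending rows.
#'
#' @param path TSV file path.
#' @return variant data.frame in the internal schema (see
#'   [validate_variants()]).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Chromosome",
                "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                "Variant_Classification")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  map <- maf_class_map()
  cons <- unname(map[raw$Variant_Classification])
  unknown <- is.na(cons)
  if (any(unknown)) {
    warning("unknown Variant_Classification mapped to 'other' at row(s): ",
            paste(utils::head(which(unknown), 10), collapse = ", "))
    cons[unknown] <- "other"
  }
  opt <- function(maf_name, default) {
    if (maf_name %in% names(raw)) raw[[maf_name]] else rep(default, nrow(raw))
  }
  out <- data.frame(
    patient_id = as.character(raw$Tumor_Sample_Barcode),
    gene = as.character(raw$Hugo_Symbol),
    chrom = as.character(raw$Chromosome),
    pos = as.integer(raw$Start_Position),
    ref = as.character(raw$Reference_Allele),
    alt = as.character(raw$Tumor_Seq_Allele2),
    consequence = cons,
    population_af = as.numeric(opt("ExAC_AF", NA_real_)),
    sift_call = as.character(opt("SIFT", "unknown")),
    polyphen_call = as.character(opt("PolyPhen", "unknown")),
    cosmic_count = as.integer(opt("COSMIC_Count", 0L)),
    in_oncokb = as.logical(opt("OncoKB", FALSE)),
    in_hotspot_catalog = as.logical(opt("Hotspot", FALSE)),
    trinucleotide_context = as.character(opt("Context3", NA_character_)),
    in_helicase_domain = as.logical(opt("Helicase_Domain", FALSE)),
    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

#' @rdname read_variant_table
#' @param variants variant data.frame in the internal schema.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  out <- data.frame(
    Tumor_Sample_Barcode = variants$patient_id,
    Hugo_Symbol = variants$gene,
    Chromosome = col_or(variants, "chrom", NA_character_),
    Start_Position = col_or(variants, "pos", NA_integer_),
    Reference_Allele = col_or(variants, "ref", NA_character_),
    Tumor_Seq_Allele2 = col_or(variants, "alt", NA_character_),
    Variant_Classification = variants$consequence,
    ExAC_AF = col_or(variants, "population_af", NA_real_),
    SIFT = col_or(variants, "sift_call", "unknown"),
    PolyPhen = col_or(variants, "polyphen_call", "unknown"),
    COSMIC_Count = col_or(variants, "cosmic_count", 0L),
    OncoKB = col_or(variants, "in_oncokb", FALSE),
    Hotspot = col_or(variants, "in_hotspot_catalog", FALSE),
    Context3 = col_or(variants, "trinucleotide_context", NA_character_),
    Helicase_Domain = col_or(variants, "in_helicase_domain", FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the copy-number call table
#'
#' TSV with columns `sample`, `gene`, `call`, `copy_number`.
#'
#' @param path file path.
#' @return CNV data.frame in the internal schema.
#' @export
read_cnv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample", "gene", "call"), names(raw))
  if (length(missing) > 0)
    stop("CNV table is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(patient_id = as.character(raw$sample),
                    gene = as.character(raw$gene),
                    call = as.character(raw$call),
                    copy_number = if ("copy_number" %in% names(raw))
                      as.numeric(raw$copy_number) else NA_real_,
                    stringsAsFactors = FALSE)
  validate_cnv_calls(out)
  out
}

#' @rdname read_cnv_table
#' @param calls CNV data.frame.
#' @export
write_cnv_table <- function(calls, path) {
  validate_cnv_calls(calls)
  out <- data.frame(sample = calls$patient_id, gene = calls$gene,
                    call = calls$call,
                    copy_number = col_or(calls, "copy_number", NA_real_),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the clinical table
#'
#' CSV with one column per clinical field (`patient_id`, `age`, `gender`,
#' `ecog`, `site`, `prior_lines`, `visceral_mets`, `nlr`, `hb`, `plt`,
#' `arm`, `cb`, `pfs_months`, `pfs_event`, `os_months`, `os_event`).
#'
#' @param path file path.
#' @return clinical data.frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(patient_id = "character"))
  if ("ecog" %in% names(out)) out$ecog <- as.character(out$ecog)
  validate_clinical(out)
  out
}

#' @rdname read_clinical_table
#' @param clinical clinical data.frame.
#' @export
write_clinical_table <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.csv(clinical, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Writes the clinical CSV, MAF-dialect variant TSV, CNV TSV and the truth
#' record + manifest JSON into a directory, using exactly the pipeline's
#' input schemas.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_clinical_table(sim$clinical, file.path(dir, "clinical.csv"))
  write_variant_table(sim$variants, file.path(dir, "variants.maf.tsv"))
  write_cnv_table(sim$cnv, file.path(dir, "cnv.tsv"))
  jsonlite::write_json(list(truth = sim$truth, config = sim$config),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(dir)
}

#' Run manifest
#'
#' Provenance record attached to pipeline outputs: configuration, input
#' digests (md5 for on-disk inputs), seed and package version.
#'
#' @param config named list of settings.
#' @param input_paths named character vector of input files (optional).
#' @param seed integer seed.
#' @return a manifest list.
#' @export
run_manifest <- function(config = list(), input_paths = character(0), seed = NA) {
  digests <- if (length(input_paths) > 0) as.list(tools::md5sum(input_paths))
             else list()
  list(config = config, input_digests = digests, seed = seed,
       package_version = as.character(utils::packageVersion("icipredict")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Run the full clinico-genomic pipeline
#'
#' Orchestrates the analysis order: feature assembly and dichotomization,
#' univariable screen at two-sided p <= 0.05, adaptive-LASSO selection
#' among the screened variables, multivariable fit with the stay criterion
#' (p <= 0.10), discrimination, and — when every retained variable is a
#' binary indicator — a derived point score with per-patient predictions.
#' Deterministic given the inputs and seed.
#'
#' @param variants,cnv_calls,clinical input tables (internal schemas).
#' @param candidates candidate variable names (columns of the dichotomized
#'   feature table) entering the screen.
#' @param rules dichotomization rule set.
#' @param screen_alpha univariable inclusion level (default 0.05).
#' @param stay_alpha multivariable stay criterion (default 0.10).
#' @param threshold point-score classification threshold, or `NULL` to
#'   choose by Youden's J on the cohort.
#' @param seed integer seed (ALASSO folds, bootstrap).
#' @param ... passed to [build_feature_table()].
#' @return list with `features`, `screen`, `selected`, `model`,
#'   `c_statistic`, `point_score`, `scores`, `manifest`.
#' @export
run_pipeline <- function(variants, cnv_calls, clinical,
                         candidates = c("visceral_mets", "nlr_ge5", "snv_ge10",
                                        "cnv_gt0", "ecog_ge1", "cdkn2b_del",
                                        "ddr_inclusive", "hb"),
                         rules = default_ruleset(), screen_alpha = 0.05,
                         stay_alpha = 0.10, threshold = NULL, seed = 1, ...) {
  features <- build_feature_table(clinical, variants, cnv_calls, ...)
  features <- dichotomize(features, rules)
  screen <- univariable_screen(features, candidates, outcome = "cb",
                               alpha = screen_alpha)
  screened <- screen$variable[screen$selected]
  model <- NULL; selected <- character(0); cstat <- NULL
  psm <- NULL; scores <- NULL
  if (length(screened) > 0) {
    cc <- stats::complete.cases(features[screened]) & !is.na(features$cb)
    X <- features[cc, screened, drop = FALSE]
    y <- features$cb[cc]
    selected <- as.character(alasso_select(X, y, family = "logistic", seed = seed))
    if (length(selected) > 0) {
      model <- fit_multivariable(X[selected], y, family = "logistic",
                                 stay_alpha = stay_alpha)
      probs <- stats::predict(model$fit, type = "response")
      cstat <- c_statistic(probs, y, seed = seed)
      binary <- vapply(model$variables, function(v)
        all(as.numeric(X[[v]]) %in% c(0, 1)), logical(1))
      if (all(binary)) {
        psm <- derive_point_score(model, threshold = 0)  # placeholder threshold
        sc <- score_patient(psm, X[model$variables])
        thr <- if (is.null(threshold))
          choose_threshold_youden(psm, sc$score, y) else threshold
        psm$threshold <- thr
        scores <- cbind(patient_id = features$patient_id[cc],
                        score_patient(psm, X[model$variables]))
      }
    }
  }
  list(features = features, screen = screen, selected = selected,
       model = model, c_statistic = cstat, point_score = psm, scores = scores,
       manifest = run_manifest(config = list(candidates = candidates,
                                             rules = rules,
                                             screen_alpha = screen_alpha,
                                             stay_alpha = stay_alpha,
                                             threshold = threshold),
                               seed = seed))
}
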