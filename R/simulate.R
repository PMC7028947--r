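# Synthetic cohort generator.  Emulates a panel-sequenced metastatic
# urothelial carcinoma cohort: per-tumour SNV counts on the 1-32 scale,
# spectra drawn from patient-specific mixtures of four signatures,
# gene-level CNV events thinned by purity-dependent detection, and clinical
# benefit / survival outcomes generated from configurable logistic and
# proportional-hazards models, with a comparator arm in which all outcome
# effects are null.

#' Simulation configuration
#'
#' Returns the full configuration list with the cohort-emulating defaults;
#' any field can be overridden by name.  Defaults echo the study cohort's
#' published marginals: mean SNV count 9.7 (negative binomial, size 3,
#' floored at 1), 73% visceral metastasis, NLR with mean about 5 and 11%
#' missingness, ECOG distribution 44/42/14% with occasional missingness,
#' and clinical-benefit coefficients equal to the published three-factor
#' model's coefficients (intercept 1.15, visceral -2.93, NLR>=5 -2.11,
#' SNV>=10 +3.21) in the ICI arm.  The taxane comparator arm draws clinical
#' benefit from an intercept-only model: every genomic and clinical effect
#' is null by construction.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; all randomness flows from it via per-patient
#'   substreams keyed by patient index.
#' @param arm `"ICI"` or `"taxane"`.
#' @param ... overrides for any default field (see the function body for
#'   the full list).
#' @return a named configuration list.
#' @export
cohort_config <- function(n_patients = 62, seed = 1, arm = c("ICI", "taxane"),
                          ...) {
  arm <- match.arg(arm)
  cfg <- list(
    n_patients = n_patients, seed = seed, arm = arm,
    # SNV count (exonic non-synonymous), negative binomial
    snv_mean = 9.7, snv_size = 3, snv_min = 1,
    # consequence mix among non-synonymous variants
    consequence_probs = c(missense = 0.78, nonsense = 0.07, splice_site = 0.05,
                          frameshift_indel = 0.07, inframe_indel = 0.03),
    syn_mean = 1.5,          # extra synonymous SNVs (Poisson)
    germline_mean = 1.0,     # high-population-AF rows removed by the filter
    # signature mixture (Dirichlet over APOBEC_a, APOBEC_b, ERCC2, C_T_CpG)
    dirichlet_alpha = c(APOBEC_a = 1.0, APOBEC_b = 1.0, ERCC2 = 1.1,
                        C_T_CpG = 1.3),
    # functional / catalogue annotations for missense variants
    p_sift_damaging = 0.40, p_polyphen_probably = 0.35,
    p_cosmic_recurrent = 0.10, p_oncokb = 0.05, p_hotspot = 0.05,
    p_ercc2_helicase = 0.5,
    # tumour purity and CNV generation
    purity_shape1 = 5, purity_shape2 = 2,
    p_9p_deletion = 0.30, p_9p_concordant = 0.85,
    tsg_del_mean = 0.4, onc_amp_mean = 0.5,
    purity_detection_slope = 6, purity_detection_intercept = 0.85,
    # clinical marginals
    age_mean = 65.6, age_sd = 9, age_range = c(41, 84),
    p_male = 0.73,
    ecog_probs = c(`0` = 0.44, `1` = 0.42, `2plus` = 0.14),
    ecog_missing_prob = 0.048,
    p_bladder = 0.74,
    prior_lines_probs = c(`0` = 0.24, `1` = 0.58, `2` = 0.18),
    p_visceral = 0.73,
    nlr_meanlog = log(4.2), nlr_sdlog = 0.55, nlr_missing_prob = 0.113,
    hb_mean = 12, hb_sd = 1.7, hb_range = c(8, 16.5),
    plt_mean = 240, plt_sd = 90, plt_range = c(60, 588),
    # clinical-benefit model (named logistic coefficients; "intercept" plus
    # feature names among visceral_mets, nlr_ge5, snv_ge10, cnv_gt0, ...)
    cb_coefficients = if (arm == "ICI")
      c(intercept = 1.15, visceral_mets = -2.93, nlr_ge5 = -2.11,
        snv_ge10 = 3.21)
    else c(intercept = -0.62),
    # proportional-hazards survival (exponential baselines, months)
    os_baseline_median = 12,
    os_loghr = if (arm == "ICI")
      c(visceral_mets = 1.2, ecog_ge1 = 0.9, nlr_ge5 = 0.6) else numeric(0),
    pfs_baseline_median = 4,
    pfs_loghr = if (arm == "ICI")
      c(visceral_mets = 0.8, snv_ge10 = -0.9, cnv_gt0 = 0.5) else numeric(0),
    censor_range = c(6, 36))
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0, cfg$snv_mean > 0, cfg$snv_size > 0)
  probs <- c(cfg$p_male, cfg$p_bladder, cfg$p_visceral, cfg$p_sift_damaging,
             cfg$p_polyphen_probably, cfg$p_cosmic_recurrent, cfg$p_oncokb,
             cfg$p_hotspot, cfg$p_9p_deletion, cfg$p_9p_concordant,
             cfg$ecog_missing_prob, cfg$nlr_missing_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(cfg$consequence_probs) - 1) > 1e-9)
    stop("consequence_probs must sum to 1")
  if (!"intercept" %in% names(cfg$cb_coefficients))
    stop("cb_coefficients must include an 'intercept' entry")
  invisible(cfg)
}

# channel -> pyrimidine-strand (ref, alt, context)
channel_to_substitution <- function(channel) {
  block <- channel %/% 16L
  b5 <- (channel %% 16L) %/% 4L
  b3 <- channel %% 4L
  subs <- matrix(c("C", "A", "C", "G", "C", "T", "T", "A", "T", "C", "T", "G"),
                 ncol = 2, byrow = TRUE)
  ref <- subs[block + 1L, 1]
  alt <- subs[block + 1L, 2]
  context <- paste0(bases()[b5 + 1L], ref, bases()[b3 + 1L])
  data.frame(ref = ref, alt = alt, trinucleotide_context = context,
             stringsAsFactors = FALSE)
}

patient_seed <- function(seed, i) as.integer((seed * 1000003 + i * 7919) %% 2147483629)

rtrunc_norm <- function(n, mean, sd, lo, hi) pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

empty_variants <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), consequence = character(0),
             population_af = numeric(0), sift_call = character(0),
             polyphen_call = character(0), cosmic_count = integer(0),
             in_oncokb = logical(0), in_hotspot_catalog = logical(0),
             trinucleotide_context = character(0),
             in_helicase_domain = logical(0), stringsAsFactors = FALSE)
}

empty_cnv <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             call = character(0), copy_number = numeric(0),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort
#'
#' Generates the three pipeline input tables (clinical, variants,
#' copy-number calls) plus a truth record storing every latent per-patient
#' quantity.  Identical configurations and seeds give byte-identical
#' outputs; per-patient random substreams are keyed by patient index, so
#' the first k patients are unchanged when `n_patients` grows.
#'
#' @param config from [cohort_config()].
#' @param catalog signature catalogue supplying the mixture profiles
#'   (default [synthetic_signature_catalog()]).
#' @param annotations gene annotation used to realize genes and CNV roles.
#' @return list with `clinical`, `variants`, `cnv`, `truth` data.frames and
#'   the `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            catalog = synthetic_signature_catalog(),
                            annotations = default_gene_annotation()) {
  validate_config(config)
  sig_names <- names(config$dirichlet_alpha)
  if (!all(sig_names %in% colnames(catalog$profiles)))
    stop("dirichlet_alpha names must match catalogue signatures")
  P <- catalog$profiles[, sig_names, drop = FALSE]
  tsg <- annotations$gene[annotations$role %in% c("tumour_suppressor", "both")]
  tsg_non9p <- setdiff(tsg, c("CDKN2A", "CDKN2B"))
  onc <- annotations$gene[annotations$role %in% c("oncogene", "both")]
  all_genes <- annotations$gene

  patients <- lapply(seq_len(config$n_patients), function(i) {
    set.seed(patient_seed(config$seed, i))
    pid <- sprintf("P%04d", i)
    cfg <- config

    ## clinical covariates
    age <- rtrunc_norm(1, cfg$age_mean, cfg$age_sd, cfg$age_range[1], cfg$age_range[2])
    gender <- if (stats::runif(1) < cfg$p_male) "male" else "female"
    ecog <- sample(names(cfg$ecog_probs), 1, prob = cfg$ecog_probs)
    ecog_missing <- stats::runif(1) < cfg$ecog_missing_prob
    site <- if (stats::runif(1) < cfg$p_bladder) "bladder" else "upper_tract"
    prior_lines <- as.integer(sample(names(cfg$prior_lines_probs), 1,
                                     prob = cfg$prior_lines_probs))
    visceral <- stats::runif(1) < cfg$p_visceral
    nlr <- stats::rlnorm(1, cfg$nlr_meanlog, cfg$nlr_sdlog)
    nlr_missing <- stats::runif(1) < cfg$nlr_missing_prob
    hb <- rtrunc_norm(1, cfg$hb_mean, cfg$hb_sd, cfg$hb_range[1], cfg$hb_range[2])
    plt <- rtrunc_norm(1, cfg$plt_mean, cfg$plt_sd, cfg$plt_range[1], cfg$plt_range[2])

    ## variants
    n_nonsyn <- max(cfg$snv_min, stats::rnbinom(1, size = cfg$snv_size,
                                                mu = cfg$snv_mean))
    mixture <- stats::rgamma(length(sig_names), cfg$dirichlet_alpha)
    mixture <- mixture / sum(mixture)
    names(mixture) <- sig_names
    cons <- sample(names(cfg$consequence_probs), n_nonsyn, replace = TRUE,
                   prob = cfg$consequence_probs)
    n_syn <- stats::rpois(1, cfg$syn_mean)
    cons <- c(cons, rep("synonymous", n_syn))
    n_total <- length(cons)
    genes <- sample(all_genes, n_total, replace = TRUE)
    is_sbs <- cons %in% c("missense", "nonsense", "splice_site", "synonymous")
    channel_probs <- drop(P %*% mixture)
    v <- data.frame(patient_id = pid, gene = genes,
                    chrom = paste0("chr", sample(1:22, n_total, replace = TRUE)),
                    pos = sample.int(2e8, n_total, replace = TRUE),
                    ref = NA_character_, alt = NA_character_,
                    consequence = cons, population_af = NA_real_,
                    sift_call = "unknown", polyphen_call = "unknown",
                    cosmic_count = 0L, in_oncokb = FALSE,
                    in_hotspot_catalog = FALSE,
                    trinucleotide_context = NA_character_,
                    in_helicase_domain = FALSE, stringsAsFactors = FALSE)
    if (any(is_sbs)) {
      ch <- sample(0:95, sum(is_sbs), replace = TRUE, prob = channel_probs)
      sub <- channel_to_substitution(ch)
      # half the calls are reported on the purine strand
      flip <- stats::runif(nrow(sub)) < 0.5
      sub$ref[flip] <- chartr("ACGT", "TGCA", sub$ref[flip])
      sub$alt[flip] <- chartr("ACGT", "TGCA", sub$alt[flip])
      sub$trinucleotide_context[flip] <- revcomp(sub$trinucleotide_context[flip])
      v$ref[is_sbs] <- sub$ref
      v$alt[is_sbs] <- sub$alt
      v$trinucleotide_context[is_sbs] <- sub$trinucleotide_context
    }
    if (any(!is_sbs)) {
      ins <- stats::runif(sum(!is_sbs)) < 0.5
      len <- ifelse(cons[!is_sbs] == "inframe_indel", 3L, 1L)
      tail <- vapply(len, function(l)
        paste(sample(bases(), l, replace = TRUE), collapse = ""), character(1))
      v$ref[!is_sbs] <- ifelse(ins, "A", paste0("A", tail))
      v$alt[!is_sbs] <- ifelse(ins, paste0("A", tail), "A")
    }
    miss <- v$consequence == "missense"
    v$sift_call[miss] <- ifelse(stats::runif(sum(miss)) < cfg$p_sift_damaging,
                                "damaging", "tolerated")
    v$polyphen_call[miss] <-
      ifelse(stats::runif(sum(miss)) < cfg$p_polyphen_probably,
             "probably_damaging",
             sample(c("possibly_damaging", "benign"), sum(miss), replace = TRUE))
    rec <- miss & stats::runif(n_total) < cfg$p_cosmic_recurrent
    v$cosmic_count[rec] <- 5L + stats::rpois(sum(rec), 3)
    v$cosmic_count[miss & !rec] <- stats::rpois(sum(miss & !rec), 0.3)
    v$in_oncokb[miss] <- stats::runif(sum(miss)) < cfg$p_oncokb
    v$in_hotspot_catalog[miss] <- stats::runif(sum(miss)) < cfg$p_hotspot
    erc <- miss & v$gene == "ERCC2"
    v$in_helicase_domain[erc] <- stats::runif(sum(erc)) < cfg$p_ercc2_helicase
    # a few annotated-but-rare population frequencies on somatic calls
    rare <- stats::runif(n_total) < 0.1
    v$population_af[rare] <- stats::runif(sum(rare), 0, 5e-4)
    # likely-germline rows the AF filter must remove
    n_germ <- stats::rpois(1, cfg$germline_mean)
    if (n_germ > 0) {
      g <- v[rep(1, n_germ), , drop = FALSE]
      g$gene <- sample(all_genes, n_germ, replace = TRUE)
      g$consequence <- "missense"
      ch <- sample(0:95, n_germ, replace = TRUE)
      sub <- channel_to_substitution(ch)
      g$ref <- sub$ref; g$alt <- sub$alt
      g$trinucleotide_context <- sub$trinucleotide_context
      g$population_af <- stats::runif(n_germ, 0.0015, 0.05)
      g$sift_call <- "unknown"; g$polyphen_call <- "unknown"
      g$cosmic_count <- 0L; g$in_oncokb <- FALSE; g$in_hotspot_catalog <- FALSE
      g$in_helicase_domain <- FALSE
      v <- rbind(v, g)
    }

    ## copy-number events with purity-dependent detection
    purity <- stats::rbeta(1, cfg$purity_shape1, cfg$purity_shape2)
    p_detect <- stats::plogis(cfg$purity_detection_intercept +
                                cfg$purity_detection_slope * (purity - 0.7))
    cnv_rows <- list()
    if (stats::runif(1) < cfg$p_9p_deletion) {
      genes9p <- if (stats::runif(1) < cfg$p_9p_concordant)
        c("CDKN2A", "CDKN2B") else sample(c("CDKN2A", "CDKN2B"), 1)
      cnv_rows <- c(cnv_rows, lapply(genes9p, function(g)
        data.frame(patient_id = pid, gene = g, call = "homozygous_deletion",
                   copy_number = round(stats::runif(1, 0, 0.4), 2),
                   stringsAsFactors = FALSE)))
    }
    n_del <- stats::rpois(1, cfg$tsg_del_mean)
    if (n_del > 0)
      cnv_rows <- c(cnv_rows, lapply(sample(tsg_non9p, min(n_del, length(tsg_non9p))),
        function(g) data.frame(patient_id = pid, gene = g,
                               call = "homozygous_deletion",
                               copy_number = round(stats::runif(1, 0, 0.4), 2),
                               stringsAsFactors = FALSE)))
    n_amp <- stats::rpois(1, cfg$onc_amp_mean)
    if (n_amp > 0)
      cnv_rows <- c(cnv_rows, lapply(sample(onc, min(n_amp, length(onc))),
        function(g) data.frame(patient_id = pid, gene = g,
                               call = "amplification",
                               copy_number = round(stats::runif(1, 6.5, 40), 1),
                               stringsAsFactors = FALSE)))
    cnv <- if (length(cnv_rows) > 0) do.call(rbind, cnv_rows) else empty_cnv()
    if (nrow(cnv) > 0) cnv <- cnv[stats::runif(nrow(cnv)) < p_detect, , drop = FALSE]
    cnv_n <- cnv_count(cnv, annotations)

    ## outcomes from the realized features
    feat <- c(visceral_mets = as.numeric(visceral),
              nlr_ge5 = as.numeric(nlr >= 5),
              snv_ge10 = as.numeric(n_nonsyn >= 10),
              cnv_gt0 = as.numeric(cnv_n > 0),
              ecog_ge1 = as.numeric(ecog != "0"))
    lp_cb <- linpred(cfg$cb_coefficients, feat)
    cb <- stats::runif(1) < stats::plogis(lp_cb)
    lam_os <- log(2) / cfg$os_baseline_median * exp(linpred(c(intercept = 0, cfg$os_loghr), feat))
    lam_pfs <- log(2) / cfg$pfs_baseline_median * exp(linpred(c(intercept = 0, cfg$pfs_loghr), feat))
    t_death <- stats::rexp(1, lam_os)
    t_prog <- stats::rexp(1, lam_pfs)
    t_pfs <- min(t_prog, t_death)
    cens <- stats::runif(1, cfg$censor_range[1], cfg$censor_range[2])

    clinical <- data.frame(
      patient_id = pid, age = round(age, 1), gender = gender,
      ecog = if (ecog_missing) NA_character_ else ecog,
      site = site, prior_lines = prior_lines, visceral_mets = visceral,
      nlr = if (nlr_missing) NA_real_ else round(nlr, 2),
      hb = round(hb, 1), plt = round(plt), arm = cfg$arm,
      cb = if (cb) "CB" else "NCB",
      pfs_months = round(min(t_pfs, cens), 2),
      pfs_event = as.integer(t_pfs <= cens),
      os_months = round(min(t_death, cens), 2),
      os_event = as.integer(t_death <= cens),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      patient_id = pid, snv_count = as.integer(n_nonsyn), cnv_count = cnv_n,
      purity = round(purity, 4),
      mix_apobec = unname(mixture[["APOBEC_a"]] + mixture[["APOBEC_b"]]),
      mix_ercc2 = unname(mixture[["ERCC2"]]),
      mix_ct_cpg = unname(mixture[["C_T_CpG"]]),
      cdkn2a_del = gene_homdel_flag(cnv, "CDKN2A"),
      cdkn2b_del = gene_homdel_flag(cnv, "CDKN2B"),
      snv_ge10 = n_nonsyn >= 10, nlr_true = round(nlr, 2),
      cb_prob = stats::plogis(lp_cb), stringsAsFactors = FALSE)
    list(clinical = clinical, variants = v, cnv = cnv, truth = truth)
  })

  bind <- function(part, empty) {
    rows <- lapply(patients, `[[`, part)
    rows <- rows[vapply(rows, nrow, integer(1)) > 0]
    if (length(rows) == 0) empty else {
      out <- do.call(rbind, rows); rownames(out) <- NULL; out
    }
  }
  empty_clin <- data.frame(patient_id = character(0), age = numeric(0),
                           gender = character(0), ecog = character(0),
                           site = character(0), prior_lines = integer(0),
                           visceral_mets = logical(0), nlr = numeric(0),
                           hb = numeric(0), plt = numeric(0), arm = character(0),
                           cb = character(0), pfs_months = numeric(0),
                           pfs_event = integer(0), os_months = numeric(0),
                           os_event = integer(0), stringsAsFactors = FALSE)
  empty_truth <- data.frame(patient_id = character(0), snv_count = integer(0),
                            cnv_count = integer(0), purity = numeric(0),
                            mix_apobec = numeric(0), mix_ercc2 = numeric(0),
                            mix_ct_cpg = numeric(0), cdkn2a_del = logical(0),
                            cdkn2b_del = logical(0), snv_ge10 = logical(0),
                            nlr_true = numeric(0), cb_prob = numeric(0),
                            stringsAsFactors = FALSE)
  list(clinical = bind("clinical", empty_clin),
       variants = bind("variants", empty_variants()),
       cnv = bind("cnv", empty_cnv()),
       truth = bind("truth", empty_truth),
       config = config)
}

linpred <- function(coefs, features) {
  lp <- if ("intercept" %in% names(coefs)) coefs[["intercept"]] else 0
  for (nm in setdiff(names(coefs), "intercept")) {
    if (!nm %in% names(features)) stop("coefficient for unknown feature: ", nm)
    lp <- lp + coefs[[nm]] * features[[nm]]
  }
  lp
}
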