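# Univariable inference.  All functions return a "test result" list with
# fields method, statistic, p_value, estimate, conf_low, conf_high, and an
# optional note (e.g. separation or undefined-test flags).

test_result <- function(method, statistic = NA_real_, p_value = NA_real_,
                        estimate = NA_real_, conf_low = NA_real_,
                        conf_high = NA_real_, note = NULL) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 estimate = estimate, conf_low = conf_low,
                 conf_high = conf_high, note = note),
            class = "ici_test")
}

#' @export
print.ici_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$estimate))
    cat(sprintf("  estimate %.4g (95%% CI %.4g, %.4g)\n",
                x$estimate, x$conf_low, x$conf_high))
  if (!is.na(x$statistic)) cat(sprintf("  statistic %.4g\n", x$statistic))
  cat(sprintf("  p = %.4g\n", x$p_value))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

as_table2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(all(dim(x) == c(2, 2)))
    m <- x
  } else {
    stopifnot(is.numeric(x), length(x) == 4)
    m <- matrix(x, 2, 2, byrow = TRUE)
  }
  if (any(m < 0)) stop("contingency table entries must be non-negative")
  if (sum(m) == 0) stop("contingency table is all zero")
  m
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test conditioning on both margins; the two-sided
#' p-value is the sum of the point probabilities of all tables (with the
#' same margins) no more probable than the observed one — the
#' point-probability (minimum-likelihood) convention.
#'
#' @param a,b,c,d cell counts, rows = group, columns = event; alternatively
#'   pass a 2x2 matrix as `a`.
#' @return a test result with the conditional odds-ratio estimate and CI.
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.null(b)) as_table2x2(a) else as_table2x2(c(a, b, c, d))
  ft <- stats::fisher.test(m)
  test_result("Fisher exact (two-sided, point-probability)",
              p_value = ft$p.value, estimate = unname(ft$estimate),
              conf_low = ft$conf.int[1], conf_high = ft$conf.int[2])
}

#' Pearson chi-square test on an r x c table
#'
#' Pearson statistic with (r-1)(c-1) degrees of freedom and no continuity
#' correction.
#'
#' @param tab matrix of counts.
#' @return a test result.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (sum(tab) == 0) stop("contingency table is all zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(sprintf("Pearson chi-square (df = %d)", ct$parameter),
              statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Rank tests for group comparisons
#'
#' Mann-Whitney U (two groups) or Kruskal-Wallis (two or more groups),
#' two-sided, with mid-rank tie handling.  The Mann-Whitney test uses exact
#' enumeration when both groups have at most 8 untied observations and the
#' tie-corrected normal approximation otherwise.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @param kind `"mann_whitney"` or `"kruskal_wallis"`.
#' @return a test result.
#' @export
rank_tests <- function(values, groups, kind = c("mann_whitney", "kruskal_wallis")) {
  kind <- match.arg(kind)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.factor(as.character(groups[keep]))
  sizes <- table(groups)
  if (any(sizes == 0) || nlevels(groups) < 2)
    stop("each group must be non-empty and there must be at least 2 groups")
  if (kind == "mann_whitney") {
    if (nlevels(groups) != 2)
      stop("mann_whitney requires exactly 2 groups")
    x <- values[groups == levels(groups)[1]]
    y <- values[groups == levels(groups)[2]]
    exact <- max(sizes) <= 8 && !any(duplicated(values))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
    test_result(if (exact) "Mann-Whitney U (exact)"
                else "Mann-Whitney U (normal approximation, tie-corrected)",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  } else {
    kt <- stats::kruskal.test(values, groups)
    test_result(sprintf("Kruskal-Wallis (df = %d)", kt$parameter),
                statistic = unname(kt$statistic), p_value = kt$p.value)
  }
}

# Heuristic separation detection for a fitted binomial glm: fitted values
# pinned to 0/1 together with exploding coefficients.
detect_separation <- function(fit) {
  probs <- fit$fitted.values
  perfect <- all(probs[fit$y == 1] > 1 - 1e-4) && all(probs[fit$y == 0] < 1e-4)
  huge <- any(abs(stats::coef(fit))[-1] > 15, na.rm = TRUE)
  perfect && huge
}

#' Univariable logistic regression
#'
#' One-covariate maximum-likelihood logistic fit with intercept, Wald
#' confidence interval and p-value for the covariate's odds ratio.
#' Complete separation is detected and flagged rather than silently
#' returning a diverged fit.
#'
#' @param x numeric or logical covariate.
#' @param y outcome: logical, 0/1, or `"CB"`/`"NCB"` labels (`"CB"` is the
#'   event).
#' @return a test result with `estimate` = odds ratio.
#' @export
univariable_logistic <- function(x, y) {
  y <- as_event(y)
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- y[keep]
  if (length(unique(x)) < 2) stop("covariate is constant")
  if (all(y == 1) || all(y == 0))
    stop("outcome has no variation (need at least one event and one non-event)")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  sep <- detect_separation(fit)
  test_result("univariable logistic (Wald)",
              statistic = beta / se,
              p_value = 2 * stats::pnorm(-abs(beta / se)),
              estimate = exp(beta),
              conf_low = exp(beta - 1.959964 * se),
              conf_high = exp(beta + 1.959964 * se),
              note = if (sep) "complete or quasi-complete separation detected")
}

as_event <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y[!is.na(y)]), c("CB", "NCB"))
    if (length(bad) > 0) stop("outcome labels must be CB/NCB; got ",
                              paste(bad, collapse = ", "))
    out <- ifelse(is.na(y), NA_integer_, as.integer(y == "CB"))
    out
  } else as.integer(y)
}

#' Univariable Cox regression
#'
#' One-covariate Cox proportional-hazards fit (Efron tie handling) with
#' Wald confidence interval and p-value for the hazard ratio.
#'
#' @param x numeric or logical covariate.
#' @param times follow-up times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return a test result with `estimate` = hazard ratio.
#' @export
univariable_cox <- function(x, times, events) {
  keep <- !is.na(x) & !is.na(times) & !is.na(events)
  x <- as.numeric(x[keep]); times <- times[keep]; events <- as.integer(events[keep])
  if (sum(events) == 0) stop("no events observed")
  fit <- survival::coxph(survival::Surv(times, events) ~ x, ties = "efron")
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[[1]]
  test_result("univariable Cox (Efron ties, Wald)",
              statistic = beta / se,
              p_value = 2 * stats::pnorm(-abs(beta / se)),
              estimate = exp(beta),
              conf_low = exp(beta - 1.959964 * se),
              conf_high = exp(beta + 1.959964 * se))
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Product-limit estimates per group and the standard log-rank test across
#' groups.  With no events anywhere the log-rank statistic is undefined and
#' the result is flagged instead of erroring.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param groups group labels.
#' @return list with `fit` (a [survival::survfit] object) and `test` (a
#'   test result).
#' @export
km_logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (anyNA(groups)) stop("unknown (missing) group labels")
  df <- data.frame(times = times, events = as.integer(events), groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  if (sum(df$events) == 0) {
    return(list(fit = fit,
                test = test_result("log-rank", note = "no events; log-rank undefined")))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
  df_lr <- length(sd$n) - 1
  list(fit = fit,
       test = test_result(sprintf("log-rank (df = %d)", df_lr),
                          statistic = sd$chisq,
                          p_value = stats::pchisq(sd$chisq, df_lr, lower.tail = FALSE)))
}

#' Univariable association screen
#'
#' Runs the univariable model for every candidate variable against the
#' chosen outcome and tabulates effect estimates and p-values; used to
#' select variables (two-sided p <= alpha) for multivariable modelling.
#'
#' @param features feature table (after [dichotomize()]).
#' @param variables character vector of column names.
#' @param outcome `"cb"` (logistic on clinical benefit), `"pfs"` or `"os"`
#'   (Cox).
#' @param alpha screening level (default 0.05).
#' @param p_adjust optional multiple-testing adjustment passed to
#'   [stats::p.adjust()] (e.g. `"bonferroni"`, `"BH"`); off by default.
#' @return data.frame with one row per variable, estimate, CI, p, and a
#'   `selected` flag.
#' @export
univariable_screen <- function(features, variables, outcome = c("cb", "pfs", "os"),
                               alpha = 0.05, p_adjust = NULL) {
  outcome <- match.arg(outcome)
  run_one <- function(v) {
    x <- features[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    res <- tryCatch(switch(outcome,
      cb = univariable_logistic(x, features$cb),
      pfs = univariable_cox(x, features$pfs_months, features$pfs_event),
      os = univariable_cox(x, features$os_months, features$os_event)),
      error = function(e) test_result("failed", note = conditionMessage(e)))
    data.frame(variable = v, estimate = res$estimate, conf_low = res$conf_low,
               conf_high = res$conf_high, p_value = res$p_value,
               note = if (is.null(res$note)) "" else res$note,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(variables, run_one))
  if (!is.null(p_adjust)) out$p_adjusted <- stats::p.adjust(out$p_value, p_adjust)
  out$selected <- !is.na(out$p_value) & out$p_value <= alpha
  rownames(out) <- NULL
  out
}
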