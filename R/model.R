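# Model building: adaptive-LASSO selection, backward-eliminated
# multivariable fits, discrimination, and the clinical point score.

as_numeric_matrix <- function(X) {
  X <- as.data.frame(X)
  m <- vapply(X, function(col) as.numeric(col), numeric(nrow(X)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(X))
  colnames(m) <- names(X)
  m
}

#' Adaptive-LASSO variable selection
#'
#' Two-stage adaptive LASSO: an initial ridge fit (stable under
#' collinearity) supplies coefficient-specific weights
#' \eqn{w_j = 1/|\hat\beta_j|^\gamma}, and a weighted-L1 path is then fitted
#' with the penalty parameter chosen by BIC (default) or seeded
#' cross-validation.  Variables with non-zero coefficients at the chosen
#' penalty are returned.
#'
#' @param X data.frame or matrix of candidate covariates (numeric or
#'   logical columns).
#' @param y outcome: CB/NCB labels or 0/1 for `family = "logistic"`; a
#'   two-column matrix / list with `times` and `events` for
#'   `family = "cox"`.
#' @param family `"logistic"` or `"cox"`.
#' @param gamma adaptive-weight exponent (default 1).
#' @param tuning `"bic"` or `"cv"`.
#' @param nfolds folds for `tuning = "cv"`.
#' @param seed integer seed controlling the cross-validation folds (both
#'   stages); results are deterministic given the seed.
#' @return character vector of selected variable names (possibly empty),
#'   with the full path and chosen lambda as attributes.
#' @export
alasso_select <- function(X, y, family = c("logistic", "cox"), gamma = 1,
                          tuning = c("bic", "cv"), nfolds = 10, seed = 1) {
  family <- match.arg(family)
  tuning <- match.arg(tuning)
  Xm <- as_numeric_matrix(X)
  keep <- apply(Xm, 2, function(col) stats::var(col) > 0)
  if (any(!keep)) {
    warning("dropping constant covariates: ",
            paste(colnames(Xm)[!keep], collapse = ", "))
    Xm <- Xm[, keep, drop = FALSE]
  }
  if (ncol(Xm) == 0) return(character(0))
  # a single candidate cannot be penalized against competitors; keep it and
  # let the downstream stay criterion decide
  if (ncol(Xm) == 1) return(colnames(Xm))
  if (family == "logistic") {
    yy <- as_event(y)
    if (length(unique(yy)) < 2) stop("outcome is constant")
    glmnet_family <- "binomial"
  } else {
    if (is.list(y) && !is.data.frame(y)) y <- cbind(time = y$times, status = y$events)
    yy <- as.matrix(y)
    colnames(yy) <- c("time", "status")
    if (sum(yy[, "status"]) == 0) stop("no events observed")
    glmnet_family <- "cox"
  }
  n <- nrow(Xm)
  foldid <- withr_seed(seed, sample(rep_len(seq_len(nfolds), n)))
  ridge_cv <- glmnet::cv.glmnet(Xm, yy, family = glmnet_family, alpha = 0,
                                foldid = foldid)
  beta_init <- as.numeric(stats::coef(ridge_cv, s = "lambda.min"))
  if (family == "logistic") beta_init <- beta_init[-1]  # drop intercept
  w <- 1 / pmax(abs(beta_init), 1e-8)^gamma
  path <- glmnet::glmnet(Xm, yy, family = glmnet_family, alpha = 1,
                         penalty.factor = w)
  if (tuning == "bic") {
    dev <- (1 - path$dev.ratio) * path$nulldev
    bic <- dev + path$df * log(n)
    lambda <- path$lambda[which.min(bic)]
  } else {
    cv <- glmnet::cv.glmnet(Xm, yy, family = glmnet_family, alpha = 1,
                            penalty.factor = w, foldid = foldid)
    lambda <- cv$lambda.min
  }
  b <- stats::coef(path, s = lambda)
  b <- b[setdiff(rownames(b), "(Intercept)"), , drop = TRUE]
  selected <- names(b)[abs(b) > 0]
  structure(selected, lambda = lambda, weights = w)
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Firth-type penalized logistic regression (Jeffreys-prior IRLS), used as a
# fallback when maximum likelihood separates.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- cbind(`(Intercept)` = 1, X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    Wv <- p * (1 - p)
    XtWX <- crossprod(X * Wv, X)
    XtWX_inv <- solve(XtWX)
    h <- rowSums((X %*% XtWX_inv) * X) * Wv
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(XtWX_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  Wv <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X * Wv, X))))
  list(coefficients = stats::setNames(beta, colnames(X)),
       se = stats::setNames(se, colnames(X)))
}

#' Multivariable model with backward elimination (stay criterion)
#'
#' Fits a multivariable logistic or Cox model on the selected variables and
#' backward-eliminates: while any Wald p-value exceeds the stay criterion
#' (default 0.10) and more than one variable remains, the variable with the
#' largest p is dropped and the model refitted.  For logistic fits with
#' complete separation, a Firth-type penalized fit replaces maximum
#' likelihood and the result is flagged.
#'
#' @param X data.frame of covariates (the ALASSO-selected set).
#' @param y outcome (see [alasso_select()]).
#' @param family `"logistic"` or `"cox"`.
#' @param stay_alpha stay criterion on the Wald p-value (default 0.10).
#' @return a fitted-model list with `variables`, `coefficients` (including
#'   the intercept for logistic), `se`, `estimate` (OR or HR), `conf_low`,
#'   `conf_high`, `p_value`, `eliminated`, `family`, `separation`, `fit`.
#' @export
fit_multivariable <- function(X, y, family = c("logistic", "cox"),
                              stay_alpha = 0.10) {
  family <- match.arg(family)
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 1)
  if (family == "cox" && is.list(y) && !is.data.frame(y))
    y <- cbind(time = y$times, status = y$events)
  vars <- names(X)
  eliminated <- character(0)
  repeat {
    fit <- fit_once(X[vars], y, family)
    pv <- fit$p_value[vars]
    if (length(vars) <= 1 || max(pv) <= stay_alpha) break
    worst <- vars[which.max(pv)]
    eliminated <- c(eliminated, worst)
    vars <- setdiff(vars, worst)
  }
  fit$eliminated <- eliminated
  fit
}

fit_once <- function(X, y, family) {
  Xm <- as_numeric_matrix(X)
  if (family == "logistic") {
    yy <- as_event(y)
    fit <- suppressWarnings(stats::glm(yy ~ ., data = as.data.frame(Xm),
                                       family = stats::binomial()))
    sep <- detect_separation(fit)
    if (sep) {
      fl <- firth_logistic(Xm, yy)
      coefs <- fl$coefficients
      se <- fl$se
    } else {
      coefs <- stats::coef(fit)
      se <- sqrt(diag(stats::vcov(fit)))
    }
    z <- coefs / se
    out <- list(family = "logistic", variables = colnames(Xm),
                coefficients = coefs, se = se,
                estimate = exp(coefs), conf_low = exp(coefs - 1.959964 * se),
                conf_high = exp(coefs + 1.959964 * se),
                p_value = 2 * stats::pnorm(-abs(z)),
                separation = sep, fit = fit)
  } else {
    yy <- as.matrix(y)
    fit <- survival::coxph(survival::Surv(yy[, 1], yy[, 2]) ~ Xm, ties = "efron")
    coefs <- stats::setNames(stats::coef(fit), colnames(Xm))
    se <- stats::setNames(sqrt(diag(stats::vcov(fit))), colnames(Xm))
    z <- coefs / se
    out <- list(family = "cox", variables = colnames(Xm),
                coefficients = coefs, se = se,
                estimate = exp(coefs), conf_low = exp(coefs - 1.959964 * se),
                conf_high = exp(coefs + 1.959964 * se),
                p_value = 2 * stats::pnorm(-abs(z)),
                separation = FALSE, fit = fit)
  }
  class(out) <- "ici_fit"
  out
}

#' @export
print.ici_fit <- function(x, ...) {
  cat(sprintf("%s model, %d variable(s)%s\n", x$family, length(x$variables),
              if (isTRUE(x$separation)) " [Firth penalized: separation]" else ""))
  tab <- data.frame(beta = x$coefficients[x$variables],
                    se = x$se[x$variables],
                    estimate = x$estimate[x$variables],
                    p = x$p_value[x$variables])
  print(round(tab, 4))
  invisible(x)
}

# Rank-based AUC: probability a random event-case outranks a non-case,
# ties counted 1/2 (mid-rank formula).
auc_rank <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrimination (c-statistic) with bootstrap CI
#'
#' For a binary outcome, the area under the ROC curve computed by the
#' mid-rank formula (ties score 1/2).  For survival, Harrell's concordance
#' over usable pairs (higher score = higher risk).  The confidence interval
#' is a seeded percentile bootstrap.
#'
#' @param scores risk scores or predicted probabilities.
#' @param y binary outcome (CB/NCB labels or 0/1); omit for survival.
#' @param times,events survival outcome; used when `y` is missing.
#' @param n_boot bootstrap resamples (default 2000); `0` skips the CI.
#' @param seed seed for the bootstrap.
#' @return list with `c`, `conf_low`, `conf_high`, `n`.
#' @export
c_statistic <- function(scores, y = NULL, times = NULL, events = NULL,
                        n_boot = 2000, seed = 1) {
  if (!is.null(y)) {
    yy <- as_event(y)
    keep <- !is.na(scores) & !is.na(yy)
    scores <- scores[keep]; yy <- yy[keep]
    if (length(unique(yy)) < 2) stop("outcome has a single class")
    point <- auc_rank(scores, yy)
    stat <- function(idx) {
      if (length(unique(yy[idx])) < 2) return(NA_real_)
      auc_rank(scores[idx], yy[idx])
    }
    n <- length(yy)
  } else {
    keep <- !is.na(scores) & !is.na(times) & !is.na(events)
    scores <- scores[keep]; times <- times[keep]; events <- as.integer(events[keep])
    if (sum(events) == 0) stop("no events observed")
    conc <- function(s, t, e)
      survival::concordance(survival::Surv(t, e) ~ s, reverse = TRUE)$concordance
    point <- conc(scores, times, events)
    stat <- function(idx) {
      if (sum(events[idx]) == 0) return(NA_real_)
      conc(scores[idx], times[idx], events[idx])
    }
    n <- length(scores)
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- withr_seed(seed, {
      vapply(seq_len(n_boot),
             function(i) stat(sample.int(n, n, replace = TRUE)), numeric(1))
    })
    ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  list(c = point, conf_low = ci[1], conf_high = ci[2], n = n)
}

round_half_away <- function(x) {
  y <- abs(x) * 2
  f <- floor(y + 1e-9)
  up <- (y - f) >= 0.5 - 1e-9
  sign(x) * (f + up) / 2
}

#' Point-score model constructors
#'
#' A point-score model is a linear predictor over binary indicators: an
#' intercept plus per-variable points, with a classification threshold
#' (score >= threshold predicts clinical benefit).  `derive_point_score()`
#' rounds a fitted logistic model's coefficients to the nearest half point
#' (ties away from zero); `point_score_model()` accepts explicit points.
#' The achievable score range and value set are computed by enumerating all
#' indicator combinations.
#'
#' @param model a logistic fitted model from [fit_multivariable()] whose
#'   variables are all binary indicators.
#' @param threshold classification threshold on the score.
#' @param rounding `"nearest_half"` or `"explicit"` (record-keeping label
#'   for `point_score_model()`).
#' @return an object of class `point_score` with `intercept`, `points`,
#'   `threshold`, `range`, `value_set`.
#' @export
derive_point_score <- function(model, threshold, rounding = "nearest_half") {
  stopifnot(model$family == "logistic")
  vars <- model$variables
  Xfit <- model$fit$model
  for (v in vars) {
    col <- Xfit[[v]]
    if (!is.null(col) && !all(col %in% c(0, 1)))
      stop("point scores require binary indicator variables; '", v,
           "' is not 0/1")
  }
  pts <- round_half_away(model$coefficients[vars])
  point_score_model(intercept = round_half_away(model$coefficients[["(Intercept)"]]),
                    points = pts, threshold = threshold, rounding = rounding,
                    source = model)
}

#' @rdname derive_point_score
#' @param intercept intercept points.
#' @param points named numeric vector of per-variable points.
#' @param source optional fitted model the points were derived from.
#' @export
point_score_model <- function(intercept, points, threshold,
                              rounding = "explicit", source = NULL) {
  stopifnot(is.numeric(points), !is.null(names(points)))
  k <- length(points)
  combos <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  colnames(combos) <- names(points)
  scores <- intercept + drop(combos %*% points)
  vs <- sort(unique(scores))
  if (threshold < min(scores) || threshold > max(scores))
    warning("threshold lies outside the achievable score range")
  structure(list(intercept = intercept, points = points,
                 threshold = threshold, rounding = rounding,
                 range = c(min(scores), max(scores)), value_set = vs,
                 combos = combos, combo_scores = scores, source = source),
            class = "point_score")
}

#' The three-factor clinical-benefit point score
#'
#' The published three-factor predictor of benefit from PD-1/PD-L1 blockade
#' in metastatic urothelial carcinoma: intercept +1, visceral metastasis
#' -2.5, NLR >= 5 -2, SNV count >= 10 +3, with scores >= -1 predicting
#' clinical benefit.  Score range: -3.5 to 4.
#'
#' @return a `point_score` model.
#' @export
reference_point_score <- function() {
  point_score_model(intercept = 1,
                    points = c(visceral_mets = -2.5, nlr_ge5 = -2, snv_ge10 = 3),
                    threshold = -1)
}

#' @export
print.point_score <- function(x, ...) {
  cat("point score: intercept", x$intercept, "\n")
  for (v in names(x$points)) cat(sprintf("  %-14s %+g\n", v, x$points[[v]]))
  cat(sprintf("threshold >= %g predicts benefit; achievable range [%g, %g]\n",
              x$threshold, x$range[1], x$range[2]))
  invisible(x)
}

#' Score patients with a point-score model
#'
#' @param psm a `point_score` model.
#' @param flags data.frame (or named list/vector for one patient) with one
#'   logical/0-1 column per scored variable.  Missing flags are an error:
#'   patients lacking a component (for example NLR) must be excluded
#'   upstream, mirroring listwise exclusion from score-based
#'   classification.
#' @return data.frame with `score` and `predicted` (`"CB"`/`"NCB"`).
#' @export
score_patient <- function(psm, flags) {
  if (!is.data.frame(flags)) flags <- as.data.frame(as.list(flags))
  missing <- setdiff(names(psm$points), names(flags))
  if (length(missing) > 0)
    stop("missing score components: ", paste(missing, collapse = ", "))
  m <- as_numeric_matrix(flags[names(psm$points)])
  if (anyNA(m))
    stop("missing flag values; exclude patients with absent components ",
         "before scoring")
  score <- psm$intercept + drop(m %*% psm$points)
  data.frame(score = score,
             predicted = ifelse(score >= psm$threshold, "CB", "NCB"),
             stringsAsFactors = FALSE)
}

#' Threshold selection by Youden's J
#'
#' Chooses, among the achievable score values of a point-score model, the
#' threshold maximizing sensitivity + specificity - 1 on supplied data
#' (smallest maximizer on ties).
#'
#' @param psm a `point_score` model.
#' @param scores numeric patient scores.
#' @param outcomes CB/NCB labels or 0/1.
#' @return the chosen threshold.
#' @export
choose_threshold_youden <- function(psm, scores, outcomes) {
  y <- as_event(outcomes)
  cand <- psm$value_set
  j <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & y == 1) / sum(y == 1)
    spec <- sum(!pred & y == 0) / sum(y == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Sensitivity and specificity of predicted benefit
#'
#' @param predicted predicted labels (`"CB"`/`"NCB"`, logical, or 0/1;
#'   positive = CB).
#' @param outcomes observed labels in the same coding.
#' @return list with the 2x2 counts, exact fractions and percentages;
#'   sensitivity is `NA` (flagged) when there are no positives, likewise
#'   specificity with no negatives.
#' @export
classification_metrics <- function(predicted, outcomes) {
  p <- as_event(predicted); o <- as_event(outcomes)
  keep <- !is.na(p) & !is.na(o)
  p <- p[keep]; o <- o[keep]
  stopifnot(length(p) > 0)
  tp <- sum(p == 1 & o == 1); fn <- sum(p == 0 & o == 1)
  tn <- sum(p == 0 & o == 0); fp <- sum(p == 1 & o == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(counts = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(predicted = c("CB", "NCB"),
                                       observed = c("CB", "NCB"))),
       sensitivity = sens, specificity = spec,
       sensitivity_pct = 100 * sens, specificity_pct = 100 * spec)
}

#' Prognostic index and risk grouping
#'
#' A linear prognostic index over continuous/indicator features with
#' ordered cutoffs defining risk groups; intervals are closed on the left
#' (low < first cutoff; last group >= last cutoff).
#'
#' @param coefficients named numeric vector.
#' @param features data.frame with one column per coefficient.
#' @param cutoffs strictly increasing numeric cutoffs (default the
#'   progression-free-survival index cutoffs -0.29 and 1.54).
#' @param labels group labels, `length(cutoffs) + 1` of them.
#' @return data.frame with `index` and `group`.
#' @export
prognostic_index <- function(coefficients, features,
                             cutoffs = c(-0.29, 1.54),
                             labels = c("low", "intermediate", "high")) {
  stopifnot(all(diff(cutoffs) > 0), length(labels) == length(cutoffs) + 1)
  missing <- setdiff(names(coefficients), names(features))
  if (length(missing) > 0)
    stop("missing features: ", paste(missing, collapse = ", "))
  m <- as_numeric_matrix(as.data.frame(features)[names(coefficients)])
  if (anyNA(m)) stop("missing feature values")
  idx <- drop(m %*% coefficients)
  grp <- labels[findInterval(idx, cutoffs) + 1]
  data.frame(index = idx, group = factor(grp, levels = labels))
}

#' Overall-survival point score
#'
#' Integer point score for overall survival after checkpoint blockade:
#' visceral metastasis 2 points, NLR >= 5 one point, ECOG performance
#' status >= 1 one point; risk groups 0-2, 3 and 4 points.
#'
#' @param visceral_mets,nlr_ge5,ecog_ge1 logical flags (vectors allowed).
#' @return data.frame with `points` (0-4) and `group`.
#' @export
os_point_score <- function(visceral_mets, nlr_ge5, ecog_ge1) {
  if (anyNA(visceral_mets) || anyNA(nlr_ge5) || anyNA(ecog_ge1))
    stop("all three flags must be present; exclude patients with missing ",
         "components upstream")
  pts <- 2L * as.integer(visceral_mets) + as.integer(nlr_ge5) +
    as.integer(ecog_ge1)
  grp <- cut(pts, breaks = c(-Inf, 2, 3, 4), labels = c("0-2", "3", "4"))
  data.frame(points = pts, group = grp)
}
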