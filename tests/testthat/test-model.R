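simulate_logistic <- function(n, betas, prev = c(0.5, 0.5, 0.5), seed = 1) {
  # betas: intercept then one per indicator
  set.seed(seed)
  k <- length(betas) - 1
  X <- sapply(seq_len(k), function(j) rbinom(n, 1, prev[j]))
  colnames(X) <- paste0("x", seq_len(k))
  y <- rbinom(n, 1, plogis(betas[1] + X %*% betas[-1]))
  list(X = as.data.frame(X), y = y)
}

test_that("adaptive LASSO keeps strong covariates and guards degenerate input", {
  set.seed(71)
  n <- 800
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, paste0("v", 1:6))))
  y <- rbinom(n, 1, plogis(-0.3 + 1.2 * X$v1 - 1.1 * X$v2))
  sel <- alasso_select(X, y, family = "logistic", seed = 7)
  expect_true(all(c("v1", "v2") %in% sel))
  expect_error(alasso_select(X, rep(1, n), family = "logistic"), "constant")
  X$flat <- 1
  expect_warning(alasso_select(X, y, family = "logistic", seed = 7), "constant covariates")
  # determinism given seed
  X$flat <- NULL
  expect_identical(as.character(alasso_select(X, y, seed = 3, tuning = "cv")),
                   as.character(alasso_select(X, y, seed = 3, tuning = "cv")))
})

test_that("adaptive LASSO works for Cox outcomes", {
  set.seed(73)
  n <- 600
  X <- as.data.frame(matrix(rnorm(n * 4), n, 4,
                            dimnames = list(NULL, paste0("v", 1:4))))
  t0 <- rexp(n, 0.1 * exp(X$v1))
  cens <- runif(n, 0, 30)
  sel <- alasso_select(X, list(times = pmin(t0, cens), events = as.integer(t0 <= cens)),
                       family = "cox", seed = 5)
  expect_true("v1" %in% sel)
})

test_that("backward elimination drops null covariates and keeps strong ones", {
  sim <- simulate_logistic(1000, c(-0.2, 1.5, -1.5, 0), seed = 81)
  fit <- fit_multivariable(sim$X, sim$y, family = "logistic", stay_alpha = 0.10)
  expect_setequal(fit$variables, c("x1", "x2"))
  expect_equal(fit$eliminated, "x3")
  # all significant -> elimination is a no-op
  sim2 <- simulate_logistic(1000, c(0, 1.5, -1.5), seed = 82)
  fit2 <- fit_multivariable(sim2$X, sim2$y, family = "logistic")
  expect_length(fit2$eliminated, 0)
  expect_setequal(fit2$variables, c("x1", "x2"))
  # effect reporting: OR = exp(beta)
  expect_equal(unname(fit2$estimate[fit2$variables]),
               unname(exp(fit2$coefficients[fit2$variables])))
})

test_that("Cox multivariable fit applies the stay criterion", {
  set.seed(83)
  n <- 800
  X <- data.frame(strong = rbinom(n, 1, 0.5), null = rbinom(n, 1, 0.5))
  t0 <- rexp(n, 0.08 * exp(0.9 * X$strong))
  cens <- runif(n, 0, 40)
  fit <- fit_multivariable(X, cbind(pmin(t0, cens), as.integer(t0 <= cens)),
                           family = "cox")
  expect_true("strong" %in% fit$variables)
  expect_gt(fit$estimate[["strong"]], 1.8)
  # stay criterion holds: every retained variable meets p <= 0.10 (or is
  # the last one standing), and dropped + kept partition the candidates
  expect_setequal(c(fit$variables, fit$eliminated), c("strong", "null"))
  if (length(fit$variables) > 1)
    expect_true(all(fit$p_value[fit$variables] <= 0.10))
})

test_that("separated logistic fits fall back to a penalized fit and are flagged", {
  X <- data.frame(x = c(0, 0, 0, 0, 1, 1, 1, 1))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- fit_multivariable(X, y, family = "logistic")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$se)))
  expect_lt(abs(fit$coefficients[["x"]]), 10)  # penalization shrinks the divergence
})

test_that("the Firth-type fit agrees with maximum likelihood away from separation", {
  sim <- simulate_logistic(2000, c(0.3, 1, -0.8), seed = 85)
  ml <- glm(sim$y ~ ., data = sim$X, family = binomial())
  fl <- icipredict:::firth_logistic(as.matrix(sim$X), sim$y)
  expect_equal(unname(fl$coefficients), unname(coef(ml)), tolerance = 0.02)
})

test_that("c-statistic matches pair counting, with documented tie behaviour", {
  expect_equal(c_statistic(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), n_boot = 0)$c, 1.0)
  expect_equal(c_statistic(rep(0.5, 6), c(0, 1, 0, 1, 0, 1), n_boot = 0)$c, 0.5)
  expect_equal(c_statistic(c(0.2, 0.1, 0.3, 0.4), c(0, 1, 0, 1), n_boot = 0)$c, 0.5)
  set.seed(91)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes present
    s <- sample(seq(0.1, 0.9, 0.1), n, replace = TRUE)
    expect_equal(c_statistic(s, y, n_boot = 0)$c, oracle_auc_pairs(s, y))
  }
  expect_error(c_statistic(1:5, rep(1, 5), n_boot = 0), "single class")
  # bootstrap CI brackets the point estimate and is seed-stable
  set.seed(92)
  s <- rnorm(80); y <- rbinom(80, 1, plogis(s))
  ci1 <- c_statistic(s, y, n_boot = 200, seed = 4)
  ci2 <- c_statistic(s, y, n_boot = 200, seed = 4)
  expect_identical(ci1, ci2)
  expect_lte(ci1$conf_low, ci1$c); expect_gte(ci1$conf_high, ci1$c)
})

test_that("survival c-statistic equals Harrell's concordance direction", {
  set.seed(93)
  n <- 200
  x <- rnorm(n)
  t0 <- rexp(n, 0.1 * exp(x)); cens <- runif(n, 0, 30)
  r <- c_statistic(x, times = pmin(t0, cens), events = as.integer(t0 <= cens),
                   n_boot = 0)
  expect_gt(r$c, 0.6)  # higher score = higher risk is concordant
})

test_that("half-point rounding is nearest-half with ties away from zero", {
  expect_equal(icipredict:::round_half_away(3.21), 3.0)
  expect_equal(icipredict:::round_half_away(-2.93), -3.0)
  expect_equal(icipredict:::round_half_away(0), 0)
  expect_equal(icipredict:::round_half_away(1.25), 1.5)
  expect_equal(icipredict:::round_half_away(-1.25), -1.5)
  expect_equal(icipredict:::round_half_away(-2.11), -2.0)
  expect_equal(icipredict:::round_half_away(1.15), 1.0)
})

test_that("the reference point score enumerates to the published strata", {
  psm <- reference_point_score()
  expect_equal(psm$range, c(-3.5, 4))
  expect_setequal(psm$value_set, c(-3.5, -1.5, -1, -0.5, 1, 1.5, 2, 4))
  # the two named strata
  worst <- score_patient(psm, data.frame(visceral_mets = TRUE, nlr_ge5 = TRUE,
                                         snv_ge10 = FALSE))
  expect_equal(worst$score, -3.5); expect_equal(worst$predicted, "NCB")
  best <- score_patient(psm, data.frame(visceral_mets = FALSE, nlr_ge5 = FALSE,
                                        snv_ge10 = TRUE))
  expect_equal(best$score, 4); expect_equal(best$predicted, "CB")
  base <- score_patient(psm, data.frame(visceral_mets = FALSE, nlr_ge5 = FALSE,
                                        snv_ge10 = FALSE))
  expect_equal(base$score, 1); expect_equal(base$predicted, "CB")
  # predicted NCB iff visceral metastasis with SNV < 10 (enumeration)
  combos <- expand.grid(v = c(FALSE, TRUE), n = c(FALSE, TRUE), s = c(FALSE, TRUE))
  sc <- score_patient(psm, data.frame(visceral_mets = combos$v, nlr_ge5 = combos$n,
                                      snv_ge10 = combos$s))
  expect_equal(sc$predicted == "NCB", combos$v & !combos$s)
  expect_error(score_patient(psm, data.frame(visceral_mets = TRUE)), "missing")
  expect_error(score_patient(psm, data.frame(visceral_mets = NA, nlr_ge5 = TRUE,
                                             snv_ge10 = TRUE)), "missing")
})

test_that("scores are monotone in favourable flags", {
  psm <- reference_point_score()
  combos <- expand.grid(v = c(FALSE, TRUE), n = c(FALSE, TRUE), s = c(FALSE, TRUE))
  sc <- score_patient(psm, data.frame(visceral_mets = combos$v, nlr_ge5 = combos$n,
                                      snv_ge10 = combos$s))$score
  for (i in seq_len(nrow(combos))) for (j in seq_len(nrow(combos))) {
    favourable_i_le_j <- combos$v[i] >= combos$v[j] && combos$n[i] >= combos$n[j] &&
      combos$s[i] <= combos$s[j]
    if (favourable_i_le_j) expect_lte(sc[i], sc[j])
  }
})

test_that("deriving points from a fitted model rounds coefficients and checks inputs", {
  sim <- simulate_logistic(1500, c(1.1, -2.9, 3.2), prev = c(0.7, 0.45), seed = 95)
  fit <- fit_multivariable(sim$X, sim$y, family = "logistic")
  psm <- derive_point_score(fit, threshold = 0)
  expect_equal(unname(psm$points),
               unname(icipredict:::round_half_away(fit$coefficients[fit$variables])))
  # non-indicator covariates are rejected
  simc <- list(X = data.frame(x1 = rnorm(200)), y = rbinom(200, 1, 0.5))
  fitc <- fit_multivariable(simc$X, simc$y, family = "logistic")
  expect_error(derive_point_score(fitc, threshold = 0), "binary indicator")
})

test_that("Youden threshold selection maximizes sensitivity + specificity", {
  psm <- reference_point_score()
  scores <- c(-3.5, -3.5, -1.5, 1, 1.5, 2, 4, 4)
  y <- c(0, 0, 0, 1, 1, 1, 1, 1)
  thr <- choose_threshold_youden(psm, scores, y)
  expect_equal(thr, -1)  # separates the strata perfectly at >= -1
})

test_that("classification metrics report exact fractions and handle no-positive input", {
  m <- classification_metrics(predicted = rep(c(1, 0), c(22, 2)), outcomes = rep(1, 24))
  expect_equal(m$sensitivity, 22 / 24)
  expect_equal(round(m$sensitivity_pct), 92)
  perfect <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity_pct, 100); expect_equal(perfect$specificity_pct, 100)
  inv <- classification_metrics(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(inv$sensitivity_pct, 0); expect_equal(inv$specificity_pct, 0)
  nopos <- classification_metrics(c(1, 0), c(0, 0))
  expect_true(is.na(nopos$sensitivity))
})

test_that("prognostic index groups by left-closed cutoffs", {
  co <- c(a = 1)
  pi <- prognostic_index(co, data.frame(a = c(-0.5, -0.29, 1.0, 1.54, 2)))
  expect_equal(as.character(pi$group),
               c("low", "intermediate", "intermediate", "high", "high"))
  expect_equal(pi$index, c(-0.5, -0.29, 1.0, 1.54, 2))
  expect_error(prognostic_index(c(a = 1, b = 2), data.frame(a = 1)), "missing features")
  expect_error(prognostic_index(co, data.frame(a = NA_real_)), "missing feature values")
  expect_error(prognostic_index(co, data.frame(a = 1), cutoffs = c(2, 1)))
})

test_that("overall-survival point score weights visceral disease double", {
  all3 <- os_point_score(TRUE, TRUE, TRUE)
  expect_equal(all3$points, 4); expect_equal(as.character(all3$group), "4")
  none <- os_point_score(FALSE, FALSE, FALSE)
  expect_equal(none$points, 0); expect_equal(as.character(none$group), "0-2")
  visc <- os_point_score(TRUE, FALSE, FALSE)
  expect_equal(visc$points, 2); expect_equal(as.character(visc$group), "0-2")
  expect_equal(as.character(os_point_score(TRUE, TRUE, FALSE)$group), "3")
  expect_error(os_point_score(NA, TRUE, TRUE), "present")
})
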