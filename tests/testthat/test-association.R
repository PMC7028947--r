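test_that("Fisher exact reproduces known values and degenerate cases", {
  # symmetric 2x2 with margins 2/2: every table is as probable as observed
  expect_equal(fisher_exact_two_sided(1, 1, 1, 1)$p_value, 1.0)
  expect_equal(round(fisher_exact_two_sided(4, 20, 0, 38)$p_value, 3), 0.019)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "zero")
  m <- matrix(c(4, 0, 20, 38), 2)
  expect_equal(fisher_exact_two_sided(m)$p_value,
               fisher_exact_two_sided(4, 20, 0, 38)$p_value)
})

test_that("Fisher p equals brute-force enumeration and is swap-invariant", {
  set.seed(17)
  for (i in 1:100) {
    t <- random_table(60)
    p <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])$p_value
    expect_equal(p, oracle_fisher_p(t[1], t[2], t[3], t[4]), tolerance = 1e-10)
    # simultaneous row and column swap leaves p unchanged
    p_swap <- fisher_exact_two_sided(t[4], t[3], t[2], t[1])$p_value
    expect_equal(p, p_swap, tolerance = 1e-12)
  }
})

test_that("chi-square test yields the Pearson statistic without correction", {
  r <- chi_square_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r2 <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r2$statistic, 20)  # hand-computed Pearson statistic, df 1
  # 2 x 4 layout accepted
  expect_s3_class(chi_square_test(matrix(c(13, 4, 6, 12, 5, 7, 0, 15), 2)),
                  "ici_test")
  expect_error(chi_square_test(matrix(0, 2, 2)), "zero")
})

test_that("rank tests handle exact and approximate regimes", {
  # complete separation of two triples: U = 0, exact two-sided p = 2/20
  r <- rank_tests(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(r$p_value, 0.1)
  expect_match(r$method, "exact")
  # identical data in both groups: symmetric, p = 1
  r1 <- rank_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r1$p_value, 1)
  # three groups go through Kruskal-Wallis
  r3 <- rank_tests(rnorm(30), rep(c("a", "b", "c"), 10), kind = "kruskal_wallis")
  expect_match(r3$method, "Kruskal")
  expect_error(rank_tests(1:4, c("a", "a", "a", "a")), "2 groups")
  expect_error(rank_tests(rnorm(9), rep(c("a", "b", "c"), 3)), "exactly 2")
})

test_that("one-indicator logistic OR equals the contingency cross-product", {
  # balanced 2x2: 20/10 vs 10/20 -> OR 4
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  r <- univariable_logistic(x, y)
  expect_equal(r$estimate, 4.0, tolerance = 1e-6)
  set.seed(23)
  for (i in 1:20) {
    a <- sample(3:30, 4, replace = TRUE)  # all four cells positive
    x <- rep(c(1, 1, 0, 0), a); y <- rep(c(1, 0, 1, 0), a)
    expect_equal(univariable_logistic(x, y)$estimate,
                 (a[1] * a[4]) / (a[2] * a[3]), tolerance = 1e-6)
  }
})

test_that("logistic under the null has OR near 1 and guards degenerate input", {
  set.seed(31)
  x <- rnorm(2000); y <- rbinom(2000, 1, 0.4)
  r <- univariable_logistic(x, y)
  expect_gt(r$estimate, 0.85); expect_lt(r$estimate, 1.18)
  expect_error(univariable_logistic(rep(1, 10), rbinom(10, 1, 0.5)), "constant")
  expect_error(univariable_logistic(rnorm(10), rep("CB", 10)), "variation")
  # complete separation is flagged, not silent
  sep <- univariable_logistic(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1))
  expect_match(sep$note, "separation")
})

test_that("Cox fit recovers hazard ratios and rejects event-free data", {
  set.seed(41)
  x <- rbinom(2000, 1, 0.5)
  t <- rexp(2000, 0.1 * exp(log(2) * x))
  cens <- rexp(2000, 0.04)
  r <- univariable_cox(x, pmin(t, cens), as.integer(t <= cens))
  expect_gt(r$estimate, 1.8); expect_lt(r$estimate, 2.2)
  expect_error(univariable_cox(x[1:10], t[1:10], rep(0L, 10)), "no events")
})

test_that("Kaplan-Meier and log-rank behave on symmetric and degenerate data", {
  t <- c(1, 2, 3, 4, 5); e <- c(1, 0, 1, 1, 0)
  dup <- km_logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 5))
  expect_equal(dup$test$p_value, 1, tolerance = 1e-12)
  none <- km_logrank(t, rep(0L, 5), c("a", "a", "b", "b", "b"))
  expect_true(is.na(none$test$p_value))
  expect_match(none$test$note, "undefined")
  expect_s3_class(dup$fit, "survfit")
  set.seed(51)
  tt <- c(rexp(500, 0.05), rexp(500, 0.15))
  cc <- runif(1000, 0, 40)
  grp <- rep(c("ref", "risk"), each = 500)
  lr <- km_logrank(pmin(tt, cc), as.integer(tt <= cc), grp)
  expect_lt(lr$test$p_value, 0.001)
})

test_that("univariable screen tabulates and selects at the chosen level", {
  set.seed(61)
  n <- 300
  ft <- data.frame(cb = ifelse(rbinom(n, 1, 0.4) == 1, "CB", "NCB"),
                   strong = NA, noise = rnorm(n))
  ft$strong <- rbinom(n, 1, ifelse(ft$cb == "CB", 0.8, 0.3))
  sc <- univariable_screen(ft, c("strong", "noise"), outcome = "cb")
  expect_true(sc$selected[sc$variable == "strong"])
  expect_false(sc$selected[sc$variable == "noise"])
  sc2 <- univariable_screen(ft, c("strong", "noise"), outcome = "cb",
                            p_adjust = "bonferroni")
  expect_true("p_adjusted" %in% names(sc2))
  expect_error(univariable_screen(ft, "nope"), "unknown variable")
})
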