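test_that("the Lilliefors statistic matches the reference implementation", {
  set.seed(4)
  x <- rnorm(200, 5, 2)
  res <- ks_normality(x, mc_reps = 4000)
  ref <- nortest::lillie.test(x)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  # Monte-Carlo p agrees with the Dallal-Wilkinson approximation loosely
  expect_equal(res$p_value, ref$p.value, tolerance = 0.1)
  # the naive asymptotic p is anti-conservative relative to Lilliefors
  expect_gt(res$p_asymptotic, res$p_value)
})

test_that("normality screening flags degenerate and non-normal samples", {
  res <- ks_normality(rep(3, 20))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 0)
  set.seed(5)
  rej <- vapply(1:100, function(i) {
    ks_normality(rexp(500), mc_reps = 2000)$p_value <= 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.99)
  expect_error(ks_normality(c(1, 2, NA, 4, 5, 6, 7, 8)),
               class = "femcurve_input_error")
})

test_that("group comparisons handle the degenerate paired cases", {
  x <- c(1, 2, 3, 4, 5)
  res <- compare_groups(x, x, "paired_t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- compare_groups(x, x + 1, "paired_t")
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 0)
  expect_error(compare_groups(1, c(1, 2), "independent_t"),
               class = "femcurve_input_error")
  expect_error(compare_groups(x, c(x, 6), "paired_t"),
               class = "femcurve_input_error")
})

test_that("comparisons are anti-symmetric in the group order", {
  set.seed(6)
  x <- rnorm(40, 0, 2); y <- rnorm(35, 1, 2)
  for (mode in c("independent_t", "mann_whitney")) {
    a <- compare_groups(x, y, mode)
    b <- compare_groups(y, x, mode)
    expect_equal(a$p_value, b$p_value)
    if (mode == "independent_t") {
      expect_equal(a$statistic, -b$statistic)
    } else {
      # U statistics of the two orders sum to n1 * n2
      expect_equal(a$statistic + b$statistic, length(x) * length(y))
    }
  }
  # pooled-variance form is the classic Student t
  a <- compare_groups(x, y, "independent_t")
  expect_equal(a$statistic, unname(t.test(x, y, var.equal = TRUE)$statistic))
  w <- compare_groups(x, y, "independent_t", var_equal = FALSE)
  expect_equal(w$statistic, unname(t.test(x, y)$statistic))
})

test_that("the correlation matrix matches a hand Sigma-formula computation", {
  tab <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  pm <- pearson_matrix(tab, c("x", "y"))
  # frozen from the closed form: r = S_xy / sqrt(S_xx S_yy) = 8/10
  expect_equal(pm$r["x", "y"], 0.8)
  expect_equal(pm$r["y", "x"], 0.8)
  expect_equal(diag(pm$r), c(x = 1, y = 1))
  expect_equal(pm$p["x", "y"], cor.test(tab$x, tab$y)$p.value)
  td <- tidy(pm)
  expect_equal(nrow(td), 1L)
  expect_equal(td$r, 0.8)
})

test_that("correlations are affine-invariant and flag constant columns", {
  set.seed(8)
  tab <- tibble::tibble(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  p1 <- pearson_matrix(tab, c("a", "b", "c"))
  tab2 <- dplyr::mutate(tab, a = 3 * a - 7, b = -0.5 * b + 2)
  p2 <- pearson_matrix(tab2, c("a", "b", "c"))
  expect_equal(abs(p1$r), abs(p2$r), tolerance = 1e-12)
  tab$k <- 5
  pk <- pearson_matrix(tab, c("a", "k"))
  expect_true(is.na(pk$r["a", "k"]))
})

test_that("variance inflation follows the closed form 1 / (1 - r^2)", {
  n <- 500
  set.seed(9)
  z <- rnorm(n)
  tab <- tibble::tibble(
    x1 = z + rnorm(n, 0, sqrt(1 / 0.81 - 1)), # corr(x1, z) ~ 0.9
    x2 = z,
    x3 = rnorm(n)
  )
  # two-candidate case reduces exactly to 1 / (1 - cor^2)
  v2 <- vif(tab, c("x1", "x2"))
  r2 <- cor(tab$x1, tab$x2)^2
  expect_equal(v2$vif[1], 1 / (1 - r2), tolerance = 1e-10)
  expect_equal(v2$vif[1], 1 / (1 - 0.81), tolerance = 0.5)
  v <- vif(tab, c("x1", "x2", "x3"))
  expect_lt(abs(v$vif[3] - 1), 0.05)
  # independent oracle: car computes the same VIFs from the full model
  tab$y <- rnorm(n)
  ref <- car::vif(lm(y ~ x1 + x2 + x3, data = tab))
  expect_equal(v$vif, unname(ref), tolerance = 1e-6)
  # perfect collinearity
  tab$dup <- tab$x2
  vd <- vif(tab, c("x2", "dup"))
  expect_true(all(is.infinite(vd$vif)))
})

test_that("stepwise limits reduce to full-model OLS and intercept-only", {
  set.seed(10)
  tab <- tibble::tibble(x1 = rnorm(80), x2 = rnorm(80), x3 = rnorm(80))
  tab$y <- 1 + 2 * tab$x1 - tab$x2 + rnorm(80)
  full <- stepwise_regression(tab, "y", c("x1", "x2", "x3"),
                              p_enter = 1, p_remove = 1)
  expect_setequal(full$terms, c("x1", "x2", "x3"))
  ref <- lm(y ~ x1 + x2 + x3, data = tab)
  expect_equal(sort(full$coefficients), sort(coef(ref)), tolerance = 1e-12)
  none <- stepwise_regression(tab, "y", c("x1", "x2", "x3"), p_enter = 0)
  expect_length(none$terms, 0)
  expect_equal(unname(none$coefficients), mean(tab$y))
})

test_that("stepwise rarely admits pure noise and logs its steps", {
  hits <- 0L
  for (r in 1:100) {
    set.seed(600 + r)
    tab <- tibble::tibble(x = rnorm(200), y = rnorm(200))
    fit <- stepwise_regression(tab, "y", "x")
    hits <- hits + (length(fit$terms) == 0L)
  }
  expect_gte(hits / 100, 0.90)

  set.seed(12)
  tab <- tibble::tibble(x1 = rnorm(300), x2 = rnorm(300))
  tab$y <- 2 * tab$x1 + rnorm(300)
  fit <- stepwise_regression(tab, "y", c("x1", "x2"))
  expect_identical(fit$terms, "x1")
  expect_identical(fit$steps$action[1], "enter")
  g <- glance(fit)
  expect_equal(g$n_terms, 1L)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("stepwise agrees with an exhaustive best-subset oracle", {
  # strong-signal design: the oracle picks the BIC-best of all 16 subsets
  agree <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    set.seed(700 + r)
    n <- 300
    tab <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
    tab$y <- 3 * tab$a - 2 * tab$b + 1.5 * tab$c + rnorm(n)
    fit <- stepwise_regression(tab, "y", c("a", "b", "c", "d"))
    cand <- c("a", "b", "c", "d")
    best <- NULL
    for (k in 0:4) for (sub in combn(cand, k, simplify = FALSE)) {
      fml <- if (k == 0) y ~ 1 else stats::reformulate(sub, "y")
      bic <- stats::BIC(lm(fml, data = tab))
      if (is.null(best) || bic < best$bic) best <- list(bic = bic, terms = sub)
    }
    agree <- agree + setequal(fit$terms, best$terms)
  }
  expect_gte(agree / n_rep, 0.95)
})

test_that("two-means sample sizes match the closed form and a power oracle", {
  res <- sample_size_two_means(sd = 20, diff = 10)
  # closed form: 2 * (1.959964 + 0.841621)^2 * 4 = 62.79 -> 63
  expect_equal(res$n_normal_approx, 63)
  # t-refined value agrees with the standard power calculator
  expect_equal(res$n_per_group,
               ceiling(power.t.test(delta = 10, sd = 20, power = 0.8)$n))
  big <- sample_size_two_means(sd = 2, diff = 20)
  expect_equal(big$n_per_group, 2)
  expect_error(sample_size_two_means(alpha = 1, power = 0.8, sd = 20, diff = 10),
               class = "femcurve_parameter_error")
})
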