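fc_env <- new.env(parent = emptyenv())

# Lilliefors statistic: one-sample K-S distance between the empirical cdf
# and a normal with the sample's own mean and SD
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean(x), sd(x))
  i <- seq_len(n)
  max(i / n - z, z - (i - 1) / n)
}

# Monte-Carlo null distribution of the Lilliefors statistic; depends only
# on n, so it is simulated once and cached for the session
ks_null_table <- function(n, reps, seed) {
  key <- paste(n, reps, seed, sep = "_")
  if (!is.null(fc_env[[key]])) return(fc_env[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tab <- vapply(seq_len(reps), function(i) lilliefors_stat(rnorm(n)), numeric(1))
  fc_env[[key]] <- tab
  tab
}

# asymptotic Kolmogorov distribution tail (naive p, parameters treated as
# known; anti-conservative when they are estimated, reported for reference)
ks_asymptotic_p <- function(D, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Kolmogorov-Smirnov normality screen (Lilliefors corrected)
#'
#' One-sample K-S test of normality with mean and SD estimated from the
#' sample. The primary p-value uses the Lilliefors-corrected null
#' distribution, obtained by Monte Carlo (`mc_reps` normal samples of the
#' same size, seeded and cached per sample size); the naive asymptotic K-S
#' p-value (anti-conservative for estimated parameters) is reported
#' alongside for reference.
#'
#' @param x numeric vector, n >= 8, no missing values.
#' @param mc_reps Monte-Carlo replicates for the null distribution.
#' @param mc_seed seed of the null-table simulation (results are invariant
#'   to the caller's RNG state).
#' @return One-row tibble: `test`, `statistic`, `p_value`,
#'   `p_asymptotic`, `n`, `degenerate`.
#' @export
ks_normality <- function(x, mc_reps = 10000L, mc_seed = 1914L) {
  if (anyNA(x) || length(x) < 8L) {
    fc_abort("x must have >= 8 non-missing values", "femcurve_input_error")
  }
  if (sd(x) < .Machine$double.eps) {
    return(tibble::tibble(test = "ks_lilliefors", statistic = NA_real_,
                          p_value = 0, p_asymptotic = 0,
                          n = length(x), degenerate = TRUE))
  }
  D <- lilliefors_stat(x)
  null_tab <- ks_null_table(length(x), mc_reps, mc_seed)
  p_mc <- (1 + sum(null_tab >= D)) / (mc_reps + 1)
  tibble::tibble(test = "ks_lilliefors", statistic = D, p_value = p_mc,
                 p_asymptotic = ks_asymptotic_p(D, length(x)),
                 n = length(x), degenerate = FALSE)
}

#' Two-group comparisons
#'
#' Two-sided comparison of two samples: classic pooled-variance Student's
#' t-test for independent groups (set `var_equal = FALSE` for the Welch
#' form), paired t-test for laterality comparisons, or the Mann-Whitney U
#' test for non-normal data. Paired differences that are constant and
#' non-zero are flagged degenerate (infinite t); identical paired samples
#' give t = 0, p = 1.
#'
#' @param x,y numeric vectors (equal length for the paired mode).
#' @param mode `"independent_t"`, `"paired_t"` or `"mann_whitney"`.
#' @param var_equal pooled-variance form for the independent t-test.
#' @return One-row tibble: `test`, `statistic`, `p_value`, `n_x`, `n_y`,
#'   `estimate` (mean difference or location shift direction),
#'   `degenerate`.
#' @export
compare_groups <- function(x, y,
                           mode = c("independent_t", "paired_t", "mann_whitney"),
                           var_equal = TRUE) {
  mode <- match.arg(mode)
  if (length(x) < 2L || length(y) < 2L) {
    fc_abort("each group needs at least 2 observations", "femcurve_input_error")
  }
  if (mode == "paired_t") {
    if (length(x) != length(y)) {
      fc_abort("paired comparison needs equal-length samples",
               "femcurve_input_error")
    }
    d <- x - y
    if (sd(d) < .Machine$double.eps) {
      if (abs(mean(d)) < .Machine$double.eps) {
        return(tibble::tibble(test = "paired_t", statistic = 0, p_value = 1,
                              n_x = length(x), n_y = length(y),
                              estimate = 0, degenerate = FALSE))
      }
      return(tibble::tibble(test = "paired_t",
                            statistic = sign(mean(d)) * Inf, p_value = 0,
                            n_x = length(x), n_y = length(y),
                            estimate = mean(d), degenerate = TRUE))
    }
    ht <- t.test(x, y, paired = TRUE)
    return(tibble::tibble(test = "paired_t",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, n_x = length(x),
                          n_y = length(y), estimate = unname(ht$estimate),
                          degenerate = FALSE))
  }
  if (mode == "independent_t") {
    ht <- t.test(x, y, var.equal = var_equal)
    return(tibble::tibble(
      test = if (var_equal) "student_t" else "welch_t",
      statistic = unname(ht$statistic), p_value = ht$p.value,
      n_x = length(x), n_y = length(y),
      estimate = unname(ht$estimate[1] - ht$estimate[2]), degenerate = FALSE))
  }
  ht <- suppressWarnings(wilcox.test(x, y))
  tibble::tibble(test = "mann_whitney", statistic = unname(ht$statistic),
                 p_value = ht$p.value, n_x = length(x), n_y = length(y),
                 estimate = median(x) - median(y), degenerate = FALSE)
}

#' Pearson correlation matrix
#'
#' Pairwise Pearson correlations between the selected cohort variables,
#' with two-sided p-values from the t transform. The print method mirrors
#' the conventional layout with r above the diagonal and p below.
#'
#' @param table cohort data frame.
#' @param variables character vector of numeric column names.
#' @return A `pearson_matrix`: list with matrices `r` and `p`, plus `n`.
#' @export
pearson_matrix <- function(table, variables) {
  stopifnot(all(variables %in% names(table)))
  x <- as.data.frame(table)[variables]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) {
    fc_abort("need at least 3 complete rows", "femcurve_input_error")
  }
  k <- length(variables)
  r <- matrix(1, k, k, dimnames = list(variables, variables))
  p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  degenerate <- vapply(x, function(col) sd(col) < .Machine$double.eps,
                       logical(1))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      if (degenerate[i] || degenerate[j]) {
        r[i, j] <- NA_real_
        next
      }
      ct <- cor.test(x[[i]], x[[j]])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nrow(x)), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  k <- ncol(x$r)
  disp <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      disp[i, j] <- if (i == j) "1"
      else if (j > i) formatC(x$r[i, j], digits = digits, format = "f")
      else paste0("p=", formatC(x$p[i, j], digits = digits, format = "g"))
    }
  }
  cat(sprintf("Pearson correlations (n = %d); r above diagonal, p below\n", x$n))
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
tidy.pearson_matrix <- function(x, ...) {
  vars <- rownames(x$r)
  out <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  out <- out[match(out$var1, vars) < match(out$var2, vars), ]
  tibble::tibble(var1 = out$var1, var2 = out$var2,
                 r = x$r[cbind(out$var1, out$var2)],
                 p_value = x$p[cbind(out$var1, out$var2)],
                 n = x$n)
}

#' Variance-inflation factors
#'
#' Collinearity screen for a candidate predictor set: each candidate is
#' regressed on the others and its VIF is `1 / (1 - R^2)`. Candidates
#' involved in a (numerically) perfect linear dependence get `Inf`. A
#' `flag` marks VIF > 10, the conventional screening threshold.
#'
#' @param table cohort data frame.
#' @param candidates character vector of predictor column names.
#' @return Tibble with `term`, `vif`, `flag`.
#' @export
vif <- function(table, candidates) {
  stopifnot(all(candidates %in% names(table)))
  x <- as.data.frame(table)[candidates]
  x <- x[complete.cases(x), , drop = FALSE]
  out <- vapply(candidates, function(v) {
    if (length(candidates) == 1L) return(1)
    fit <- lm(stats::reformulate(setdiff(candidates, v), response = v),
              data = x)
    # a perfectly collinear candidate triggers lm's "perfect fit" warning;
    # that is exactly the case the Inf flag reports
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = candidates, vif = unname(out), flag = out > 10)
}

#' Stepwise linear regression with p-to-enter / p-to-remove
#'
#' Classic bidirectional stepwise selection as implemented in clinical
#' statistics packages: at each step the candidate with the smallest
#' partial-F p-value enters if it is at most `p_enter`; then any included
#' term whose p-value has risen to `p_remove` or above is removed; the
#' model is refit by ordinary least squares after every change and the
#' procedure stops when no term enters or leaves. With one predictor the
#' partial F equals the squared coefficient t, so coefficient p-values are
#' used throughout.
#'
#' @param table cohort data frame (rows >= candidates + 10).
#' @param response response column name.
#' @param candidates character vector of candidate predictor names.
#' @param p_enter entry threshold (default 0.05).
#' @param p_remove removal threshold (default 0.10).
#' @return A `fem_stepwise` object: `terms` (in entry order),
#'   `coefficients` (named, including `(Intercept)`), `r_squared`,
#'   `steps` (tibble log of entries/removals with p), `model` (the final
#'   `lm`), `n`. Supports [tidy()] and [glance()].
#' @export
stepwise_regression <- function(table, response, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(all(c(response, candidates) %in% names(table)))
  x <- as.data.frame(table)[c(response, candidates)]
  x <- x[complete.cases(x), , drop = FALSE]
  if (nrow(x) < length(candidates) + 10L) {
    fc_abort("need at least candidates + 10 rows", "femcurve_input_error")
  }
  included <- character(0)
  steps <- list()
  fit_with <- function(terms) {
    fml <- if (length(terms) == 0) stats::reformulate("1", response = response)
    else stats::reformulate(terms, response = response)
    lm(fml, data = x)
  }
  coef_p <- function(fit) {
    cf <- summary(fit)$coefficients
    setNames(cf[, 4], rownames(cf))
  }
  repeat {
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool) > 0 && p_enter > 0) {
      entry_p <- vapply(pool, function(v) {
        p <- coef_p(fit_with(c(included, v)))
        unname(p[v])
      }, numeric(1))
      entry_p[is.na(entry_p)] <- 1 # aliased candidate cannot enter
      best <- which.min(entry_p)
      if (entry_p[best] <= p_enter) {
        included <- c(included, pool[best])
        steps[[length(steps) + 1L]] <-
          data.frame(step = length(steps) + 1L, action = "enter",
                     term = pool[best], p = entry_p[best])
        changed <- TRUE
      }
    }
    repeat {
      if (length(included) == 0) break
      p <- coef_p(fit_with(included))[included]
      worst <- which.max(p)
      if (!is.na(p[worst]) && p[worst] >= p_remove) {
        steps[[length(steps) + 1L]] <-
          data.frame(step = length(steps) + 1L, action = "remove",
                     term = included[worst], p = unname(p[worst]))
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- fit_with(included)
  structure(list(
    response = response,
    terms = included,
    coefficients = coef(fit),
    r_squared = summary(fit)$r.squared,
    steps = tibble::as_tibble(do.call(rbind, steps) %||%
                                data.frame(step = integer(), action = character(),
                                           term = character(), p = numeric())),
    model = fit,
    n = nrow(x)
  ), class = "fem_stepwise")
}

#' @export
print.fem_stepwise <- function(x, ...) {
  cat(sprintf("<fem_stepwise> %s ~ %s\n", x$response,
              if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"))
  eq <- sprintf("%.4g", x$coefficients[["(Intercept)"]])
  for (tm in x$terms) {
    eq <- paste0(eq, sprintf(" %+.4g x %s", x$coefficients[[tm]], tm))
  }
  cat("  ", x$response, " = ", eq, "\n", sep = "")
  cat(sprintf("  R^2 = %.3f, n = %d, %d selection steps\n",
              x$r_squared, x$n, nrow(x$steps)))
  invisible(x)
}

#' @export
tidy.fem_stepwise <- function(x, ...) {
  cf <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
}

#' @export
glance.fem_stepwise <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, n = x$n, n_terms = length(x$terms),
                 n_steps = nrow(x$steps))
}

#' @export
autoplot.fem_stepwise <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", ]
  df$lo <- df$estimate - 1.96 * df$std.error
  df$hi <- df$estimate + 1.96 * df$std.error
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::labs(x = "coefficient (95% CI)", y = NULL,
                  title = paste("Stepwise model for", object$response))
}

#' Sample size for comparing two means
#'
#' Per-group sample size for a two-sided two-sample comparison of means:
#' the normal-approximation closed form
#' `n = ceil(2 * (z_{1-alpha/2} + z_power)^2 * (sd / diff)^2)` and an
#' iterative refinement using the exact noncentral-t power of the pooled
#' t-test. Both are reported; `n_per_group` is the t-refined value, which
#' is what a power calculator returns.
#'
#' @param alpha two-sided type-I error (0, 1).
#' @param power target power (0, 1).
#' @param sd common standard deviation.
#' @param diff difference in means to detect.
#' @return One-row tibble: `n_per_group` (t-refined), `n_normal_approx`,
#'   `alpha`, `power`, `sd`, `diff`.
#' @export
sample_size_two_means <- function(alpha = 0.05, power = 0.80, sd, diff) {
  check_number(alpha, "alpha", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(power, "power", lower = 0, upper = 1,
               closed_lower = FALSE, closed_upper = FALSE)
  check_number(sd, "sd", lower = 0, closed_lower = FALSE)
  check_number(diff, "diff", lower = 0, closed_lower = FALSE)
  n_normal <- max(2, ceiling(2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 *
                               (sd / diff)^2))
  t_power <- function(n) {
    df <- 2 * n - 2
    ncp <- diff / (sd * sqrt(2 / n))
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  }
  n_t <- max(2, n_normal - 2)
  while (t_power(n_t) < power) n_t <- n_t + 1
  tibble::tibble(n_per_group = n_t, n_normal_approx = n_normal,
                 alpha = alpha, power = power, sd = sd, diff = diff)
}
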