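## Statistical kernels: paired t, normality tests (Shapiro-Wilk and a
## Lilliefors-corrected Kolmogorov-Smirnov), one-way ANOVA, Kruskal-Wallis
## with tie correction, Tukey HSD post hoc, and OLS with 95% mean-response
## bands. All tests are two-sided at alpha = 0.05. Results come back as
## uniform `test_result` records so the pipeline can serialize them.

test_result <- function(test_name, statistic, df, p_value, n, extra = NULL) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value), n = unname(n)),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (n = %s)\n",
              x$test_name, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Paired two-sided t-test
#'
#' Student t on the per-subject differences, df = n - 1. Degenerate cases
#' are defined rather than erroring: identical pairs give statistic 0,
#' p = 1; zero-variance differences with a nonzero mean give p = 0 with a
#' warning.
#'
#' @param x,y paired samples of equal length (>= 2).
#' @return a `test_result`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples of unequal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(test_result("paired t-test", 0, n - 1, 1, n))
    }
    warning("zero-variance nonzero-mean differences: p -> 0")
    return(test_result("paired t-test", sign(mean(d)) * Inf, n - 1, 0, n))
  }
  tt <- t.test(x, y, paired = TRUE)
  test_result("paired t-test", tt$statistic, tt$parameter, tt$p.value, n,
              extra = list(mean_diff = mean(d)))
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation (the standard W test), n in 3..5000.
#'
#' @param x numeric sample.
#' @return a `test_result`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (sd(x) == 0) stop("constant sample", call. = FALSE)
  s <- shapiro.test(x)
  test_result("Shapiro-Wilk", s$statistic, NA_real_, s$p.value, length(x))
}

# cached Monte-Carlo null distributions of the Lilliefors D statistic,
# keyed by sample size; generated with an internal fixed seed so p-values
# are deterministic and independent of the caller's RNG state.
.lilliefors_cache <- new.env(parent = emptyenv())

.lilliefors_D <- function(x) {
  n <- length(x)
  z <- (sort(x) - mean(x)) / sd(x)
  u <- pnorm(z)
  i <- seq_len(n)
  max(max(i / n - u), max(u - (i - 1) / n))
}

.lilliefors_null <- function(n, B = 20000) {
  key <- as.character(n)
  hit <- .lilliefors_cache[[key]]
  if (!is.null(hit)) return(hit)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(20260911 %% .Machine$integer.max)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
    else rm(".Random.seed", envir = .GlobalEnv)
  })
  m <- matrix(rnorm(n * B), nrow = B)
  m <- t(apply(m, 1, sort))
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (n - 1))
  u <- pnorm((m - mu) / s)
  i <- matrix(seq_len(n) / n, nrow = B, ncol = n, byrow = TRUE)
  D0 <- pmax(apply(i - u, 1, max), apply(u - (i - 1 / n), 1, max))
  D0 <- sort(D0)
  .lilliefors_cache[[key]] <- D0
  D0
}

#' Kolmogorov-Smirnov normality test with Lilliefors correction
#'
#' D statistic against a normal with moments estimated from the sample;
#' the p-value accounts for the estimation (Lilliefors correction) via a
#' seeded Monte-Carlo null distribution of D, cached per sample size.
#'
#' @param x numeric sample (n >= 5).
#' @param B Monte-Carlo replicates for the null distribution.
#' @return a `test_result`.
#' @export
ks_normality <- function(x, B = 20000) {
  n <- length(x)
  if (n < 5) stop("Lilliefors KS needs n >= 5", call. = FALSE)
  if (sd(x) == 0) stop("constant sample", call. = FALSE)
  D <- .lilliefors_D(x)
  D0 <- .lilliefors_null(n, B)
  p <- (1 + sum(D0 >= D)) / (length(D0) + 1)
  test_result("Lilliefors KS", D, NA_real_, p, n)
}

.as_group_list <- function(groups) {
  if (is.data.frame(groups)) stop("pass a list of numeric vectors")
  if (!is.list(groups)) stop("groups must be a list of samples")
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test, df = (k - 1, N - k). Groups identical
#' in mean give F = 0; if additionally the within-group variance is zero
#' the statistic is defined as 0 with p = 1.
#'
#' @param groups list of numeric samples (each n >= 2).
#' @return a `test_result`.
#' @export
anova_oneway <- function(groups) {
  g <- .as_group_list(groups)
  k <- length(g)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(g) < 2)) stop("each group needs n >= 2", call. = FALSE)
  n <- lengths(g)
  N <- sum(n)
  gm <- mean(unlist(g))
  ssb <- sum(n * (vapply(g, mean, 0) - gm)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0 && ssb == 0) {
    return(test_result("one-way ANOVA", 0, c(df1, df2), 1, n))
  }
  if (ssw == 0) {
    warning("zero within-group variance: p -> 0")
    return(test_result("one-way ANOVA", Inf, c(df1, df2), 0, n))
  }
  f <- (ssb / df1) / (ssw / df2)
  test_result("one-way ANOVA", f, c(df1, df2), pf(f, df1, df2,
                                                  lower.tail = FALSE), n)
}

#' Kruskal-Wallis rank test
#'
#' H with tie correction; p from the chi-square approximation with k - 1
#' df. All-tied data give H = 0, p = 1.
#'
#' @param groups list of numeric samples.
#' @return a `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  g <- .as_group_list(groups)
  k <- length(g)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(g) < 1) || sum(lengths(g)) < 5) {
    stop("need n >= 1 per group and total N >= 5", call. = FALSE)
  }
  x <- unlist(g)
  if (diff(range(x)) == 0) {
    return(test_result("Kruskal-Wallis", 0, k - 1, 1, lengths(g)))
  }
  kt <- kruskal.test(g)
  test_result("Kruskal-Wallis", kt$statistic, kt$parameter, kt$p.value,
              lengths(g))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range pairwise comparisons at family alpha = 0.05, the
#' standard companion to a significant one-way ANOVA.
#'
#' @param groups named list of numeric samples.
#' @return a data frame with one row per pair: `pair`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `flagged` (p_adj < 0.05).
#' @export
tukey_hsd <- function(groups) {
  g <- .as_group_list(groups)
  if (is.null(names(g))) names(g) <- paste0("g", seq_along(g))
  if (length(g) < 2 || any(lengths(g) < 2)) {
    stop("need >= 2 groups of n >= 2", call. = FALSE)
  }
  df <- data.frame(
    y = unlist(g),
    grp = factor(rep(names(g), lengths(g)), levels = names(g))
  )
  tk <- TukeyHSD(aov(y ~ grp, data = df))$grp
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  out$flagged <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Ordinary least squares with 95% mean-response band
#'
#' @param x predictor; requires n >= 3 and nonzero variance.
#' @param y response.
#' @param band_x x values at which to evaluate the confidence band
#'   (defaults to the sorted observed x).
#' @return a `regression_result` list: `slope`, `slope_se`, `intercept`,
#'   `r_squared`, `ci_band` (data frame x/fit/lwr/upr), `n`, `residual_sd`.
#' @export
ols <- function(x, y, band_x = sort(unique(x))) {
  if (length(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (var(x) == 0) stop("zero predictor variance", call. = FALSE)
  fit <- lm(y ~ x)
  pr <- predict(fit, newdata = data.frame(x = band_x),
                interval = "confidence", level = 0.95)
  structure(list(
    slope = unname(coef(fit)[2]),
    slope_se = unname(summary(fit)$coefficients[2, "Std. Error"]),
    intercept = unname(coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    ci_band = data.frame(x = band_x, fit = pr[, "fit"],
                         lwr = pr[, "lwr"], upr = pr[, "upr"]),
    n = length(x),
    residual_sd = summary(fit)$sigma
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope %.4g, intercept %.4g, R^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Normality gate used by the pipeline
#'
#' A dataset passes only if both the Shapiro-Wilk and the Lilliefors KS
#' p-values exceed `alpha` in every group; the pipeline's parametric branch
#' requires all compared groups to pass.
#'
#' @param groups list of numeric samples.
#' @param alpha gate level.
#' @return list with `normal` (logical), and per-group `sw_p`, `ks_p`.
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  g <- .as_group_list(groups)
  sw <- vapply(g, function(x) shapiro_wilk(x)$p_value, 0)
  ks <- vapply(g, function(x) ks_normality(x)$p_value, 0)
  list(normal = all(sw > alpha) && all(ks > alpha), sw_p = sw, ks_p = ks,
       alpha = alpha)
}
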