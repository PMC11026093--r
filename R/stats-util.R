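#' Shared statistical kernels
#'
#' Thin, validated wrappers over the base R implementations used throughout
#' the pipeline: pooled two-sample t, Welch's t, Benjamini-Hochberg FDR,
#' Pearson correlation and simple OLS. All tests are two-sided.
#'
#' @param xs,ys numeric vectors (each of length >= 2 for the t tests).
#' @return `two_sample_t`/`welch_t`: one-row tibble with `t`, `p`, `df`, and
#'   `degenerate` (TRUE when both groups have zero variance).
#' @name stats_util
NULL

#' @rdname stats_util
#' @export
two_sample_t <- function(xs, ys) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  if (length(xs) < 2L || length(ys) < 2L) stop("each group needs n >= 2")
  if (var(xs) == 0 && var(ys) == 0) {
    eq <- mean(xs) == mean(ys)
    return(tibble::tibble(t = if (eq) 0 else sign(mean(xs) - mean(ys)) * Inf,
                          p = if (eq) 1 else 0,
                          df = length(xs) + length(ys) - 2,
                          degenerate = TRUE))
  }
  ht <- t.test(xs, ys, var.equal = TRUE)
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter), degenerate = FALSE)
}

#' @rdname stats_util
#' @export
welch_t <- function(xs, ys) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  if (length(xs) < 2L || length(ys) < 2L) stop("each group needs n >= 2")
  if (var(xs) == 0 && var(ys) == 0) {
    eq <- mean(xs) == mean(ys)
    return(tibble::tibble(t = if (eq) 0 else sign(mean(xs) - mean(ys)) * Inf,
                          p = if (eq) 1 else 0,
                          df = NA_real_, degenerate = TRUE))
  }
  ht <- t.test(xs, ys, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter), degenerate = FALSE)
}

#' @rdname stats_util
#' @param pvalues numeric vector of p-values.
#' @return `fdr_bh`: adjusted p-values (Benjamini-Hochberg step-up,
#'   monotone, each <= 1), in the input order.
#' @export
fdr_bh <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' @rdname stats_util
#' @return `pearson`: the correlation coefficient.
#' @export
pearson <- function(xs, ys) {
  ok <- complete.cases(xs, ys)
  cor(xs[ok], ys[ok])
}

#' @rdname stats_util
#' @return `ols`: one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_slope`.
#' @export
ols <- function(xs, ys) {
  ok <- complete.cases(xs, ys)
  fit <- lm(ys[ok] ~ xs[ok])
  s <- suppressWarnings(summary(fit))   # exact fits warn inside summary.lm
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    p_slope = if (nrow(s$coefficients) < 2L) NA_real_ else s$coefficients[2, 4]
  )
}
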