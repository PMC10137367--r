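#' Two-way ANOVA mean squares for a complete ratings matrix
#'
#' Decomposes a subjects x raters matrix into the row (subject), column
#' (rater) and residual mean squares of the crossed two-way model that
#' underlies the absolute-agreement intraclass correlation. The sums of
#' squares satisfy SST = SSR + SSC + SSE exactly.
#'
#' @param m numeric matrix, subjects in rows, raters in columns, no missing
#'   entries, at least 2 rows and 2 columns.
#' @return list with `MSR`, `MSC`, `MSE`, `n` (subjects), `k` (raters).
#' @examples
#' anova_mean_squares(matrix(1:6, nrow = 3, byrow = TRUE))
#' @export
anova_mean_squares <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ratings matrix contains missing entries", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop(sprintf("insufficient data: need >= 2 subjects and >= 2 raters (got %d x %d)",
                 n, k), call. = FALSE)
  }
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  list(MSR = ssr / (n - 1),
       MSC = ssc / (k - 1),
       MSE = sse / ((n - 1) * (k - 1)),
       n = n, k = k)
}

#' Single-rating intraclass correlation, two-way random, absolute agreement
#'
#' ICC(A,1): the correlation between single ratings of the same subject by
#' randomly drawn raters, penalising systematic rater offsets. Computed from
#' the two-way ANOVA mean squares as
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#'
#' @inheritParams anova_mean_squares
#' @return the ICC, a number in \[-1, 1\].
#' @export
icc_a1 <- function(m) {
  ms <- anova_mean_squares(m)
  denom <- ms$MSR + (ms$k - 1) * ms$MSE + (ms$k / ms$n) * (ms$MSC - ms$MSE)
  if (abs(denom) < .Machine$double.eps * 100) {
    stop("degenerate data: no variance anywhere, ICC undefined", call. = FALSE)
  }
  (ms$MSR - ms$MSE) / denom
}

#' Qualitative interpretation of an ICC value
#'
#' Bins: poor (< 0.50), moderate (0.50-0.75), good (0.75-0.90),
#' excellent (>= 0.90).
#'
#' @param icc finite numeric (vectorised).
#' @return character vector of classifications.
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc))) stop("`icc` must be finite", call. = FALSE)
  cut(icc, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE)
}

#' Percentile bootstrap confidence interval for a matrix statistic
#'
#' Resamples subjects (matrix rows) with replacement, recomputes the
#' statistic, and returns the percentile bounds. When rows come in blocks
#' that must move together (e.g. the x- and y-rows of one patient case),
#' supply `blocks`; whole blocks are then resampled.
#'
#' @param m numeric matrix (subjects x raters).
#' @param statistic function of a matrix returning one number.
#' @param n_boot number of bootstrap replicates (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the interval is deterministic given the seed.
#' @param blocks optional vector (length `nrow(m)`) identifying resampling
#'   blocks; `NULL` means every row is its own block.
#' @return named numeric `c(low, high)` with attribute `n_failed`.
#' @export
bootstrap_ci <- function(m, statistic, n_boot = 500L, level = 0.95,
                         seed = 1L, blocks = NULL) {
  m <- as.matrix(m)
  stopifnot_scalar_number(n_boot, "n_boot", min = 1)
  stopifnot_scalar_number(level, "level", min = 0, strict_min = TRUE)
  if (level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  if (is.null(blocks)) blocks <- seq_len(nrow(m))
  if (length(blocks) != nrow(m)) {
    stop("`blocks` must have one entry per matrix row", call. = FALSE)
  }
  ublocks <- unique(blocks)
  rows_by_block <- split(seq_len(nrow(m)), factor(blocks, levels = ublocks))

  stats_boot <- with_seed(seed, {
    draws <- matrix(sample.int(length(ublocks),
                               length(ublocks) * n_boot, replace = TRUE),
                    nrow = n_boot)
    apply(draws, 1L, function(ix) {
      rows <- unlist(rows_by_block[ix], use.names = FALSE)
      tryCatch(statistic(m[rows, , drop = FALSE]),
               error = function(e) NA_real_)
    })
  })
  n_failed <- sum(is.na(stats_boot))
  if (n_failed > n_boot / 2) {
    stop(sprintf("bootstrap failure: statistic failed on %d of %d resamples",
                 n_failed, n_boot), call. = FALSE)
  }
  alpha <- (1 - level) / 2
  ci <- stats::quantile(stats_boot, probs = c(alpha, 1 - alpha),
                        na.rm = TRUE, names = FALSE)
  structure(c(low = ci[1], high = ci[2]), n_failed = n_failed)
}

#' ICC with bootstrap confidence interval and classification
#'
#' Convenience wrapper bundling [icc_a1()], [bootstrap_ci()] and
#' [classify_icc()] into the per-row reliability result.
#'
#' @inheritParams bootstrap_ci
#' @return list of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_raters`, `n_boot`, `classification`.
#' @export
icc_with_ci <- function(m, n_boot = 500L, level = 0.95, seed = 1L,
                        blocks = NULL) {
  m <- as.matrix(m)
  icc <- icc_a1(m)
  ci <- bootstrap_ci(m, icc_a1, n_boot = n_boot, level = level, seed = seed,
                     blocks = blocks)
  structure(
    list(icc = icc, ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
         n_subjects = nrow(m), n_raters = ncol(m), n_boot = as.integer(n_boot),
         classification = as.character(classify_icc(icc))),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (95%% CI %.3f-%.3f), %s; n = %d subjects x %d raters\n",
              x$icc, x$ci_low, x$ci_high, x$classification,
              x$n_subjects, x$n_raters))
  invisible(x)
}
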