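# In-code fixtures: tiny annotation sets built deterministically.

# A complete rectangular annotation table: every rater labels every
# case/view with all 20 points. Coordinates are a fixed stacked-rectangle
# layout plus an optional per-rater pixel offset (to make raters distinct).
make_annotation_df <- function(case_ids = c("c1", "c2"),
                               views = "AP",
                               rater_ids = c("r1", "r2"),
                               rater_offset_px = NULL) {
  base <- expand.grid(point_id = c("p1", "p2", "p3", "p4"),
                      vertebra = paste0("L", 1:5),
                      view = views, case_id = case_ids,
                      rater_id = rater_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  v_idx <- match(base$vertebra, paste0("L", 1:5)) - 1L
  left <- base$point_id %in% c("p1", "p3")
  upper <- base$point_id %in% c("p1", "p2")
  base$x_px <- 800 + ifelse(left, -140, 140) +
    10 * (match(base$case_id, unique(base$case_id)) - 1L)
  base$y_px <- 500 + v_idx * 240 + ifelse(upper, -90, 90)
  if (!is.null(rater_offset_px)) {
    off <- rater_offset_px[base$rater_id]
    base$x_px <- base$x_px + off
    base$y_px <- base$y_px + off
  }
  base[c("case_id", "view", "rater_id", "vertebra", "point_id",
         "x_px", "y_px")]
}

make_set <- function(...) {
  annotation_set(make_annotation_df(...))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# explicit-summation oracle for the two-way mean squares, independent of the
# implementation (no rowMeans/colMeans shortcuts)
oracle_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- sum(m) / (n * k)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (sum(m[i, ]) / k - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (sum(m[, j]) / n - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - sum(m[i, ]) / k - sum(m[, j]) / n + grand)^2
  }
  list(MSR = ssr / (n - 1), MSC = ssc / (k - 1), MSE = sse / ((n - 1) * (k - 1)))
}

# draw a two-way random-effects ratings matrix
# y_ij = mu + subject_i + rater_j + error_ij
sim_two_way_matrix <- function(n, k, var_s, var_r, var_e, mu = 10) {
  s <- stats::rnorm(n, 0, sqrt(var_s))
  r <- stats::rnorm(k, 0, sqrt(var_r))
  outer(s, r, "+") + mu + matrix(stats::rnorm(n * k, 0, sqrt(var_e)), n, k)
}
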