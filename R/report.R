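#' Run the full reliability pipeline
#'
#' Consensus construction, deviation and angle statistics, ICC tables per
#' scope (group A, group B, and all raters on the common cases) and view,
#' and the between-group homogeneity tests. When `out_dir` is given the
#' tables are written as CSV together with a JSON run manifest; re-running
#' with identical inputs and seed reproduces identical files.
#'
#' @param set an [annotation_set()] (or a CSV path accepted by
#'   [read_annotations()]).
#' @param design a [study_design()] (or a stem accepted by [read_design()]).
#' @param n_boot bootstrap replicates for ICC CIs (default 500).
#' @param ci_level confidence level (default 0.95).
#' @param pooling coordinate pooling for point ICCs, see
#'   [point_reliability()].
#' @param rmse_aggregation see [angle_reliability()].
#' @param seed integer seed for all bootstrap resampling.
#' @param out_dir optional output directory for CSVs and the manifest.
#' @param scopes analysis scopes to compute (default all three).
#' @return list of class `study_report`: `point_table`, `angle_table`,
#'   `group_tests`, `metadata`.
#' @export
run_pipeline <- function(set, design, n_boot = 500L, ci_level = 0.95,
                         pooling = "xy_pooled",
                         rmse_aggregation = "per_rater_mean", seed = 1L,
                         out_dir = NULL, scopes = c("A", "B", "all12")) {
  if (is.character(set)) set <- read_annotations(set)
  if (is.character(design)) design <- read_design(design)
  stopifnot(inherits(set, "annotation_set"), inherits(design, "study_design"))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  point_table <- stage("point_reliability", do.call(rbind, lapply(
    scopes, function(sc) point_reliability(
      set, design, scope = sc, pooling = pooling, n_boot = n_boot,
      ci_level = ci_level, seed = derive_seed(seed, match(sc, scopes))))))
  angle_tbl <- stage("angle_reliability", do.call(rbind, lapply(
    scopes, function(sc) angle_reliability(
      set, design, scope = sc, rmse_aggregation = rmse_aggregation,
      n_boot = n_boot, ci_level = ci_level,
      seed = derive_seed(seed, 100L + match(sc, scopes))))))
  group_tests <- stage("group_homogeneity",
                       group_homogeneity_report(set, design))

  metadata <- list(
    package_version = as.character(utils::packageVersion("vertrel")),
    seed = seed, n_boot = n_boot, ci_level = ci_level,
    pooling = pooling, rmse_aggregation = rmse_aggregation,
    scopes = scopes,
    bootstrap_resampling = "patient cases (percentile method)",
    lmm = "random intercept per case, REML, Wald t with df = n_cases - 2 (approximate)",
    calibration = unclass(set$calibration),
    n_cases = length(set$cases), n_raters = length(set$raters),
    n_annotations = nrow(set$annotations),
    n_missing_triples = nrow(set$missing)
  )

  report <- structure(
    list(point_table = point_table, angle_table = angle_tbl,
         group_tests = group_tests, metadata = metadata),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "<study_report> %d point rows, %d angle rows, %d group tests | %d cases x %d raters\n",
    nrow(x$point_table), nrow(x$angle_table), nrow(x$group_tests),
    x$metadata$n_cases, x$metadata$n_raters))
  invisible(x)
}

round_cols <- function(df, digits = 3L) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Write a study report to CSV files plus a JSON manifest
#'
#' Numeric columns are rounded to 3 decimals at serialization only (matching
#' the precision of published reliability tables); the in-memory report keeps
#' full precision.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return the output paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("point_reliability.csv",
                                "angle_reliability.csv",
                                "group_tests.csv", "manifest.json"))
  utils::write.csv(round_cols(report$point_table), paths[1], row.names = FALSE)
  utils::write.csv(round_cols(report$angle_table), paths[2], row.names = FALSE)
  utils::write.csv(round_cols(report$group_tests), paths[3], row.names = FALSE)
  jsonlite::write_json(report$metadata, paths[4], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Plausibility screen over a study report
#'
#' Flags reliability rows outside user-supplied bounds. Report-only: returns
#' counts and the offending labels, never mutates the report.
#'
#' @param report a `study_report`.
#' @param icc_min minimum plausible ICC (applied to point and angle rows).
#' @param mean_max maximum plausible mean deviation / RMSE.
#' @return list with `n_rows`, `n_flagged`, `flagged` (data.frame
#'   `table, label, view, scope, icc, mean`).
#' @export
range_check <- function(report, icc_min = -Inf, mean_max = Inf) {
  stopifnot(inherits(report, "study_report"))
  screen <- function(df, table_name) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    bad <- (!is.na(df$icc) & df$icc < icc_min) |
      (!is.na(df$mean) & df$mean > mean_max)
    if (!any(bad)) return(NULL)
    data.frame(table = table_name,
               df[bad, c("label", "view", "scope", "icc", "mean")],
               stringsAsFactors = FALSE)
  }
  flagged <- rbind(screen(report$point_table, "point"),
                   screen(report$angle_table, "angle"))
  if (is.null(flagged)) {
    flagged <- data.frame(table = character(), label = character(),
                          view = character(), scope = character(),
                          icc = numeric(), mean = numeric(),
                          stringsAsFactors = FALSE)
  }
  rownames(flagged) <- NULL
  list(n_rows = nrow(report$point_table) + nrow(report$angle_table),
       n_flagged = nrow(flagged), flagged = flagged)
}
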