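#' Restrict an annotation set to an analysis scope
#'
#' Scope `"A"` / `"B"`: that group's raters on that group's assigned cases.
#' Scope `"all12"`: all raters, but only the common cases assigned to both
#' groups (the cases every rater labelled).
#'
#' @param set an [annotation_set()].
#' @param design a [study_design()].
#' @param scope `"A"`, `"B"` or `"all12"`.
#' @return an [annotation_set()] restricted to the scope.
#' @export
subset_scope <- function(set, design, scope = c("A", "B", "all12")) {
  scope <- match.arg(scope)
  stopifnot(inherits(set, "annotation_set"), inherits(design, "study_design"))
  cg <- design$case_groups
  if (scope == "all12") {
    raters <- names(design$rater_groups)
    cases <- cg$case_id[cg$in_A & cg$in_B]
  } else {
    raters <- names(design$rater_groups)[design$rater_groups == scope]
    cases <- cg$case_id[if (scope == "A") cg$in_A else cg$in_B]
  }
  ann <- set$annotations
  ann <- ann[ann$rater_id %in% raters & ann$case_id %in% cases, , drop = FALSE]
  msg <- set$missing
  msg <- msg[msg$rater_id %in% raters & msg$case_id %in% cases, , drop = FALSE]
  annotation_set(ann, calibration = set$calibration,
                 raters = raters, cases = intersect(set$cases, cases),
                 missing = msg, check_bounds = FALSE)
}

# cases x raters matrix of one value column; returns matrix with possible NAs
ratings_matrix <- function(df, value_col, row_keys, rater_ids) {
  rows <- unique(row_keys)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(rater_ids),
              dimnames = list(rows, rater_ids))
  m[cbind(match(row_keys, rows), match(df$rater_id, rater_ids))] <-
    df[[value_col]]
  m
}

# drop rows with any NA; for block structures drop whole blocks
complete_blocks <- function(m, blocks) {
  ok_row <- stats::complete.cases(m)
  ok_block <- tapply(ok_row, factor(blocks, levels = unique(blocks)), all)
  keep <- as.logical(ok_block[match(blocks, names(ok_block))])
  list(m = m[keep, , drop = FALSE], blocks = blocks[keep])
}

new_reliability_row <- function(label, view, scope, mean, sd, icc_res, note = NA_character_) {
  data.frame(
    label = label, view = view, scope = scope,
    mean = mean, sd = sd,
    icc = icc_res$icc %||% NA_real_,
    ci_low = icc_res$ci_low %||% NA_real_,
    ci_high = icc_res$ci_high %||% NA_real_,
    classification = icc_res$classification %||% NA_character_,
    n_subjects = icc_res$n_subjects %||% NA_integer_,
    n_raters = icc_res$n_raters %||% NA_integer_,
    note = note,
    stringsAsFactors = FALSE
  )
}

empty_icc <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  classification = NA_character_, n_subjects = NA_integer_,
                  n_raters = NA_integer_)

#' Landmark-point reliability table
#'
#' For each (view, vertebra, point) within an analysis scope: the mean and SD
#' of the per-rater-per-case Euclidean deviation from the consensus location
#' (mm), and the ICC(A,1) of the landmark coordinates with a percentile
#' bootstrap CI. Under the default `xy_pooled` pooling the ratings matrix
#' stacks each case's x- and y-coordinates (in mm) as two subject rows,
#' yielding one ICC per landmark point; `per_axis` reports separate x and y
#' rows (labels suffixed `_x`/`_y`). Cases with any missing rater in scope
#' are dropped listwise from the ICC matrix; bootstrap resampling moves
#' whole cases.
#'
#' @param set an [annotation_set()].
#' @param design a [study_design()].
#' @param scope `"A"`, `"B"` or `"all12"`.
#' @param pooling `"xy_pooled"` (default) or `"per_axis"`.
#' @param n_boot bootstrap replicates for the CI (default 500).
#' @param ci_level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return data.frame of reliability rows: `label, view, scope, mean, sd,
#'   icc, ci_low, ci_high, classification, n_subjects, n_raters, note`
#'   (note is NA unless the row's ICC failed, e.g. insufficient data).
#' @export
point_reliability <- function(set, design, scope = c("A", "B", "all12"),
                              pooling = c("xy_pooled", "per_axis"),
                              n_boot = 500L, ci_level = 0.95, seed = 1L) {
  scope <- match.arg(scope)
  pooling <- match.arg(pooling)
  sset <- subset_scope(set, design, scope)
  cons <- consensus_locations(sset)
  dev <- deviation_table(sset, cons)
  ann <- sset$annotations
  mmpp <- sset$calibration$mm_per_px

  rows <- list()
  i <- 0L
  for (view in VIEWS) {
    for (vertebra in VERTEBRAE) {
      for (point in POINT_IDS) {
        i <- i + 1L
        d <- dev[dev$view == view & dev$vertebra == vertebra &
                   dev$point_id == point, , drop = FALSE]
        a <- ann[ann$view == view & ann$vertebra == vertebra &
                   ann$point_id == point, , drop = FALSE]
        if (nrow(d) == 0L) next
        mean_dev <- mean(d$dev_mm)
        sd_dev <- stats::sd(d$dev_mm)
        label0 <- paste0(vertebra, "_", point)

        make_icc <- function(m, blocks) {
          cb <- complete_blocks(m, blocks)
          icc_with_ci(cb$m, n_boot = n_boot, level = ci_level,
                      seed = derive_seed(seed, i), blocks = cb$blocks)
        }

        if (pooling == "xy_pooled") {
          # centre each axis at its grand mean before stacking: the x-vs-y
          # offset is an artefact of where the vertebra sits in the image,
          # not subject variance; a single constant per axis leaves the ICC
          # of each axis block (and the rater-offset penalty) untouched.
          ax <- rbind(
            data.frame(a[c("case_id", "rater_id")], axis = "x",
                       value = (a$x_px - mean(a$x_px)) * mmpp,
                       stringsAsFactors = FALSE),
            data.frame(a[c("case_id", "rater_id")], axis = "y",
                       value = (a$y_px - mean(a$y_px)) * mmpp,
                       stringsAsFactors = FALSE))
          ax <- ax[order(match(ax$case_id, sset$cases), ax$axis), ]
          keys <- paste(ax$case_id, ax$axis, sep = "/")
          m <- ratings_matrix(ax, "value", keys, sset$raters)
          blocks <- sub("/[xy]$", "", rownames(m))
          res <- tryCatch(make_icc(m, blocks), error = function(e) e)
          rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
            new_reliability_row(label0, view, scope, mean_dev, sd_dev,
                                empty_icc, note = conditionMessage(res))
          } else {
            new_reliability_row(label0, view, scope, mean_dev, sd_dev, res)
          }
        } else {
          for (axis in c("x", "y")) {
            col <- paste0(axis, "_px")
            df <- data.frame(a[c("case_id", "rater_id")],
                             value = a[[col]] * mmpp, stringsAsFactors = FALSE)
            m <- ratings_matrix(df, "value", df$case_id, sset$raters)
            dev_col <- d[[paste0("dev_", axis, "_mm")]]
            res <- tryCatch(make_icc(m, rownames(m)), error = function(e) e)
            lab <- paste0(label0, "_", axis)
            rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
              new_reliability_row(lab, view, scope, mean(abs(dev_col)),
                                  stats::sd(abs(dev_col)), empty_icc,
                                  note = conditionMessage(res))
            } else {
              new_reliability_row(lab, view, scope, mean(abs(dev_col)),
                                  stats::sd(abs(dev_col)), res)
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Endplate-angle reliability table
#'
#' For each (view, vertebra, line) within a scope: the mean and SD of the
#' per-rater RMSE of the rater's endplate angle against the consensus angle
#' (default), or of the pooled per-rater-per-case absolute angle errors; and
#' the ICC(A,1) of the case x rater matrix of angle values with a percentile
#' bootstrap CI.
#'
#' @inheritParams point_reliability
#' @param rmse_aggregation `"per_rater_mean"` (default: RMSE per rater, then
#'   mean/SD across raters) or `"pooled"` (absolute errors pooled over
#'   rater x case).
#' @return data.frame of reliability rows as in [point_reliability()].
#' @export
angle_reliability <- function(set, design, scope = c("A", "B", "all12"),
                              rmse_aggregation = c("per_rater_mean", "pooled"),
                              n_boot = 500L, ci_level = 0.95, seed = 1L) {
  scope <- match.arg(scope)
  rmse_aggregation <- match.arg(rmse_aggregation)
  sset <- subset_scope(set, design, scope)
  cons <- consensus_locations(sset)
  angles <- angle_table(sset, cons)

  rows <- list()
  i <- 0L
  for (view in VIEWS) {
    for (vertebra in VERTEBRAE) {
      for (line in LINES) {
        i <- i + 1L
        sub <- angles[angles$view == view & angles$vertebra == vertebra &
                        angles$line == line, , drop = FALSE]
        if (nrow(sub) == 0L) next
        cons_sub <- sub[sub$rater_id == CONSENSUS_ID, c("case_id", "angle_deg")]
        rat <- sub[sub$rater_id != CONSENSUS_ID, , drop = FALSE]
        err <- angle_difference(
          rat$angle_deg,
          cons_sub$angle_deg[match(rat$case_id, cons_sub$case_id)])

        if (rmse_aggregation == "per_rater_mean") {
          rmse_by_rater <- tapply(err, rat$rater_id,
                                  function(e) sqrt(mean(e^2)))
          mean_stat <- mean(rmse_by_rater)
          sd_stat <- stats::sd(rmse_by_rater)
        } else {
          mean_stat <- mean(abs(err))
          sd_stat <- stats::sd(abs(err))
        }

        m <- ratings_matrix(rat, "angle_deg", rat$case_id, sset$raters)
        res <- tryCatch({
          cb <- complete_blocks(m, rownames(m))
          icc_with_ci(cb$m, n_boot = n_boot, level = ci_level,
                      seed = derive_seed(seed, 1000L + i), blocks = cb$blocks)
        }, error = function(e) e)
        lab <- paste0(vertebra, "_", line)
        rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
          new_reliability_row(lab, view, scope, mean_stat, sd_stat, empty_icc,
                              note = conditionMessage(res))
        } else {
          new_reliability_row(lab, view, scope, mean_stat, sd_stat, res)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
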