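#' Consensus landmark locations
#'
#' The pipeline's ground truth: for each (case, view, vertebra, point) the
#' arithmetic mean of the available raters' pixel coordinates. (case, view)
#' combinations labelled by fewer than two raters carry no meaningful mean
#' and are excluded; the exclusions are attached as an attribute.
#'
#' @param set an [annotation_set()].
#' @return data.frame `case_id, view, vertebra, point_id, x_px, y_px,
#'   n_raters`, with attribute `excluded` (data.frame case_id, view,
#'   n_raters) for combinations below the two-rater minimum.
#' @export
consensus_locations <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  ann <- set$annotations
  cv <- unique(ann[c("case_id", "view", "rater_id")])
  n_by_cv <- stats::aggregate(
    list(n_raters = cv$rater_id),
    by = cv[c("case_id", "view")], FUN = length)
  excluded <- n_by_cv[n_by_cv$n_raters < 2L, , drop = FALSE]
  rownames(excluded) <- NULL

  keep_key <- paste(n_by_cv$case_id[n_by_cv$n_raters >= 2L],
                    n_by_cv$view[n_by_cv$n_raters >= 2L], sep = "/")
  ann <- ann[paste(ann$case_id, ann$view, sep = "/") %in% keep_key, ,
             drop = FALSE]

  if (nrow(ann) == 0L) {
    out <- data.frame(case_id = character(), view = character(),
                      vertebra = character(), point_id = character(),
                      x_px = numeric(), y_px = numeric(),
                      n_raters = integer(), stringsAsFactors = FALSE)
    attr(out, "excluded") <- excluded
    return(out)
  }

  agg <- stats::aggregate(
    ann[c("x_px", "y_px")],
    by = ann[c("case_id", "view", "vertebra", "point_id")],
    FUN = mean)
  agg$n_raters <- n_by_cv$n_raters[
    match(paste(agg$case_id, agg$view, sep = "/"),
          paste(n_by_cv$case_id, n_by_cv$view, sep = "/"))]
  agg <- agg[order(match(agg$case_id, set$cases), match(agg$view, VIEWS),
                   match(agg$vertebra, VERTEBRAE),
                   match(agg$point_id, POINT_IDS)), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "excluded") <- excluded
  agg
}

#' Per-annotation deviations from consensus
#'
#' Joins every annotation to its consensus landmark and returns, in
#' millimetres, the Euclidean deviation and the signed per-axis deviations
#' (annotation minus consensus).
#'
#' @param set an [annotation_set()].
#' @param consensus optional precomputed [consensus_locations()] output.
#' @return data.frame `case_id, view, vertebra, point_id, rater_id, dev_mm,
#'   dev_x_mm, dev_y_mm, n_raters`.
#' @export
deviation_table <- function(set, consensus = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  if (is.null(consensus)) consensus <- consensus_locations(set)
  ann <- set$annotations
  key_cols <- c("case_id", "view", "vertebra", "point_id")
  idx <- match(do.call(paste, c(ann[key_cols], sep = "/")),
               do.call(paste, c(consensus[key_cols], sep = "/")))
  keep <- !is.na(idx)
  ann <- ann[keep, , drop = FALSE]
  idx <- idx[keep]
  mmpp <- set$calibration$mm_per_px
  dx <- (ann$x_px - consensus$x_px[idx]) * mmpp
  dy <- (ann$y_px - consensus$y_px[idx]) * mmpp
  out <- data.frame(
    ann[c(key_cols, "rater_id")],
    dev_mm = sqrt(dx^2 + dy^2),
    dev_x_mm = dx,
    dev_y_mm = dy,
    n_raters = consensus$n_raters[idx],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

check_same_landmark <- function(annotation, consensus) {
  key_cols <- c("case_id", "view", "vertebra", "point_id")
  a <- unlist(annotation[key_cols])
  b <- unlist(consensus[key_cols])
  if (!identical(unname(a), unname(b))) {
    stop(sprintf("annotation (%s) and consensus (%s) refer to different landmarks",
                 paste(a, collapse = "/"), paste(b, collapse = "/")),
         call. = FALSE)
  }
}

#' Euclidean deviation of one annotation from its consensus landmark
#'
#' @param annotation one-row data.frame (or list) with the landmark key and
#'   `x_px`, `y_px`.
#' @param consensus matching one-row consensus record.
#' @param calibration a [calibration()] object.
#' @return deviation in millimetres (>= 0).
#' @export
euclidean_deviation <- function(annotation, consensus,
                                calibration = vertrel::calibration()) {
  check_same_landmark(annotation, consensus)
  dx <- as.numeric(annotation$x_px) - as.numeric(consensus$x_px)
  dy <- as.numeric(annotation$y_px) - as.numeric(consensus$y_px)
  sqrt(dx^2 + dy^2) * calibration$mm_per_px
}

#' Signed per-axis deviation of one annotation from its consensus landmark
#'
#' @inheritParams euclidean_deviation
#' @param axis `"x"` or `"y"`.
#' @return signed deviation in millimetres (annotation minus consensus).
#' @export
axis_deviation <- function(annotation, consensus,
                           calibration = vertrel::calibration(),
                           axis = c("x", "y")) {
  axis <- match.arg(axis)
  check_same_landmark(annotation, consensus)
  col <- paste0(axis, "_px")
  (as.numeric(annotation[[col]]) - as.numeric(consensus[[col]])) *
    calibration$mm_per_px
}

#' Endplate line angle from its two endpoint landmarks
#'
#' Angle of the line through `left` (p1 or p3) and `right` (p2 or p4) against
#' the image horizontal, in degrees, mapped to (-90, 90]. Image y grows
#' downward, so the sign is flipped to make "line rises toward the right in
#' anatomical display" positive. Lines are unoriented: swapping the endpoints
#' leaves the angle unchanged; a vertical line is 90 by convention.
#'
#' @param left,right numeric length-2 vectors `c(x_px, y_px)` or one-row
#'   records with `x_px`, `y_px`.
#' @return angle in degrees in (-90, 90].
#' @export
endplate_angle <- function(left, right) {
  pt <- function(p) {
    if (is.numeric(p) && length(p) == 2L) unname(p)
    else c(as.numeric(p$x_px), as.numeric(p$y_px))
  }
  l <- pt(left); r <- pt(right)
  dx <- r[1] - l[1]
  dy <- r[2] - l[2]
  if (dx == 0 && dy == 0) {
    stop("degenerate geometry: endplate endpoints coincide", call. = FALSE)
  }
  ang <- atan2(-dy, dx) * 180 / pi
  # fold ray direction onto line orientation in (-90, 90]
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

# vectorised internal version used by angle_table
endplate_angle_vec <- function(xl, yl, xr, yr, context = NULL) {
  degen <- xl == xr & yl == yr
  if (any(degen)) {
    where <- if (is.null(context)) which(degen)[1L] else context[which(degen)[1L]]
    stop("degenerate geometry: endplate endpoints coincide at ", where,
         call. = FALSE)
  }
  ang <- atan2(-(yr - yl), xr - xl) * 180 / pi
  ang[ang <= -90] <- ang[ang <= -90] + 180
  ang[ang > 90] <- ang[ang > 90] - 180
  ang
}

# smallest signed difference between two line orientations, in (-90, 90]
angle_difference <- function(a, b) {
  d <- a - b
  d <- d - 180 * round(d / 180)
  d[d <= -90] <- d[d <= -90] + 180  # unreachable after rounding, kept for safety
  d
}

#' Endplate angles for every rater and the consensus
#'
#' One angle per (case, view, vertebra, line, rater): the upper endplate line
#' UVEL joins p1-p2, the lower line LVEL joins p3-p4. The consensus angle
#' (rater_id `"CONSENSUS"`) is computed from the consensus endpoint
#' locations, not by averaging rater angles.
#'
#' @param set an [annotation_set()].
#' @param consensus optional precomputed [consensus_locations()] output.
#' @return data.frame `case_id, view, vertebra, line, rater_id, angle_deg`.
#' @export
angle_table <- function(set, consensus = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  if (is.null(consensus)) consensus <- consensus_locations(set)

  one_source <- function(df, rater_label = NULL) {
    if (nrow(df) == 0L) return(NULL)
    key <- c("case_id", "view", "vertebra",
             if (is.null(rater_label)) "rater_id")
    wide <- stats::reshape(
      df[c(key, "point_id", "x_px", "y_px")],
      idvar = key, timevar = "point_id", direction = "wide")
    res <- lapply(c(UVEL = "UVEL", LVEL = "LVEL"), function(line) {
      lp <- if (line == "UVEL") "p1" else "p3"
      rp <- if (line == "UVEL") "p2" else "p4"
      ctx <- paste(wide$case_id, wide$view, wide$vertebra, line, sep = "/")
      data.frame(
        wide[c("case_id", "view", "vertebra")],
        line = line,
        rater_id = if (is.null(rater_label)) wide$rater_id else rater_label,
        angle_deg = endplate_angle_vec(
          wide[[paste0("x_px.", lp)]], wide[[paste0("y_px.", lp)]],
          wide[[paste0("x_px.", rp)]], wide[[paste0("y_px.", rp)]],
          context = ctx),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, res)
  }

  # rater angles only for (case, view) retained in the consensus
  key_cv <- unique(consensus[c("case_id", "view")])
  ann <- set$annotations
  ann <- ann[paste(ann$case_id, ann$view, sep = "/") %in%
               paste(key_cv$case_id, key_cv$view, sep = "/"), , drop = FALSE]

  out <- rbind(one_source(ann), one_source(consensus, CONSENSUS_ID))
  if (is.null(out)) {
    return(data.frame(case_id = character(), view = character(),
                      vertebra = character(), line = character(),
                      rater_id = character(), angle_deg = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(match(out$case_id, set$cases), match(out$view, VIEWS),
                   match(out$vertebra, VERTEBRAE), match(out$line, LINES),
                   out$rater_id != CONSENSUS_ID, out$rater_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Root-mean-square angle error of one rater against the consensus
#'
#' RMSE over cases of the (orientation-aware) difference between the rater's
#' endplate angle and the consensus angle, for one (view, vertebra, line).
#'
#' @param angles output of [angle_table()].
#' @param rater_id,view,vertebra,line the cell to evaluate.
#' @return RMSE in degrees.
#' @export
rater_angle_rmse <- function(angles, rater_id, view, vertebra, line) {
  sub <- angles[angles$view == view & angles$vertebra == vertebra &
                  angles$line == line, , drop = FALSE]
  r <- sub[sub$rater_id == rater_id, c("case_id", "angle_deg")]
  cons <- sub[sub$rater_id == CONSENSUS_ID, c("case_id", "angle_deg")]
  m <- merge(r, cons, by = "case_id", suffixes = c("_rater", "_cons"))
  if (nrow(m) == 0L) {
    stop(sprintf(
      "insufficient data: no case with both rater %s and consensus angles for %s/%s/%s",
      rater_id, view, vertebra, line), call. = FALSE)
  }
  sqrt(mean(angle_difference(m$angle_deg_rater, m$angle_deg_cons)^2))
}
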