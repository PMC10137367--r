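#' Multi-rater landmark annotation set
#'
#' The central data container: one row per (case, view, rater, vertebra,
#' point) with pixel coordinates, plus the calibration and an explicit record
#' of wholly-missing (case, view, rater) labellings. A rater either labels
#' all 20 points of a view for a case (4 corner points p1..p4 on each of
#' L1..L5) or none of them; partial labellings are rejected because the
#' missingness mechanism in these studies (disagreement over which vertebra
#' is L1) invalidates the whole case, not single points.
#'
#' @param annotations data.frame with columns `case_id`, `view`, `rater_id`,
#'   `vertebra`, `point_id`, `x_px`, `y_px`.
#' @param calibration a [calibration()] object.
#' @param raters optional character vector of all rater ids (defaults to the
#'   ids present in `annotations`).
#' @param cases optional character vector of all case ids.
#' @param missing data.frame with columns `case_id`, `view`, `rater_id`
#'   listing wholly-unlabelled case/view/rater triples.
#' @param check_bounds if TRUE, reject coordinates outside the image.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(annotations,
                           calibration = vertrel::calibration(),
                           raters = NULL, cases = NULL,
                           missing = NULL, check_bounds = TRUE) {
  required <- c("case_id", "view", "rater_id", "vertebra", "point_id",
                "x_px", "y_px")
  miss_cols <- setdiff(required, names(annotations))
  if (length(miss_cols) > 0L) {
    stop("annotation table lacks column(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  ann <- as.data.frame(annotations)[required]
  for (col in c("case_id", "view", "rater_id", "vertebra", "point_id")) {
    ann[[col]] <- as.character(ann[[col]])
  }
  ann$x_px <- as.numeric(ann$x_px)
  ann$y_px <- as.numeric(ann$y_px)

  bad_view <- setdiff(unique(ann$view), VIEWS)
  if (length(bad_view) > 0L) {
    stop("invalid view value(s): ", paste(bad_view, collapse = ", "),
         call. = FALSE)
  }
  bad_vert <- setdiff(unique(ann$vertebra), VERTEBRAE)
  if (length(bad_vert) > 0L) {
    stop("invalid vertebra value(s): ", paste(bad_vert, collapse = ", "),
         call. = FALSE)
  }
  bad_pt <- setdiff(unique(ann$point_id), POINT_IDS)
  if (length(bad_pt) > 0L) {
    stop("invalid point_id value(s): ", paste(bad_pt, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(ann$x_px)) || any(is.na(ann$y_px))) {
    stop("coordinates contain missing values", call. = FALSE)
  }
  if (any(ann$x_px < 0) || any(ann$y_px < 0)) {
    stop("coordinates must be non-negative", call. = FALSE)
  }
  if (check_bounds) {
    out <- ann$x_px >= calibration$image_width |
      ann$y_px >= calibration$image_height
    if (any(out)) {
      stop(sprintf("%d coordinate(s) outside the %d x %d image, e.g. %s",
                   sum(out), calibration$image_width, calibration$image_height,
                   key_string(ann[which(out)[1L], , drop = FALSE],
                              c("case_id", "view", "rater_id", "vertebra",
                                "point_id"))),
           call. = FALSE)
    }
  }

  key <- key_string(ann, c("case_id", "view", "rater_id", "vertebra",
                           "point_id"))
  if (anyDuplicated(key)) {
    stop("duplicate annotation key(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "),
         call. = FALSE)
  }

  # completeness: each (case, view, rater) carries exactly 20 points
  cvr <- paste(ann$case_id, ann$view, ann$rater_id, sep = "/")
  n_pts <- table(cvr)
  partial <- names(n_pts)[n_pts != 20L]
  if (length(partial) > 0L) {
    stop("incomplete labelling (must be 20 points per case/view/rater) for: ",
         paste(utils::head(partial, 3L), collapse = "; "), call. = FALSE)
  }

  raters <- sort(unique(c(raters, ann$rater_id)))
  cases <- unique(c(cases, ann$case_id))
  cases <- cases[order(suppressWarnings(as.numeric(cases)), cases)]

  if (is.null(missing)) {
    missing <- data.frame(case_id = character(), view = character(),
                          rater_id = character(), stringsAsFactors = FALSE)
  } else {
    missing <- as.data.frame(missing)[c("case_id", "view", "rater_id")]
    for (col in names(missing)) missing[[col]] <- as.character(missing[[col]])
    both <- intersect(paste(missing$case_id, missing$view, missing$rater_id,
                            sep = "/"), cvr)
    if (length(both) > 0L) {
      stop("triple(s) listed as missing but annotated: ",
           paste(utils::head(both, 3L), collapse = "; "), call. = FALSE)
    }
  }

  structure(
    list(annotations = ann, calibration = calibration,
         raters = raters, cases = cases, missing = missing),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set> %d annotations | %d cases | %d raters | %d missing case/view/rater triples\n",
    nrow(x$annotations), length(x$cases), length(x$raters), nrow(x$missing)))
  cat(sprintf("  calibration: %g mm/px (%d x %d px)\n",
              x$calibration$mm_per_px, x$calibration$image_width,
              x$calibration$image_height))
  invisible(x)
}

#' Read landmark annotations from CSV
#'
#' Expects the long dialect `case_id,view,rater_id,vertebra,point_id,x_px,y_px`
#' (one point per row). A (case, view, rater) triple with rows elsewhere in
#' the file but none for this combination is recorded as wholly missing;
#' a triple with 1-19 of its 20 points present is an error.
#'
#' @param path CSV file path.
#' @param calibration a [calibration()] object.
#' @param check_bounds reject out-of-image coordinates (default TRUE).
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, calibration = vertrel::calibration(),
                             check_bounds = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("case_id", "view", "rater_id", "vertebra", "point_id",
                "x_px", "y_px")
  miss_cols <- setdiff(required, names(df))
  if (length(miss_cols) > 0L) {
    stop("malformed header: missing column(s) ",
         paste(miss_cols, collapse = ", "), call. = FALSE)
  }
  df$x_px <- as.numeric(df$x_px)
  df$y_px <- as.numeric(df$y_px)

  set <- annotation_set(df, calibration = calibration,
                        check_bounds = check_bounds)

  # wholly-absent (case, view, rater) triples: a rater who appears anywhere
  # and a case/view that appears anywhere, but no rows for the combination.
  ann <- set$annotations
  seen_cv <- unique(ann[c("case_id", "view")])
  grid <- merge(seen_cv, data.frame(rater_id = set$raters), by = NULL)
  have <- paste(ann$case_id, ann$view, ann$rater_id, sep = "/")
  grid_key <- paste(grid$case_id, grid$view, grid$rater_id, sep = "/")
  absent <- grid[!grid_key %in% unique(have), , drop = FALSE]
  rownames(absent) <- NULL
  set$missing <- absent[c("case_id", "view", "rater_id")]
  set
}

#' Write landmark annotations to CSV
#'
#' Writes the canonical long dialect; wholly-missing triples are simply
#' absent from the file and are recovered on re-read. Round-trips through
#' [read_annotations()] reproduce every field exactly.
#'
#' @param set an [annotation_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  ann <- set$annotations
  ord <- order(match(ann$case_id, set$cases), match(ann$view, VIEWS),
               ann$rater_id, match(ann$vertebra, VERTEBRAE),
               match(ann$point_id, POINT_IDS))
  ann <- ann[ord, , drop = FALSE]
  ann$x_px <- format(ann$x_px, digits = 17, trim = TRUE, scientific = FALSE)
  ann$y_px <- format(ann$y_px, digits = 17, trim = TRUE, scientific = FALSE)
  ok <- tryCatch({
    utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write annotations to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}
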