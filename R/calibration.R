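#' Image calibration
#'
#' Maps pixel distances to millimetres for a radiograph series. The defaults
#' describe a 1953 x 3000 pixel lumbar spine X-ray digitised at
#' 0.143 mm per pixel.
#'
#' @param mm_per_px millimetres per pixel (> 0).
#' @param image_width image width in pixels.
#' @param image_height image height in pixels.
#' @return an object of class `calibration`.
#' @examples
#' cal <- calibration()
#' px_to_mm(10, cal)
#' @export
calibration <- function(mm_per_px = 0.143, image_width = 1953L,
                        image_height = 3000L) {
  stopifnot_scalar_number(mm_per_px, "mm_per_px", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(image_width, "image_width", min = 1)
  stopifnot_scalar_number(image_height, "image_height", min = 1)
  structure(
    list(mm_per_px = mm_per_px,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height)),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %g mm/px, image %d x %d px\n",
              x$mm_per_px, x$image_width, x$image_height))
  invisible(x)
}

#' Convert a pixel distance to millimetres
#'
#' @param distance_px non-negative pixel distance (vectorised).
#' @param calibration a [calibration()] object.
#' @return distance in millimetres.
#' @export
px_to_mm <- function(distance_px, calibration = vertrel::calibration()) {
  if (!inherits(calibration, "calibration")) {
    stop("`calibration` must be a calibration object", call. = FALSE)
  }
  if (any(is.na(distance_px)) || any(distance_px < 0)) {
    stop("`distance_px` must be non-negative", call. = FALSE)
  }
  distance_px * calibration$mm_per_px
}

#' Read calibration settings from a YAML or JSON config file
#'
#' The file may carry any subset of `mm_per_px`, `image_width`,
#' `image_height`; absent keys keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [calibration()] object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- calibration()
  calibration(
    mm_per_px = cfg$mm_per_px %||% defaults$mm_per_px,
    image_width = cfg$image_width %||% defaults$image_width,
    image_height = cfg$image_height %||% defaults$image_height
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
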