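#' Simulator configuration
#'
#' Parameters of the synthetic multi-rater labelling study. Defaults describe
#' a 1000-case, 12-rater (two groups of six) lumbar study: per-coordinate
#' labelling noise of 1.2 mm everywhere except the L5 vertebra on the AP
#' view, where superposition by the sacrum doubles it to 2.4 mm; a small
#' systematic per-rater bias (SD 0.3 mm per coordinate, drawn once per
#' rater x point role); and 2% of (case, view, rater) labellings wholly
#' missing (disagreement over which vertebra is L1 invalidates the case for
#' that rater).
#'
#' @param n_cases number of patient cases.
#' @param raters_per_group raters per group (two groups).
#' @param noise_sd_mm per-coordinate labelling noise SD in mm: either one
#'   number (applied everywhere, with AP/L5 doubled) or a named list/vector
#'   keyed `"<view>.<vertebra>"` (e.g. `AP.L5`) covering all 10 combinations.
#' @param rater_bias_sd_mm SD of the per-rater systematic bias, mm.
#' @param missing_rate probability a (case, view, rater) labelling is wholly
#'   missing.
#' @param tilt_sd_deg SD of the per-vertebra endplate tilt across cases.
#' @param position_sd_mm SD of the per-case global position jitter.
#' @param width_mean_mm,width_sd_mm vertebral body width distribution.
#' @param height_mean_mm,height_sd_mm vertebral body height distribution.
#' @param gap_mm disc space between consecutive vertebrae, mm.
#' @param calibration a [calibration()] object.
#' @param seed integer seed; the whole study is deterministic given it.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_cases = 1000L, raters_per_group = 6L,
                         noise_sd_mm = 1.2, rater_bias_sd_mm = 0.3,
                         missing_rate = 0.02, tilt_sd_deg = 4,
                         position_sd_mm = 8, width_mean_mm = 40,
                         width_sd_mm = 3, height_mean_mm = 27,
                         height_sd_mm = 2, gap_mm = 8,
                         calibration = vertrel::calibration(), seed = 1L) {
  stopifnot_scalar_number(n_cases, "n_cases", min = 1)
  stopifnot_scalar_number(raters_per_group, "raters_per_group", min = 1)
  stopifnot_scalar_number(rater_bias_sd_mm, "rater_bias_sd_mm", min = 0)
  stopifnot_scalar_number(missing_rate, "missing_rate", min = 0)
  if (missing_rate >= 1) stop("`missing_rate` must be < 1", call. = FALSE)
  stopifnot_scalar_number(tilt_sd_deg, "tilt_sd_deg", min = 0)

  keys <- as.vector(outer(VIEWS, VERTEBRAE, paste, sep = "."))
  if (length(noise_sd_mm) == 1L && is.null(names(noise_sd_mm))) {
    noise <- stats::setNames(rep(as.numeric(noise_sd_mm), length(keys)), keys)
    noise["AP.L5"] <- 2 * as.numeric(noise_sd_mm)
  } else {
    noise <- unlist(noise_sd_mm)
    miss <- setdiff(keys, names(noise))
    if (length(miss) > 0L) {
      stop("noise_sd_mm lacks entries for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    noise <- noise[keys]
  }
  if (any(noise < 0)) stop("noise SDs must be >= 0", call. = FALSE)

  structure(
    list(n_cases = as.integer(n_cases),
         raters_per_group = as.integer(raters_per_group),
         n_raters = 2L * as.integer(raters_per_group),
         noise_sd_mm = noise, rater_bias_sd_mm = rater_bias_sd_mm,
         missing_rate = missing_rate, tilt_sd_deg = tilt_sd_deg,
         position_sd_mm = position_sd_mm,
         width_mean_mm = width_mean_mm, width_sd_mm = width_sd_mm,
         height_mean_mm = height_mean_mm, height_sd_mm = height_sd_mm,
         gap_mm = gap_mm, calibration = calibration,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d cases, %d raters (2 x %d), seed %d\n",
              x$n_cases, x$n_raters, x$raters_per_group, x$seed))
  cat(sprintf("  noise SD %s mm; bias SD %g mm; missing %g%%\n",
              paste(format(unique(unname(x$noise_sd_mm))), collapse = "/"),
              x$rater_bias_sd_mm, 100 * x$missing_rate))
  invisible(x)
}

#' Generate true lumbar geometry for every case and view
#'
#' Models each vertebral body's projection as a tilted rectangle: five bodies
#' (L1 cranial to L5 caudal) stacked down the image, with case-specific
#' width, height, tilt and position drawn from the configured distributions.
#' Deterministic given `config$seed`.
#'
#' @param config a [study_config()].
#' @return data.frame of class `true_anatomy`: one row per (case, view,
#'   vertebra, point) with true pixel coordinates `x_px, y_px`, plus
#'   `width_mm`, `height_mm`, `tilt_deg`.
#' @export
generate_anatomy <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cal <- config$calibration
  mmpp <- cal$mm_per_px
  n <- config$n_cases

  with_seed(derive_seed(config$seed, 11L), {
    grid <- expand.grid(point_id = POINT_IDS, vertebra = VERTEBRAE,
                        view = VIEWS, case_id = as.character(seq_len(n)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # per case x view draws
    ncv <- n * length(VIEWS)
    width <- stats::rnorm(ncv, config$width_mean_mm, config$width_sd_mm)
    height <- stats::rnorm(ncv, config$height_mean_mm, config$height_sd_mm)
    jx <- stats::rnorm(ncv, 0, config$position_sd_mm)
    jy <- stats::rnorm(ncv, 0, config$position_sd_mm)
    # per case x view x vertebra tilt
    tilt <- stats::rnorm(ncv * length(VERTEBRAE), 0, config$tilt_sd_deg)

    icv <- rep(seq_len(ncv), each = length(VERTEBRAE) * length(POINT_IDS))
    icvv <- rep(seq_len(ncv * length(VERTEBRAE)), each = length(POINT_IDS))
    w <- width[icv]; h <- height[icv]
    th <- tilt[icvv] * pi / 180
    v_idx <- match(grid$vertebra, VERTEBRAE) - 1L

    # column geometry in mm, image origin top-left, y downward
    cx <- cal$image_width * mmpp / 2 + jx[icv]
    top_margin <- (cal$image_height * mmpp -
                     5 * config$height_mean_mm - 4 * config$gap_mm) / 2
    cy <- top_margin + config$height_mean_mm / 2 +
      v_idx * (config$height_mean_mm + config$gap_mm) + jy[icv]

    sx <- ifelse(grid$point_id %in% c("p1", "p3"), -1, 1)
    sy <- ifelse(grid$point_id %in% c("p1", "p2"), -1, 1)
    dx0 <- sx * w / 2
    dy0 <- sy * h / 2
    # rotation consistent with the display convention: positive tilt means
    # the endplate rises toward the right (image y grows downward)
    dx <- dx0 * cos(th) + dy0 * sin(th)
    dy <- -dx0 * sin(th) + dy0 * cos(th)

    out <- data.frame(
      case_id = grid$case_id, view = grid$view, vertebra = grid$vertebra,
      point_id = grid$point_id,
      x_px = (cx + dx) / mmpp, y_px = (cy + dy) / mmpp,
      width_mm = w, height_mm = h, tilt_deg = tilt[icvv],
      stringsAsFactors = FALSE
    )
    bad <- out$x_px < 0 | out$x_px >= cal$image_width |
      out$y_px < 0 | out$y_px >= cal$image_height
    if (any(bad)) {
      stop("generated geometry out of image bounds for case(s): ",
           paste(utils::head(unique(out$case_id[bad]), 3L), collapse = ", "),
           call. = FALSE)
    }
    class(out) <- c("true_anatomy", class(out))
    out
  })
}

#' Simulate rater annotations over a true anatomy
#'
#' Each rater's point is the true point plus a rater-specific systematic
#' bias (one draw per rater x point role, per coordinate, SD
#' `rater_bias_sd_mm`) plus isotropic Gaussian noise with the (view,
#' vertebra)-specific SD, all specified in mm and converted to pixels. Each
#' (case, view, rater) labelling is independently wholly missing with
#' probability `missing_rate`. When a `design` is supplied, raters only
#' label cases assigned to their group. Deterministic given `config$seed`.
#'
#' @param anatomy output of [generate_anatomy()].
#' @param config the matching [study_config()].
#' @param design optional [study_design()]; `NULL` means every rater labels
#'   every case.
#' @return an [annotation_set()].
#' @export
simulate_raters <- function(anatomy, config, design = NULL) {
  stopifnot(inherits(config, "study_config"))
  cal <- config$calibration
  mmpp <- cal$mm_per_px
  rater_ids <- sprintf("r%02d", seq_len(config$n_raters))

  with_seed(derive_seed(config$seed, 29L), {
    bias <- expand.grid(rater_id = rater_ids, point_id = POINT_IDS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    bias$bx <- stats::rnorm(nrow(bias), 0, config$rater_bias_sd_mm)
    bias$by <- stats::rnorm(nrow(bias), 0, config$rater_bias_sd_mm)

    per_rater <- lapply(rater_ids, function(r) {
      anat <- anatomy
      if (!is.null(design)) {
        g <- design$rater_groups[[r]]
        cg <- design$case_groups
        cases_g <- cg$case_id[if (g == "A") cg$in_A else cg$in_B]
        anat <- anat[anat$case_id %in% cases_g, , drop = FALSE]
      }
      if (nrow(anat) == 0L) return(NULL)
      b <- bias[bias$rater_id == r, , drop = FALSE]
      bi <- match(anat$point_id, b$point_id)
      sdm <- unname(config$noise_sd_mm[paste(anat$view, anat$vertebra,
                                             sep = ".")])
      df <- data.frame(
        case_id = anat$case_id, view = anat$view, rater_id = r,
        vertebra = anat$vertebra, point_id = anat$point_id,
        x_px = anat$x_px + (b$bx[bi] + stats::rnorm(nrow(anat), 0, sdm)) / mmpp,
        y_px = anat$y_px + (b$by[bi] + stats::rnorm(nrow(anat), 0, sdm)) / mmpp,
        stringsAsFactors = FALSE
      )
      # case-level missingness: drop whole (case, view) labellings
      cv <- unique(df[c("case_id", "view")])
      drop <- stats::runif(nrow(cv)) < config$missing_rate
      if (any(drop)) {
        gone <- paste(cv$case_id[drop], cv$view[drop], sep = "/")
        miss <- data.frame(case_id = cv$case_id[drop], view = cv$view[drop],
                           rater_id = r, stringsAsFactors = FALSE)
        df <- df[!paste(df$case_id, df$view, sep = "/") %in% gone, ,
                 drop = FALSE]
      } else {
        miss <- NULL
      }
      list(ann = df, miss = miss)
    })

    ann <- do.call(rbind, lapply(per_rater, `[[`, "ann"))
    miss <- do.call(rbind, lapply(per_rater, `[[`, "miss"))
    # clamp the rare noise excursion past the image border
    ann$x_px <- pmin(pmax(ann$x_px, 0), cal$image_width - 1e-9)
    ann$y_px <- pmin(pmax(ann$y_px, 0), cal$image_height - 1e-9)
    annotation_set(ann, calibration = cal, raters = rater_ids,
                   cases = unique(anatomy$case_id), missing = miss)
  })
}

#' Simulate a complete two-group labelling study
#'
#' Composes [make_two_group_design()], [generate_anatomy()] and
#' [simulate_raters()]: raters label exactly the cases assigned to their
#' group, so the common middle-fifth cases are labelled by all raters and the
#' rest by one group of six.
#'
#' @param config a [study_config()] with `n_cases` divisible by 5.
#' @return list with elements `set` ([annotation_set()]), `design`
#'   ([study_design()]) and `anatomy` ([generate_anatomy()] output).
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  design <- make_two_group_design(config$n_cases, config$raters_per_group)
  anatomy <- generate_anatomy(config)
  set <- simulate_raters(anatomy, config, design)
  list(set = set, design = design, anatomy = anatomy)
}
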