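test_that("consensus is the arithmetic mean of available raters", {
  # two raters offset symmetrically: consensus at the midpoint
  df <- make_annotation_df(case_ids = "c1", rater_ids = c("r1", "r2"),
                           rater_offset_px = c(r1 = 0, r2 = 2))
  set <- annotation_set(df)
  cons <- consensus_locations(set)
  expect_equal(nrow(cons), 20L)
  expect_true(all(cons$n_raters == 2L))
  a1 <- df[df$rater_id == "r1", ]
  key <- paste(cons$vertebra, cons$point_id)
  a1k <- paste(a1$vertebra, a1$point_id)
  expect_equal(cons$x_px, a1$x_px[match(key, a1k)] + 1)
  expect_equal(cons$y_px, a1$y_px[match(key, a1k)] + 1)

  # idempotence: identical raters reproduce their common location
  df6 <- make_annotation_df(case_ids = "c1", rater_ids = sprintf("r%d", 1:6))
  cons6 <- consensus_locations(annotation_set(df6))
  expect_equal(cons6$x_px, a1$x_px[match(key, a1k)])
  expect_true(all(cons6$n_raters == 6L))
})

test_that("consensus over five raters matches explicit summation when one is missing", {
  offsets <- c(r1 = 0, r2 = 1, r3 = 2, r4 = 3, r5 = 4, r6 = 5)
  df <- make_annotation_df(case_ids = c("c1", "c2"),
                           rater_ids = names(offsets),
                           rater_offset_px = offsets)
  df <- df[!(df$case_id == "c1" & df$rater_id == "r6"), ]
  set <- read_annotations(write_temp_csv(df))
  cons <- consensus_locations(set)
  c1 <- cons[cons$case_id == "c1", ]
  expect_true(all(c1$n_raters == 5L))
  # oracle: explicit summation over the five available raters
  sub <- df[df$case_id == "c1", ]
  for (i in seq_len(nrow(c1))) {
    pts <- sub[sub$vertebra == c1$vertebra[i] & sub$point_id == c1$point_id[i], ]
    expect_equal(c1$x_px[i], sum(pts$x_px) / 5)
    expect_equal(c1$y_px[i], sum(pts$y_px) / 5)
  }
})

test_that("case/views with fewer than two raters are excluded and reported", {
  df <- make_annotation_df(case_ids = c("c1", "c2"), rater_ids = c("r1", "r2"))
  df <- df[!(df$case_id == "c2" & df$rater_id == "r2"), ]
  set <- read_annotations(write_temp_csv(df))
  cons <- consensus_locations(set)
  expect_false("c2" %in% cons$case_id)
  excl <- attr(cons, "excluded")
  expect_equal(excl$case_id, "c2")
  expect_equal(excl$n_raters, 1L)
})

test_that("euclidean and axis deviations follow the calibration", {
  cal <- calibration()
  ann <- data.frame(case_id = "c1", view = "AP", vertebra = "L1",
                    point_id = "p1", x_px = 13, y_px = 24,
                    stringsAsFactors = FALSE)
  cons <- data.frame(case_id = "c1", view = "AP", vertebra = "L1",
                     point_id = "p1", x_px = 10, y_px = 20,
                     stringsAsFactors = FALSE)
  expect_equal(euclidean_deviation(ann, cons, cal), 5 * 0.143)  # 3-4-5
  expect_equal(axis_deviation(ann, cons, cal, "x"), 3 * 0.143)
  expect_equal(axis_deviation(ann, cons, cal, "y"), 4 * 0.143)
  expect_equal(euclidean_deviation(cons, cons, cal), 0)
  expect_equal(axis_deviation(cons, cons, cal, "x"), 0)
  expect_equal(axis_deviation(cons, cons, cal, "y"), 0)

  mismatched <- cons
  mismatched$vertebra <- "L2"
  expect_error(euclidean_deviation(ann, mismatched, cal), "different landmarks")
})

test_that("per-point deviations from consensus average to zero exactly", {
  offsets <- c(r1 = -3, r2 = 0, r3 = 1, r4 = 5)
  set <- annotation_set(make_annotation_df(case_ids = "c1",
                                           rater_ids = names(offsets),
                                           rater_offset_px = offsets))
  dev <- deviation_table(set)
  sums <- aggregate(dev[c("dev_x_mm", "dev_y_mm")],
                    by = dev[c("vertebra", "point_id")], FUN = mean)
  expect_equal(sums$dev_x_mm, rep(0, 20), tolerance = 1e-12)
  expect_equal(sums$dev_y_mm, rep(0, 20), tolerance = 1e-12)
})

test_that("endplate angles use the display convention on (-90, 90]", {
  expect_equal(endplate_angle(c(0, 100), c(50, 100)), 0)    # horizontal
  expect_equal(endplate_angle(c(0, 100), c(100, 0)), 45)    # rises rightward
  expect_equal(endplate_angle(c(0, 0), c(0, 50)), 90)       # vertical
  expect_equal(endplate_angle(c(0, 0), c(100, 100)), -45)   # falls rightward
  # unoriented: swapping endpoints changes nothing
  for (pts in list(list(c(0, 100), c(50, 100)), list(c(0, 0), c(30, 70)),
                   list(c(10, 10), c(10, 90)))) {
    expect_equal(endplate_angle(pts[[1]], pts[[2]]),
                 endplate_angle(pts[[2]], pts[[1]]))
  }
  expect_error(endplate_angle(c(5, 5), c(5, 5)), "degenerate")
})

test_that("angle table carries one row per rater plus consensus, per line", {
  offsets <- c(r1 = 0, r2 = 1, r3 = 2, r4 = 3, r5 = 4, r6 = 5)
  set <- annotation_set(make_annotation_df(case_ids = "c1",
                                           rater_ids = names(offsets),
                                           rater_offset_px = offsets))
  ang <- angle_table(set)
  expect_equal(nrow(ang), 70L)  # 5 vertebrae x 2 lines x (6 raters + consensus)
  # pure translation between raters: every angle equals the consensus angle
  for (key in unique(paste(ang$vertebra, ang$line))) {
    sub <- ang[paste(ang$vertebra, ang$line) == key, ]
    expect_equal(sub$angle_deg, rep(sub$angle_deg[1], nrow(sub)))
  }
})

test_that("consensus angle comes from consensus endpoints, not mean rater angles", {
  # two raters tilt the upper endplate by +/- 1 degree around horizontal;
  # consensus endpoints are the midpoints, giving an exactly horizontal UVEL
  base <- make_annotation_df(case_ids = "c1", rater_ids = c("r1", "r2"))
  uvel <- base$vertebra == "L1" & base$point_id %in% c("p1", "p2")
  half_w <- 140
  dy <- half_w * tan(1 * pi / 180)
  r1 <- base$rater_id == "r1"
  base$y_px[uvel & r1 & base$point_id == "p1"] <-
    base$y_px[uvel & r1 & base$point_id == "p1"] + dy
  base$y_px[uvel & r1 & base$point_id == "p2"] <-
    base$y_px[uvel & r1 & base$point_id == "p2"] - dy
  r2 <- base$rater_id == "r2"
  base$y_px[uvel & r2 & base$point_id == "p1"] <-
    base$y_px[uvel & r2 & base$point_id == "p1"] - dy
  base$y_px[uvel & r2 & base$point_id == "p2"] <-
    base$y_px[uvel & r2 & base$point_id == "p2"] + dy
  ang <- angle_table(annotation_set(base))
  l1u <- ang[ang$vertebra == "L1" & ang$line == "UVEL", ]
  expect_equal(sort(l1u$angle_deg[l1u$rater_id != "CONSENSUS"]), c(-1, 1))
  expect_equal(l1u$angle_deg[l1u$rater_id == "CONSENSUS"], 0)
})

test_that("rater angle RMSE matches hand-computed errors", {
  offsets <- c(r1 = 0, r2 = 2)
  set <- annotation_set(make_annotation_df(case_ids = c("c1", "c2"),
                                           rater_ids = names(offsets),
                                           rater_offset_px = offsets))
  ang <- angle_table(set)
  # translations leave angles equal: RMSE is exactly zero
  expect_equal(rater_angle_rmse(ang, "r1", "AP", "L1", "UVEL"), 0)

  # synthetic errors {3, 4} degrees over two cases -> sqrt(12.5)
  ang2 <- data.frame(
    case_id = c("c1", "c1", "c2", "c2"),
    view = "AP", vertebra = "L1", line = "UVEL",
    rater_id = c("r1", "CONSENSUS", "r1", "CONSENSUS"),
    angle_deg = c(3, 0, -4, 0),
    stringsAsFactors = FALSE
  )
  expect_equal(rater_angle_rmse(ang2, "r1", "AP", "L1", "UVEL"),
               sqrt(12.5))
  expect_error(rater_angle_rmse(ang2, "r9", "AP", "L1", "UVEL"),
               "insufficient data")
})

test_that("deviations and angle differences are translation invariant", {
  offsets <- c(r1 = 0, r2 = 3, r3 = 7)
  df <- make_annotation_df(case_ids = c("c1", "c2"),
                           rater_ids = names(offsets),
                           rater_offset_px = offsets)
  set <- annotation_set(df)
  shifted <- df
  shift_rows <- shifted$case_id == "c1"
  shifted$x_px[shift_rows] <- shifted$x_px[shift_rows] + 37
  shifted$y_px[shift_rows] <- shifted$y_px[shift_rows] - 25
  set2 <- annotation_set(shifted)

  canon <- function(d) d[order(d$case_id, d$rater_id, d$vertebra, d$point_id), ]
  d1 <- canon(deviation_table(set))
  d2 <- canon(deviation_table(set2))
  expect_equal(d2$dev_mm, d1$dev_mm, tolerance = 1e-12)
  expect_equal(d2$dev_x_mm, d1$dev_x_mm, tolerance = 1e-12)

  diffs <- function(s) {
    ang <- angle_table(s)
    cons <- ang[ang$rater_id == "CONSENSUS", ]
    rat <- ang[ang$rater_id != "CONSENSUS", ]
    ci <- match(paste(rat$case_id, rat$view, rat$vertebra, rat$line),
                paste(cons$case_id, cons$view, cons$vertebra, cons$line))
    d <- rat$angle_deg - cons$angle_deg[ci]
    d[order(rat$case_id, rat$rater_id, rat$vertebra, rat$line)]
  }
  expect_equal(diffs(set2), diffs(set), tolerance = 1e-12)
})
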