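test_that("a complete rectangular CSV reads into a full annotation set", {
  df <- make_annotation_df(case_ids = c("c1", "c2"), rater_ids = c("r1", "r2"))
  set <- read_annotations(write_temp_csv(df))
  expect_s3_class(set, "annotation_set")
  expect_equal(nrow(set$annotations), 80L)  # 2 cases x 1 view x 2 raters x 20
  expect_equal(nrow(set$missing), 0L)
  expect_setequal(set$raters, c("r1", "r2"))
  expect_setequal(set$cases, c("c1", "c2"))
})

test_that("a wholly-absent case/view/rater is recorded as missing", {
  df <- make_annotation_df(case_ids = c("c1", "c2"), rater_ids = c("r1", "r2"))
  df <- df[!(df$case_id == "c1" & df$rater_id == "r2"), ]
  set <- read_annotations(write_temp_csv(df))
  expect_equal(nrow(set$missing), 1L)
  expect_equal(set$missing$case_id, "c1")
  expect_equal(set$missing$view, "AP")
  expect_equal(set$missing$rater_id, "r2")
})

test_that("a partially labelled case/view/rater is an integrity error", {
  df <- make_annotation_df(case_ids = c("c1", "c2"), rater_ids = c("r1", "r2"))
  drop_one <- which(df$case_id == "c1" & df$rater_id == "r2")[1L]
  expect_error(read_annotations(write_temp_csv(df[-drop_one, ])),
               "incomplete labelling")
})

test_that("malformed headers, duplicates and out-of-range coordinates error", {
  df <- make_annotation_df()
  bad <- df
  names(bad)[names(bad) == "x_px"] <- "x"
  expect_error(read_annotations(write_temp_csv(bad)), "x_px")

  expect_error(annotation_set(rbind(df, df[1, ])), "duplicate")

  oob <- df
  oob$x_px[1] <- 5000  # image is 1953 px wide
  expect_error(annotation_set(oob), "outside")

  neg <- df
  neg$y_px[1] <- -2
  expect_error(annotation_set(neg), "non-negative")
})

test_that("write/read round-trips an annotation set exactly", {
  withr::with_seed(42, {
    df <- make_annotation_df(case_ids = sprintf("c%d", 1:4),
                             views = c("AP", "LAT"),
                             rater_ids = sprintf("r%d", 1:3))
    df$x_px <- df$x_px + runif(nrow(df), -5, 5)  # sub-pixel coordinates
    df$y_px <- df$y_px + runif(nrow(df), -5, 5)
    # knock out a few whole case/view/rater triples
    cvr <- unique(df[c("case_id", "view", "rater_id")])
    gone <- cvr[sample(nrow(cvr), 3), ]
    df <- df[!paste(df$case_id, df$view, df$rater_id) %in%
               paste(gone$case_id, gone$view, gone$rater_id), ]
  })
  set <- read_annotations(write_temp_csv(df))
  path <- tempfile(fileext = ".csv")
  write_annotations(set, path)
  set2 <- read_annotations(path)

  canon <- function(a) {
    a <- a[do.call(order, unname(as.list(a[intersect(
      c("case_id", "view", "rater_id", "vertebra", "point_id"),
      names(a))]))), ]
    rownames(a) <- NULL
    a
  }
  expect_identical(canon(set2$annotations), canon(set$annotations))
  expect_identical(canon(set2$missing[c("case_id", "view", "rater_id")]),
                   canon(set$missing[c("case_id", "view", "rater_id")]))
  expect_identical(set2$raters, set$raters)
})

test_that("an empty annotation set writes a header-only CSV", {
  empty <- annotation_set(make_annotation_df()[0, ])
  path <- tempfile(fileext = ".csv")
  write_annotations(empty, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^case_id,view,rater_id,vertebra,point_id,x_px,y_px$")
})

test_that("pixel-to-mm conversion is exact, linear, and guards its domain", {
  cal <- calibration()
  expect_equal(px_to_mm(1, cal), 0.143)
  expect_equal(px_to_mm(0, cal), 0)
  expect_equal(px_to_mm(10, cal), 1.43)
  expect_error(px_to_mm(-1, cal), "non-negative")
  for (ab in list(c(1, 2), c(0.5, 7.25), c(0, 3))) {
    expect_equal(px_to_mm(sum(ab), cal), sum(px_to_mm(ab, cal)))
  }
})

test_that("calibration can be read from YAML and JSON config files", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("mm_per_px: 0.2", "image_width: 1000"), yml)
  cal <- read_calibration(yml)
  expect_equal(cal$mm_per_px, 0.2)
  expect_equal(cal$image_width, 1000L)
  expect_equal(cal$image_height, 3000L)  # default retained

  jsn <- tempfile(fileext = ".json")
  writeLines('{"mm_per_px": 0.25}', jsn)
  expect_equal(read_calibration(jsn)$mm_per_px, 0.25)
})

test_that("the canonical design splits cases 600/600 with a 200-case overlap", {
  d <- make_two_group_design()
  cg <- d$case_groups
  expect_length(d$rater_groups, 12L)
  expect_equal(sum(d$rater_groups == "A"), 6L)
  expect_equal(sum(cg$in_A), 600L)
  expect_equal(sum(cg$in_B), 600L)
  expect_equal(sum(cg$in_A & cg$in_B), 200L)
  expect_true(all(cg$case_id[cg$in_A & cg$in_B] %in% as.character(401:600)))
  # |A| + |B| - |both| = n
  expect_equal(sum(cg$in_A) + sum(cg$in_B) - sum(cg$in_A & cg$in_B), 1000L)
})

test_that("the proportional design rule enumerates correctly at n = 5", {
  d <- make_two_group_design(n_cases = 5)
  cg <- d$case_groups
  expect_setequal(cg$case_id[cg$in_A], c("1", "2", "3"))
  expect_setequal(cg$case_id[cg$in_B], c("3", "4", "5"))
  expect_equal(sum(cg$in_A & cg$in_B), 1L)
  expect_error(make_two_group_design(n_cases = 7), "divisible by 5")
})

test_that("design validation flags out-of-group annotations and counts cases", {
  cfg <- study_config(n_cases = 20, seed = 3, missing_rate = 0)
  st <- simulate_study(cfg)
  v <- validate_design(st$set, st$design)
  expect_equal(nrow(v$violations), 0L)
  expect_equal(v$n_cases_A, 12L)
  expect_equal(v$n_cases_B, 12L)
  expect_equal(v$n_common, 4L)

  # rater r01 (group A) labelling a B-only case is a violation
  extra <- make_annotation_df(case_ids = "19", views = "AP",
                              rater_ids = "r01")
  bad <- annotation_set(rbind(st$set$annotations, extra),
                        calibration = st$set$calibration)
  vb <- validate_design(bad, st$design)
  expect_equal(nrow(vb$violations), 1L)
  expect_equal(vb$violations$rater_id, "r01")
  expect_equal(vb$violations$case_id, "19")

  empty <- annotation_set(make_annotation_df()[0, ])
  ve <- validate_design(empty, st$design)
  expect_equal(nrow(ve$violations), 0L)
})

test_that("study designs round-trip through their CSV representation", {
  d <- make_two_group_design(n_cases = 25, raters_per_group = 3)
  stem <- tempfile()
  write_design(d, stem)
  d2 <- read_design(stem)
  expect_identical(d2$rater_groups, d$rater_groups)
  expect_identical(d2$case_groups, d$case_groups)
})
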