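#' Two-group rater study design
#'
#' @param rater_groups named character vector mapping rater_id to "A" or "B".
#' @param case_groups data.frame with columns `case_id`, `in_A`, `in_B`
#'   (logicals); a case may belong to both groups (common cases).
#' @return an object of class `study_design`.
#' @export
study_design <- function(rater_groups, case_groups) {
  if (is.null(names(rater_groups)) || any(names(rater_groups) == "")) {
    stop("`rater_groups` must be a named vector (names = rater ids)",
         call. = FALSE)
  }
  if (!all(rater_groups %in% c("A", "B"))) {
    stop("rater groups must be 'A' or 'B'", call. = FALSE)
  }
  cg <- as.data.frame(case_groups)
  stopifnot(all(c("case_id", "in_A", "in_B") %in% names(cg)))
  cg$case_id <- as.character(cg$case_id)
  if (anyDuplicated(cg$case_id)) stop("duplicate case ids", call. = FALSE)
  if (any(!cg$in_A & !cg$in_B)) {
    stop("every case must belong to at least one group", call. = FALSE)
  }
  structure(list(rater_groups = rater_groups,
                 case_groups = cg[c("case_id", "in_A", "in_B")]),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d raters (A: %d, B: %d) | cases A: %d, B: %d, common: %d\n",
    length(x$rater_groups), sum(x$rater_groups == "A"),
    sum(x$rater_groups == "B"), sum(x$case_groups$in_A),
    sum(x$case_groups$in_B), sum(x$case_groups$in_A & x$case_groups$in_B)))
  invisible(x)
}

#' The canonical two-group labelling design
#'
#' Reproduces the split used in large multi-rater labelling studies: raters
#' are divided into two equal groups; with `n_cases = 1000` cases 1-600 are
#' assigned to group A, cases 401-1000 to group B, so cases 401-600 (the
#' middle fifth) are labelled by both groups. For other `n_cases` divisible
#' by 5 the same proportional rule applies: each group receives 3/5 of the
#' cases and the middle fifth is common.
#'
#' @param n_cases number of cases (divisible by 5).
#' @param raters_per_group raters in each of the two groups.
#' @return a [study_design()]. Rater ids are `r01`, `r02`, ... with the first
#'   `raters_per_group` in group A; case ids are `"1"` ... `"n_cases"`.
#' @examples
#' d <- make_two_group_design()
#' sum(d$case_groups$in_A)                      # 600
#' sum(d$case_groups$in_A & d$case_groups$in_B) # 200
#' @export
make_two_group_design <- function(n_cases = 1000L, raters_per_group = 6L) {
  stopifnot_scalar_number(n_cases, "n_cases", min = 1)
  stopifnot_scalar_number(raters_per_group, "raters_per_group", min = 1)
  if (n_cases %% 5 != 0) {
    stop("`n_cases` must be divisible by 5 for the 3/5 + middle-fifth rule",
         call. = FALSE)
  }
  n_raters <- 2L * as.integer(raters_per_group)
  rater_ids <- sprintf("r%02d", seq_len(n_raters))
  rater_groups <- stats::setNames(
    rep(c("A", "B"), each = raters_per_group), rater_ids)

  fifth <- n_cases / 5
  idx <- seq_len(n_cases)
  case_groups <- data.frame(
    case_id = as.character(idx),
    in_A = idx <= 3 * fifth,
    in_B = idx > 2 * fifth,
    stringsAsFactors = FALSE
  )
  study_design(rater_groups, case_groups)
}

#' Check an annotation set against a study design
#'
#' Report-only validation: lists annotations whose rater labelled a case not
#' assigned to that rater's group, and tallies the per-group case counts.
#'
#' @param set an [annotation_set()].
#' @param design a [study_design()].
#' @return a list with `violations` (data.frame rater_id, case_id, view),
#'   `n_cases_A`, `n_cases_B`, `n_common`.
#' @export
validate_design <- function(set, design) {
  stopifnot(inherits(set, "annotation_set"), inherits(design, "study_design"))
  ann <- unique(set$annotations[c("case_id", "view", "rater_id")])
  cg <- design$case_groups
  grp <- design$rater_groups[ann$rater_id]
  in_grp <- ifelse(grp == "A",
                   cg$in_A[match(ann$case_id, cg$case_id)],
                   cg$in_B[match(ann$case_id, cg$case_id)])
  in_grp[is.na(in_grp)] <- FALSE
  violations <- ann[!in_grp, c("rater_id", "case_id", "view"), drop = FALSE]
  rownames(violations) <- NULL
  list(
    violations = violations,
    n_cases_A = sum(cg$in_A),
    n_cases_B = sum(cg$in_B),
    n_common = sum(cg$in_A & cg$in_B)
  )
}

#' Write a study design to CSV files
#'
#' Writes `<stem>_raters.csv` (`rater_id,group`) and `<stem>_cases.csv`
#' (`case_id,groups` with groups semicolon-joined).
#'
#' @param design a [study_design()].
#' @param stem file-path stem.
#' @return the two paths, invisibly.
#' @export
write_design <- function(design, stem) {
  stopifnot(inherits(design, "study_design"))
  rp <- paste0(stem, "_raters.csv")
  cp <- paste0(stem, "_cases.csv")
  utils::write.csv(
    data.frame(rater_id = names(design$rater_groups),
               group = unname(design$rater_groups)),
    rp, row.names = FALSE, quote = FALSE)
  groups <- ifelse(design$case_groups$in_A & design$case_groups$in_B, "A;B",
                   ifelse(design$case_groups$in_A, "A", "B"))
  utils::write.csv(
    data.frame(case_id = design$case_groups$case_id, groups = groups),
    cp, row.names = FALSE, quote = FALSE)
  invisible(c(raters = rp, cases = cp))
}

#' Read a study design written by [write_design()]
#'
#' @param stem file-path stem used at write time.
#' @return a [study_design()].
#' @export
read_design <- function(stem) {
  rd <- utils::read.csv(paste0(stem, "_raters.csv"),
                        stringsAsFactors = FALSE, colClasses = "character")
  cd <- utils::read.csv(paste0(stem, "_cases.csv"),
                        stringsAsFactors = FALSE, colClasses = "character")
  gl <- strsplit(cd$groups, ";", fixed = TRUE)
  study_design(
    stats::setNames(rd$group, rd$rater_id),
    data.frame(case_id = cd$case_id,
               in_A = vapply(gl, function(g) "A" %in% g, logical(1)),
               in_B = vapply(gl, function(g) "B" %in% g, logical(1)),
               stringsAsFactors = FALSE)
  )
}
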