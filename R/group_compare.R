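# Random-intercept linear mixed model for rater-group homogeneity.
#
# Model: value = mu + beta * 1[group == B] + u_case + eps,
#        u_case ~ N(0, sigma2_c), eps ~ N(0, sigma2_e), fitted by REML.
# The variance ratio lambda = sigma2_c / sigma2_e is profiled numerically;
# for fixed lambda the GLS estimates and the profiled REML criterion have
# closed forms because V* = I + lambda Z Z' is block diagonal by case:
# inv(I + lambda J_ni) = I - lambda / (1 + lambda ni) J_ni.

# profiled REML pieces for a given lambda; X has p columns
reml_eval <- function(lambda, y, X, case_idx, case_sizes) {
  w <- lambda / (1 + lambda * case_sizes)   # per-case shrinkage weight
  # case-wise sums of X columns and y
  Sx <- rowsum(X, case_idx, reorder = TRUE)
  Sy <- rowsum(y, case_idx, reorder = TRUE)[, 1L]
  XtVX <- crossprod(X) - crossprod(Sx * w, Sx)
  XtVy <- crossprod(X, y) - crossprod(Sx * w, Sy)
  ytVy <- sum(y^2) - sum(w * Sy^2)
  beta <- solve(XtVX, XtVy)
  rss <- as.numeric(ytVy - crossprod(beta, XtVy))
  rss <- max(rss, 0)
  N <- length(y); p <- ncol(X)
  sigma2_e <- rss / (N - p)
  logdet_V <- sum(log1p(lambda * case_sizes))
  logdet_XtVX <- determinant(XtVX, logarithm = TRUE)$modulus
  crit <- if (sigma2_e > 0) {
    (N - p) * log(sigma2_e) + logdet_V + as.numeric(logdet_XtVX)
  } else {
    -1e300  # perfect fit; large finite value keeps the optimizer well-posed
  }
  list(criterion = crit, beta = as.numeric(beta), sigma2_e = sigma2_e,
       XtVX = XtVX, rss = rss)
}

#' Fit the rater-group homogeneity mixed model
#'
#' Fits `value = mu + beta * 1[group == B] + u_case + eps` by REML, profiling
#' the case-to-residual variance ratio with Brent's method (with an explicit
#' boundary check at ratio zero), and tests `beta = 0` with a Wald t
#' statistic on `(number of distinct cases) - 2` degrees of freedom. Patient
#' case is the clustering unit: common cases rated by both groups share one
#' random intercept, which is what makes the between-group contrast fair.
#'
#' @param data data.frame with columns `case_id`, `rater_id`, `group`
#'   (`"A"`/`"B"`), `value`.
#' @return list of class `group_test`: `effect` (B - A), `se`, `t`, `df`,
#'   `p_value`, `var_case`, `var_resid`, `lambda`, `n_cases`, `n_obs`,
#'   `reml_criterion`.
#' @export
fit_group_lmm <- function(data) {
  req <- c("case_id", "rater_id", "group", "value")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(data$group %in% c("A", "B"))) {
    stop("`group` must be 'A' or 'B'", call. = FALSE)
  }
  tab <- table(unique(data[c("case_id", "group")])$group)
  if (length(tab) < 2L) {
    stop("both groups must be present", call. = FALSE)
  }
  if (any(tab < 2L)) {
    stop("need >= 2 cases per group", call. = FALSE)
  }
  y <- as.numeric(data$value)
  if (anyNA(y)) stop("`value` contains missing entries", call. = FALSE)
  X <- cbind(intercept = 1, groupB = as.numeric(data$group == "B"))
  case_f <- factor(data$case_id)
  case_idx <- as.integer(case_f)
  case_sizes <- as.numeric(table(case_f))
  n_cases <- nlevels(case_f)

  crit_of_loglam <- function(loglam) {
    reml_eval(exp(loglam), y, X, case_idx, case_sizes)$criterion
  }
  at0 <- reml_eval(0, y, X, case_idx, case_sizes)
  if (at0$sigma2_e == 0) {
    # zero residual variance at lambda = 0: perfect fit, nothing to profile
    lambda_hat <- 0
    fit <- at0
  } else if ({opt <- stats::optimize(crit_of_loglam, interval = c(-14, 14))
              at0$criterion <= opt$objective}) {
    lambda_hat <- 0
    fit <- at0
  } else {
    lambda_hat <- exp(opt$minimum)
    fit <- reml_eval(lambda_hat, y, X, case_idx, case_sizes)
  }

  effect <- fit$beta[2L]
  vcov_beta <- fit$sigma2_e * solve(fit$XtVX)
  se <- sqrt(max(vcov_beta[2L, 2L], 0))
  df <- n_cases - 2
  if (se == 0) {
    t_stat <- if (abs(effect) < .Machine$double.eps * 100) 0 else
      sign(effect) * Inf
  } else {
    t_stat <- effect / se
  }
  p <- if (is.infinite(t_stat)) 0 else 2 * stats::pt(-abs(t_stat), df = df)

  structure(
    list(effect = effect, se = se, t = t_stat, df = df, p_value = p,
         var_case = lambda_hat * fit$sigma2_e, var_resid = fit$sigma2_e,
         lambda = lambda_hat, n_cases = n_cases, n_obs = length(y),
         reml_criterion = fit$criterion),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "<group_test> effect (B-A) = %.4g, se = %.4g, t = %.3f (df = %g), p = %.4g\n",
    x$effect, x$se, x$t, x$df, x$p_value))
  cat(sprintf("  var(case) = %.4g, var(resid) = %.4g, %d cases / %d obs\n",
              x$var_case, x$var_resid, x$n_cases, x$n_obs))
  invisible(x)
}

# profiled REML criterion as a function of lambda, for diagnostics/tests
reml_profile <- function(data, lambdas) {
  y <- as.numeric(data$value)
  X <- cbind(1, as.numeric(data$group == "B"))
  case_f <- factor(data$case_id)
  case_idx <- as.integer(case_f)
  case_sizes <- as.numeric(table(case_f))
  vapply(lambdas,
         function(l) reml_eval(l, y, X, case_idx, case_sizes)$criterion,
         numeric(1))
}

#' Group-homogeneity tests for every landmark point and endplate line
#'
#' Builds, for each (view, vertebra, point), the per-rater-per-case Euclidean
#' deviations from the within-group consensus, and for each (view, vertebra,
#' line) the per-rater-per-case absolute angle errors, then fits
#' [fit_group_lmm()] per row: 20 point rows + 10 line rows per view.
#'
#' @param set an [annotation_set()].
#' @param design a [study_design()].
#' @return data.frame `label, view, measure, effect, se, t, df, p_value,
#'   var_case, var_resid, note`.
#' @export
group_homogeneity_report <- function(set, design) {
  stopifnot(inherits(set, "annotation_set"), inherits(design, "study_design"))

  per_group <- lapply(c(A = "A", B = "B"), function(g) {
    sset <- subset_scope(set, design, g)
    cons <- consensus_locations(sset)
    dev <- deviation_table(sset, cons)
    dev$group <- g
    ang <- angle_table(sset, cons)
    cons_key <- ang$rater_id == CONSENSUS_ID
    cona <- ang[cons_key, c("case_id", "view", "vertebra", "line", "angle_deg")]
    rat <- ang[!cons_key, , drop = FALSE]
    ci <- match(paste(rat$case_id, rat$view, rat$vertebra, rat$line),
                paste(cona$case_id, cona$view, cona$vertebra, cona$line))
    rat$abs_err <- abs(angle_difference(rat$angle_deg, cona$angle_deg[ci]))
    rat$group <- g
    list(dev = dev, ang = rat)
  })
  dev_all <- rbind(per_group$A$dev, per_group$B$dev)
  ang_all <- rbind(per_group$A$ang, per_group$B$ang)

  fit_row <- function(df, label, view, measure) {
    res <- tryCatch(fit_group_lmm(df), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(label = label, view = view, measure = measure,
                 effect = NA_real_, se = NA_real_, t = NA_real_,
                 df = NA_real_, p_value = NA_real_, var_case = NA_real_,
                 var_resid = NA_real_, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = label, view = view, measure = measure,
                 effect = res$effect, se = res$se, t = res$t, df = res$df,
                 p_value = res$p_value, var_case = res$var_case,
                 var_resid = res$var_resid, note = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }

  rows <- list()
  for (view in VIEWS) {
    for (vertebra in VERTEBRAE) {
      for (point in POINT_IDS) {
        d <- dev_all[dev_all$view == view & dev_all$vertebra == vertebra &
                       dev_all$point_id == point, , drop = FALSE]
        if (nrow(d) == 0L) next
        rows[[length(rows) + 1L]] <- fit_row(
          data.frame(case_id = d$case_id, rater_id = d$rater_id,
                     group = d$group, value = d$dev_mm,
                     stringsAsFactors = FALSE),
          paste0(vertebra, "_", point), view, "point_deviation_mm")
      }
      for (line in LINES) {
        a <- ang_all[ang_all$view == view & ang_all$vertebra == vertebra &
                       ang_all$line == line, , drop = FALSE]
        if (nrow(a) == 0L) next
        rows[[length(rows) + 1L]] <- fit_row(
          data.frame(case_id = a$case_id, rater_id = a$rater_id,
                     group = a$group, value = a$abs_err,
                     stringsAsFactors = FALSE),
          paste0(vertebra, "_", line), view, "angle_abs_error_deg")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
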