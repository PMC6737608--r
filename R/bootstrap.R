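#' Stratified bootstrap confidence intervals for PAF estimates
#'
#' Nonparametric percentile bootstrap respecting the case-control
#' design: cases and controls are resampled with replacement
#' separately, preserving `n_cases` and `n_controls`, and the whole
#' estimation pipeline (logistic refit, exposure distributions, exact
#' and approximate PAF) is rerun on each resample.  For continuous
#' exposures the spline basis (knots) is held at its full-data
#' configuration and the minimum-risk reference value is re-selected
#' for each replicate's refitted curve.
#'
#' Replicates whose refit fails (non-convergence, separation, or an
#' exposure level absent from one outcome stratum in the resample) are
#' skipped and counted; more than 10% failures is an error.
#'
#' @param object A `"paf"` fit from [paf()] on subject-level data.
#' @param n_reps Number of bootstrap replicates (>= 2).
#' @param level Confidence level in (0, 1); default 0.99.
#' @param seed Seed for the resampling stream; results are
#'   deterministic given `(object, n_reps, seed)`.
#'
#' @return An object of class `"paf_boot"`: percentile intervals
#'   `exact` and `approx` (length-2 vectors), the `replicates` matrix
#'   (`n_reps` x 2, `NA` rows for failed refits), `n_fail`, `level`,
#'   `n_reps` and `seed`.
#' @export
bootstrap_ci <- function(object, n_reps = 199L, level = 0.99, seed = 1L) {
  stopifnot(inherits(object, "paf"))
  if (is.null(object$model) || is.null(object$model$prep))
    stop("bootstrap_ci needs a fit produced from subject-level data")
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")

  prep <- object$model$prep
  kind <- object$exposure_kind
  spline_df <- if (kind == "continuous") object$model$spline_df else 4L
  mm <- cc_model_matrix(prep, spline_df)
  X <- mm$X
  y <- prep$y
  idx_a <- seq_len(mm$n_exposure_cols) + 1L
  i_case <- which(y == 1L)
  i_ctrl <- which(y == 0L)

  if (kind == "continuous") {
    trim <- object$model$trim
    qs <- stats::quantile(object$model$exposure_values, probs = trim,
                          names = FALSE)
    grid <- seq(qs[1], qs[2], length.out = 501L)
    Bgrid <- stats::predict(mm$basis, grid)
    # per-subject basis rows, for curve evaluation at resampled values
    Bsubj <- unclass(mm$basis)
  } else {
    acode <- as.integer(prep$a)
    n_lev <- nlevels(prep$a)
  }

  reps <- matrix(NA_real_, n_reps, 2L,
                 dimnames = list(NULL, c("exact", "approx")))
  n_fail <- 0L
  set.seed(seed)
  for (r in seq_len(n_reps)) {
    idx <- c(sample(i_case, replace = TRUE), sample(i_ctrl, replace = TRUE))
    yr <- y[idx]
    est <- tryCatch({
      if (kind != "continuous") {
        tc <- tabulate(acode[idx][yr == 1L], nbins = n_lev)
        tk <- tabulate(acode[idx][yr == 0L], nbins = n_lev)
        if (any(tc == 0L) || any(tk == 0L))
          stop("level absent in resample")
      }
      fit <- fit_logistic(X[idx, , drop = FALSE], yr)
      cf <- fit$coefficients
      if (!fit$converged || anyNA(cf) || max(abs(cf)) > 15)
        stop("refit failed")
      if (kind == "continuous") {
        bcoef <- cf[idx_a]
        gvals <- drop(Bgrid %*% bcoef)
        anchor <- gvals[which.min(gvals)]
        curve_subj <- drop(Bsubj[idx, , drop = FALSE] %*% bcoef) - anchor
        bave <- mean(curve_subj[yr == 0L])
        exact <- mean(1 - exp(-curve_subj[yr == 1L]))
        c(exact, 1 * bave)
      } else {
        betas <- c(0, unname(cf[idx_a]))
        case_probs <- tc / sum(tc)
        control_probs <- tk / sum(tk)
        exact <- sum(case_probs[-1L] * (1 - exp(-betas[-1L])))
        prev <- 1 - control_probs[1L]
        bave <- sum(control_probs[-1L] * betas[-1L]) / prev
        c(exact, prev * bave)
      }
    }, error = function(e) NULL)
    if (is.null(est)) n_fail <- n_fail + 1L else reps[r, ] <- est
  }

  if (n_fail == n_reps)
    stop("bootstrap failure: every resample failed to refit")
  if (n_fail > 0.1 * n_reps)
    stop("bootstrap failure: ", n_fail, " of ", n_reps,
         " resamples failed to refit (> 10%)")

  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(
    list(exact = unname(stats::quantile(reps[, 1L], probs, na.rm = TRUE)),
         approx = unname(stats::quantile(reps[, 2L], probs, na.rm = TRUE)),
         replicates = reps, n_fail = n_fail, n_reps = n_reps,
         level = level, seed = seed),
    class = "paf_boot"
  )
}

#' @export
print.paf_boot <- function(x, ...) {
  cat("Stratified bootstrap, ", x$n_reps, " replicates (",
      x$n_fail, " failed), level ", x$level, "\n", sep = "")
  cat("  exact PAF:  [", format(x$exact[1], digits = 4), ", ",
      format(x$exact[2], digits = 4), "]\n", sep = "")
  cat("  approx PAF: [", format(x$approx[1], digits = 4), ", ",
      format(x$approx[2], digits = 4), "]\n", sep = "")
  invisible(x)
}
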