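#' Summary of a discrete (binary or multi-category) exposure
#'
#' Bundles the pieces needed to compute attributable fractions for an
#' exposure with levels `0, 1, ..., K`, level 0 being the (minimum-risk)
#' reference: the exposure distribution among controls and among cases,
#' and the per-level log-odds ratios relative to the reference.
#'
#' @param control_probs Probabilities `P(A = j | Y = 0)`, one per level,
#'   reference level first; must sum to 1.
#' @param case_probs Probabilities `P(A = j | Y = 1)`, same layout.
#' @param betas Log-odds ratios (natural log) per level; `betas[1]`, the
#'   reference, must be 0.
#' @param labels Optional level labels; defaults to `"0", "1", ...`.
#'
#' @return An object of class `"level_summary"`.
#' @seealso [exact_paf_discrete()], [beta_ave_discrete()]
#' @export
#' @examples
#' level_summary(c(0.9, 0.1), c(0.7, 0.3), c(0, log(2)))
level_summary <- function(control_probs, case_probs, betas, labels = NULL) {
  k1 <- length(control_probs)
  if (k1 < 2L || length(case_probs) != k1 || length(betas) != k1)
    stop("control_probs, case_probs and betas must have a common length K+1 >= 2")
  if (!all(is.finite(control_probs)) || !all(is.finite(case_probs)) ||
      !all(is.finite(betas)))
    stop("all entries of a level summary must be finite")
  for (nm in c("control_probs", "case_probs")) {
    p <- get(nm)
    if (any(p < 0) || any(p > 1))
      stop(nm, " must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      stop(nm, " must sum to 1 (within 1e-9); got ", format(sum(p), digits = 12))
  }
  if (abs(betas[1L]) > 1e-12)
    stop("the reference-level log-odds ratio betas[1] must be 0")
  if (is.null(labels)) labels <- as.character(seq_len(k1) - 1L)
  if (length(labels) != k1) stop("labels must match the number of levels")
  structure(
    list(labels = as.character(labels),
         control_probs = as.numeric(control_probs),
         case_probs = as.numeric(case_probs),
         betas = as.numeric(betas)),
    class = "level_summary"
  )
}

#' @export
print.level_summary <- function(x, ...) {
  cat("Discrete exposure summary (", length(x$labels) - 1L,
      " non-reference level(s))\n", sep = "")
  m <- rbind(`P(A=j|Y=0)` = x$control_probs,
             `P(A=j|Y=1)` = x$case_probs,
             `log OR` = x$betas)
  colnames(m) <- x$labels
  print(round(m, 4), ...)
  invisible(x)
}

#' Summary of a continuous exposure
#'
#' Holds the empirical exposure distributions among controls and cases
#' together with a fitted log-odds-ratio curve anchored at a reference
#' (minimum-risk) exposure value.  The integrals against the conditional
#' exposure densities that define the continuous-exposure attributable
#' fraction are evaluated as plug-in means over these samples.
#'
#' @param control_values Exposure values observed among controls.
#' @param case_values Exposure values observed among cases.
#' @param beta_curve Function mapping exposure value `j` to the log-odds
#'   ratio relative to the reference value; must be vectorised and
#'   satisfy `beta_curve(reference_value) == 0` (within 1e-9).
#' @param reference_value The anchoring value `j0`.
#'
#' @return An object of class `"continuous_summary"`.
#' @seealso [exact_paf_continuous()], [beta_ave_continuous()]
#' @export
continuous_summary <- function(control_values, case_values, beta_curve,
                               reference_value) {
  if (!length(control_values) || !length(case_values))
    stop("control_values and case_values must be non-empty")
  if (!is.function(beta_curve))
    stop("beta_curve must be a function of the exposure value")
  if (!is.numeric(reference_value) || length(reference_value) != 1L ||
      !is.finite(reference_value))
    stop("reference_value must be a single finite number")
  b0 <- beta_curve(reference_value)
  if (!is.finite(b0) || abs(b0) > 1e-9)
    stop("beta_curve must be 0 at the reference value (got ",
         format(b0), ")")
  structure(
    list(control_values = as.numeric(control_values),
         case_values = as.numeric(case_values),
         beta_curve = beta_curve,
         reference_value = reference_value),
    class = "continuous_summary"
  )
}

#' @export
print.continuous_summary <- function(x, ...) {
  cat("Continuous exposure summary\n",
      "  controls: n = ", length(x$control_values),
      ", cases: n = ", length(x$case_values), "\n",
      "  reference value j0 = ", format(x$reference_value), "\n", sep = "")
  invisible(x)
}

#' Approximate population attributable fraction
#'
#' The first-order approximation to the PAF: the exposure prevalence
#' among controls multiplied by the (average) log-odds ratio.  For small
#' log-odds ratios this tracks the exact case-side calculation closely;
#' see [bias_surface()] for when it does not.  The value is returned
#' as-is even when it exceeds 1 (with a warning), so that graphical
#' devices built on it stay honest.
#'
#' @param control_prevalence `P(A != reference | Y = 0)`, in `(0, 1]`.
#'   For continuous exposures this is 1 by convention.
#' @param beta_ave Average log-odds ratio (natural log); a negative
#'   value triggers a warning (the exposure coding should make the
#'   reference the minimum-risk level) but is still used.
#'
#' @return `control_prevalence * beta_ave`, a proportion (possibly > 1).
#' @export
#' @examples
#' approx_paf(0.474, 1.093)  # ~ 0.518
approx_paf <- function(control_prevalence, beta_ave) {
  if (!is.numeric(control_prevalence) || !is.numeric(beta_ave) ||
      !all(is.finite(control_prevalence)) || !all(is.finite(beta_ave)))
    stop("control_prevalence and beta_ave must be finite numbers")
  if (any(control_prevalence <= 0) || any(control_prevalence > 1))
    stop("control_prevalence must lie in (0, 1]")
  if (any(beta_ave < 0))
    warning("negative beta_ave: the reference level does not appear to be ",
            "the minimum-risk level; the approximate PAF will be negative")
  out <- control_prevalence * beta_ave
  if (any(out > 1))
    warning("approximate PAF exceeds 1; the approximation is not reliable ",
            "at this prevalence/odds-ratio combination")
  out
}

#' Exact attributable fraction for a discrete exposure
#'
#' Case-side plug-in estimator
#' `sum_j P(A=j|Y=1) * (exp(beta_j) - 1) / exp(beta_j)` over the
#' non-reference levels, valid under the rare-disease assumption where
#' odds ratios approximate relative risks.  For a binary exposure this
#' is the familiar `pi_c * (OR - 1) / OR`.
#'
#' @param summary A [level_summary()].
#' @return The exact PAF, a proportion.
#' @export
#' @examples
#' s <- level_summary(c(0.9, 0.1), c(0.7, 0.3), c(0, log(27 / 7)))
#' exact_paf_discrete(s)  # 0.3 * (1 - 7/27)
exact_paf_discrete <- function(summary) {
  stopifnot(inherits(summary, "level_summary"))
  sum(summary$case_probs[-1L] * (1 - exp(-summary$betas[-1L])))
}

#' Average log-odds ratio for a discrete exposure
#'
#' Control-distribution-weighted mean of the non-reference log-odds
#' ratios:
#' `sum_j P(A=j|Y=0) beta_j / (1 - P(A=0|Y=0))`.
#' For a binary exposure this reduces to the single log-odds ratio.
#'
#' @param summary A [level_summary()].
#' @return The averaged log-odds ratio (natural log).
#' @export
beta_ave_discrete <- function(summary) {
  stopifnot(inherits(summary, "level_summary"))
  p0 <- summary$control_probs[1L]
  if (p0 >= 1 - 1e-12)
    stop("degenerate exposure: all controls are at the reference level, ",
         "so the average log-odds ratio is undefined")
  sum(summary$control_probs[-1L] * summary$betas[-1L]) / (1 - p0)
}

#' Average log-odds ratio for a continuous exposure
#'
#' Empirical version of the integral of the log-odds-ratio curve against
#' the control exposure density: the mean of `beta_curve` over the
#' control sample.
#'
#' @param summary A [continuous_summary()].
#' @return The averaged log-odds ratio (natural log).
#' @export
beta_ave_continuous <- function(summary) {
  stopifnot(inherits(summary, "continuous_summary"))
  if (!length(summary$control_values)) stop("empty control sample")
  mean(summary$beta_curve(summary$control_values))
}

#' Exact attributable fraction for a continuous exposure
#'
#' Empirical version of the case-density integral
#' `int f(j|1) (exp(beta(j)) - 1) / exp(beta(j)) dj`: the mean of
#' `1 - exp(-beta_curve(a))` over the case sample.
#'
#' @param summary A [continuous_summary()].
#' @return The exact PAF, a proportion.
#' @export
exact_paf_continuous <- function(summary) {
  stopifnot(inherits(summary, "continuous_summary"))
  if (!length(summary$case_values)) stop("empty case sample")
  mean(1 - exp(-summary$beta_curve(summary$case_values)))
}

#' Approximate impact fraction of a partial intervention
#'
#' The approximate proportional reduction in disease prevalence from an
#' intervention that lowers the exposure prevalence from
#' `control_prevalence` to `new_prevalence`: the difference of the two
#' approximate PAFs, `(control_prevalence - new_prevalence) * beta_ave`.
#' For an intervention that halves the prevalence this numerically
#' equals `approx_paf(new_prevalence, beta_ave)`; full elimination
#' (`new_prevalence = 0`) recovers the approximate PAF itself.
#'
#' @param control_prevalence Current exposure prevalence in controls.
#' @param new_prevalence Post-intervention prevalence; must not exceed
#'   `control_prevalence`.
#' @param beta_ave Average log-odds ratio (natural log).
#' @return The approximate impact fraction, a proportion.
#' @export
#' @examples
#' impact_fraction_approx(0.474, 0.474 / 2, 1.093)
impact_fraction_approx <- function(control_prevalence, new_prevalence,
                                   beta_ave) {
  if (!all(is.finite(control_prevalence), is.finite(new_prevalence),
           is.finite(beta_ave)))
    stop("all arguments must be finite")
  if (any(new_prevalence < 0) || any(control_prevalence > 1))
    stop("prevalences must lie in [0, 1]")
  if (any(new_prevalence > control_prevalence))
    stop("invalid intervention: new_prevalence exceeds control_prevalence")
  if (any(beta_ave < 0))
    warning("negative beta_ave passed to impact_fraction_approx")
  (control_prevalence - new_prevalence) * beta_ave
}
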