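#' Estimate population attributable fractions from case-control data
#'
#' The main fitting function.  `paf()` fits the logistic exposure model
#' for one exposure of interest, extracts the control/case exposure
#' distributions, and composes them into the exact (case-side) and
#' approximate (prevalence times average log-odds ratio) attributable
#' fractions.  The first term on the right-hand side of `formula` is
#' the exposure; any remaining terms are confounders adjusted for in
#' the logistic fit.
#'
#' The exact PAF is
#' `sum_j P(A=j|Y=1) (e^{beta_j} - 1) / e^{beta_j}` (its integral
#' analogue for continuous exposures), valid under the standard causal
#' identification assumptions, no exposure-confounder interaction, and
#' a rare disease.  The approximate PAF is `P * beta_ave` where `P` is
#' the prevalence of a non-reference exposure level among controls
#' (fixed to 1 for continuous exposures) and `beta_ave` the
#' control-weighted average log-odds ratio.
#'
#' @param formula `outcome ~ exposure + confounder1 + ...`; the outcome
#'   must be binary (1 = case).
#' @param data Subject-level data frame.
#' @param kind Exposure kind (`"auto"` infers from the column type).
#' @param ref Reference level label for discrete exposures.
#' @param spline_df Natural-spline degrees of freedom for continuous
#'   exposures.
#' @param trim Quantile pair bounding the reference-value search for
#'   continuous exposures.
#' @param boot Number of stratified bootstrap replicates for confidence
#'   intervals; 0 (default) skips the bootstrap.
#' @param level Confidence level for the bootstrap interval.
#' @param seed Seed for the bootstrap resampling stream.
#'
#' @return An object of class `"paf"`: a list with `factor_name`,
#'   `exposure_kind`, `control_prevalence`, `beta_ave`, `or_ave`,
#'   `exact_paf`, `approx_paf`, optional `ci_lower`/`ci_upper` (each a
#'   named pair for the exact and approximate PAF), `ci_level`, the
#'   fitted `model` and the exposure `summary` object.
#' @seealso [bootstrap_ci()], [fan_layout()], [nomogram_layout()]
#' @export
#' @examples
#' d <- data.frame(y = rep(c(1, 0), c(100, 100)),
#'                 x = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)))
#' fit <- paf(y ~ x, data = d)
#' fit
paf <- function(formula, data, kind = "auto", ref = NULL, spline_df = 4L,
                trim = c(0.01, 0.99), boot = 0L, level = 0.99,
                seed = NULL) {
  stopifnot(inherits(formula, "formula"))
  tm <- stats::terms(formula, data = data)
  if (attr(tm, "response") != 1L)
    stop("formula must have a binary outcome on the left-hand side")
  outcome <- as.character(attr(tm, "variables"))[2L]
  labs <- attr(tm, "term.labels")
  if (!length(labs))
    stop("formula must name at least the exposure on the right-hand side")
  exposure <- labs[1L]
  confounders <- labs[-1L]

  model <- fit_exposure_model(data, exposure, confounders, outcome = outcome,
                              kind = kind, ref = ref, spline_df = spline_df,
                              trim = trim)
  dist <- control_case_distributions(data, exposure, confounders,
                                     outcome = outcome, kind = kind,
                                     ref = ref)
  res <- compose_paf(model, dist)
  res$call <- match.call()
  res$spline_df <- spline_df
  res$trim <- trim
  class(res) <- "paf"

  if (boot > 0L) {
    bt <- bootstrap_ci(res, n_reps = boot, level = level,
                       seed = if (is.null(seed)) 1L else seed)
    res$ci_lower <- c(exact = bt$exact[1L], approx = bt$approx[1L])
    res$ci_upper <- c(exact = bt$exact[2L], approx = bt$approx[2L])
    res$ci_level <- level
    res$boot <- bt
  }
  res
}

# Internal: combine a fitted exposure model with empirical exposure
# distributions into the PAF quantities.
compose_paf <- function(model, dist) {
  if (model$exposure_kind == "continuous") {
    s <- continuous_summary(dist$control_values, dist$case_values,
                            model$beta_curve, model$reference_value)
    beta_ave <- beta_ave_continuous(s)
    exact <- exact_paf_continuous(s)
    prevalence <- 1
  } else {
    s <- level_summary(dist$control_probs, dist$case_probs,
                       model$betas, labels = dist$labels)
    beta_ave <- beta_ave_discrete(s)
    exact <- exact_paf_discrete(s)
    prevalence <- 1 - dist$control_probs[1L]
  }
  list(
    factor_name = model$exposure,
    exposure_kind = model$exposure_kind,
    control_prevalence = prevalence,
    beta_ave = beta_ave,
    or_ave = exp(beta_ave),
    exact_paf = exact,
    approx_paf = approx_paf(prevalence, beta_ave),
    ci_lower = NULL, ci_upper = NULL, ci_level = NULL,
    model = model,
    summary = s,
    n_cases = model$n_cases,
    n_controls = model$n_controls
  )
}

#' Attributable-fraction result from published summary inputs
#'
#' Builds a `"paf"` object from a (prevalence, average log-odds ratio)
#' pair alone, the entry path for pre-computed summary rows (risk
#' factor name, control prevalence, average log-OR) when subject-level
#' data are unavailable.  Only the approximate PAF is computable from
#' these inputs; `exact_paf` is `NA`.
#'
#' @param prevalence Exposure prevalence among controls, in (0, 1].
#' @param beta_ave Average log-odds ratio (natural log).
#' @param factor_name Risk factor label.
#' @param kind Exposure kind label (metadata only).
#' @return An object of class `"paf"`.
#' @export
#' @examples
#' paf_from_summary(0.837, 0.501, "physical inactivity")  # approx 41.9%
paf_from_summary <- function(prevalence, beta_ave, factor_name = "exposure",
                             kind = "binary") {
  structure(
    list(factor_name = factor_name, exposure_kind = kind,
         control_prevalence = prevalence, beta_ave = beta_ave,
         or_ave = exp(beta_ave), exact_paf = NA_real_,
         approx_paf = approx_paf(prevalence, beta_ave),
         ci_lower = NULL, ci_upper = NULL, ci_level = NULL,
         model = NULL, summary = NULL,
         n_cases = NA_integer_, n_controls = NA_integer_),
    class = "paf"
  )
}

#' @export
print.paf <- function(x, digits = 4, ...) {
  cat("Population attributable fraction for '", x$factor_name, "' (",
      x$exposure_kind, ")\n", sep = "")
  cat("  control prevalence P:", format(x$control_prevalence, digits = digits),
      "\n")
  cat("  average log-OR:", format(x$beta_ave, digits = digits),
      " (OR ", format(x$or_ave, digits = digits), ")\n")
  cat("  exact PAF:  ", format(x$exact_paf, digits = digits), "\n")
  cat("  approx PAF: ", format(x$approx_paf, digits = digits),
      "  (= P x average log-OR)\n")
  if (!is.null(x$ci_lower)) {
    cat("  ", format(100 * x$ci_level), "% bootstrap CI (exact): [",
        format(x$ci_lower[["exact"]], digits = digits), ", ",
        format(x$ci_upper[["exact"]], digits = digits), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.paf <- function(object, ...) {
  structure(list(fit = object), class = "summary.paf")
}

#' @export
print.summary.paf <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (!is.null(f$model)) {
    cat("\n")
    print(f$model)
  }
  if (!is.null(f$boot)) {
    cat("\nBootstrap: ", f$boot$n_reps, " stratified replicates, ",
        f$boot$n_fail, " failed refits\n", sep = "")
    cat("  approx PAF CI: [",
        format(f$ci_lower[["approx"]], digits = 4), ", ",
        format(f$ci_upper[["approx"]], digits = 4), "]\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.paf <- function(object, ...) {
  if (is.null(object$model))
    return(c(beta_ave = object$beta_ave))
  if (object$exposure_kind == "continuous")
    c(beta_ave = object$beta_ave)
  else
    object$model$betas
}

#' Bootstrap confidence interval for a fitted PAF
#'
#' @param object A `"paf"` fit produced by [paf()] on subject-level
#'   data.
#' @param parm Ignored (both PAF flavours are returned).
#' @param level Confidence level.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Resampling seed.
#' @param ... Unused.
#' @return A 2x2 matrix with rows `exact_paf`, `approx_paf`.
#' @export
confint.paf <- function(object, parm, level = 0.99, n_reps = 199L,
                        seed = 1L, ...) {
  bt <- if (!is.null(object$boot) && isTRUE(object$ci_level == level))
    object$boot
  else
    bootstrap_ci(object, n_reps = n_reps, level = level, seed = seed)
  out <- rbind(exact_paf = bt$exact, approx_paf = bt$approx)
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' @export
plot.paf <- function(x, ...) {
  plot(fan_layout(list(x)), ...)
  invisible(x)
}

#' Tabulate attributable fractions for several risk factors
#'
#' Assembles `"paf"` fits (or a summary data frame with `prevalence`
#' and `beta_ave` columns) into the standard summary-table schema,
#' ranked by approximate PAF in descending order.
#'
#' @param x A list of `"paf"` objects, a single `"paf"` object, or a
#'   data frame with at least `factor`, `prevalence`, `beta_ave`.
#' @return A data frame with columns `factor`, `kind`, `prevalence`,
#'   `beta_ave`, `or_ave`, `approx_paf`, `exact_paf`, `ci_lower`,
#'   `ci_upper`, sorted by `approx_paf` descending, with a `rank`
#'   column.
#' @export
paf_table <- function(x) {
  tab <- as_paf_table(x)
  tab <- tab[order(-tab$approx_paf), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

# Internal: normalise the many accepted inputs (paf fits, lists of
# them, summary data frames) into one canonical data frame.
as_paf_table <- function(x) {
  if (inherits(x, "paf")) x <- list(x)
  if (is.data.frame(x)) {
    req <- c("prevalence", "beta_ave")
    miss <- setdiff(req, names(x))
    if (length(miss))
      stop("summary table is missing required column(s): ",
           paste(miss, collapse = ", "))
    if (!nrow(x)) stop("no rows in summary table")
    fac <- if ("factor" %in% names(x)) as.character(x$factor)
           else paste0("factor", seq_len(nrow(x)))
    data.frame(
      factor = fac,
      kind = if ("kind" %in% names(x)) as.character(x$kind) else "binary",
      prevalence = as.numeric(x$prevalence),
      beta_ave = as.numeric(x$beta_ave),
      or_ave = exp(as.numeric(x$beta_ave)),
      approx_paf = approx_paf(as.numeric(x$prevalence),
                              as.numeric(x$beta_ave)),
      exact_paf = if ("exact_paf" %in% names(x)) as.numeric(x$exact_paf)
                  else NA_real_,
      ci_lower = if ("ci_lower" %in% names(x)) as.numeric(x$ci_lower)
                 else NA_real_,
      ci_upper = if ("ci_upper" %in% names(x)) as.numeric(x$ci_upper)
                 else NA_real_
    )
  } else if (is.list(x) && all(vapply(x, inherits, TRUE, "paf"))) {
    if (!length(x)) stop("no risk factors supplied")
    data.frame(
      factor = vapply(x, `[[`, "", "factor_name"),
      kind = vapply(x, `[[`, "", "exposure_kind"),
      prevalence = vapply(x, `[[`, 0, "control_prevalence"),
      beta_ave = vapply(x, `[[`, 0, "beta_ave"),
      or_ave = vapply(x, `[[`, 0, "or_ave"),
      approx_paf = vapply(x, `[[`, 0, "approx_paf"),
      exact_paf = vapply(x, `[[`, 0, "exact_paf"),
      ci_lower = vapply(x, function(f)
        if (is.null(f$ci_lower)) NA_real_ else f$ci_lower[["exact"]], 0),
      ci_upper = vapply(x, function(f)
        if (is.null(f$ci_upper)) NA_real_ else f$ci_upper[["exact"]], 0)
    )
  } else {
    stop("cannot interpret input as attributable-fraction results")
  }
}
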