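# Case-control preparation and exposure-model fitting.
#
# The disease model is logistic:
#   logit P(Y=1 | A=j, C=c) = mu + beta_j + gamma(c)      (discrete A)
#   logit P(Y=1 | A=j, C=c) = mu + beta(j) + gamma(c)     (continuous A)
# with beta anchored to 0 at the reference level/value.  Under
# outcome-dependent (case-control) sampling only the intercept changes,
# so the beta terms remain estimable by ordinary logistic regression.

# Internal: validate and coerce one exposure + confounders out of a
# subject-level data frame.  Rows with missing values in any used
# column are dropped with a message.
prepare_cc <- function(data, outcome, exposure, confounders = character(),
                       kind = c("auto", "binary", "multicategory",
                                "continuous"),
                       ref = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(data))
  used <- c(outcome, exposure, confounders)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(data[used])
  n_drop <- sum(!cc)
  if (n_drop > 0) {
    message("dropped ", n_drop, " row(s) with missing values")
    data <- data[cc, , drop = FALSE]
  }
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y) && nlevels(y) == 2L) y <- as.integer(y) - 1L
  if (!is.numeric(y) || !all(y %in% c(0, 1)))
    stop("outcome column '", outcome, "' must be binary (0/1)")
  if (!any(y == 1) || !any(y == 0))
    stop("data must contain at least one case and one control")

  a <- data[[exposure]]
  if (kind == "auto") {
    kind <- if (is.numeric(a) && length(unique(a)) > 2L) "continuous"
            else if (length(unique(a[!is.na(a)])) > 2L) "multicategory"
            else "binary"
  }
  if (kind %in% c("binary", "multicategory")) {
    a <- factor(a)
    if (nlevels(a) < 2L)
      stop("exposure '", exposure, "' has a single level")
    if (kind == "binary" && nlevels(a) != 2L)
      stop("exposure '", exposure, "' declared binary but has ",
           nlevels(a), " levels")
    if (!is.null(ref)) {
      if (!as.character(ref) %in% levels(a))
        stop("reference label '", ref, "' does not occur in exposure '",
             exposure, "'")
      a <- stats::relevel(a, ref = as.character(ref))
    }
  } else {
    if (!is.numeric(a))
      stop("exposure '", exposure, "' declared continuous but is not numeric")
  }
  conf <- data[confounders]
  conf[] <- lapply(conf, function(v) if (is.character(v)) factor(v) else v)
  list(y = as.integer(y), a = a, conf = conf, kind = kind,
       exposure = exposure, confounders = confounders,
       n_cases = sum(y == 1), n_controls = sum(y == 0), n_dropped = n_drop)
}

# Internal: design matrix for the exposure model (used by the fit and
# re-used row-wise by the bootstrap).
cc_model_matrix <- function(prep, spline_df = 4L) {
  if (prep$kind == "continuous") {
    basis <- splines::ns(prep$a, df = spline_df)
    Xa <- basis
    colnames(Xa) <- paste0("s", seq_len(ncol(Xa)))
  } else {
    basis <- NULL
    Xa <- stats::model.matrix(~a, data.frame(a = prep$a))[, -1L, drop = FALSE]
  }
  if (length(prep$confounders)) {
    Xc <- stats::model.matrix(~., prep$conf)[, -1L, drop = FALSE]
  } else {
    Xc <- matrix(numeric(0), nrow = length(prep$y), ncol = 0L)
  }
  X <- cbind(`(Intercept)` = 1, Xa, Xc)
  list(X = X, basis = basis, n_exposure_cols = ncol(Xa))
}

# Internal: unscaled covariance of a glm.fit object (as summary.glm
# computes it, honouring pivoting).
glm_fit_vcov <- function(fit) {
  p1 <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p1]
  covm <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(covm)) return(NULL)
  V <- matrix(NA_real_, length(fit$coefficients), length(fit$coefficients))
  V[piv, piv] <- covm
  V
}

# Internal: logistic ML fit on an explicit design matrix.
fit_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100))
  )
  fit
}

#' Fit the logistic exposure model to case-control data
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' exposure of interest (indicator contrasts against a reference level
#' for discrete exposures; a natural cubic spline for continuous ones)
#' plus additive confounder terms.  Coefficients are returned relative
#' to the reference level; for continuous exposures the minimum-risk
#' reference value is located with [select_reference_level()] and the
#' fitted log-odds-ratio curve is re-anchored so it is 0 there.
#'
#' @param data Subject-level data frame.
#' @param exposure Name of the exposure column.
#' @param confounders Character vector of confounder column names
#'   (categorical columns are expanded to indicator contrasts, numeric
#'   ones enter linearly).
#' @param outcome Name of the binary outcome column (1 = case).
#' @param kind Exposure kind; `"auto"` infers it from the column type.
#' @param ref Reference level label for discrete exposures (defaults to
#'   the first factor level).
#' @param spline_df Degrees of freedom of the natural spline for
#'   continuous exposures (>= 2).
#' @param trim Quantile pair for the reference-value search grid of
#'   continuous exposures.
#'
#' @return An object of class `"exposure_model"` with elements
#'   `exposure_kind`, `betas` (discrete; named, reference first and
#'   exactly 0) or `beta_curve`/`reference_value` (continuous),
#'   `intercept`, `confounder_effects`, `converged`, `n_cases`,
#'   `n_controls`.
#' @export
#' @examples
#' d <- data.frame(y = rep(c(1, 0), c(100, 100)),
#'                 x = rep(c(1, 0, 1, 0), c(30, 70, 10, 90)))
#' fit_exposure_model(d, "x", outcome = "y")$betas  # log(27/7)
fit_exposure_model <- function(data, exposure, confounders = character(),
                               outcome = "y",
                               kind = c("auto", "binary", "multicategory",
                                        "continuous"),
                               ref = NULL, spline_df = 4L,
                               trim = c(0.01, 0.99)) {
  prep <- prepare_cc(data, outcome, exposure, confounders, kind, ref)
  if (prep$kind == "continuous" && spline_df < 2L)
    stop("spline_df must be >= 2 for continuous exposures")

  if (prep$kind != "continuous") {
    tab <- table(prep$a, factor(prep$y, levels = 0:1))
    bad <- rownames(tab)[tab[, 1L] == 0 | tab[, 2L] == 0]
    if (length(bad))
      stop("degenerate level(s) of exposure '", exposure,
           "' absent among cases or controls: ",
           paste(bad, collapse = ", "))
  }

  mm <- cc_model_matrix(prep, spline_df)
  fit <- fit_logistic(mm$X, prep$y)
  cf <- fit$coefficients
  if (!fit$converged || anyNA(cf) || max(abs(cf)) > 15)
    stop("logistic fit failed for exposure '", exposure,
         "' (non-convergence or separation); coefficient range [",
         paste(format(range(cf, na.rm = TRUE), digits = 3), collapse = ", "),
         "]")

  idx_a <- seq_len(mm$n_exposure_cols) + 1L
  conf_eff <- cf[-c(1L, idx_a)]

  out <- list(
    exposure_kind = prep$kind,
    exposure = exposure,
    intercept = unname(cf[1L]),
    confounder_effects = conf_eff,
    converged = fit$converged,
    n_cases = prep$n_cases,
    n_controls = prep$n_controls,
    n_dropped = prep$n_dropped,
    coefficients = cf,
    vcov = glm_fit_vcov(fit),
    prep = prep
  )

  if (prep$kind == "continuous") {
    beta_basis <- cf[idx_a]
    basis <- mm$basis
    raw_curve <- function(j) {
      drop(stats::predict(basis, j) %*% beta_basis)
    }
    out$raw_curve <- raw_curve
    out$exposure_values <- as.numeric(prep$a)
    out$trim <- trim
    out$spline_df <- spline_df
    class(out) <- "exposure_model"
    j0 <- select_reference_level(out, trim = trim)
    out$reference_value <- j0
    b0 <- raw_curve(j0)
    out$beta_curve <- function(j) raw_curve(j) - b0
  } else {
    betas <- c(0, unname(cf[idx_a]))
    names(betas) <- levels(prep$a)
    out$betas <- betas
    out$ref <- levels(prep$a)[1L]
    class(out) <- "exposure_model"
  }
  out
}

#' @export
print.exposure_model <- function(x, ...) {
  cat("Logistic exposure model for '", x$exposure, "' (",
      x$exposure_kind, ")\n", sep = "")
  cat("  cases:", x$n_cases, " controls:", x$n_controls, "\n")
  if (x$exposure_kind == "continuous") {
    cat("  spline df:", x$spline_df,
        " reference value j0:", format(x$reference_value), "\n")
  } else {
    cat("  log-odds ratios (reference '", x$ref, "'):\n", sep = "")
    print(round(x$betas, 4))
  }
  invisible(x)
}

#' Minimum-risk reference value of a continuous exposure
#'
#' Scans the fitted log-odds-ratio curve over a grid spanning the
#' trimmed observed range of the exposure and returns the argmin: the
#' realizable exposure value with the lowest fitted risk.  Trimming
#' keeps the reference away from the extreme tails where the spline is
#' poorly supported.  Ties (e.g. a constant curve) are broken to the
#' smallest value.
#'
#' @param model A continuous [fit_exposure_model()] fit.
#' @param trim Quantile pair `(low, high)` delimiting the search range.
#' @param n_grid Number of grid points.
#' @return The reference exposure value `j0`.
#' @export
select_reference_level <- function(model, trim = c(0.01, 0.99),
                                   n_grid = 501L) {
  if (!inherits(model, "exposure_model") ||
      model$exposure_kind != "continuous")
    stop("select_reference_level requires a continuous exposure model")
  if (length(trim) != 2L || trim[1] < 0 || trim[2] > 1 || trim[1] >= trim[2])
    stop("trim must be an increasing quantile pair inside [0, 1]")
  qs <- stats::quantile(model$exposure_values, probs = trim, names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = n_grid)
  vals <- model$raw_curve(grid)
  grid[which.min(vals)]  # which.min takes the first (smallest) on ties
}

#' Exposure distributions among controls and cases
#'
#' Empirical level proportions (discrete exposures) or raw value
#' samples (continuous exposures), split by outcome.  These are the
#' plug-in estimates of `P(A = j | Y = 0)` and `P(A = j | Y = 1)` (or
#' of the conditional exposure densities) that the attributable
#' fraction estimators consume.
#'
#' @inheritParams fit_exposure_model
#' @return For discrete exposures, a list with `labels`,
#'   `control_probs`, `case_probs` and a `degenerate` flag (all
#'   controls at the reference level); for continuous exposures, a list
#'   with `control_values` and `case_values`.
#' @export
control_case_distributions <- function(data, exposure,
                                       confounders = character(),
                                       outcome = "y",
                                       kind = c("auto", "binary",
                                                "multicategory",
                                                "continuous"),
                                       ref = NULL) {
  prep <- prepare_cc(data, outcome, exposure, confounders, kind, ref)
  if (prep$kind == "continuous") {
    list(kind = "continuous",
         control_values = as.numeric(prep$a[prep$y == 0]),
         case_values = as.numeric(prep$a[prep$y == 1]))
  } else {
    ctrl <- table(prep$a[prep$y == 0])
    cas <- table(prep$a[prep$y == 1])
    control_probs <- as.numeric(ctrl) / sum(ctrl)
    case_probs <- as.numeric(cas) / sum(cas)
    list(kind = prep$kind,
         labels = levels(prep$a),
         control_probs = control_probs,
         case_probs = case_probs,
         degenerate = control_probs[1L] >= 1 - 1e-12)
  }
}
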