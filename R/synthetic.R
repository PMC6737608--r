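# Synthetic case-control data with known counterfactuals.
#
# Cohorts are generated from the same logistic disease model the
# estimators assume:
#   logit P(Y=1 | A=j, C=c) = mu + beta_j + gamma_y * c
# with the exposure itself depending on the confounder through
#   (discrete)   shifted level log-odds;  (continuous) a location shift.
# Potential outcomes Y^{a=j} are materialised from a single uniform
# draw per subject (monotone coupling), so Y == Y^{a=A} by construction
# and the true PAF is computable by Monte Carlo.

#' Simulation configuration for a synthetic case-control study
#'
#' Defaults describe a common lifestyle-type risk factor in a rare
#' disease: a binary exposure with control-side prevalence about 0.4,
#' conditional odds ratio 1.5, baseline disease log-odds
#' `qlogis(0.01)`, and one binary confounder (prevalence 0.5) that
#' raises both exposure and disease log-odds by 0.5, inducing
#' confounding that an adjusted fit must remove.
#'
#' @param kind Exposure kind.
#' @param exposure_prev Binary exposure probability at confounder 0.
#' @param level_probs Multicategory level probabilities (reference
#'   first) at confounder 0.
#' @param betas True log-odds ratios: a single value (binary), one per
#'   non-reference level (multicategory), or ignored for continuous
#'   (see `beta_curve`).
#' @param beta_curve For continuous exposures, a vectorised function of
#'   the exposure value giving the log-odds ratio relative to
#'   `reference_value`; default linear with slope `beta_slope`.
#' @param beta_slope Slope of the default linear curve.
#' @param exposure_mean,exposure_sd Normal exposure distribution
#'   (continuous kind) at confounder 0.
#' @param reference_value Counterfactual reference value `j0` for
#'   continuous exposures; default two standard deviations below the
#'   mean (a realizable low-exposure value).
#' @param mu Baseline log-odds of disease at reference exposure and
#'   confounder 0.
#' @param confounder `NULL` for no confounding, or a list with `type`
#'   (`"binary"` or `"normal"`), `prev` (binary) or `mean`/`sd`
#'   (normal), `on_exposure` and `on_outcome` log-odds effects.
#' @param n Cohort size.
#'
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(kind = c("binary", "multicategory", "continuous"),
                       exposure_prev = 0.4,
                       level_probs = NULL,
                       betas = log(1.5),
                       beta_curve = NULL,
                       beta_slope = 0.2,
                       exposure_mean = 0, exposure_sd = 1,
                       reference_value = NULL,
                       mu = stats::qlogis(0.01),
                       confounder = list(type = "binary", prev = 0.5,
                                         on_exposure = 0.5,
                                         on_outcome = 0.5),
                       n = 1e5) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(mu)) stop("mu must be finite")
  if (!is.null(confounder)) {
    if (!is.list(confounder) || is.null(confounder$type))
      stop("confounder must be NULL or a list with a 'type' element")
    confounder$type <- match.arg(confounder$type, c("binary", "normal"))
    confounder$on_exposure <- confounder$on_exposure %||% 0
    confounder$on_outcome <- confounder$on_outcome %||% 0
    if (confounder$type == "binary")
      confounder$prev <- confounder$prev %||% 0.5
    else {
      confounder$mean <- confounder$mean %||% 0
      confounder$sd <- confounder$sd %||% 1
    }
  }
  if (kind == "binary") {
    if (exposure_prev <= 0 || exposure_prev >= 1)
      stop("exposure_prev must lie in (0, 1)")
    level_probs <- c(1 - exposure_prev, exposure_prev)
    if (length(betas) != 1L) stop("binary kind needs a single beta")
    betas <- c(0, betas)
  } else if (kind == "multicategory") {
    if (is.null(level_probs)) level_probs <- c(0.5, 0.3, 0.2)
    if (length(level_probs) < 3L)
      stop("multicategory kind needs at least 3 level probabilities")
    if (any(level_probs <= 0) || abs(sum(level_probs) - 1) > 1e-9)
      stop("level_probs must be positive and sum to 1")
    if (length(betas) == 1L)
      betas <- rep(betas, length(level_probs) - 1L)
    if (length(betas) != length(level_probs) - 1L)
      stop("need one beta per non-reference level")
    betas <- c(0, betas)
  } else {
    if (exposure_sd <= 0) stop("exposure_sd must be positive")
    if (is.null(reference_value))
      reference_value <- exposure_mean - 2 * exposure_sd
    if (is.null(beta_curve)) {
      force(beta_slope); rv <- reference_value
      beta_curve <- function(j) beta_slope * (j - rv)
    }
    b0 <- beta_curve(reference_value)
    if (abs(b0) > 1e-9)
      stop("beta_curve must be 0 at reference_value")
  }
  # implied disease probabilities must stay inside (0, 1); probe the
  # extremes of the linear predictor for discrete kinds
  if (kind != "continuous") {
    gmax <- if (is.null(confounder)) 0 else abs(confounder$on_outcome) *
      (if (confounder$type == "binary") 1 else 6 * confounder$sd)
    lp <- mu + c(min(betas) - gmax, max(betas) + gmax)
    pr <- stats::plogis(lp)
    if (any(pr <= 0) || any(pr >= 1))
      stop("implied disease probabilities fall outside (0, 1)")
  }
  structure(
    list(kind = kind, level_probs = level_probs, betas = betas,
         beta_curve = if (kind == "continuous") beta_curve else NULL,
         exposure_mean = exposure_mean, exposure_sd = exposure_sd,
         reference_value = if (kind == "continuous") reference_value
                           else NULL,
         mu = mu, confounder = confounder, n = as.integer(n)),
    class = "sim_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: derive independent substream seeds from one root seed, one
# per named simulation stage, so adding a stage never perturbs earlier
# draws.
substream_seeds <- function(seed, stages = c("confounder", "exposure",
                                             "outcome", "sampling")) {
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

#' Simulate a cohort with potential outcomes
#'
#' Draws confounders, exposures given confounders, then potential
#' disease outcomes from the logistic model at every exposure level
#' (discrete kinds) or at the reference value (continuous kind); the
#' factual outcome follows by consistency (`y == y^{a=A}`).  All
#' potential outcomes of a subject share one uniform draw, a monotone
#' coupling that fixes the marginals the attributable fraction needs.
#'
#' @param config A [sim_config()].
#' @param seed Root seed; named substreams are derived from it.
#' @return A data frame of class `"sim_cohort"` with columns `c`
#'   (confounder; 0 when none), `a` (exposure), `y` (factual outcome),
#'   `po_ref` (potential outcome at the reference level), and for
#'   discrete kinds `po_<level>` for every level.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  seeds <- substream_seeds(seed)

  set.seed(seeds[["confounder"]])
  cf <- config$confounder
  cvals <- if (is.null(cf)) rep(0, n)
           else if (cf$type == "binary") stats::rbinom(n, 1L, cf$prev)
           else stats::rnorm(n, cf$mean, cf$sd)
  g_a <- if (is.null(cf)) 0 else cf$on_exposure
  g_y <- if (is.null(cf)) 0 else cf$on_outcome

  set.seed(seeds[["exposure"]])
  if (config$kind == "continuous") {
    a <- stats::rnorm(n, config$exposure_mean + g_a * cvals,
                      config$exposure_sd)
  } else {
    # shift the log-odds of each non-reference level by g_a * c
    base <- log(config$level_probs)
    eta <- outer(rep(1, n), base)
    eta[, -1L] <- eta[, -1L] + g_a * cvals
    pr <- exp(eta) / rowSums(exp(eta))
    u <- stats::runif(n)
    cum <- pr
    for (j in seq_len(ncol(pr))[-1L]) cum[, j] <- cum[, j - 1L] + pr[, j]
    a <- rowSums(u > cum)  # 0-based level index
  }

  set.seed(seeds[["outcome"]])
  u <- stats::runif(n)
  if (config$kind == "continuous") {
    p_fact <- stats::plogis(config$mu + config$beta_curve(a) + g_y * cvals)
    p_ref <- stats::plogis(config$mu + g_y * cvals)
    y <- as.integer(u < p_fact)
    po_ref <- as.integer(u < p_ref)
    out <- data.frame(c = cvals, a = a, y = y, po_ref = po_ref)
  } else {
    K1 <- length(config$level_probs)
    po <- matrix(0L, n, K1)
    for (j in seq_len(K1)) {
      pj <- stats::plogis(config$mu + config$betas[j] + g_y * cvals)
      po[, j] <- as.integer(u < pj)
    }
    y <- po[cbind(seq_len(n), a + 1L)]
    out <- data.frame(c = cvals, a = a, y = y, po_ref = po[, 1L])
    colnames(po) <- paste0("po_", seq_len(K1) - 1L)
    out <- cbind(out, po)
  }
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("sim_cohort", "data.frame")
  out
}

#' Outcome-dependent sample from a simulated cohort
#'
#' Uniform sampling without replacement within outcome strata, as in a
#' case-control study; potential-outcome columns are stripped so the
#' sample looks like real study data.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param n_cases,n_controls Stratum sizes to draw.
#' @param seed Sampling seed.
#' @return A data frame with columns `y`, `a`, `c`.
#' @export
sample_case_control <- function(cohort, n_cases, n_controls, seed = 1L) {
  stopifnot(inherits(cohort, "sim_cohort"))
  i_case <- which(cohort$y == 1L)
  i_ctrl <- which(cohort$y == 0L)
  if (length(i_case) < n_cases || length(i_ctrl) < n_controls)
    stop("cohort has ", length(i_case), " cases and ", length(i_ctrl),
         " controls; requested ", n_cases, "/", n_controls)
  set.seed(seed)
  idx <- c(sample(i_case, n_cases), sample(i_ctrl, n_controls))
  out <- as.data.frame(cohort)[idx, c("y", "a", "c")]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo true attributable fraction of a configuration
#'
#' Simulates a cohort and evaluates the counterfactual definition of
#' the PAF directly:
#' `(P(Y=1) - P(Y^{a=ref}=1)) / P(Y=1)`, the proportion of disease
#' removed in a population where everyone is set to the reference
#' exposure.  A delta-method standard error (binomial sampling of both
#' prevalences, accounting for their covariance) accompanies the
#' estimate.
#'
#' @param config A [sim_config()]; its `n` is overridden by `n`.
#' @param n Simulation size (>= 1000).
#' @param seed Root seed.
#' @return A list with `paf`, `se`, `n`, `p_factual`, `p_reference`.
#' @export
true_paf_monte_carlo <- function(config, n = 1e6, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (n < 1000) stop("n must be >= 1000 for a stable Monte-Carlo estimate")
  cfg <- config
  cfg$n <- as.integer(n)
  coh <- simulate_cohort(cfg, seed = seed)
  p1 <- mean(coh$y)
  if (p1 == 0)
    stop("no cases simulated; increase n or raise mu")
  p0 <- mean(coh$po_ref)
  d <- coh$y - coh$po_ref
  paf <- mean(d) / p1
  # delta method for mean(d)/mean(y) from the sample covariance
  S <- stats::cov(cbind(d, coh$y)) / nrow(coh)
  grad <- c(1 / p1, -mean(d) / p1^2)
  se <- sqrt(drop(t(grad) %*% S %*% grad))
  list(paf = paf, se = se, n = as.integer(n),
       p_factual = p1, p_reference = p0)
}
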