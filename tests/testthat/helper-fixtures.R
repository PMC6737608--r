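# Shared fixtures, all built in code.

# 2x2 toy study: 30/70 exposed/unexposed cases, 10/90 controls.
# Closed-form log-OR is log(27/7).
toy_2x2 <- function() {
  data.frame(y = rep(c(1L, 0L), c(100L, 100L)),
             x = rep(c(1L, 0L, 1L, 0L), c(30L, 70L, 10L, 90L)))
}

# Published ten-risk-factor summary table shipped with the package.
stroke_table <- function() {
  read_summary_table(interstroke_summary_path())
}

# Random valid discrete exposure summary with K non-reference levels
# and non-negative log-odds ratios.
random_level_summary <- function(k = 2L, beta_max = 1) {
  cp <- as.numeric(stats::rgamma(k + 1L, 2))
  cp <- cp / sum(cp)
  qp <- as.numeric(stats::rgamma(k + 1L, 2))
  qp <- qp / sum(qp)
  level_summary(cp, qp, c(0, stats::runif(k, 0, beta_max)))
}

# Expected counts implied by a binary no-interaction logistic
# simulation config without confounder: returns the population joint
# P(A, Y) as a 2x2 matrix (rows A = 0/1, cols Y = 0/1).
binary_joint_probs <- function(prev, beta, mu) {
  p1 <- stats::plogis(mu + c(0, beta))
  pa <- c(1 - prev, prev)
  cbind(pa * (1 - p1), pa * p1)
}
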