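# Independent oracle for the posterior P(L|D): exhaustive enumeration of the
# four-cell joint distribution (fitness class x diagnosis) at an explicit
# baseline diagnosis probability p. The closed form must be invariant to p.
oracle_posterior_low <- function(r, p_low, p) {
  stopifnot(r * p <= 1)
  joint_LD <- p_low * (r * p)        # low-fitness and diagnosed
  joint_HD <- (1 - p_low) * p        # high-fitness and diagnosed
  joint_LD / (joint_LD + joint_HD)
}

# Exact binomial CI for stochastic checks. The level is deliberately
# conservative: these tests run on one fixed arbitrary seed each, so the
# per-check false-alarm rate must be negligible across the whole suite.
binom_ci <- function(k, n, conf = 0.9999) {
  stats::binom.test(k, n, conf.level = conf)$conf.int
}

# Normal-approximation CI on a sample mean, same conservative level.
mean_ci <- function(x, conf = 0.9999) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  mean(x) + c(-1, 1) * z * stats::sd(x) / sqrt(length(x))
}

default_sim_params <- function(n_families = 2000, seed = 1, r = 3, d = 1,
                               W = 1, ...) {
  simulation_params(ssm_params(r = r, d = d, W = W),
                    n_families = n_families, seed = seed, ...)
}
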