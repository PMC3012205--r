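#' Parameters of the family-fitness ascertainment model
#'
#' Bundles the parameters of the analytic model of fertility estimation in
#' schizotypal families: the relative risk of diagnosis by family fitness
#' class, the fertility difference between classes, the true mean relative
#' fertility of schizotypal-family members, and the prior probability that a
#' schizotypal family is low-fitness.
#'
#' Relative fertility is expressed on the population scale, i.e. the
#' population mean is 1. The class means are derived:
#' `w_high = W + p_low * d` and `w_low = W - (1 - p_low) * d`, so that
#' `w_high - w_low = d` and `(1 - p_low) * w_high + p_low * w_low = W`.
#'
#' @param r Relative risk of a schizophrenia diagnosis in low- versus
#'   high-fitness schizotypal families, `P(D|L) / P(D|H)`. Must be >= 1;
#'   `r = 1` is the degenerate no-signal case.
#' @param d Fertility difference `w_high - w_low` between the class means,
#'   in relative-fertility units. Must be >= 0; it includes the
#'   fertility-reducing effects of schizophrenia itself.
#' @param W True mean relative fertility of a random member of a schizotypal
#'   family (1 = selective neutrality). Default 1.
#' @param p_low Prior probability that a schizotypal family is low-fitness,
#'   `P(L)`. Default 0.5, the symmetric-fitness assumption; other values are
#'   an extension of the symmetric model.
#'
#' @return An object of class `ssm_params`: a list with fields `r`, `d`,
#'   `W`, `p_low` and the derived class means `w_high`, `w_low`.
#' @examples
#' p <- ssm_params(r = 3, d = 1, W = 1)
#' p$w_high  # 1.5
#' p$w_low   # 0.5
#' @export
ssm_params <- function(r, d, W = 1, p_low = 0.5) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(W), length(W) == 1L, is.finite(W),
            is.numeric(p_low), length(p_low) == 1L, is.finite(p_low))
  if (r < 1)
    stop("'r' must be >= 1: the model assumes diagnosis risk is at least as ",
         "high against low fitness (r = 1 is the no-signal case)", call. = FALSE)
  if (d < 0)
    stop("'d' must be >= 0 (w_high >= w_low)", call. = FALSE)
  if (p_low <= 0 || p_low >= 1)
    stop("'p_low' must lie strictly in (0, 1)", call. = FALSE)
  w_high <- W + p_low * d
  w_low  <- W - (1 - p_low) * d
  if (w_low < 0)
    stop("derived low-class fertility w_low = W - (1 - p_low) * d is ",
         "negative (", format(w_low), "); fertilities must be non-negative",
         call. = FALSE)
  structure(
    list(r = r, d = d, W = W, p_low = p_low, w_high = w_high, w_low = w_low),
    class = "ssm_params"
  )
}

#' @export
print.ssm_params <- function(x, ...) {
  cat("Family-fitness ascertainment model parameters\n")
  cat(sprintf("  relative risk r        : %g\n", x$r))
  cat(sprintf("  fertility difference d : %g\n", x$d))
  cat(sprintf("  true relative W        : %g\n", x$W))
  cat(sprintf("  prior P(L)             : %g\n", x$p_low))
  cat(sprintf("  class means w_high/w_low: %g / %g\n", x$w_high, x$w_low))
  invisible(x)
}

#' Parameters of the synthetic family-population simulator
#'
#' Extends [ssm_params()] with the population-level quantities needed to
#' draw a concrete population of families: counts, family size, baseline
#' diagnosis probabilities and the offspring scale.
#'
#' @param ssm An [ssm_params()] object.
#' @param n_families Number of families to simulate (>= 1).
#' @param prop_schizotypal Proportion of families labelled schizotypal.
#' @param family_size Members per family (fixed positive integer).
#' @param p_diag_high Baseline per-member diagnosis probability in
#'   high-fitness schizotypal families, `P(D|H)`. The low-fitness
#'   probability is `r * p_diag_high` and must not exceed 1.
#' @param p_diag_nonschizotypal Per-member diagnosis probability in
#'   non-schizotypal families; default 0 (negligibly small by assumption).
#' @param base_mean_offspring Population-mean offspring count; class-mean
#'   offspring are `base_mean_offspring` times the class relative fertility.
#' @param seed Integer random seed; mandatory for reproducibility.
#'
#' @return An object of class `simulation_params`.
#' @examples
#' sp <- simulation_params(ssm_params(r = 3, d = 1), n_families = 1000, seed = 1)
#' @export
simulation_params <- function(ssm,
                              n_families,
                              prop_schizotypal = 0.5,
                              family_size = 5L,
                              p_diag_high = 0.01,
                              p_diag_nonschizotypal = 0,
                              base_mean_offspring = 2,
                              seed) {
  if (!inherits(ssm, "ssm_params"))
    stop("'ssm' must be an ssm_params object", call. = FALSE)
  stopifnot(is.numeric(n_families), length(n_families) == 1L,
            n_families >= 1, n_families == floor(n_families),
            is.numeric(prop_schizotypal), length(prop_schizotypal) == 1L,
            prop_schizotypal >= 0, prop_schizotypal <= 1,
            is.numeric(family_size), length(family_size) == 1L,
            family_size >= 1, family_size == floor(family_size),
            is.numeric(p_diag_high), length(p_diag_high) == 1L,
            is.numeric(p_diag_nonschizotypal),
            length(p_diag_nonschizotypal) == 1L,
            is.numeric(base_mean_offspring), length(base_mean_offspring) == 1L,
            base_mean_offspring > 0,
            is.numeric(seed), length(seed) == 1L, seed == floor(seed))
  if (p_diag_high <= 0)
    stop("'p_diag_high' must be > 0", call. = FALSE)
  if (ssm$r * p_diag_high > 1)
    stop("r * p_diag_high = ", format(ssm$r * p_diag_high),
         " exceeds 1 and is not a valid diagnosis probability", call. = FALSE)
  if (p_diag_nonschizotypal < 0 || p_diag_nonschizotypal >= p_diag_high)
    stop("'p_diag_nonschizotypal' must satisfy 0 <= value < p_diag_high ",
         "(diagnoses in non-schizotypal families are negligibly rare)",
         call. = FALSE)
  structure(
    list(ssm = ssm,
         n_families = as.integer(n_families),
         prop_schizotypal = prop_schizotypal,
         family_size = as.integer(family_size),
         p_diag_high = p_diag_high,
         p_diag_nonschizotypal = p_diag_nonschizotypal,
         base_mean_offspring = base_mean_offspring,
         seed = as.integer(seed)),
    class = "simulation_params"
  )
}

#' @export
print.simulation_params <- function(x, ...) {
  print(x$ssm)
  cat("Simulation settings\n")
  cat(sprintf("  families: %d x %d members, %.0f%% schizotypal\n",
              x$n_families, x$family_size, 100 * x$prop_schizotypal))
  cat(sprintf("  P(D|H) = %g, P(D|L) = %g, P(D|non-schizotypal) = %g\n",
              x$p_diag_high, x$ssm$r * x$p_diag_high, x$p_diag_nonschizotypal))
  cat(sprintf("  mean offspring scale = %g, seed = %d\n",
              x$base_mean_offspring, x$seed))
  invisible(x)
}
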