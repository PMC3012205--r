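#' Ascertain families through diagnosed probands
#'
#' Samples families the way a patient study does: through diagnosed
#' individuals (probands). Under the default proband-wise scheme every
#' diagnosed individual is a proband and a family enters the sample once per
#' proband, so the inclusion weight of a family is proportional to its
#' diagnosed count — the sampling law under which the empirical low-fitness
#' fraction converges to the posterior `P(L|D)`. Setting `n_probands` draws
#' that many probands uniformly at random (with replacement) from the
#' diagnosed individuals instead. The alternative `scheme = "family"`
#' includes each family with at least one diagnosed member exactly once;
#' this diverges from the posterior law whenever families can contain
#' several patients and is provided for comparison only.
#'
#' @param pop A `population` object with at least one diagnosed member.
#' @param n_probands Optional number of probands to draw uniformly with
#'   replacement; `NULL` (default) takes every diagnosed individual once.
#' @param scheme `"proband"` (default, patient-uniform) or `"family"`.
#' @param seed Optional integer seed used when `n_probands` is given.
#' @return A data frame of ascertained families (columns of
#'   `pop$families` minus the offspring list, plus `offspring_total` and a
#'   `multiplicity` column counting how many probands brought the family in).
#' @export
ascertain_by_proband <- function(pop, n_probands = NULL,
                                 scheme = c("proband", "family"),
                                 seed = NULL) {
  stopifnot(inherits(pop, "population"))
  scheme <- match.arg(scheme)
  tot <- family_totals(pop)
  diagnosed <- tot$n_diagnosed
  if (sum(diagnosed) == 0L)
    stop("population contains no diagnosed individuals; increase n_families ",
         "or p_diag_high", call. = FALSE)
  has_case <- diagnosed > 0L
  if (scheme == "family") {
    mult <- as.integer(has_case)
  } else if (is.null(n_probands)) {
    mult <- diagnosed
  } else {
    stopifnot(is.numeric(n_probands), length(n_probands) == 1L, n_probands >= 1)
    if (!is.null(seed)) set.seed(seed)
    fam_of_proband <- rep(tot$family_id, diagnosed)
    draws <- sample(fam_of_proband, size = n_probands, replace = TRUE)
    mult <- integer(nrow(tot))
    cnt <- table(draws)
    mult[as.integer(names(cnt))] <- as.integer(cnt)
  }
  out <- tot[mult > 0L, , drop = FALSE]
  out$multiplicity <- mult[mult > 0L]
  rownames(out) <- NULL
  out
}

#' Estimate the true mean relative fertility of schizotypal-family members
#'
#' Empirical counterpart of the population quantity `W`: the mean offspring
#' count over all members of schizotypal families divided by the mean
#' offspring count over the whole population. The standard error is obtained
#' by a nonparametric bootstrap over families (families, not individuals,
#' are the independent units), resampling the whole population and
#' recomputing the ratio.
#'
#' @param pop A `population` object containing schizotypal families.
#' @param n_boot Number of bootstrap resamples for the standard error;
#'   0 skips the bootstrap (`se = NA`). Default 500.
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with `estimate`, `se`, `n_families_schizotypal`.
#' @export
estimate_true_fertility <- function(pop, n_boot = 500L, seed = NULL) {
  stopifnot(inherits(pop, "population"))
  tot <- family_totals(pop)
  if (!any(tot$schizotypal))
    stop("population contains no schizotypal families", call. = FALSE)
  ratio <- function(idx) {
    t2 <- tot[idx, ]
    s <- t2$schizotypal
    (sum(t2$offspring_total[s]) / sum(t2$n_members[s])) /
      (sum(t2$offspring_total) / sum(t2$n_members))
  }
  est <- ratio(seq_len(nrow(tot)))
  se <- NA_real_
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(tot), replace = TRUE)
      if (!any(tot$schizotypal[idx])) return(NA_real_)
      ratio(idx)
    }, numeric(1))
    se <- stats::sd(reps, na.rm = TRUE)
  }
  list(estimate = est, se = se,
       n_families_schizotypal = sum(tot$schizotypal))
}

#' Estimate the ascertained mean relative fertility
#'
#' Empirical counterpart of the patient-study estimate `w_hat`: the mean
#' offspring count over all members (patients and relatives) of the
#' ascertained families, weighted by each family's sampling multiplicity,
#' divided by the whole-population mean offspring count. The population mean
#' in the denominator is treated as a fixed reference; the bootstrap
#' resamples the ascertained families (the sampled units) with their
#' multiplicities.
#'
#' @param pop The `population` object the sample was drawn from.
#' @param sample A data frame from [ascertain_by_proband()]; must be
#'   non-empty.
#' @param n_boot Number of bootstrap resamples for the standard error;
#'   0 skips it. Default 500.
#' @param seed Optional integer seed for the bootstrap.
#' @return A list with `estimate`, `se`, `n_ascertained` (number of
#'   proband-weighted family draws).
#' @export
estimate_ascertained_fertility <- function(pop, sample, n_boot = 500L,
                                           seed = NULL) {
  stopifnot(inherits(pop, "population"), is.data.frame(sample))
  if (nrow(sample) == 0L)
    stop("ascertained sample is empty", call. = FALSE)
  tot <- family_totals(pop)
  pop_mean <- sum(tot$offspring_total) / sum(tot$n_members)
  w <- sample$multiplicity
  est <- (sum(w * sample$offspring_total) / sum(w * sample$n_members)) / pop_mean
  se <- NA_real_
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(sample), replace = TRUE, prob = w)
      (sum(sample$offspring_total[idx]) / sum(sample$n_members[idx])) / pop_mean
    }, numeric(1))
    se <- stats::sd(reps)
  }
  list(estimate = est, se = se, n_ascertained = sum(w))
}

#' Monte-Carlo validation of the closed-form bias
#'
#' Runs the full simulate → ascertain → estimate pipeline across independent
#' replicates and compares the Monte-Carlo means of the true fertility, the
#' ascertained fertility and their difference against the analytic values
#' `W`, `w_hat` and `bias`. Any analytic value outside the chosen confidence
#' interval of the corresponding Monte-Carlo mean is flagged.
#'
#' @param params A [simulation_params()] object; its `seed` field is ignored
#'   in favour of `seed`, from which one sub-seed per replicate is derived.
#' @param n_replicates Number of independent populations to simulate (>= 1).
#' @param seed Integer master seed.
#' @param conf Confidence level of the interval on the Monte-Carlo means.
#'   Default 0.99.
#' @return An object of class `mc_report`: a list with `replicates` (one row
#'   per replicate: `w_true_hat`, `w_ascertained_hat`, `bias_hat`),
#'   `summary` (one row per quantity: analytic value, Monte-Carlo mean,
#'   confidence bounds, `analytic_outside_ci`), `prop_estimate_below_1`, and
#'   the inputs.
#' @examples
#' sp <- simulation_params(ssm_params(r = 3, d = 1), n_families = 500, seed = 1)
#' rep <- compare_analytic_mc(sp, n_replicates = 20, seed = 7)
#' rep$summary
#' @export
compare_analytic_mc <- function(params, n_replicates, seed, conf = 0.99) {
  stopifnot(inherits(params, "simulation_params"),
            is.numeric(n_replicates), length(n_replicates) == 1L,
            n_replicates >= 1, n_replicates == floor(n_replicates),
            is.numeric(seed), length(seed) == 1L, seed == floor(seed),
            is.numeric(conf), length(conf) == 1L, conf > 0, conf < 1)
  n_replicates <- as.integer(n_replicates)
  reps <- matrix(NA_real_, nrow = n_replicates, ncol = 3,
                 dimnames = list(NULL, c("w_true_hat", "w_ascertained_hat",
                                         "bias_hat")))
  for (i in seq_len(n_replicates)) {
    rep_seed <- (as.double(seed) + i) %% 2147483647
    p_i <- simulation_params(
      ssm = params$ssm, n_families = params$n_families,
      prop_schizotypal = params$prop_schizotypal,
      family_size = params$family_size, p_diag_high = params$p_diag_high,
      p_diag_nonschizotypal = params$p_diag_nonschizotypal,
      base_mean_offspring = params$base_mean_offspring, seed = rep_seed)
    pop <- simulate_population(p_i)
    smp <- ascertain_by_proband(pop)
    wt <- estimate_true_fertility(pop, n_boot = 0L)
    wa <- estimate_ascertained_fertility(pop, smp, n_boot = 0L)
    reps[i, ] <- c(wt$estimate, wa$estimate, wt$estimate - wa$estimate)
  }
  analytic <- c(true_fertility(params$ssm), estimated_fertility(params$ssm),
                fertility_bias(params$ssm))
  mc_mean <- colMeans(reps)
  mc_se <- apply(reps, 2, stats::sd) / sqrt(n_replicates)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  summary <- data.frame(
    quantity = c("w_true", "w_ascertained", "bias"),
    analytic = analytic,
    mc_mean = mc_mean,
    mc_se = mc_se,
    ci_lower = mc_mean - z * mc_se,
    ci_upper = mc_mean + z * mc_se,
    row.names = NULL
  )
  summary$analytic_outside_ci <-
    analytic < summary$ci_lower | analytic > summary$ci_upper
  structure(
    list(replicates = as.data.frame(reps),
         summary = summary,
         prop_estimate_below_1 = mean(reps[, "w_ascertained_hat"] < 1),
         params = params, n_replicates = n_replicates, seed = seed,
         conf = conf),
    class = "mc_report"
  )
}

#' @export
print.mc_report <- function(x, ...) {
  cat(sprintf("Monte-Carlo validation: %d replicates x %d families (seed %d)\n",
              x$n_replicates, x$params$n_families, x$seed))
  print(x$summary, digits = 4)
  cat(sprintf("ascertained estimate below 1 in %.1f%% of replicates\n",
              100 * x$prop_estimate_below_1))
  invisible(x)
}
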