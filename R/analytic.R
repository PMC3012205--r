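#' Posterior probability that a patient's family is low-fitness
#'
#' Bayes posterior that a randomly selected diagnosed patient comes from a
#' low-fitness schizotypal family, given the relative risk `r = P(D|L)/P(D|H)`
#' and the prior `P(L)`:
#' \deqn{P(L|D) = \frac{r\,P(L)}{r\,P(L) + 1 - P(L)}.}
#' With the symmetric prior `P(L) = 0.5` this reduces to `r / (r + 1)`.
#' The result does not depend on the absolute baseline `P(D|H)`, only on the
#' ratio `r`.
#'
#' @param r Relative risk of diagnosis in low- versus high-fitness
#'   schizotypal families; vectorised, each element >= 1.
#' @param p_low Prior probability that a schizotypal family is low-fitness;
#'   vectorised, each element strictly in (0, 1). Default 0.5.
#' @return Posterior probability `P(L|D)`, always >= `p_low`.
#' @seealso [posterior_high_given_diagnosis()]
#' @examples
#' posterior_low_given_diagnosis(r = 3)        # 0.75
#' posterior_low_given_diagnosis(r = 1, 0.3)   # prior unchanged
#' @export
posterior_low_given_diagnosis <- function(r, p_low = 0.5) {
  check_posterior_args(r, p_low)
  r * p_low / (r * p_low + (1 - p_low))
}

#' Posterior probability that a patient's family is high-fitness
#'
#' Complement of [posterior_low_given_diagnosis()]:
#' `P(H|D) = 1 - P(L|D)`, at most `1 - p_low` when `r >= 1`.
#'
#' @inheritParams posterior_low_given_diagnosis
#' @return Posterior probability `P(H|D)`.
#' @examples
#' posterior_high_given_diagnosis(r = 3)  # 0.25
#' @export
posterior_high_given_diagnosis <- function(r, p_low = 0.5) {
  check_posterior_args(r, p_low)
  (1 - p_low) / (r * p_low + (1 - p_low))
}

check_posterior_args <- function(r, p_low) {
  stopifnot(is.numeric(r), is.numeric(p_low))
  if (any(!is.finite(r)) || any(r < 1))
    stop("'r' must be finite and >= 1", call. = FALSE)
  if (any(!is.finite(p_low)) || any(p_low <= 0) || any(p_low >= 1))
    stop("'p_low' must lie strictly in (0, 1)", call. = FALSE)
  invisible(NULL)
}

#' True mean relative fertility of schizotypal-family members
#'
#' Population-weighted mean of the class fertilities,
#' `W = (1 - p_low) * w_high + p_low * w_low`. Because the class means are
#' derived from the stored `W` and `d`, this recovers `params$W` exactly;
#' the function exists to make that round trip explicit and testable.
#'
#' @param params An [ssm_params()] object.
#' @return The true mean relative fertility `W`.
#' @export
true_fertility <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  (1 - params$p_low) * params$w_high + params$p_low * params$w_low
}

#' Ascertainment-distorted estimate of mean relative fertility
#'
#' The mean relative fertility a study would estimate when families are
#' sampled through diagnosed patients: the class means weighted by the
#' posterior class probabilities rather than the prior,
#' \deqn{\hat W = P(H|D)\,w_{high} + P(L|D)\,w_{low}.}
#' Because low-fitness families are over-represented among patients
#' (`P(L|D) >= p_low` for `r >= 1`), this never exceeds the true fertility.
#'
#' @param params An [ssm_params()] object.
#' @return The ascertained mean relative fertility `w_hat`.
#' @details Numerically, the estimate is evaluated as
#' `true_fertility(params) - fertility_bias(params)`, which is algebraically
#' identical to the posterior-weighted mean but keeps the consistency
#' identity, and the zero-bias cases `r = 1` and `d = 0`, exact in floating
#' point.
#' @examples
#' estimated_fertility(ssm_params(r = 3, d = 1, W = 1))  # 0.75
#' @export
estimated_fertility <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  true_fertility(params) - fertility_bias(params)
}

#' Underestimation bias of patient-family fertility studies
#'
#' The difference between the true and the ascertainment-distorted mean
#' relative fertility,
#' \deqn{W - \hat W = d\,(P(L|D) - P(L)),}
#' which for the symmetric prior `p_low = 0.5` equals
#' `d * (r - 1) / (2 * (r + 1))`. The bias is strictly positive whenever
#' `r > 1` and `d > 0`, zero at `r = 1` or `d = 0`, increasing in `r` and
#' linear in `d`; it does not depend on `W`.
#'
#' @param params An [ssm_params()] object.
#' @return The bias `W - w_hat`, in relative-fertility units.
#' @examples
#' fertility_bias(ssm_params(r = 3, d = 1))  # 0.25
#' @export
fertility_bias <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  # the closed form d * (P(L|D) - P(L)) is exact at the degenerate points:
  # r = 1 gives P(L|D) identical to the prior, d = 0 annihilates the product
  pl <- posterior_low_given_diagnosis(params$r, params$p_low)
  params$d * (pl - params$p_low)
}

#' Selection-regime flip condition
#'
#' A study sampling through patients estimates `w_hat = W - bias`, so it
#' reports apparent negative selection (`w_hat < 1`) despite true neutrality
#' or positive selection (`W >= 1`) exactly when
#' \deqn{1 \le W < 1 + d\,(P(L|D) - P(L)).}
#' The upper endpoint `1 + bias` is returned as the flip threshold.
#'
#' @param params An [ssm_params()] object.
#' @return A list with `flips` (logical: is the true regime non-negative but
#'   the estimated regime negative?) and `flip_threshold` (the upper bound
#'   on `W` below which `w_hat < 1`).
#' @examples
#' flip_condition(ssm_params(r = 3, d = 1, W = 1))    # flips, threshold 1.25
#' flip_condition(ssm_params(r = 3, d = 1, W = 1.5))  # no flip
#' @export
flip_condition <- function(params) {
  stopifnot(inherits(params, "ssm_params"))
  # W < 1 + bias is evaluated as w_hat < 1 (the same inequality rearranged)
  # so the verdict agrees bit-for-bit with classifying the estimate itself
  list(flips = params$W >= 1 && estimated_fertility(params) < 1,
       flip_threshold = 1 + fertility_bias(params))
}

#' Classify a relative fertility into a selection regime
#'
#' Labels a relative fertility as indicating negative selection (`w < 1`),
#' selective neutrality (`w = 1`) or positive selection (`w > 1`). A
#' tolerance band around 1 makes neutrality representable for noisy or
#' floating-point values; with `tol = 0` the classification is exact.
#'
#' @param w Relative fertility value(s), >= 0; vectorised.
#' @param tol Half-width of the neutrality band, >= 0. Default 0.01
#'   relative-fertility units.
#' @return Character vector with elements in
#'   `c("negative", "neutral", "positive")`.
#' @examples
#' classify_regime(c(0.75, 1, 1.25))
#' @export
classify_regime <- function(w, tol = 0.01) {
  stopifnot(is.numeric(w), is.numeric(tol), length(tol) == 1L, tol >= 0)
  if (any(!is.finite(w)) || any(w < 0))
    stop("'w' must be finite and non-negative", call. = FALSE)
  ifelse(w < 1 - tol, "negative", ifelse(w > 1 + tol, "positive", "neutral"))
}

#' Full analytic bias report for one parameter set
#'
#' Assembles the closed-form quantities for a parameter set: the posterior
#' fitness-class probabilities of a patient's family, the true and
#' ascertained mean relative fertility, the underestimation bias, the flip
#' threshold, and the selection-regime labels implied by the true versus the
#' ascertained fertility. `misclassified` is `TRUE` exactly when the
#' estimated regime is negative while the true regime is not.
#'
#' @param params An [ssm_params()] object.
#' @param tol Neutrality tolerance passed to [classify_regime()].
#' @return An object of class `bias_result`; a list with fields
#'   `params`, `posterior_low`, `posterior_high`, `w_true`, `w_hat`, `bias`,
#'   `flip_threshold`, `regime_true`, `regime_estimated`, `misclassified`.
#' @examples
#' bias_result(ssm_params(r = 3, d = 1, W = 1))
#' @export
bias_result <- function(params, tol = 0.01) {
  stopifnot(inherits(params, "ssm_params"))
  pl <- posterior_low_given_diagnosis(params$r, params$p_low)
  ph <- posterior_high_given_diagnosis(params$r, params$p_low)
  w_true <- true_fertility(params)
  w_hat <- estimated_fertility(params)
  flip <- flip_condition(params)
  regime_true <- classify_regime(w_true, tol)
  regime_est <- classify_regime(w_hat, tol)
  structure(
    list(params = params,
         posterior_low = pl,
         posterior_high = ph,
         w_true = w_true,
         w_hat = w_hat,
         bias = w_true - w_hat,
         flip_threshold = flip$flip_threshold,
         regime_true = regime_true,
         regime_estimated = regime_est,
         misclassified = regime_est == "negative" && regime_true != "negative"),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  p <- x$params
  cat(sprintf("Analytic ascertainment bias (r = %g, d = %g, W = %g, P(L) = %g)\n",
              p$r, p$d, p$W, p$p_low))
  cat(sprintf("  P(L|D) = %.4f, P(H|D) = %.4f\n", x$posterior_low, x$posterior_high))
  cat(sprintf("  true W = %.4f (%s), ascertained W = %.4f (%s)\n",
              x$w_true, x$regime_true, x$w_hat, x$regime_estimated))
  cat(sprintf("  bias = %.4f, flip threshold = %.4f, misclassified: %s\n",
              x$bias, x$flip_threshold, if (x$misclassified) "yes" else "no"))
  invisible(x)
}

#' Serialise a bias report to a flat list
#'
#' Flattens a [bias_result()] into a named list of scalars suitable for
#' `jsonlite::toJSON(..., auto_unbox = TRUE)`.
#'
#' @param x A `bias_result` object.
#' @param ... Unused.
#' @return A named list with keys `r`, `d`, `W`, `p_low`, `posterior_low`,
#'   `posterior_high`, `w_hat`, `bias`, `flip_threshold`, `regime_true`,
#'   `regime_estimated`, `misclassified`.
#' @export
as.list.bias_result <- function(x, ...) {
  p <- x$params
  list(r = p$r, d = p$d, W = p$W, p_low = p$p_low,
       posterior_low = x$posterior_low, posterior_high = x$posterior_high,
       w_hat = x$w_hat, bias = x$bias, flip_threshold = x$flip_threshold,
       regime_true = x$regime_true, regime_estimated = x$regime_estimated,
       misclassified = x$misclassified)
}
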