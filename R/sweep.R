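#' Define a parameter grid for bias and misclassification sweeps
#'
#' @param r_values Strictly increasing relative risks, all >= 1.
#' @param d_values Strictly increasing fertility differences, all >= 0.
#' @param W_values Strictly increasing true relative fertilities. Default 1.
#' @param p_low Fitness-class prior shared across the grid. Default 0.5.
#' @return An object of class `sweep_grid`.
#' @export
sweep_grid <- function(r_values, d_values, W_values = 1, p_low = 0.5) {
  check_axis <- function(x, name) {
    if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
      stop("'", name, "' must be a non-empty finite numeric vector",
           call. = FALSE)
    if (length(x) > 1L && any(diff(x) <= 0))
      stop("'", name, "' must be strictly increasing", call. = FALSE)
    x
  }
  check_axis(r_values, "r_values")
  check_axis(d_values, "d_values")
  check_axis(W_values, "W_values")
  if (any(r_values < 1)) stop("all r_values must be >= 1", call. = FALSE)
  if (any(d_values < 0)) stop("all d_values must be >= 0", call. = FALSE)
  if (p_low <= 0 || p_low >= 1)
    stop("'p_low' must lie strictly in (0, 1)", call. = FALSE)
  structure(list(r_values = r_values, d_values = d_values,
                 W_values = W_values, p_low = p_low),
            class = "sweep_grid")
}

#' Bias surface over relative risk and fertility difference
#'
#' Evaluates the closed-form underestimation bias and flip threshold on the
#' `(r, d)` grid. The bias does not depend on `W`, so the surface has one
#' row per `(r, d)` pair; within the table, bias is non-decreasing along
#' increasing `r` at fixed `d` and linear along increasing `d` at fixed `r`.
#'
#' @param grid A [sweep_grid()] object.
#' @return A data frame with columns `r`, `d`, `bias`, `flip_threshold`.
#' @examples
#' sweep_bias(sweep_grid(r_values = c(1, 2, 3), d_values = c(0, 1)))
#' @export
sweep_bias <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- expand.grid(d = grid$d_values, r = grid$r_values,
                       KEEP.OUT.ATTRS = FALSE)
  pl <- posterior_low_given_diagnosis(cells$r, grid$p_low)
  bias <- cells$d * (pl - grid$p_low)
  data.frame(r = cells$r, d = cells$d, bias = bias,
             flip_threshold = 1 + bias)
}

#' Map of selection-regime misclassification over (r, d, W)
#'
#' For each grid cell, labels the true and the ascertainment-distorted
#' fertility with [classify_regime()] and flags the cells where a patient
#' study would report negative selection although the true regime is
#' neutral or positive. With `tol = 0` (the default here) the flagged set
#' coincides exactly with the analytic flip region
#' `1 <= W < 1 + bias(r, d)`.
#'
#' Cells whose derived low-class fertility would be negative
#' (`W < (1 - p_low) * d`) are invalid; they are skipped with a warning, or
#' raise an error when `strict = TRUE`.
#'
#' @param grid A [sweep_grid()] object.
#' @param tol Neutrality tolerance for [classify_regime()]. Default 0 for
#'   exact agreement with the analytic flip region; use a positive value
#'   when classifying noisy estimates.
#' @param strict Error (rather than warn and skip) on invalid cells.
#' @return A data frame with columns `r`, `d`, `W`, `bias`, `w_hat`,
#'   `regime_true`, `regime_estimated`, `misclassified`.
#' @examples
#' g <- sweep_grid(r_values = c(1, 3), d_values = c(0.5, 1),
#'                 W_values = c(0.9, 1, 1.3))
#' subset(sweep_misclassification(g), misclassified)
#' @export
sweep_misclassification <- function(grid, tol = 0, strict = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- expand.grid(W = grid$W_values, d = grid$d_values, r = grid$r_values,
                       KEEP.OUT.ATTRS = FALSE)
  invalid <- cells$W - (1 - grid$p_low) * cells$d < 0
  if (any(invalid)) {
    msg <- paste0(sum(invalid), " grid cell(s) imply negative low-class ",
                  "fertility (W < (1 - p_low) * d)")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "; skipped", call. = FALSE)
    cells <- cells[!invalid, , drop = FALSE]
  }
  pl <- posterior_low_given_diagnosis(cells$r, grid$p_low)
  w_high <- cells$W + grid$p_low * cells$d
  w_low <- cells$W - (1 - grid$p_low) * cells$d
  w_true <- (1 - grid$p_low) * w_high + grid$p_low * w_low
  bias <- cells$d * (pl - grid$p_low)
  w_hat <- w_true - bias
  regime_true <- classify_regime(cells$W, tol)
  regime_est <- classify_regime(w_hat, tol)
  data.frame(
    r = cells$r, d = cells$d, W = cells$W, bias = bias, w_hat = w_hat,
    regime_true = regime_true, regime_estimated = regime_est,
    misclassified = regime_est == "negative" & regime_true != "negative",
    row.names = NULL
  )
}
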