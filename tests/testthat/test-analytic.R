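test_that("posterior of low fitness given a diagnosis follows Bayes' rule", {
  # symmetric prior: P(L|D) = r / (r + 1)
  expect_equal(posterior_low_given_diagnosis(r = 3, p_low = 0.5), 0.75)
  expect_equal(posterior_high_given_diagnosis(r = 3, p_low = 0.5), 0.25)
  # no risk signal leaves any prior unchanged
  expect_equal(posterior_low_given_diagnosis(r = 1, p_low = 0.5), 0.5)
  expect_equal(posterior_low_given_diagnosis(r = 1, p_low = 0.3), 0.3)
  expect_equal(posterior_high_given_diagnosis(r = 1, p_low = 0.5), 0.5)
})

test_that("posteriors normalise, over-represent the low class, and vanish in the large-r limit", {
  rs <- c(1, 1.5, 2, 3, 5, 10, 50)
  priors <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (pl in priors) {
    lo <- posterior_low_given_diagnosis(rs, pl)
    hi <- posterior_high_given_diagnosis(rs, pl)
    expect_equal(lo + hi, rep(1, length(rs)))
    expect_true(all(lo >= pl))
    expect_true(all(hi <= 1 - pl))
    expect_true(all(diff(hi) < 0))  # monotone decrease in r
  }
  expect_lt(posterior_high_given_diagnosis(1e9, 0.5), 1e-8)
})

test_that("posteriors match four-cell joint-table enumeration for any baseline", {
  for (p in c(0.001, 0.01, 0.05)) {
    for (r in c(1, 2, 3, 7, 15)) {
      for (pl in c(0.1, 0.25, 0.5, 0.8)) {
        expect_equal(posterior_low_given_diagnosis(r, pl),
                     oracle_posterior_low(r, pl, p),
                     tolerance = 1e-14)
      }
    }
  }
})

test_that("posterior arguments are validated", {
  expect_error(posterior_low_given_diagnosis(0.5), ">= 1")
  expect_error(posterior_low_given_diagnosis(3, p_low = 0), "(0, 1)", fixed = TRUE)
  expect_error(posterior_high_given_diagnosis(3, p_low = 1), "(0, 1)", fixed = TRUE)
})

test_that("class fertility means are derived consistently from W and d", {
  p <- ssm_params(r = 3, d = 1, W = 1)
  expect_equal(p$w_high, 1.5)
  expect_equal(p$w_low, 0.5)
  expect_equal(true_fertility(p), 1)

  p0 <- ssm_params(r = 3, d = 0, W = 1)
  expect_equal(p0$w_high, 1)
  expect_equal(p0$w_low, 1)
  expect_equal(true_fertility(p0), 1)

  # round trip: the prior-weighted class means recover the stored W
  for (W in c(0.5, 0.9, 1, 1.4)) {
    for (d in c(0, 0.4, 1)) {
      for (pl in c(0.2, 0.5, 0.8)) {
        if (W - (1 - pl) * d < 0) next
        prm <- ssm_params(r = 2, d = d, W = W, p_low = pl)
        expect_equal(true_fertility(prm), W)
      }
    }
  }
})

test_that("parameter construction rejects invalid combinations", {
  expect_error(ssm_params(r = 0.9, d = 1), ">= 1")
  expect_error(ssm_params(r = 3, d = -0.1), ">= 0")
  expect_error(ssm_params(r = 3, d = 1, p_low = 0), "(0, 1)", fixed = TRUE)
  # W = 0.4, d = 1, p_low = 0.5 gives w_low = -0.1
  expect_error(ssm_params(r = 3, d = 1, W = 0.4), "negative")
})

test_that("ascertained fertility reproduces the worked example and its degenerate cases", {
  expect_equal(estimated_fertility(ssm_params(r = 3, d = 1, W = 1)), 0.75)
  expect_equal(estimated_fertility(ssm_params(r = 1, d = 1, W = 1)), 1)
  expect_equal(estimated_fertility(ssm_params(r = 3, d = 0, W = 1.2)), 1.2)
})

test_that("underestimation bias matches the closed form and is consistent with the estimate", {
  expect_equal(fertility_bias(ssm_params(r = 3, d = 1)), 0.25)
  expect_equal(fertility_bias(ssm_params(r = 1, d = 5, W = 3)), 0)
  expect_equal(fertility_bias(ssm_params(r = 3, d = 2, W = 1.5)), 0.5)

  # bias = W - w_hat exactly, and reduces to d(r-1)/(2(r+1)) at p_low = 0.5
  for (r in c(1, 1.5, 2, 4, 10)) {
    for (d in c(0, 0.3, 1, 2)) {
      prm <- ssm_params(r = r, d = d, W = 2)
      expect_identical(estimated_fertility(prm),
                       true_fertility(prm) - fertility_bias(prm))
      expect_equal(fertility_bias(prm), d * (r - 1) / (2 * (r + 1)))
    }
  }
  # general prior: bias = d * (P(L|D) - p_low)
  prm <- ssm_params(r = 4, d = 0.8, W = 1.2, p_low = 0.3)
  expect_equal(fertility_bias(prm),
               0.8 * (posterior_low_given_diagnosis(4, 0.3) - 0.3))
})

test_that("bias is positive for r > 1 and d > 0, zero otherwise, and monotone in r and d", {
  set.seed(20260922)
  for (i in 1:200) {
    r <- 1 + stats::rexp(1)
    d <- stats::rexp(1, rate = 2)
    W <- d  # guarantees w_low >= 0 at p_low = 0.5
    b <- fertility_bias(ssm_params(r = r, d = d, W = W))
    if (d > 0) expect_gt(b, 0)
    expect_equal(fertility_bias(ssm_params(r = 1, d = d, W = W)), 0)
    expect_equal(fertility_bias(ssm_params(r = r, d = 0, W = W)), 0)
  }
  # monotone non-decreasing in r at fixed d; linear in d at fixed r
  rs <- seq(1, 12, length.out = 40)
  b_r <- vapply(rs, function(r) fertility_bias(ssm_params(r, d = 1, W = 1)),
                numeric(1))
  expect_true(all(diff(b_r) >= 0))
  ds <- seq(0, 2, length.out = 25)
  b_d <- vapply(ds, function(d) fertility_bias(ssm_params(3, d = d, W = 2)),
                numeric(1))
  expect_equal(b_d, ds * (3 - 1) / (2 * (3 + 1)))
})

test_that("flip condition brackets W between 1 and 1 + bias", {
  f <- flip_condition(ssm_params(r = 3, d = 1, W = 1))
  expect_true(f$flips)
  expect_equal(f$flip_threshold, 1.25)
  expect_false(flip_condition(ssm_params(r = 3, d = 1, W = 1.5))$flips)
  expect_false(flip_condition(ssm_params(r = 3, d = 1, W = 0.9))$flips)
  # agreement with a direct comparison of the ascertained estimate with 1
  set.seed(42)
  for (i in 1:100) {
    r <- 1 + stats::rexp(1)
    d <- stats::runif(1, 0, 1.5)
    W <- stats::runif(1, max(0.6, (1 - 0.5) * d), 1.8)
    prm <- ssm_params(r = r, d = d, W = W)
    expect_identical(flip_condition(prm)$flips,
                     W >= 1 && estimated_fertility(prm) < 1)
  }
})

test_that("selection regimes are classified with an explicit neutrality band", {
  expect_identical(classify_regime(c(0.75, 1, 1.25)),
                   c("negative", "neutral", "positive"))
  expect_identical(classify_regime(0.995, tol = 0.01), "neutral")
  expect_identical(classify_regime(0.995, tol = 0), "negative")
  expect_error(classify_regime(-0.1), "non-negative")
})

test_that("the full bias report is internally consistent and serialisable", {
  res <- bias_result(ssm_params(r = 3, d = 1, W = 1))
  expect_s3_class(res, "bias_result")
  expect_equal(res$posterior_low + res$posterior_high, 1)
  expect_equal(res$bias, res$w_true - res$w_hat)
  expect_identical(res$regime_true, "neutral")
  expect_identical(res$regime_estimated, "negative")
  expect_true(res$misclassified)
  expect_lt(res$w_hat, 1)
  expect_lte(1, res$flip_threshold)

  lst <- as.list(res)
  expect_named(lst, c("r", "d", "W", "p_low", "posterior_low",
                      "posterior_high", "w_hat", "bias", "flip_threshold",
                      "regime_true", "regime_estimated", "misclassified"))
  expect_silent(jsonlite::toJSON(lst, auto_unbox = TRUE))

  # no misclassification when the true regime is already negative
  res2 <- bias_result(ssm_params(r = 3, d = 1, W = 0.9))
  expect_false(res2$misclassified)
})
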