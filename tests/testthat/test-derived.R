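test_that("inverse logit is exact and stable in the tails", {
  expect_equal(inv_logit(0), 0.5)
  expect_equal(round(inv_logit(2.322), 2), 0.91)
  expect_equal(round(inv_logit(1.189), 2), 0.77)
  expect_equal(inv_logit(800), 1)
  expect_equal(inv_logit(-800), 0)
  expect_false(any(is.nan(inv_logit(c(-1e6, 1e6)))))
})

test_that("biweekly survival under the figure-caption profile matches hand sums", {
  th <- theta_published()
  # independent arithmetic: intercept + age poly + logit-mean year effect
  ym <- (0.026 + 0 + 0.655 + 0.404 + 0.543) / 5
  lp_f <- 1.661 + 0.550 * 3 - 0.071 * 9 + ym
  expect_equal(biweekly_survival(th, prediction_profile("F"), "BS"),
               1 / (1 + exp(-lp_f)), tolerance = 1e-12)
  expect_equal(biweekly_survival(th, prediction_profile("M"), "BS"),
               1 / (1 + exp(-(lp_f + 0.668))), tolerance = 1e-12)
  expect_equal(biweekly_survival(parameter_vector(), prediction_profile("F", age = 0), "BS"),
               0.5)
})

test_that("cumulative survival is a simple power with guarded arguments", {
  expect_equal(cumulative_survival(0.952, 0), 1)
  expect_equal(cumulative_survival(1.0, 17), 1)
  expect_equal(cumulative_survival(0.9, 3), 0.9^3)
  expect_error(cumulative_survival(0.9, -1), ">= 0")
  expect_error(cumulative_survival(1.2, 2), "\\[0, 1\\]")
})

test_that("annual survival decomposes over seasons and never exceeds either", {
  th <- theta_published()
  ann <- annual_survival(th, prediction_profile("M"))
  expect_equal(ann$annual, ann$bs_cumulative * ann$rest_cumulative,
               tolerance = 1e-12)
  set.seed(33)
  for (i in 1:20) {
    a <- annual_survival(random_theta(),
                         prediction_profile(sample(c("F", "M"), 1),
                                            fed = sample(0:1, 1),
                                            habitat_z = rnorm(1)))
    expect_lte(a$annual, min(a$bs_cumulative, a$rest_cumulative) + 1e-12)
  }
  all_surv <- parameter_vector(surv_intercept_BS = 60, surv_intercept_REST = 60)
  expect_equal(annual_survival(all_surv, prediction_profile("F", age = 0))$annual, 1)
})

test_that("supplementation contrast reproduces the reported annual gains", {
  th <- theta_published()
  expect_equal(supplementation_contrast(parameter_vector(surv_intercept_BS = 1,
                                                         surv_intercept_REST = 2),
                                        prediction_profile("F", age = 0)), 0)
  expect_lt(abs(supplementation_contrast(th, prediction_profile("F")) - 0.16),
            0.05)
  expect_lt(abs(supplementation_contrast(th, prediction_profile("M")) - 0.13),
            0.05)
})

test_that("habitat-by-supplementation interaction reverses sign between seasons", {
  th <- theta_published()
  fed_gain <- function(hab, period) {
    biweekly_survival(th, prediction_profile("F", fed = 1, habitat_z = hab),
                      period) -
      biweekly_survival(th, prediction_profile("F", fed = 0, habitat_z = hab),
                        period)
  }
  gains_bs <- vapply(c(-1, 0, 1), fed_gain, numeric(1), period = "BS")
  gains_rest <- vapply(c(-1, 0, 1), fed_gain, numeric(1), period = "REST")
  expect_true(all(diff(gains_bs) > 0))    # supplementation helps more in rich habitat
  expect_true(all(diff(gains_rest) < 0))  # and less in rich habitat after breeding
})

test_that("interval-count convention shifts annual survival by under 0.02", {
  th <- theta_published()
  for (sex in c("F", "M")) for (fed in 0:1) {
    pr <- prediction_profile(sex, fed = fed)
    a_9_17 <- annual_survival(th, pr, n_bs = 9, n_rest = 17)$annual
    a_8_18 <- annual_survival(th, pr, n_bs = 8, n_rest = 18)$annual
    expect_lt(abs(a_9_17 - a_8_18), 0.02)
  }
})

test_that("posterior-derived quantities average draw-by-draw, not at the mean", {
  th <- theta_published()
  pr <- prediction_profile("F")
  # degenerate posterior: plug-in exactly
  const <- make_samples(list(matrix(rep(as.numeric(th), each = 50),
                                    50, length(param_names),
                                    dimnames = list(NULL, param_names))))
  pd <- posterior_derived(const, pr, "annual")
  expect_equal(pd$mean, annual_survival(th, pr)$annual, tolerance = 1e-12)
  expect_equal(pd$cri_low, pd$cri_high)

  # Jensen: with the predictor in the concave region of the inverse logit,
  # the mean of the back-transformed draws falls below the plug-in value
  set.seed(44)
  draws <- matrix(rnorm(4000, 1.661, 0.43), ncol = 1,
                  dimnames = list(NULL, "surv_intercept_BS"))
  smp <- make_samples(list(draws))
  pd_bs <- posterior_derived(smp, pr, "biweekly_BS", theta_fixed = th)
  plug_in <- biweekly_survival(th, pr, "BS")
  expect_lt(pd_bs$mean, plug_in)
  expect_lt(plug_in - pd_bs$mean, 0.05)

  # wider posterior -> wider derived interval
  wide <- make_samples(list(matrix(rnorm(4000, 1.661, 0.86), ncol = 1,
                                   dimnames = list(NULL, "surv_intercept_BS"))))
  pd_wide <- posterior_derived(wide, pr, "biweekly_BS", theta_fixed = th)
  expect_gt(pd_wide$cri_high - pd_wide$cri_low, pd_bs$cri_high - pd_bs$cri_low)

  expect_error(posterior_derived(smp, pr, "no_such_quantity"), "unknown")
})

test_that("plug-in and posterior-mean annual survival differ by at most the Jensen gap", {
  # synthetic posterior over the period intercepts with spread matching the
  # reported credible intervals (~0.43 sd on the logit scale); remaining
  # parameters held at their point values, as the dominant uncertainty in
  # the derived annual survival comes through the intercepts
  set.seed(55)
  th <- theta_published()
  n_draws <- 4000
  draws <- cbind(
    surv_intercept_BS = rnorm(n_draws, th["surv_intercept_BS"], 0.43),
    surv_intercept_REST = rnorm(n_draws, th["surv_intercept_REST"], 0.43)
  )
  smp <- make_samples(list(draws))
  for (sex in c("F", "M")) {
    pr <- prediction_profile(sex)
    gap <- abs(posterior_derived(smp, pr, "annual", theta_fixed = th)$mean -
                 annual_survival(th, pr)$annual)
    expect_lt(gap, 0.05)
  }
})

test_that("the derived-quantity table covers all profile-by-quantity cells", {
  th <- theta_published()
  tab <- derive_table(th, list(prediction_profile("F"),
                               prediction_profile("M", fed = 1)))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("biweekly_BS", "biweekly_REST", "cumulative_BS",
                    "cumulative_REST", "annual", "contrast") %in% names(tab)))
  expect_equal(tab$annual[1], annual_survival(th, prediction_profile("F"))$annual)
})
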