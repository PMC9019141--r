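#' Prediction profile for derived survival quantities
#'
#' The convention behind the published prediction figures: individual age
#' 3 years, all standardized covariates at their means (0), and a mean
#' year effect (arithmetic mean of the five year coefficients on the
#' logit scale, reference 2010 = 0).
#'
#' @param sex "F" or "M".
#' @param fed 0/1 supplementation indicator.
#' @param habitat_z,clutch_z,mass_dev10 Scaled covariate values
#'   (defaults 0 = dataset means).
#' @param age Age in years (default 3).
#' @param year Either "mean" (default) or a specific calendar-year label.
#' @return List of class `prediction_profile`.
#' @export
prediction_profile <- function(sex = "F", fed = 0, habitat_z = 0,
                               clutch_z = 0, mass_dev10 = 0, age = 3,
                               year = "mean") {
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'", call. = FALSE)
  structure(list(sex = sex, male = as.integer(sex == "M"), fed = fed,
                 habitat_z = habitat_z, clutch_z = clutch_z,
                 mass_dev10 = mass_dev10, age = age, year = year),
            class = "prediction_profile")
}

profile_year_effect <- function(theta, profile) {
  if (identical(profile$year, "mean")) mean_year_effect(theta)
  else year_effect(theta, profile$year)
}

#' Biweekly survival probability under a prediction profile
#'
#' Back-transforms the period-matched survival linear predictor to a
#' fortnightly survival probability.
#'
#' @param theta A `parameter_vector`.
#' @param profile A [prediction_profile()].
#' @param period "BS" (breeding season) or "REST" (rest of year).
#' @return Probability.
#' @examples
#' biweekly_survival(theta_published(), prediction_profile("F"), "BS")
#' @export
biweekly_survival <- function(theta, profile, period = c("BS", "REST")) {
  period <- match.arg(period)
  inv_logit(unname(survival_linear_predictor(
    theta, period, profile$male, profile$fed, profile$habitat_z,
    profile$clutch_z, profile$mass_dev10, profile$age,
    profile_year_effect(theta, profile)
  )))
}

#' Cumulative survival over repeated biweekly intervals
#'
#' @param biweekly Per-interval survival probability in \[0, 1\].
#' @param n_intervals Number of intervals (>= 0); 9 for the breeding
#'   season, 17 for the rest of the year.
#' @return `biweekly ^ n_intervals`.
#' @export
cumulative_survival <- function(biweekly, n_intervals) {
  if (any(n_intervals < 0)) stop("n_intervals must be >= 0", call. = FALSE)
  if (any(biweekly < 0 | biweekly > 1)) {
    stop("biweekly survival must be in [0, 1]", call. = FALSE)
  }
  biweekly^n_intervals
}

#' Annual survival with seasonal decomposition
#'
#' Multiplies the biweekly survival rates through the year: the breeding
#' season contributes 9 fortnights, the rest of the year 17.
#'
#' @inheritParams biweekly_survival
#' @param n_bs,n_rest Interval counts per period (defaults 9 and 17).
#' @return List with `annual`, `bs_biweekly`, `rest_biweekly`,
#'   `bs_cumulative`, `rest_cumulative`.
#' @examples
#' annual_survival(theta_published(), prediction_profile("M"))$annual  # ~0.61
#' @export
annual_survival <- function(theta, profile, n_bs = 9L, n_rest = 17L) {
  s_bs <- biweekly_survival(theta, profile, "BS")
  s_rest <- biweekly_survival(theta, profile, "REST")
  cum_bs <- cumulative_survival(s_bs, n_bs)
  cum_rest <- cumulative_survival(s_rest, n_rest)
  list(annual = cum_bs * cum_rest,
       bs_biweekly = s_bs, rest_biweekly = s_rest,
       bs_cumulative = cum_bs, rest_cumulative = cum_rest)
}

#' Annual-survival gain from nestling food supplementation
#'
#' Difference in annual survival between a supplemented and an otherwise
#' identical un-supplemented parent.
#'
#' @inheritParams annual_survival
#' @return `annual_survival(fed = 1) - annual_survival(fed = 0)`.
#' @export
supplementation_contrast <- function(theta, profile, n_bs = 9L, n_rest = 17L) {
  fed <- profile; fed$fed <- 1
  unfed <- profile; unfed$fed <- 0
  annual_survival(theta, fed, n_bs, n_rest)$annual -
    annual_survival(theta, unfed, n_bs, n_rest)$annual
}

derived_quantity_fns <- function() {
  list(
    biweekly_BS = function(th, pr) biweekly_survival(th, pr, "BS"),
    biweekly_REST = function(th, pr) biweekly_survival(th, pr, "REST"),
    cumulative_BS = function(th, pr) annual_survival(th, pr)$bs_cumulative,
    cumulative_REST = function(th, pr) annual_survival(th, pr)$rest_cumulative,
    annual = function(th, pr) annual_survival(th, pr)$annual,
    contrast = function(th, pr) supplementation_contrast(th, pr)
  )
}

#' Posterior distribution of a derived quantity
#'
#' Applies a derived quantity draw-by-draw over the posterior and then
#' summarizes — the estimand behind the published figures (posterior mean
#' of the derived quantity, not the derived value at the posterior mean).
#' Parameters not sampled are held at `theta_fixed`.
#'
#' @param samples A `posterior_samples` object.
#' @param profile A [prediction_profile()].
#' @param quantity One of "biweekly_BS", "biweekly_REST", "cumulative_BS",
#'   "cumulative_REST", "annual", "contrast".
#' @param theta_fixed Values for parameters absent from the samples.
#' @return One-row data frame: `quantity`, `mean`, `cri_low`, `cri_high`,
#'   `f`.
#' @export
posterior_derived <- function(samples, profile, quantity,
                              theta_fixed = parameter_vector()) {
  fns <- derived_quantity_fns()
  if (!quantity %in% names(fns)) {
    stop("unknown derived quantity '", quantity, "'; choose one of: ",
         paste(names(fns), collapse = ", "), call. = FALSE)
  }
  fn <- fns[[quantity]]
  all_draws <- do.call(rbind, samples$draws)
  th <- theta_fixed
  vals <- apply(all_draws, 1, function(d) {
    th[samples$params] <- d
    fn(th, profile)
  })
  data.frame(quantity = quantity, mean = mean(vals),
             cri_low = unname(stats::quantile(vals, 0.025)),
             cri_high = unname(stats::quantile(vals, 0.975)),
             f = f_value(vals), stringsAsFactors = FALSE)
}

#' Derived-quantity table for a set of profiles
#'
#' Plug-in evaluation of all derived survival quantities for each profile
#' (the table behind the `derive` command-line subcommand).
#'
#' @param theta A `parameter_vector`.
#' @param profiles List of [prediction_profile()] objects.
#' @return Data frame: one row per profile with sex, fed, habitat_z and
#'   the six derived quantities.
#' @export
derive_table <- function(theta, profiles) {
  fns <- derived_quantity_fns()
  do.call(rbind, lapply(profiles, function(pr) {
    vals <- vapply(fns, function(f) f(theta, pr), numeric(1))
    cbind(data.frame(sex = pr$sex, fed = pr$fed, habitat_z = pr$habitat_z,
                     age = pr$age, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  }))
}
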