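#' Standardize a covariate to mean 0, sd 1
#'
#' Sample standardization with the n-1 denominator, returning the scaling
#' constants so the same transform can be reapplied to new data.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param center,scale Optional pinned constants; estimated from `x` when
#'   NULL.
#' @return List with `z` (standardized values), `center`, `scale`.
#' @examples
#' standardize(c(1, 2, 3))$z
#' @export
standardize <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- mean(x)
  if (is.null(scale)) scale <- stats::sd(x)
  if (!is.finite(scale) || scale <= 0) {
    stop("cannot standardize a (near-)constant vector: sd is 0", call. = FALSE)
  }
  list(z = (x - center) / scale, center = center, scale = scale)
}

#' Sex-specific body-mass deviation in 10 g units
#'
#' Body mass is expressed as the deviation from the sex-specific mean,
#' divided by 10: a value of 1 means 10 g heavier than the sex mean
#' (defaults 158.5 g for females, 152.8 g for males).
#'
#' @param mass_raw Body mass in grams (> 0), vectorized.
#' @param sex "F" or "M", recycled against `mass_raw`.
#' @param sex_means Named vector `c(F = ..., M = ...)` of sex mean masses
#'   in grams; override to re-estimate from a dataset.
#' @return Numeric mass deviations (10 g units).
#' @examples
#' scale_mass(168.5, "F")  # 1.0
#' @export
scale_mass <- function(mass_raw, sex, sex_means = c(F = 158.5, M = 152.8)) {
  if (!all(sex %in% c("F", "M"))) {
    stop("sex must be 'F' or 'M'", call. = FALSE)
  }
  if (any(mass_raw <= 0)) stop("mass_raw must be positive", call. = FALSE)
  (mass_raw - sex_means[sex]) / 10
}

#' Scale a raw covariate table for the survival model
#'
#' Takes raw per-individual covariates (`id`, `sex`, `fed`, `habitat`,
#' `clutch`, `mass`, `age`, `entry_year`) and produces the design inputs:
#' male indicator, supplementation indicator, habitat and clutch size
#' standardized to mean 0 / sd 1 across the dataset, body mass as the
#' sex-mean deviation in 10 g units, and age in years.
#'
#' @param raw Data frame of raw covariates in the documented CSV dialect.
#' @param scaling Optional scaling constants from a previous call (fields
#'   `habitat`, `clutch` with `center`/`scale`, and `sex_means`), to pin
#'   the transform for new data.
#' @return List with `scaled` (data frame: `id`, `male`, `fed`,
#'   `habitat_z`, `clutch_z`, `mass_dev10`, `age`, `entry_year`) and
#'   `scaling` (the constants used).
#' @export
scale_covariates <- function(raw, scaling = NULL) {
  stopifnot(all(c("id", "sex", "fed", "habitat", "clutch", "mass", "age") %in%
                  names(raw)))
  if (any(raw$habitat < 0 | raw$habitat > 1)) {
    stop("habitat must be a proportion in [0, 1]", call. = FALSE)
  }
  if (any(raw$age < 1)) stop("age must be >= 1 year", call. = FALSE)
  hab <- standardize(raw$habitat, scaling$habitat$center, scaling$habitat$scale)
  clu <- standardize(raw$clutch, scaling$clutch$center, scaling$clutch$scale)
  sex_means <- if (is.null(scaling$sex_means)) c(F = 158.5, M = 152.8) else
    scaling$sex_means
  scaled <- data.frame(
    id = as.character(raw$id),
    male = as.integer(raw$sex == "M"),
    fed = as.integer(raw$fed),
    habitat_z = hab$z,
    clutch_z = clu$z,
    mass_dev10 = as.numeric(scale_mass(raw$mass, raw$sex, sex_means)),
    age = as.integer(raw$age),
    entry_year = if ("entry_year" %in% names(raw)) as.integer(raw$entry_year)
      else NA_integer_,
    stringsAsFactors = FALSE
  )
  list(
    scaled = scaled,
    scaling = list(habitat = hab[c("center", "scale")],
                   clutch = clu[c("center", "scale")],
                   sex_means = sex_means)
  )
}

# Linear predictor of biweekly survival on the logit scale for one
# period, given covariate values and an explicit age and year effect.
# Shared by the likelihood design matrices and the prediction profiles.
survival_linear_predictor <- function(theta, period, male, fed, habitat_z,
                                      clutch_z, mass_dev10, age, year_eff) {
  if (period == "BS") {
    theta["surv_intercept_BS"] + theta["male_BS"] * male +
      theta["feed_BS"] * fed + theta["habitat_BS"] * habitat_z +
      theta["habfeed_BS"] * habitat_z * fed +
      theta["clutch"] * clutch_z + theta["mass"] * mass_dev10 +
      theta["age_lin"] * age + theta["age_quad"] * age^2 + year_eff
  } else {
    theta["surv_intercept_REST"] + theta["male_REST"] * male +
      theta["feed_REST"] * fed + theta["habitat_REST"] * habitat_z +
      theta["habfeed_REST"] * habitat_z * fed +
      theta["clutch"] * clutch_z + theta["mass"] * mass_dev10 +
      theta["age_lin"] * age + theta["age_quad"] * age^2 + year_eff
  }
}

#' Survival linear predictor for an individual at an occasion
#'
#' Assembles the period-matched logit-scale survival predictor: the
#' occasion's period (BS or REST) selects the intercept and the
#' period-specific sex, supplementation, habitat and interaction effects;
#' clutch, mass and the age polynomial are shared; the occasion's
#' calendar year contributes its fixed effect (2010 = 0). Age increments
#' by one year at each study-year boundary when `entry_year` is known.
#'
#' @param theta A `parameter_vector`.
#' @param x One row of scaled covariates (list or one-row data frame with
#'   `male`, `fed`, `habitat_z`, `clutch_z`, `mass_dev10`, `age`, and
#'   optionally `entry_year`).
#' @param occasion Occasion index within the calendar.
#' @param calendar An `occasion_calendar`.
#' @return Logit-scale survival predictor (scalar).
#' @export
survival_logit <- function(theta, x, occasion, calendar) {
  check_occasion(calendar, occasion)
  yr <- year_of(calendar, occasion)
  age <- x$age
  if (!is.null(x$entry_year) && !is.na(x$entry_year)) {
    age <- age + (yr - x$entry_year)
  }
  unname(survival_linear_predictor(
    theta, period_of(calendar, occasion), x$male, x$fed, x$habitat_z,
    x$clutch_z, x$mass_dev10, age, year_effect(theta, yr)
  ))
}

#' Detection linear predictor
#'
#' Era-specific intercept (the 2009 pilot year, with its higher
#' transmitter loss, versus all later years combined) plus a male effect.
#'
#' @param theta A `parameter_vector`.
#' @param sex "F" or "M".
#' @param year Calendar-year label of the occasion.
#' @return Logit-scale detection predictor (scalar).
#' @examples
#' detection_logit(theta_published(), "F", 2010)  # 2.322
#' @export
detection_logit <- function(theta, sex, year) {
  if (!sex %in% c("F", "M")) stop("sex must be 'F' or 'M'", call. = FALSE)
  base <- if (year == 2009) theta["det_intercept_2009"] else
    theta["det_intercept_rest"]
  unname(base + if (sex == "M") theta["det_male"] else 0)
}

#' Read a raw covariate table from CSV
#'
#' Dialect: header `id,sex,fed,habitat,clutch,mass,age,entry_year`,
#' sex in {F, M}, fed in {0, 1}.
#'
#' @param path CSV file path.
#' @return Raw covariate data frame, ready for [scale_covariates()].
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "fed", "habitat", "clutch", "mass", "age")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("covariate CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'", call. = FALSE)
  if (!all(df$fed %in% c(0L, 1L))) stop("fed must be 0 or 1", call. = FALSE)
  df$id <- as.character(df$id)
  df
}

#' Write a raw covariate table to CSV
#'
#' @param covariates Raw covariate data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
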