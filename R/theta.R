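#' Canonical parameter names
#'
#' Order of the full model parameter vector: three detection parameters
#' (era intercepts and a male effect, logit scale), the constant
#' dead-recovery probability (probability scale), then the survival
#' coefficients (logit scale): period intercepts, period-specific sex,
#' supplementation, food-rich-habitat and habitat-by-supplementation
#' effects, clutch size, body mass, linear and quadratic age, and fixed
#' year effects with 2010 as the reference.
#'
#' @format Character vector of length 22.
#' @export
param_names <- c(
  "det_intercept_2009", "det_intercept_rest", "det_male",
  "recovery_r",
  "surv_intercept_BS", "surv_intercept_REST",
  "male_BS", "male_REST",
  "feed_BS", "feed_REST",
  "habitat_BS", "habitat_REST",
  "habfeed_BS", "habfeed_REST",
  "clutch", "mass", "age_lin", "age_quad",
  "year_2009", "year_2011", "year_2012", "year_2013"
)

surv_param_names <- param_names[5:22]

#' Build a full parameter vector
#'
#' Starts from all coefficients 0 and `recovery_r = 0.5`, then overrides
#' any named entries.
#'
#' @param ... Named scalar overrides, e.g. `surv_intercept_BS = 1.661`.
#' @return Named numeric vector of class `parameter_vector` over
#'   [param_names].
#' @examples
#' parameter_vector(surv_intercept_BS = 1.661, recovery_r = 0.623)
#' @export
parameter_vector <- function(...) {
  theta <- stats::setNames(numeric(length(param_names)), param_names)
  theta["recovery_r"] <- 0.5
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), param_names)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    theta[names(dots)] <- dots
  }
  if (is.na(theta["recovery_r"]) || theta["recovery_r"] <= 0 ||
      theta["recovery_r"] >= 1) {
    stop("recovery_r must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(theta))) stop("parameters must be finite", call. = FALSE)
  structure(theta, class = c("parameter_vector", "numeric"))
}

#' Published posterior means of the fitted little owl survival model
#'
#' The posterior means of the biweekly multistate survival model fitted
#' to the 125 radio-tracked adult little owls (67 females, 58 males).
#' Useful as generating values for simulation studies and for plug-in
#' derived quantities.
#'
#' @return A `parameter_vector`.
#' @export
theta_published <- function() {
  parameter_vector(
    det_intercept_2009 = 1.189,
    det_intercept_rest = 2.322,
    det_male = 0.347,
    recovery_r = 0.623,
    surv_intercept_BS = 1.661,
    surv_intercept_REST = 2.649,
    male_BS = 0.668,
    male_REST = 0.148,
    feed_BS = 0.627,
    feed_REST = 0.517,
    habitat_BS = -0.177,
    habitat_REST = 0.210,
    habfeed_BS = 0.887,
    habfeed_REST = -0.658,
    clutch = 0.236,
    mass = 0.064,
    age_lin = 0.550,
    age_quad = -0.071,
    year_2009 = 0.026,
    year_2011 = 0.655,
    year_2012 = 0.404,
    year_2013 = 0.543
  )
}

# Fixed year effect on the logit scale for a calendar-year label;
# 2010 is the reference (0), unknown years also map to the reference.
year_effect <- function(theta, year) {
  nm <- paste0("year_", year)
  out <- numeric(length(year))
  hit <- nm %in% names(theta)
  out[hit] <- theta[nm[hit]]
  out
}

#' Mean year effect on the logit scale
#'
#' Arithmetic mean of the five fixed year effects (2009-2013, reference
#' 2010 = 0) on the logit scale, the convention used for prediction
#' profiles.
#'
#' @param theta A `parameter_vector`.
#' @return Scalar logit-scale year effect.
#' @export
mean_year_effect <- function(theta) {
  mean(c(theta["year_2009"], 0, theta["year_2011"], theta["year_2012"],
         theta["year_2013"]))
}

#' Read a parameter vector from YAML
#'
#' Keys are [param_names]; missing coefficients default to 0 and
#' `recovery_r` to 0.5. The package ships its fitted-model generating
#' values at `system.file("extdata", "generating_values.yaml",
#' package = "owlcmr")`.
#'
#' @param path YAML file path.
#' @return A `parameter_vector`.
#' @export
read_parameters <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(parameter_vector, lapply(vals, as.numeric))
}
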