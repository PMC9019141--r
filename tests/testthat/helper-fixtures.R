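# Shared fixtures: constant-rate parameter vectors, neutral covariates,
# random model draws, and an independent alternative-parameterization
# likelihood used as an oracle.

# theta giving constant biweekly survival s, detection p and recovery r
# for an individual with all-zero covariates and age 0
const_theta <- function(s, p, r) {
  parameter_vector(
    surv_intercept_BS = stats::qlogis(s),
    surv_intercept_REST = stats::qlogis(s),
    det_intercept_2009 = stats::qlogis(p),
    det_intercept_rest = stats::qlogis(p),
    recovery_r = r
  )
}

# covariate row(s) contributing nothing to the linear predictors
zero_covs <- function(id = "a", sex = "F") {
  data.frame(id = id, male = as.integer(sex == "M"), fed = 0L, habitat_z = 0,
             clutch_z = 0, mass_dev10 = 0, age = 0L, entry_year = NA_integer_,
             sex = sex, stringsAsFactors = FALSE)
}

# random but well-behaved full parameter vector
random_theta <- function() {
  vals <- stats::rnorm(length(param_names), 0, 1)
  names(vals) <- param_names
  vals["recovery_r"] <- stats::runif(1, 0.05, 0.95)
  vals[c("surv_intercept_BS", "surv_intercept_REST")] <-
    stats::rnorm(2, 1.5, 0.7)
  vals[c("det_intercept_2009", "det_intercept_rest")] <-
    stats::rnorm(2, 1.5, 0.7)
  do.call(parameter_vector, as.list(vals))
}

# random scaled-covariate row
random_covs <- function(id = "x") {
  sex <- sample(c("F", "M"), 1)
  data.frame(id = id, male = as.integer(sex == "M"),
             fed = sample(0:1, 1), habitat_z = stats::rnorm(1),
             clutch_z = stats::rnorm(1), mass_dev10 = stats::rnorm(1, 0, 0.8),
             age = sample(1:8, 1), entry_year = NA_integer_, sex = sex,
             stringsAsFactors = FALSE)
}

# all valid observation sequences of a given span starting at first capture
all_valid_obs <- function(span) {
  if (span == 1L) return(list(1L))
  tails <- expand.grid(rep(list(1:3), span - 1L))
  seqs <- lapply(seq_len(nrow(tails)), function(i) c(1L, unlist(tails[i, ])))
  Filter(function(o) {
    h <- encounter_history("tmp", 1L, o, length(o))
    length(validate_history(h)) == 0L
  }, seqs)
}

# Independent oracle: same model with recovery moved from the transition
# to the emission. States: alive, recently dead (recovered or not), long
# dead. Transition alive -> recently dead with 1 - s; emission of the
# recently-dead state is code 2 with probability r, code 3 otherwise.
alt_history_loglik <- function(theta, x, h, calendar) {
  r <- unname(theta["recovery_r"])
  sex <- if (!is.null(x$sex)) x$sex else if (x$male == 1) "M" else "F"
  tmax <- length(h$obs)
  if (h$first_capture >= tmax) return(0)
  alpha <- c(1, 0, 0)
  ll <- 0
  for (t in seq(h$first_capture + 1L, tmax)) {
    s <- inv_logit(survival_logit(theta, x, t - 1L, calendar))
    p <- inv_logit(detection_logit(theta, sex, year_of(calendar, t)))
    gam <- matrix(c(s, 1 - s, 0,
                    0, 0, 1,
                    0, 0, 1), 3, 3, byrow = TRUE)
    emi <- matrix(c(p, 0, 1 - p,
                    0, r, 1 - r,
                    0, 0, 1), 3, 3, byrow = TRUE)
    f <- (alpha %*% gam) * emi[, h$obs[t]]
    tot <- sum(f)
    if (tot <= 0) return(-Inf)
    ll <- ll + log(tot)
    alpha <- as.numeric(f) / tot
  }
  ll
}

# wrap plain draw matrices as a posterior_samples object
make_samples <- function(draws_list, params = colnames(draws_list[[1]])) {
  structure(list(draws = lapply(draws_list, function(d) {
    colnames(d) <- params
    d
  }), params = params, config = NULL, acceptance = NULL),
  class = "posterior_samples")
}
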