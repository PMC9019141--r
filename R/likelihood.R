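#' Numerically stable inverse logit
#'
#' @param x Logit-scale value(s).
#' @return Probabilities 1 / (1 + exp(-x)).
#' @examples
#' inv_logit(0)      # 0.5
#' inv_logit(2.322)  # 0.911
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Latent-state transition matrix for one biweekly interval
#'
#' States: 1 = alive, 2 = recently dead and recovered, 3 = dead and gone
#' (absorbing). A live bird survives the interval with probability `s`;
#' if it dies, its transmitter or remains are recovered with probability
#' `r`, otherwise it passes unobserved into the absorbing state. The
#' recovered state lasts one interval only.
#'
#' @param s Interval survival probability in \[0, 1\].
#' @param r Dead-recovery probability in \[0, 1\].
#' @return 3 x 3 row-stochastic matrix.
#' @examples
#' transition_matrix(0.9, 0.6)
#' @export
transition_matrix <- function(s, r) {
  if (!is.finite(s) || s < 0 || s > 1) stop("s must be in [0, 1]", call. = FALSE)
  if (!is.finite(r) || r < 0 || r > 1) stop("r must be in [0, 1]", call. = FALSE)
  matrix(c(
    s, (1 - s) * r, (1 - s) * (1 - r),
    0, 0, 1,
    0, 0, 1
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("ALIVE", "DEAD_RECOVERED", "DEAD_GONE"), NULL))
}

#' Observation (emission) matrix for one occasion
#'
#' Rows are true states, columns the observation codes 1/2/3. A live bird
#' is seen with detection probability `p` and otherwise unobserved; a
#' recovered carcass is always coded 2; the absorbing dead state is never
#' observed.
#'
#' @param p Detection probability in \[0, 1\].
#' @return 3 x 3 row-stochastic matrix.
#' @export
emission_matrix <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  matrix(c(
    p, 0, 1 - p,
    0, 1, 0,
    0, 0, 1
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("ALIVE", "DEAD_RECOVERED", "DEAD_GONE"),
                  c("SEEN_ALIVE", "RECOVERED_DEAD", "NOT_OBSERVED")))
}

# Interval t -> t+1 carries the period and year label of its starting
# occasion t, so each study year contains exactly 9 BS and 17 REST
# intervals.
interval_survival <- function(theta, x, t, calendar) {
  inv_logit(survival_logit(theta, x, t, calendar))
}

#' Marginal log-likelihood of one encounter history
#'
#' Forward-algorithm sum over latent state paths, conditioning on the
#' bird being alive at first capture. Interval survival comes from
#' [survival_logit()] (interval t to t+1 uses the period and year of
#' occasion t), detection at each occasion from [detection_logit()], and
#' the dead-recovery probability is `theta["recovery_r"]`, constant over
#' intervals.
#'
#' @param theta A `parameter_vector`.
#' @param x One individual's scaled covariates (see [survival_logit()];
#'   must also carry `sex` or `male` for the detection model).
#' @param h An `encounter_history` valid under [validate_history()].
#' @param calendar An `occasion_calendar`.
#' @return Log-likelihood (scalar, <= 0).
#' @export
history_loglik <- function(theta, x, h, calendar) {
  v <- validate_history(h)
  if (length(v)) stop(paste(v, collapse = "; "), call. = FALSE)
  tmax <- length(h$obs)
  if (tmax > calendar$n_occasions) {
    stop("history longer than calendar horizon", call. = FALSE)
  }
  sex <- if (!is.null(x$sex)) x$sex else if (x$male == 1) "M" else "F"
  r <- unname(theta["recovery_r"])
  alpha <- c(1, 0, 0)
  ll <- 0
  if (h$first_capture >= tmax) return(0)
  for (t in seq(h$first_capture + 1L, tmax)) {
    s <- interval_survival(theta, x, t - 1L, calendar)
    p <- inv_logit(detection_logit(theta, sex, year_of(calendar, t)))
    f <- (alpha %*% transition_matrix(s, r)) * emission_matrix(p)[, h$obs[t]]
    tot <- sum(f)
    if (tot <= 0) return(-Inf)
    ll <- ll + log(tot)
    alpha <- as.numeric(f) / tot
  }
  ll
}

#' Brute-force log-likelihood by latent-path enumeration
#'
#' Test oracle: explicitly sums the probability of every latent state
#' sequence compatible with the history. Exponential in the history span,
#' so it refuses spans above `max_span`.
#'
#' @inheritParams history_loglik
#' @param max_span Maximum span (occasions from first capture to horizon)
#'   accepted; default 8.
#' @return Log-likelihood; equals [history_loglik()] to ~1e-12.
#' @export
brute_force_loglik <- function(theta, x, h, calendar, max_span = 8L) {
  v <- validate_history(h)
  if (length(v)) stop(paste(v, collapse = "; "), call. = FALSE)
  tmax <- length(h$obs)
  span <- tmax - h$first_capture + 1L
  if (span > max_span) {
    stop(sprintf("history span %d exceeds enumeration guard %d", span, max_span),
         call. = FALSE)
  }
  if (span == 1L) return(0)
  sex <- if (!is.null(x$sex)) x$sex else if (x$male == 1) "M" else "F"
  r <- unname(theta["recovery_r"])
  occ <- seq(h$first_capture + 1L, tmax)
  gammas <- lapply(occ, function(t)
    transition_matrix(interval_survival(theta, x, t - 1L, calendar), r))
  emis <- lapply(occ, function(t)
    emission_matrix(inv_logit(detection_logit(theta, sex, year_of(calendar, t)))))
  paths <- as.matrix(expand.grid(rep(list(1:3), span - 1L)))
  total <- 0
  for (k in seq_len(nrow(paths))) {
    z <- c(1L, paths[k, ])
    pr <- 1
    for (j in seq_along(occ)) {
      pr <- pr * gammas[[j]][z[j], z[j + 1L]] * emis[[j]][z[j + 1L], h$obs[occ[j]]]
    }
    total <- total + pr
  }
  unname(log(total))
}

# Precompute design matrices so repeated likelihood evaluations (MLE,
# MCMC) reduce to two matrix products and a vectorized forward pass.
# Returns a closure environment with everything the forward pass needs.
prepare_model_data <- function(set, covariates, calendar) {
  stopifnot(inherits(set, "encounter_history_set"))
  idx <- match(set$id, covariates$id)
  if (anyNA(idx)) {
    stop("missing covariates for individual(s): ",
         paste(set$id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  cv <- covariates[idx, , drop = FALSE]
  n <- length(set$id)
  tmax <- set$n_occasions
  n_int <- tmax - 1L
  # survival design: rows (interval-major) for individual i, interval t
  per <- calendar$period[seq_len(n_int)]
  yr <- calendar$year[seq_len(n_int)]
  # age increments at each study-year boundary when entry year is known
  yr_mat <- matrix(rep(yr, each = n), n, n_int)
  age_shift <- sweep(yr_mat, 1, ifelse(is.na(cv$entry_year), NA_integer_,
                                       cv$entry_year), "-")
  age_shift[is.na(age_shift)] <- 0
  age <- cv$age + age_shift
  bs <- matrix(rep(per == "BS", each = n), n, n_int)
  Xs <- matrix(0, n * n_int, length(surv_param_names),
               dimnames = list(NULL, surv_param_names))
  Xs[, "surv_intercept_BS"] <- as.numeric(bs)
  Xs[, "surv_intercept_REST"] <- as.numeric(!bs)
  Xs[, "male_BS"] <- as.numeric(bs) * cv$male
  Xs[, "male_REST"] <- as.numeric(!bs) * cv$male
  Xs[, "feed_BS"] <- as.numeric(bs) * cv$fed
  Xs[, "feed_REST"] <- as.numeric(!bs) * cv$fed
  Xs[, "habitat_BS"] <- as.numeric(bs) * cv$habitat_z
  Xs[, "habitat_REST"] <- as.numeric(!bs) * cv$habitat_z
  Xs[, "habfeed_BS"] <- as.numeric(bs) * cv$habitat_z * cv$fed
  Xs[, "habfeed_REST"] <- as.numeric(!bs) * cv$habitat_z * cv$fed
  Xs[, "clutch"] <- rep(cv$clutch_z, n_int)
  Xs[, "mass"] <- rep(cv$mass_dev10, n_int)
  Xs[, "age_lin"] <- as.numeric(age)
  Xs[, "age_quad"] <- as.numeric(age)^2
  for (y in c(2009L, 2011L, 2012L, 2013L)) {
    Xs[, paste0("year_", y)] <- as.numeric(matrix(rep(yr == y, each = n), n, n_int))
  }
  # detection design for occasions 2..tmax (detection enters after entry)
  yr_det <- calendar$year[2:tmax]
  Xp <- matrix(0, n * n_int, 3,
               dimnames = list(NULL, param_names[1:3]))
  e2009 <- matrix(rep(yr_det == 2009L, each = n), n, n_int)
  Xp[, "det_intercept_2009"] <- as.numeric(e2009)
  Xp[, "det_intercept_rest"] <- as.numeric(!e2009)
  Xp[, "det_male"] <- rep(cv$male, n_int)
  list(n = n, tmax = tmax, n_int = n_int, obs = set$obs,
       first_capture = set$first_capture, Xs = Xs, Xp = Xp)
}

# Vectorized forward pass over all histories at once. logit_s and
# logit_p are n x (tmax-1) matrices (interval t -> t+1 and occasion t+1
# respectively); r is the scalar recovery probability.
forward_loglik <- function(md, logit_s, logit_p, r) {
  n <- md$n
  if (n == 0L) return(numeric(0))
  a1 <- rep(1, n); a2 <- numeric(n); a3 <- numeric(n)
  ll <- numeric(n)
  if (md$tmax < 2L) return(ll)
  s_all <- inv_logit(logit_s)
  p_all <- inv_logit(logit_p)
  for (t in 2:md$tmax) {
    active <- md$first_capture < t
    s <- s_all[, t - 1L]
    p <- p_all[, t - 1L]
    n1 <- a1 * s
    n2 <- a1 * (1 - s) * r
    n3 <- a1 * (1 - s) * (1 - r) + a2 + a3
    o <- md$obs[, t]
    f1 <- ifelse(o == 1L, n1 * p, ifelse(o == 3L, n1 * (1 - p), 0))
    f2 <- ifelse(o == 2L, n2, 0)
    f3 <- ifelse(o == 3L, n3, 0)
    tot <- f1 + f2 + f3
    upd <- active & tot > 0
    ll[upd] <- ll[upd] + log(tot[upd])
    ll[active & tot <= 0] <- -Inf
    a1 <- ifelse(upd, f1 / tot, ifelse(active, a1, 1))
    a2 <- ifelse(upd, f2 / tot, ifelse(active, a2, 0))
    a3 <- ifelse(upd, f3 / tot, ifelse(active, a3, 0))
  }
  ll
}

#' Marginal log-likelihood of an encounter-history set
#'
#' Sums the forward-algorithm log-likelihood over all histories, using a
#' vectorized engine with precomputed design matrices.
#'
#' @param theta A `parameter_vector`.
#' @param covariates Scaled covariate data frame (`$scaled` from
#'   [scale_covariates()]) with one row per individual id in the set.
#' @param set An `encounter_history_set`.
#' @param calendar Calendar; defaults to the set's.
#' @param per_history Also return the per-history vector (default FALSE).
#' @return List of class `likelihood_result` with `total` and, when
#'   requested, `per_history` (named by individual id).
#' @export
dataset_loglik <- function(theta, covariates, set, calendar = set$calendar,
                           per_history = FALSE) {
  if (length(set$id) == 0L) {
    return(structure(list(total = 0, per_history = numeric(0)),
                     class = "likelihood_result"))
  }
  md <- prepare_model_data(set, covariates, calendar)
  beta_s <- theta[surv_param_names]
  beta_p <- theta[param_names[1:3]]
  logit_s <- matrix(md$Xs %*% beta_s, md$n, md$n_int)
  logit_p <- matrix(md$Xp %*% beta_p, md$n, md$n_int)
  ll <- forward_loglik(md, logit_s, logit_p, unname(theta["recovery_r"]))
  structure(
    list(total = sum(ll),
         per_history = if (per_history) stats::setNames(ll, set$id)),
    class = "likelihood_result"
  )
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("Total log-likelihood: %.4f\n", x$total))
  invisible(x)
}
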