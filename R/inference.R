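#' MCMC configuration
#'
#' Defaults mirror the original analysis: three chains, an adaptive phase
#' of 10,000 iterations, then 100,000 iterations with a burn-in of 50,000
#' and no thinning.
#'
#' @param n_chains Number of chains (>= 1; >= 2 for diagnostics).
#' @param n_adapt Adaptive-phase iterations (proposal scales tuned here
#'   and then frozen).
#' @param n_iter Post-adaptation iterations per chain.
#' @param n_burnin Iterations discarded from the start of the
#'   post-adaptation phase (< n_iter).
#' @param thin Thinning interval.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param prior_sd Standard deviation of the Normal(0, prior_sd) prior on
#'   every logit-scale coefficient (default sqrt(10)); the dead-recovery
#'   probability has a Uniform(0, 1) prior.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_adapt = 10000L, n_iter = 100000L,
                        n_burnin = 50000L, thin = 1L, seed = 1L,
                        prior_sd = sqrt(10)) {
  stopifnot(n_chains >= 1, n_adapt >= 0, n_iter >= 1, thin >= 1, prior_sd > 0)
  if (n_burnin >= n_iter) stop("n_burnin must be < n_iter", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_sd = prior_sd),
            class = "mcmc_config")
}

# Parameters structurally identifiable from the design: year effects and
# the 2009 detection era drop out when those years are absent from the
# occasions actually observed.
default_free_params <- function(set, calendar = set$calendar) {
  yrs <- unique(calendar$year[seq_len(set$n_occasions)])
  free <- param_names
  if (!2009L %in% yrs) {
    free <- setdiff(free, c("det_intercept_2009", "year_2009"))
  }
  for (y in c(2011L, 2012L, 2013L)) {
    if (!y %in% yrs) free <- setdiff(free, paste0("year_", y))
  }
  free
}

# Objective machinery shared by fit_mle and fit_mcmc: precomputes design
# matrices once and maps an unconstrained working vector (recovery_r on
# the logit scale for the MLE path) to the total log-likelihood.
make_loglik_engine <- function(set, covariates, calendar, free, theta_fixed) {
  md <- prepare_model_data(set, covariates, calendar)
  theta_full <- as.numeric(theta_fixed)[match(param_names, names(theta_fixed))]
  names(theta_full) <- param_names
  free_idx <- match(free, param_names)
  function(values) {
    th <- theta_full
    th[free_idx] <- values
    if (th["recovery_r"] <= 0 || th["recovery_r"] >= 1) return(-Inf)
    logit_s <- matrix(md$Xs %*% th[surv_param_names], md$n, md$n_int)
    logit_p <- matrix(md$Xp %*% th[param_names[1:3]], md$n, md$n_int)
    sum(forward_loglik(md, logit_s, logit_p, th["recovery_r"]))
  }
}

#' Fit the multistate model by maximum marginal likelihood
#'
#' Maximizes the forward-algorithm likelihood with BFGS from a neutral
#' start (all coefficients 0, recovery probability 0.5). The recovery
#' probability is optimized on the logit scale; its standard error is
#' delta-method back-transformed. Standard errors come from the inverse
#' observed information (numerical Hessian at the optimum).
#'
#' @param set An `encounter_history_set`.
#' @param covariates Scaled covariate data frame ([scale_covariates()]).
#' @param calendar Calendar; defaults to the set's.
#' @param free Character vector of parameters to estimate; defaults to
#'   every parameter identifiable from the design (year effects for years
#'   absent from the calendar, and the 2009 detection era when 2009 is
#'   not observed, are held fixed).
#' @param theta_init Starting/fixed values (`parameter_vector`); fixed
#'   parameters keep these values.
#' @return List of class `mle_fit`: `theta` (full vector at the optimum),
#'   `estimate`, `se` (named over `free`), `vcov`, `loglik`, `converged`
#'   (flag, not an exception on failure), `optim` (raw result).
#' @export
fit_mle <- function(set, covariates, calendar = set$calendar,
                    free = default_free_params(set, calendar),
                    theta_init = parameter_vector()) {
  if (length(set$id) == 0L) stop("cannot fit an empty history set", call. = FALSE)
  free <- match.arg(free, param_names, several.ok = TRUE)
  engine <- make_loglik_engine(set, covariates, calendar, free, theta_init)
  r_pos <- match("recovery_r", free)
  to_working <- function(v) { if (!is.na(r_pos)) v[r_pos] <- stats::qlogis(v[r_pos]); v }
  to_natural <- function(u) { if (!is.na(r_pos)) u[r_pos] <- stats::plogis(u[r_pos]); u }
  negll <- function(u) {
    ll <- engine(to_natural(u))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  u0 <- to_working(as.numeric(theta_init[free]))
  opt <- stats::optim(u0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10),
                      hessian = TRUE)
  est_u <- opt$par
  est <- stats::setNames(to_natural(est_u), free)
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  se <- rep(NA_real_, length(free))
  if (!is.null(vc) && all(diag(vc) > 0)) {
    se <- sqrt(diag(vc))
    if (!is.na(r_pos)) {   # delta method: d plogis/du = r (1 - r)
      se[r_pos] <- se[r_pos] * est[r_pos] * (1 - est[r_pos])
    }
  } else {
    warning("observed information not invertible; SEs unavailable")
  }
  theta_hat <- theta_init
  theta_hat[free] <- est
  structure(
    list(theta = theta_hat, estimate = est, se = stats::setNames(se, free),
         vcov = vc, loglik = -opt$value, converged = opt$convergence == 0L,
         free = free, optim = opt),
    class = "mle_fit"
  )
}

#' @export
print.mle_fit <- function(x, ...) {
  cat(sprintf("Maximum marginal-likelihood fit: loglik %.3f, %sconverged\n",
              x$loglik, if (x$converged) "" else "NOT "))
  print(data.frame(estimate = round(x$estimate, 4), se = round(x$se, 4)))
  invisible(x)
}

#' Fit the multistate model by adaptive random-walk Metropolis
#'
#' Componentwise random-walk Metropolis on the marginalized (forward)
#' likelihood times the priors: Normal(0, prior_sd) on logit-scale
#' coefficients and Uniform(0, 1) on the dead-recovery probability.
#' Proposal scales are tuned toward 44% acceptance during the adaptive
#' phase and frozen afterwards, preserving ergodicity of the main run.
#'
#' @inheritParams fit_mle
#' @param config An [mcmc_config()].
#' @param theta_init Initial/fixed values; chains are overdispersed by
#'   jittering the initial free values.
#' @return Object of class `posterior_samples`: list with `draws` (one
#'   retained-draws matrix per chain, iterations x parameters, natural
#'   scale), `params`, `config`, `acceptance` (per chain x parameter).
#' @export
fit_mcmc <- function(set, covariates, calendar = set$calendar,
                     config = mcmc_config(),
                     free = default_free_params(set, calendar),
                     theta_init = parameter_vector()) {
  free <- match.arg(free, param_names, several.ok = TRUE)
  engine <- make_loglik_engine(set, covariates, calendar, free, theta_init)
  is_r <- free == "recovery_r"
  prior_sd <- config$prior_sd
  log_post <- function(v) {
    if (any(is_r) && (v[is_r] <= 0 || v[is_r] >= 1)) return(-Inf)
    ll <- engine(v)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dnorm(v[!is_r], 0, prior_sd, log = TRUE))
  }
  k <- length(free)
  n_keep <- length(seq(config$n_burnin + 1L, config$n_iter, by = config$thin))
  draws <- vector("list", config$n_chains)
  acc <- matrix(0, config$n_chains, k, dimnames = list(NULL, free))
  for (chain in seq_len(config$n_chains)) {
    set.seed(config$seed + chain - 1L)
    cur <- as.numeric(theta_init[free])
    cur[!is_r] <- cur[!is_r] + stats::rnorm(sum(!is_r), 0, 0.25)
    if (any(is_r)) cur[is_r] <- stats::runif(1, 0.2, 0.8)
    lp <- log_post(cur)
    if (!is.finite(lp)) {
      stop("non-finite log posterior at initial values", call. = FALSE)
    }
    scales <- rep(0.1, k)
    acc_win <- numeric(k)
    out <- matrix(NA_real_, n_keep, k, dimnames = list(NULL, free))
    row <- 0L
    total <- config$n_adapt + config$n_iter
    for (it in seq_len(total)) {
      for (j in seq_len(k)) {
        prop <- cur
        prop[j] <- prop[j] + stats::rnorm(1, 0, scales[j])
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          cur <- prop
          lp <- lp_prop
          acc_win[j] <- acc_win[j] + 1
          if (it > config$n_adapt) acc[chain, j] <- acc[chain, j] + 1
        }
      }
      if (it <= config$n_adapt && it %% 50L == 0L) {
        rate <- acc_win / 50
        scales <- scales * exp(0.5 * (rate - 0.44))
        acc_win[] <- 0
      }
      if (it > config$n_adapt) {
        m <- it - config$n_adapt
        if (m > config$n_burnin &&
            (m - config$n_burnin - 1L) %% config$thin == 0L) {
          row <- row + 1L
          out[row, ] <- cur
        }
      }
    }
    draws[[chain]] <- out
  }
  structure(
    list(draws = draws, params = free, config = config,
         acceptance = acc / config$n_iter),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: %d chain(s) x %d retained draws x %d parameters\n",
              length(x$draws), nrow(x$draws[[1]]), length(x$params)))
  invisible(x)
}

#' Flatten posterior samples to a data frame
#'
#' @param x A `posterior_samples` object.
#' @param ... Unused.
#' @return Data frame `chain, iter, <parameters...>` (retained draws).
#' @export
as.data.frame.posterior_samples <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$draws), function(ch) {
    data.frame(chain = ch, iter = seq_len(nrow(x$draws[[ch]])),
               x$draws[[ch]], check.names = FALSE)
  }))
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classic (non-rank-normalized) potential scale reduction factor per
#' parameter, comparing between- and within-chain variances of the
#' retained draws.
#'
#' @param samples A `posterior_samples` object with >= 2 chains and >= 10
#'   retained draws.
#' @return Named numeric vector of Rhat values. Parameters with zero
#'   within- and between-chain variance return 1 with a warning.
#' @export
gelman_rubin <- function(samples) {
  m <- length(samples$draws)
  if (m < 2L) stop("need at least 2 chains", call. = FALSE)
  n <- nrow(samples$draws[[1L]])
  if (n < 10L) stop("need at least 10 retained iterations", call. = FALSE)
  vapply(seq_along(samples$params), function(j) {
    ch <- vapply(samples$draws, function(d) d[, j], numeric(n))
    W <- mean(apply(ch, 2, stats::var))
    B_over_n <- stats::var(colMeans(ch))
    if (W == 0) {
      if (B_over_n == 0) {
        warning("constant chains for ", samples$params[j],
                "; Rhat set to 1", call. = FALSE)
        return(1)
      }
      return(Inf)
    }
    sqrt((n - 1) / n + B_over_n / W)
  }, numeric(1)) -> rhat
  stats::setNames(rhat, samples$params)
}

#' Posterior probability of a common sign (f-statistic)
#'
#' Proportion of posterior draws lying on the same side of zero as the
#' posterior mean. Draws exactly equal to zero are excluded from both the
#' numerator and the denominator (measure-zero under the model); a
#' posterior mean of exactly zero returns 0.5.
#'
#' @param draws Numeric vector of posterior draws (>= 1).
#' @return Proportion in \[0.5, 1\] (for non-degenerate draws).
#' @examples
#' f_value(c(-1, 2, 3, 4))  # 0.75
#' @export
f_value <- function(draws) {
  if (length(draws) < 1L) stop("need at least one draw", call. = FALSE)
  m <- mean(draws)
  nz <- draws[draws != 0]
  if (m == 0 || length(nz) == 0L) return(0.5)
  mean(sign(nz) == sign(m))
}

#' Summarize posterior samples
#'
#' Posterior mean, equal-tailed 95% credible interval and f-statistic per
#' parameter, in canonical parameter order — the layout of the published
#' model-output table.
#'
#' @param samples A `posterior_samples` object (retained draws).
#' @return Data frame with `parameter`, `mean`, `cri_low` (2.5%),
#'   `cri_high` (97.5%), `f`.
#' @export
summarize_posterior <- function(samples) {
  all_draws <- do.call(rbind, samples$draws)
  out <- data.frame(
    parameter = samples$params,
    mean = colMeans(all_draws),
    cri_low = apply(all_draws, 2, stats::quantile, probs = 0.025),
    cri_high = apply(all_draws, 2, stats::quantile, probs = 0.975),
    f = apply(all_draws, 2, f_value),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(match(out$parameter, param_names)), , drop = FALSE]
}
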