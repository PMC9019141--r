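test_that("transition and emission matrices have the dead-recovery structure", {
  g <- transition_matrix(0.9, 0.6)
  expect_equal(unname(g[1, ]), c(0.9, 0.06, 0.04))
  expect_equal(unname(g[2, ]), c(0, 0, 1))   # recovered lasts one interval
  expect_equal(unname(g[3, ]), c(0, 0, 1))   # absorbing
  expect_equal(unname(transition_matrix(1, 0.3)[1, ]), c(1, 0, 0))
  expect_equal(unname(transition_matrix(0, 1)[1, ]), c(0, 1, 0))
  expect_error(transition_matrix(1.2, 0.5), "\\[0, 1\\]")
  expect_error(transition_matrix(0.5, -0.1), "\\[0, 1\\]")

  e <- emission_matrix(0.8)
  expect_equal(unname(e[1, ]), c(0.8, 0, 0.2))
  expect_equal(unname(e[2, ]), c(0, 1, 0))
  expect_equal(unname(e[3, ]), c(0, 0, 1))
  expect_error(emission_matrix(2), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:50) {
    s <- runif(1); r <- runif(1); p <- runif(1)
    expect_equal(unname(rowSums(transition_matrix(s, r))), rep(1, 3),
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(emission_matrix(p))), rep(1, 3),
                 tolerance = 1e-12)
  }
})

test_that("forward likelihood matches closed forms for one interval", {
  cal <- build_calendar(1, start_year = 2010)
  th <- const_theta(0.9, 0.8, 0.6)
  x <- zero_covs()
  expect_equal(history_loglik(th, x, encounter_history("a", 2, c(3, 1), 2), cal), 0)
  expect_equal(history_loglik(th, x, encounter_history("a", 1, c(1, 1), 2), cal),
               log(0.9 * 0.8), tolerance = 1e-12)
  expect_equal(history_loglik(th, x, encounter_history("a", 1, c(1, 3), 2), cal),
               log(0.9 * 0.2 + 0.1 * 0.4), tolerance = 1e-12)
  expect_equal(history_loglik(th, x, encounter_history("a", 1, c(1, 2), 2), cal),
               log(0.1 * 0.6), tolerance = 1e-12)
  expect_error(history_loglik(th, x, encounter_history("a", 1, c(1, 2, 1), 3), cal),
               "after dead recovery")
})

test_that("one-step observation probabilities from the alive state sum to 1", {
  probs_one_step <- function(s, p, r) {
    g <- transition_matrix(s, r)
    e <- emission_matrix(p)
    vapply(1:3, function(code) sum(g[1, ] * e[, code]), numeric(1))
  }
  expect_equal(probs_one_step(0.9, 0.8, 0.6), c(0.72, 0.06, 0.22),
               tolerance = 1e-12)
  expect_equal(sum(probs_one_step(0.9, 0.8, 0.6)), 1, tolerance = 1e-12)
})

test_that("forward, brute-force and recovery-as-emission likelihoods agree", {
  cal <- build_calendar(2)
  set.seed(101)
  for (rep in 1:30) {
    th <- random_theta()
    x <- random_covs()
    span <- sample(2:5, 1)
    start <- sample(seq_len(cal$n_occasions - span + 1L), 1)
    obs_tail <- sample(1:3, span - 1L, replace = TRUE)
    obs <- c(1L, obs_tail)
    h <- encounter_history("z", start, obs, start + span - 1L)
    if (length(validate_history(h))) next
    ll <- history_loglik(th, x, h, cal)
    expect_equal(brute_force_loglik(th, x, h, cal), ll, tolerance = 1e-10)
    expect_equal(alt_history_loglik(th, x, h, cal), ll, tolerance = 1e-10)
  }
  h_long <- encounter_history("z", 1, rep(1L, 12), 12)
  expect_error(brute_force_loglik(random_theta(), zero_covs(), h_long, cal),
               "enumeration guard")
})

test_that("dataset likelihood is additive and agrees with the per-history loop", {
  cal <- build_calendar(1, start_year = 2010)
  th <- const_theta(0.92, 0.85, 0.6)
  empty <- encounter_history_set(list(), cal)
  expect_equal(dataset_loglik(th, zero_covs(), empty)$total, 0)

  covs <- rbind(zero_covs("a"), zero_covs("b"))
  h <- c(1, 1, 3, 1, rep(3, 22))
  set2 <- encounter_history_set(list(
    encounter_history("a", 1, h, 26), encounter_history("b", 1, h, 26)
  ), cal)
  single <- history_loglik(th, zero_covs("a"), get_history(set2, 1), cal)
  expect_equal(dataset_loglik(th, covs, set2)$total, 2 * single,
               tolerance = 1e-10)

  # vectorized engine equals the reference loop on heterogeneous data
  sim_covs <- scale_covariates(simulate_individuals(
    sim_config(n_individuals = 25, n_years = 2, start_year = 2010, seed = 51)))$scaled
  cal2 <- build_calendar(2, start_year = 2010)
  set <- simulate_histories(theta_published(), sim_covs, cal2, seed = 52)
  res <- dataset_loglik(theta_published(), sim_covs, set, per_history = TRUE)
  loop <- vapply(seq_along(set$id), function(i) {
    history_loglik(theta_published(), sim_covs[i, ], get_history(set, i), cal2)
  }, numeric(1))
  expect_equal(unname(res$per_history), loop, tolerance = 1e-10)
  expect_equal(res$total, sum(loop), tolerance = 1e-10)

  expect_error(dataset_loglik(th, zero_covs("other"), set2),
               "missing covariates")
})

test_that("with certain detection and recovery the likelihood is a Bernoulli product", {
  cal <- build_calendar(1, start_year = 2010)
  s <- 0.88
  # detection and recovery effectively 1 (logit 40; r within the open interval)
  th <- parameter_vector(surv_intercept_BS = qlogis(s),
                         surv_intercept_REST = qlogis(s),
                         det_intercept_rest = 40, det_intercept_2009 = 40,
                         recovery_r = 1 - 1e-12)
  covs <- do.call(rbind, lapply(1:80, function(i) zero_covs(paste0("i", i))))
  set <- simulate_histories(th, covs, cal, seed = 61, t_max = 20)
  # every fate observed: count survival and death events straight off the codes
  n_surv <- 0L; n_die <- 0L
  for (i in seq_along(set$id)) {
    o <- set$obs[i, ]
    death <- which(o == 2L)
    last_alive <- if (length(death)) death - 1L else max(which(o == 1L))
    n_surv <- n_surv + (last_alive - set$first_capture[i])
    n_die <- n_die + length(death)
  }
  closed_form <- n_surv * log(s) + n_die * log(1 - s)
  expect_equal(dataset_loglik(th, covs, set)$total, closed_form,
               tolerance = 1e-6)
})

test_that("likelihood of an all-seen-alive history increases with survival", {
  cal <- build_calendar(1, start_year = 2010)
  x <- zero_covs()
  h <- encounter_history("a", 1, rep(1L, 10), 10)
  lls <- vapply(seq(0.05, 0.95, by = 0.1), function(s) {
    history_loglik(const_theta(s, 0.8, 0.5), x, h, cal)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
})
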