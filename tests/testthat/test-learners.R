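test_that("kalman gain follows the variance-ratio formula", {
  expect_equal(kalman_gain(16, 16), 0.5)
  expect_equal(kalman_gain(48, 16), 0.75)
  expect_lt(kalman_gain(1e-12, 16), 1e-10)  # vanishing prior variance
  expect_gt(kalman_gain(1e12, 16), 1 - 1e-10)
  expect_error(kalman_gain(0, 16), "positive")
  expect_error(kalman_gain(16, -1), "positive")
})

test_that("kalman_observe matches the conjugate-Gaussian arithmetic", {
  lp <- learner_params()
  st <- kalman_state(lp)
  st$mean[] <- 50
  st$var[] <- 16
  res <- kalman_observe(st, chosen = 2, reward = 66, params = lp)
  expect_equal(res$record$kalman_gain, 0.5)
  expect_equal(res$record$prediction_error, 16)
  expect_equal(res$record$posterior_mean, 58)
  expect_equal(res$record$posterior_var, 8)
  # unchosen bandits' posteriors equal their priors within the trial
  expect_equal(res$state$mean[-2], st$mean[-2])
  expect_equal(res$state$var[-2], st$var[-2])
  # posterior variance always shrinks, even with zero prediction error
  res0 <- kalman_observe(st, 1, reward = st$mean[1], params = lp)
  expect_equal(res0$record$prediction_error, 0)
  expect_equal(res0$state$mean[1], st$mean[1])
  expect_lt(res0$state$var[1], st$var[1])
  expect_error(kalman_observe(st, 1, NaN, lp), "finite")
  expect_error(kalman_observe(st, 9, 50, lp), "range")
})

test_that("kalman_observe agrees with a grid-Bayes oracle", {
  lp <- learner_params()
  set.seed(101)
  for (i in 1:100) {
    pm <- runif(1, 20, 80)
    pv <- runif(1, 1, 300)
    r <- runif(1, 0, 100)
    st <- kalman_state(lp)
    st$mean[1] <- pm
    st$var[1] <- pv
    res <- kalman_observe(st, 1, r, lp)
    oracle <- grid_bayes_update(pm, sqrt(pv), r, sqrt(lp$est_obs_var))
    expect_equal(res$state$mean[1], oracle$mean, tolerance = 1e-3)
    expect_equal(sqrt(res$state$var[1]), oracle$sd, tolerance = 1e-3)
    expect_gt(res$record$kalman_gain, 0)
    expect_lt(res$record$kalman_gain, 1)
  }
})

test_that("between-trial drift contracts toward the stationary prior", {
  lp <- learner_params()
  st <- kalman_state(lp)
  st$mean[] <- 50
  st$var[] <- 0 + 1e-300
  d1 <- kalman_drift(st, lp)
  expect_equal(d1$mean, rep(50, 4))   # decay center is a fixed point
  expect_equal(d1$var, rep(7.84, 4))  # fully confident prior regains sigma_d^2

  # iterated drift converges to the AR(1) fixed point sigma_d^2/(1-lambda^2)
  st$var[] <- 1
  for (i in 1:2000) st <- kalman_drift(st, lp)
  expect_equal(st$var, rep(lp$est_diff_var / (1 - lp$est_lambda^2), 4),
               tolerance = 1e-8)
  expect_equal(st$var, rep(stationary_sd(walk_params())^2, 4),
               tolerance = 1e-8)
})

test_that("delta rule updates only the chosen value", {
  st <- delta_state(learning_rate = 1)
  expect_equal(delta_update(st, 2, 70)$value, c(50, 70, 50, 50))
  st0 <- delta_state(learning_rate = 0)
  expect_equal(delta_update(st0, 2, 70)$value, rep(50, 4))
  st5 <- delta_state(learning_rate = 0.5)
  expect_equal(delta_update(st5, 1, 70)$value, c(60, 50, 50, 50))
  expect_error(delta_state(learning_rate = 1.2))
})

test_that("run_learner composes observe and drift without lookahead", {
  lp <- learner_params()
  d <- toy_sequence()
  traj <- run_learner(d, lp, "kalman")
  expect_identical(nrow(traj), 10L)
  # trial 1 is the untouched initial prior
  expect_equal(unlist(traj[1, paste0("mu_pre_", 1:4)]),
               rep(lp$init_mean, 4), ignore_attr = TRUE)
  expect_equal(unlist(traj[1, paste0("sd_pre_", 1:4)]),
               rep(lp$init_sd, 4), ignore_attr = TRUE)

  # independent composition oracle in R from the exported primitives
  st <- kalman_state(lp)
  for (t in 1:10) {
    expect_equal(unlist(traj[t, paste0("mu_pre_", 1:4)]), st$mean,
                 ignore_attr = TRUE)
    expect_equal(unlist(traj[t, paste0("sd_pre_", 1:4)]), sqrt(st$var),
                 ignore_attr = TRUE)
    st <- kalman_observe(st, d$choice[t], d$reward[t], lp)$state
    st <- kalman_drift(st, lp)
  }

  # single-trial dataset: trajectory of length 1 with the initial prior
  one <- run_learner(d[1, ], lp, "kalman")
  expect_identical(nrow(one), 1L)
  expect_equal(one$mu_pre_1, lp$init_mean)
})

test_that("missed trials skip the observation but still drift", {
  lp <- learner_params()
  d <- toy_sequence()
  d$responded <- rep(c(TRUE, FALSE), 5)
  traj <- run_learner(d, lp, "kalman")
  # state after a missed trial = drift of the previous state, no update
  st <- kalman_state(lp)
  st <- kalman_observe(st, d$choice[1], d$reward[1], lp)$state
  st <- kalman_drift(st, lp)             # trial 1 (responded)
  expect_equal(unlist(traj[2, paste0("mu_pre_", 1:4)]), st$mean,
               ignore_attr = TRUE)
  st <- kalman_drift(st, lp)             # trial 2 (missed): drift only
  expect_equal(unlist(traj[3, paste0("mu_pre_", 1:4)]), st$mean,
               ignore_attr = TRUE)
  expect_true(is.na(traj$prediction_error[2]))
  # a missing reward on a responded trial is rejected
  d2 <- toy_sequence()
  d2$reward[3] <- NA
  expect_error(run_learner(d2, lp, "kalman"), "reward")
})

test_that("variance dynamics move toward their respective fixed points", {
  lp <- learner_params()
  stat_var <- lp$est_diff_var / (1 - lp$est_lambda^2)
  # observed-bandit fixed point of var -> drift(observe(var))
  f <- function(v) lp$est_lambda^2 * (1 - v / (v + lp$est_obs_var)) * v +
    lp$est_diff_var
  v_obs <- 10
  for (i in 1:500) v_obs <- f(v_obs)

  st <- kalman_state(lp) # starts at stationary variance
  for (t in 1:50) {
    v_chosen_before <- st$var[1]
    v_unchosen_before <- st$var[2]
    st <- kalman_drift(kalman_observe(st, 1, 55, lp)$state, lp)
    if (v_chosen_before > v_obs + 1e-9) {
      expect_lt(st$var[1], v_chosen_before)
    }
    expect_lte(st$var[2], stat_var + 1e-9)
  }
  expect_equal(st$var[1], v_obs, tolerance = 1e-6)

  # unchosen variance rises monotonically toward stationary when below it
  st$var[2] <- 5
  for (t in 1:20) {
    before <- st$var[2]
    st <- kalman_drift(kalman_observe(st, 1, 55, lp)$state, lp)
    expect_gt(st$var[2], before)
  }
})

test_that("delta rule is the constant-gain special case of the filter", {
  # On a single repeatedly chosen bandit with lambda_hat = 1 and the prior
  # variance at its observed fixed point v* (sigma_d^2 = kappa v*), the gain
  # stays at kappa and the Kalman mean updates equal Delta-rule updates.
  kap <- 0.5
  v_star <- 16
  lp <- learner_params(est_lambda = 1, est_center = 50,
                       est_obs_var = v_star * (1 - kap) / kap,
                       est_diff_var = kap * v_star,
                       init_mean = 50, init_sd = sqrt(v_star))
  d <- toy_sequence()
  d$choice <- 1L
  ktraj <- run_learner(d, lp, "kalman")
  dtraj <- run_learner(d, lp, "delta", alpha = kap)
  expect_equal(ktraj$mu_pre_1, dtraj$mu_pre_1, tolerance = 1e-12)
  expect_true(all(abs(ktraj$kalman_gain - kap) < 1e-12))
})
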