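# shared fixtures, built in code and cached for the duration of a test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# one short handcrafted sequence used across modules
toy_sequence <- function() {
  tibble::tibble(
    trial = 1:10,
    choice = c(1L, 1L, 2L, 3L, 1L, 4L, 4L, 2L, 1L, 3L),
    reward = c(55, 61, 38, 45, 58, 70, 66, 41, 52, 47)
  )
}

# small simulated single-condition cohort at the reduced test scale
small_cohort <- function() {
  fixture("small_cohort", {
    spec <- cohort_spec(n_subjects = 8, conditions = "placebo", seed = 11)
    simulate_cohort(spec)
  })
}

small_fit <- function() {
  fixture("small_fit", {
    suppressWarnings(
      fit_hierarchical(small_cohort(), "bayes_smep",
                       sampler = ci_profile(seed = 3))
    )
  })
}

# grid-discretized Bayesian update: independent oracle for the Kalman filter
grid_bayes_update <- function(prior_mean, prior_sd, reward, obs_sd,
                              n_grid = 40001) {
  lo <- min(prior_mean - 10 * prior_sd, reward - 10 * obs_sd)
  hi <- max(prior_mean + 10 * prior_sd, reward + 10 * obs_sd)
  x <- seq(lo, hi, length.out = n_grid)
  post <- dnorm(x, prior_mean, prior_sd) * dnorm(reward, x, obs_sd)
  post <- post / sum(post)
  m <- sum(x * post)
  list(mean = m, sd = sqrt(sum((x - m)^2 * post)))
}
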