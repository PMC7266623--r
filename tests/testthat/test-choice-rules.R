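# independent high-precision evaluation of the augmented-value softmax
oracle_prob <- function(means, sds = NULL, beta, phi = 0, rho = 0,
                        gamma = 0, prev = NULL) {
  v <- means
  if (!is.null(sds)) v <- v + phi * sds
  if (!is.null(prev)) v[prev] <- v[prev] + rho
  if (gamma != 0) v <- v + gamma * means / sum(sds)
  exp(beta * v) / sum(exp(beta * v))
}

test_that("plain softmax matches direct evaluation and its limits", {
  expect_equal(choice_prob_sm(rep(50, 4), beta = 0.29), rep(0.25, 4))
  expect_equal(choice_prob_sm(c(90, 10, 30, 70), beta = 0), rep(0.25, 4))
  p <- choice_prob_sm(c(60, 50, 50, 50), beta = 0.1)
  expect_equal(p[1], 1 / (1 + 3 * exp(-1)))
  expect_equal(p[1], 0.4754, tolerance = 1e-4)
  # huge values do not overflow thanks to log-sum-exp
  expect_equal(sum(choice_prob_sm(c(1e4, 0, 0, 0), beta = 10)), 1)
  expect_error(choice_prob_sm(c(NA, 1, 1, 1), 1), "finite")
  expect_error(choice_prob_sm(rep(1, 4), beta = -1), "beta")
})

test_that("uncertainty bonus steers choice toward or away from uncertainty", {
  means <- rep(50, 4)
  sds <- c(2, 8, 4, 6)
  expect_equal(choice_prob_sme(means, sds, 0.3, phi = 0),
               choice_prob_sm(means, 0.3))
  expect_identical(which.max(choice_prob_sme(means, sds, 0.3, phi = 1)), 2L)
  expect_identical(which.max(choice_prob_sme(means, sds, 0.3, phi = -1)), 1L)
  expect_error(choice_prob_sme(means, c(0, 1, 1, 1), 0.3, 1), "sds")
})

test_that("perseveration bonus boosts only the previous choice", {
  means <- rep(50, 4)
  sds <- rep(5, 4)
  expect_equal(choice_prob_smep(means, sds, 0.29, 1.34, rho = 0, 2),
               choice_prob_sme(means, sds, 0.29, 1.34))
  # no previous choice on a session's first trial: no bonus for anyone
  expect_equal(choice_prob_smep(means, sds, 0.29, 1.34, rho = 4.11, NULL),
               rep(0.25, 4))
  # direct evaluation at the representative subject's posterior medians
  p <- choice_prob_smep(means, sds, beta = 0.29, phi = 0, rho = 4.11,
                        previous_choice = 1)
  expect_equal(p[1], exp(0.29 * 4.11) / (exp(0.29 * 4.11) + 3))
  expect_equal(p[1], 0.5233, tolerance = 1e-4)
  # enormous bonus pins the previous choice
  p_inf <- choice_prob_smep(means, sds, 0.29, 0, rho = 1e6, 3)
  expect_gt(p_inf[3], 1 - 1e-12)
})

test_that("total-uncertainty term vanishes as overall uncertainty grows", {
  means <- c(55, 48, 52, 45)
  sds <- c(3, 7, 5, 6)
  expect_equal(choice_prob_smerp(means, sds, 0.29, 1.34, 4.11, gamma = 0, 2),
               choice_prob_smep(means, sds, 0.29, 1.34, 4.11, 2))
  # as total sd grows the gamma term washes out (phi = 0 isolates it)
  big <- choice_prob_smerp(means, sds * 1e8, 0.29, 0, 4.11, gamma = 5, 2)
  ref <- choice_prob_smep(means, sds * 1e8, 0.29, 0, 4.11, 2)
  expect_equal(big, ref, tolerance = 1e-6)
})

test_that("all four rules match a brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:50) {
    means <- runif(4, 20, 80)
    sds <- runif(4, 0.5, 20)
    beta <- runif(1, 0, 1)
    phi <- runif(1, -3, 3)
    rho <- runif(1, -8, 8)
    gamma <- runif(1, -5, 5)
    prev <- sample(4, 1)
    expect_equal(choice_prob_sm(means, beta), oracle_prob(means, beta = beta))
    expect_equal(choice_prob_sme(means, sds, beta, phi),
                 oracle_prob(means, sds, beta, phi))
    expect_equal(choice_prob_smep(means, sds, beta, phi, rho, prev),
                 oracle_prob(means, sds, beta, phi, rho, prev = prev))
    expect_equal(choice_prob_smerp(means, sds, beta, phi, rho, gamma, prev),
                 oracle_prob(means, sds, beta, phi, rho, gamma, prev))
  }
})

test_that("rules normalize, nest, translate and permute correctly", {
  set.seed(303)
  for (i in 1:25) {
    means <- runif(4, 0, 100)
    sds <- runif(4, 0.1, 25)
    beta <- runif(1, 0, 2)
    prev <- sample(4, 1)
    # normalization
    p4 <- choice_prob_smerp(means, sds, beta, 1.1, -2.3, 0.7, prev)
    expect_equal(sum(p4), 1, tolerance = 1e-12)
    expect_true(all(p4 >= 0))
    # nesting under parameter zeroing (exact)
    expect_identical(choice_prob_smerp(means, sds, beta, 1.1, -2.3, 0, prev),
                     choice_prob_smep(means, sds, beta, 1.1, -2.3, prev))
    expect_identical(choice_prob_smep(means, sds, beta, 1.1, 0, prev),
                     choice_prob_sme(means, sds, beta, 1.1))
    expect_identical(choice_prob_sme(means, sds, beta, 0),
                     choice_prob_sm(means, beta))
    # translation invariance of the augmented values
    expect_equal(choice_prob_sm(means + 123.4, beta),
                 choice_prob_sm(means, beta))
    # label equivariance
    perm <- sample(4)
    expect_equal(choice_prob_sme(means[perm], sds[perm], beta, 1.1),
                 choice_prob_sme(means, sds, beta, 1.1)[perm])
  }
})

test_that("the registry enumerates the eight models", {
  reg <- model_registry()
  expect_identical(nrow(reg), 8L)
  expect_setequal(reg$learner, c("bayes", "delta"))
  expect_identical(sort(unique(reg$choice_rule)), 1:4)
  # delta models carry the learning rate as an extra free parameter
  expect_setequal(reg$free_params[reg$model == "bayes_smep"][[1]],
                  c("beta", "phi", "rho"))
  expect_setequal(reg$free_params[reg$model == "delta_smerp"][[1]],
                  c("alpha", "beta", "phi", "rho", "gamma"))
  expect_error(choice_log_likelihood(toy_sequence(), "bayes_smx",
                                     list(beta = 1)), "unknown model")
})

test_that("sequence log-likelihood composes per-trial probabilities", {
  d <- toy_sequence()
  # beta = 0: every rule collapses to uniform over 4 bandits
  expect_equal(choice_log_likelihood(d, "bayes_sm", list(beta = 0)),
               10 * log(0.25))
  expect_equal(choice_log_likelihood(d[1, ], "bayes_smep",
                                     list(beta = 0.29, phi = 0, rho = 0)),
               log(0.25))

  # composition oracle built from the exported R primitives
  pars <- list(beta = 0.29, phi = 1.34, rho = 4.11)
  lp <- learner_params()
  st <- kalman_state(lp)
  prev <- NULL
  ll <- 0
  for (t in 1:10) {
    p <- choice_prob_smep(st$mean, sqrt(st$var), pars$beta, pars$phi,
                          pars$rho, prev)
    ll <- ll + log(p[d$choice[t]])
    st <- kalman_drift(kalman_observe(st, d$choice[t], d$reward[t], lp)$state,
                       lp)
    prev <- d$choice[t]
  }
  expect_equal(choice_log_likelihood(d, "bayes_smep", pars), ll,
               tolerance = 1e-12)

  # the same oracle for a delta-learner model (uncertainty from the filter)
  parsd <- list(alpha = 0.4, beta = 0.29, phi = 1.34, rho = 4.11)
  std <- delta_state(parsd$alpha)
  stv <- kalman_state(lp)
  prev <- NULL
  lld <- 0
  for (t in 1:10) {
    p <- choice_prob_smep(std$value, sqrt(stv$var), parsd$beta, parsd$phi,
                          parsd$rho, prev)
    lld <- lld + log(p[d$choice[t]])
    std <- delta_update(std, d$choice[t], d$reward[t])
    stv <- kalman_drift(kalman_observe(stv, d$choice[t], d$reward[t],
                                       lp)$state, lp)
    prev <- d$choice[t]
  }
  expect_equal(choice_log_likelihood(d, "delta_smep", parsd), lld,
               tolerance = 1e-12)

  # missed trials contribute nothing
  dm <- d
  dm$responded <- c(TRUE, FALSE, rep(TRUE, 8))
  llm <- choice_log_likelihood(dm, "bayes_sm", list(beta = 0))
  expect_equal(llm, 9 * log(0.25))
})
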