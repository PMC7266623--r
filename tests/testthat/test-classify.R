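test_that("binary and trinary trial classes follow the argmax definitions", {
  mu <- c(10, 20, 15, 5)
  expect_identical(classify_binary(mu, 2), "exploit")
  expect_identical(classify_binary(mu, 3), "explore")
  expect_identical(classify_binary(rep(7, 4), 4), "exploit") # ties exploit

  sds <- c(1, 2, 9, 3)
  expect_identical(classify_trinary(mu, sds, 3), "directed")
  expect_identical(classify_trinary(mu, sds, 4), "random")
  expect_identical(classify_trinary(mu, sds, 1), "random")
  # exploitation takes precedence over a max-uncertainty choice
  expect_identical(classify_trinary(mu, c(1, 9, 2, 3), 2), "exploit")
})

test_that("regressors carry beliefs, probabilities and classes per trial", {
  d <- toy_sequence()
  d <- dplyr::mutate(d, subject = 1, condition = "placebo")
  pars <- c(beta = 0.29, phi = 1.34, rho = 4.11)
  regs <- compute_regressors(d, "bayes_smep", pars)
  lp <- learner_params()
  expect_identical(nrow(regs), 10L)
  # trial 1: all prior sds at their initial value
  expect_equal(regs$sigma_pre_chosen[1], lp$init_sd)
  expect_equal(regs$sum_sigma_pre[1], 4 * lp$init_sd)
  expect_identical(regs$class_binary[1], "exploit") # tie rule at trial 1
  # perseveration indicator marks exact repeats of the previous choice
  expect_identical(regs$persev_indicator,
                   as.integer(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 0)))
  # probabilities are proper and match the trajectory
  expect_true(all(regs$p_chosen > 0 & regs$p_chosen < 1))
  # trinary refines binary
  expect_identical(regs$class_binary == "explore",
                   regs$class_trinary %in% c("directed", "random"))
  # delta is reward minus the chosen prior mean
  expect_equal(regs$delta, regs$reward - regs$mu_pre_chosen)

  path <- withr::local_tempfile(fileext = ".tsv")
  export_regressors(regs, path)
  back <- read.delim(path)
  expect_equal(back$sum_sigma_pre, regs$sum_sigma_pre, tolerance = 1e-10)
  expect_identical(back$class_trinary, regs$class_trinary)
})

test_that("total uncertainty rises under exploitation, drops after exploring", {
  lp <- learner_params()
  # start from the observed-bandit fixed point (beliefs after long learning)
  f <- function(v) lp$est_lambda^2 * (1 - v / (v + lp$est_obs_var)) * v +
    lp$est_diff_var
  v_obs <- 10
  for (i in 1:500) v_obs <- f(v_obs)
  lp_low <- learner_params(init_sd = sqrt(v_obs))

  # 30 exploitations of bandit 1, then one choice of the max-sd bandit 2
  d <- tibble::tibble(subject = 1, condition = "c", trial = 1:32,
                      choice = c(rep(1L, 30), 2L, 1L),
                      reward = rep(55, 32))
  regs <- compute_regressors(d, "bayes_sm", c(beta = 0.2),
                             learner_params = lp_low)
  sigma <- regs$sum_sigma_pre
  expect_true(all(diff(sigma[1:31]) >= -1e-9)) # non-decreasing while exploiting
  expect_lt(sigma[32], sigma[31])              # collapses after exploration
})

test_that("best-bandit percentage uses latent means and the block scheme", {
  cfg <- session_config(n_trials = 300, block_length = 75)
  w <- generate_walk(config = cfg, seed = 17)
  lm <- matrix(w$latent_mean, nrow = 300)
  best <- max.col(lm)
  # omniscient greedy agent: 100% in every block
  d_greedy <- tibble::tibble(subject = 1, condition = "c", trial = 1:300,
                             choice = best,
                             reward = matrix(w$payoff, 300)[cbind(1:300, best)],
                             responded = TRUE)
  rate <- best_bandit_rate(d_greedy, walks = list(c = w))
  expect_true(all(rate$pct_best_bandit == 100))
  expect_setequal(as.character(rate$block),
                  c("1-10", "11-50", "51-100", "101-150", "151-200",
                    "201-250", "251-300"))
  expect_equal(sum(rate$n_trials), 300)

  # handcrafted 10-trial dataset against a hand count
  w10 <- generate_walk(config = session_config(n_trials = 10, n_bandits = 4,
                                               block_length = 10), seed = 18)
  best10 <- max.col(matrix(w10$latent_mean, 10))
  ch <- c(best10[1:4], 5 - best10[5:10]) # 4 hits, 6 guaranteed misses
  d10 <- tibble::tibble(subject = 1, condition = "c", trial = 1:10,
                        choice = ifelse(ch %in% 1:4, ch, 1L),
                        reward = 50, responded = TRUE)
  r10 <- best_bandit_rate(d10, walks = list(c = w10))
  expect_equal(r10$pct_best_bandit[r10$block == "1-10"],
               100 * mean(d10$choice == best10))
})

test_that("switch rate counts changes between consecutive responded trials", {
  base <- tibble::tibble(subject = 1, condition = "c", trial = 1:5,
                         reward = 50, responded = TRUE)
  expect_equal(switch_rate(dplyr::mutate(base, choice = c(1, 1, 2, 1, 3)))
               $pct_switches, 75)
  expect_equal(switch_rate(dplyr::mutate(base, choice = rep(2, 5)))
               $pct_switches, 0)
  expect_equal(switch_rate(dplyr::mutate(base, choice = c(1, 2, 1, 2, 1)))
               $pct_switches, 100)
  # a missed trial bridges its neighbours rather than breaking the run
  miss <- dplyr::mutate(base, choice = c(1, NA, 1, 2, 2),
                        responded = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(switch_rate(miss)$pct_switches, 100 * 1 / 3)
})

test_that("behavioural summary percentages are coherent", {
  d <- small_cohort()
  regs <- compute_regressors(d, "bayes_smep", attr(d, "true_params"))
  summ <- behavioral_summary(regs)
  o <- summ$overall
  expect_equal(o$pct_exploit + o$pct_directed + o$pct_random,
               rep(100, nrow(o)), tolerance = 1e-9)
  expect_true(all(o$pct_exploit >= 0 & o$pct_exploit <= 100))
  expect_equal(o$payout_cents,
               floor(o$total_points * 5 / 100 + 0.5))
  b <- summ$by_block
  expect_setequal(unique(b$block50), 1:6)
  expect_equal(b$pct_exploit + b$pct_directed + b$pct_random,
               rep(100, nrow(b)), tolerance = 1e-9)
})

test_that("directed exploration rises with the exploration bonus", {
  frac_directed <- vapply(c(0, 0.5, 1, 2), function(phi) {
    spec <- cohort_spec(n_subjects = 6, conditions = "placebo",
                        group_means = c(beta = 0.29, phi = phi, rho = 4.11),
                        group_sds = c(beta = 1e-6, phi = 1e-6, rho = 1e-6),
                        seed = 77)
    d <- simulate_cohort(spec)
    regs <- compute_regressors(d, "bayes_smep", attr(d, "true_params"))
    mean(regs$class_trinary == "directed")
  }, numeric(1))
  expect_true(all(diff(frac_directed) > 0))
})
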