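#' Fixed parameters of the learning models
#'
#' The learner's internal model of the payoff walk. Defaults equal the true
#' generative values: \eqn{\hat\lambda = 0.9836}, \eqn{\hat\vartheta = 50},
#' \eqn{\hat\sigma_o^2 = 16}, \eqn{\hat\sigma_d^2 = 7.84}. The initial prior
#' is \eqn{N(50, \sigma_1^2)} with \eqn{\sigma_1} the stationary sd
#' (about 15.5 points); the Delta learner starts all values at `v1 = 50`.
#'
#' @param est_lambda Assumed decay \eqn{\hat\lambda}, in (0, 1].
#' @param est_center Assumed decay center \eqn{\hat\vartheta} (points).
#' @param est_obs_var Assumed observation variance \eqn{\hat\sigma_o^2}.
#' @param est_diff_var Assumed diffusion variance \eqn{\hat\sigma_d^2}.
#' @param init_mean Initial prior mean \eqn{\hat\mu_1^{pre}} (points).
#' @param init_sd Initial prior sd \eqn{\hat\sigma_1^{pre}} (points).
#' @param v1 Initial Delta-rule value for all bandits (points).
#' @return A list of class `learner_params`.
#' @export
learner_params <- function(est_lambda = 0.9836, est_center = 50,
                           est_obs_var = 16, est_diff_var = 7.84,
                           init_mean = 50,
                           init_sd = sqrt(est_diff_var / (1 - est_lambda^2)),
                           v1 = 50) {
  stopifnot(est_lambda > 0, est_lambda <= 1, est_obs_var > 0,
            est_diff_var > 0, init_sd > 0, is.finite(init_mean),
            is.finite(v1))
  structure(list(est_lambda = est_lambda, est_center = est_center,
                 est_obs_var = est_obs_var, est_diff_var = est_diff_var,
                 init_mean = init_mean, init_sd = init_sd, v1 = v1),
            class = "learner_params")
}

#' Initial Kalman belief state
#'
#' @param params A [learner_params()] object.
#' @param n_bandits Number of bandits.
#' @return A list of class `kalman_state` with per-bandit `mean` and `var`.
#' @export
kalman_state <- function(params = learner_params(), n_bandits = 4) {
  structure(list(mean = rep(params$init_mean, n_bandits),
                 var = rep(params$init_sd^2, n_bandits)),
            class = "kalman_state")
}

#' Kalman gain
#'
#' Fraction of the prediction error used for updating:
#' \eqn{\kappa = \sigma^2_{pre} / (\sigma^2_{pre} + \sigma_o^2)}.
#'
#' @param prior_var Prior variance of the chosen bandit (> 0).
#' @param obs_var Assumed observation variance (> 0).
#' @return Gain in (0, 1).
#' @export
kalman_gain <- function(prior_var, obs_var) {
  if (any(prior_var <= 0) || any(obs_var <= 0)) {
    stop("variances must be strictly positive.", call. = FALSE)
  }
  prior_var / (prior_var + obs_var)
}

#' Within-trial Bayesian update of the chosen bandit
#'
#' The chosen bandit's prior is combined with the reward observation:
#' posterior mean \eqn{\mu^{pre} + \kappa\delta} with prediction error
#' \eqn{\delta = r - \mu^{pre}}, posterior variance
#' \eqn{(1-\kappa)\sigma^2_{pre}}. Unchosen bandits' posteriors equal their
#' priors within the trial.
#'
#' @param state A `kalman_state`.
#' @param chosen 1-based bandit index.
#' @param reward Observed reward in points.
#' @param params A [learner_params()] object.
#' @return A list with the updated `state` and a `record` (one-row tibble
#'   with `kalman_gain`, `prediction_error`, `posterior_mean`,
#'   `posterior_var`).
#' @export
kalman_observe <- function(state, chosen, reward,
                           params = learner_params()) {
  stopifnot(inherits(state, "kalman_state"))
  k <- length(state$mean)
  if (chosen < 1 || chosen > k) stop("`chosen` out of range.", call. = FALSE)
  if (!is.finite(reward)) stop("`reward` must be finite.", call. = FALSE)
  kap <- kalman_gain(state$var[chosen], params$est_obs_var)
  delta <- reward - state$mean[chosen]
  state$mean[chosen] <- state$mean[chosen] + kap * delta
  state$var[chosen] <- (1 - kap) * state$var[chosen]
  list(state = state,
       record = tibble::tibble(kalman_gain = kap, prediction_error = delta,
                               posterior_mean = state$mean[chosen],
                               posterior_var = state$var[chosen]))
}

#' Between-trial drift of all bandit beliefs
#'
#' Applies the learner's model of the random walk to every bandit:
#' \eqn{\mu' = \hat\lambda\mu + (1-\hat\lambda)\hat\vartheta},
#' \eqn{\sigma^{2\prime} = \hat\lambda^2\sigma^2 + \hat\sigma_d^2}.
#'
#' @inheritParams kalman_observe
#' @return The drifted `kalman_state`.
#' @export
kalman_drift <- function(state, params = learner_params()) {
  stopifnot(inherits(state, "kalman_state"))
  lam <- params$est_lambda
  state$mean <- lam * state$mean + (1 - lam) * params$est_center
  state$var <- lam^2 * state$var + params$est_diff_var
  state
}

#' Initial Delta-rule state
#'
#' @param learning_rate Constant learning rate \eqn{\alpha} in \[0, 1\].
#' @param value Initial value for all bandits (points).
#' @param n_bandits Number of bandits.
#' @return A list of class `delta_state`.
#' @export
delta_state <- function(learning_rate, value = 50, n_bandits = 4) {
  stopifnot(learning_rate >= 0, learning_rate <= 1)
  structure(list(value = rep(value, n_bandits),
                 learning_rate = learning_rate),
            class = "delta_state")
}

#' Delta-rule value update
#'
#' Only the chosen bandit changes:
#' \eqn{v \leftarrow v + \alpha (r - v)}.
#'
#' @param state A `delta_state`.
#' @param chosen 1-based bandit index.
#' @param reward Observed reward in points.
#' @return The updated `delta_state`.
#' @export
delta_update <- function(state, chosen, reward) {
  stopifnot(inherits(state, "delta_state"))
  if (chosen < 1 || chosen > length(state$value)) {
    stop("`chosen` out of range.", call. = FALSE)
  }
  if (!is.finite(reward)) stop("`reward` must be finite.", call. = FALSE)
  state$value[chosen] <- state$value[chosen] +
    state$learning_rate * (reward - state$value[chosen])
  state
}

#' Run a learner over one choice sequence
#'
#' Replays a single subject-condition sequence through the observe-then-drift
#' cycle and returns the pre-choice belief trajectory. Trial `t`'s state
#' reflects history through trial `t - 1` only. Missed trials receive no
#' within-trial update but still drift.
#'
#' @param data A tibble with columns `trial`, `choice`, `reward` and
#'   optionally `responded` (default all `TRUE`), for one subject and
#'   condition, sorted by trial.
#' @param params A [learner_params()] object.
#' @param learner `"kalman"` or `"delta"`. The Delta learner also carries the
#'   (reward-independent) Kalman variance recursion so that uncertainty-bonus
#'   choice rules remain defined.
#' @param alpha Delta-rule learning rate (required when `learner = "delta"`).
#' @return A tibble with one row per trial: `trial`, pre-choice means
#'   `mu_pre_1..4`, sds `sd_pre_1..4`, `kalman_gain` and `prediction_error`
#'   (NA on missed trials), and `prev_choice` (0 when none).
#' @export
run_learner <- function(data, params = learner_params(),
                        learner = c("kalman", "delta"), alpha = NULL) {
  learner <- match.arg(learner)
  data <- check_sequence(data)
  if (learner == "delta") {
    if (is.null(alpha)) stop("`alpha` is required for the delta learner.",
                             call. = FALSE)
    stopifnot(alpha >= 0, alpha <= 1)
  } else {
    alpha <- 0
  }
  res <- .filter_cpp(as.integer(data$choice), as.numeric(data$reward),
                     data$responded,
                     learner = if (learner == "kalman") 0L else 1L,
                     rule = 1L, alpha = alpha, beta = 1, phi = 0, rho = 0,
                     gamma = 0, lambda = params$est_lambda,
                     center = params$est_center,
                     obs_var = params$est_obs_var,
                     diff_var = params$est_diff_var,
                     init_mean = params$init_mean,
                     init_var = params$init_sd^2, v1 = params$v1,
                     trajectory = TRUE)
  traj_tibble(data$trial, res)
}

traj_tibble <- function(trials, res) {
  mu <- res$mu_pre
  sdp <- res$sd_pre
  colnames(mu) <- paste0("mu_pre_", seq_len(ncol(mu)))
  colnames(sdp) <- paste0("sd_pre_", seq_len(ncol(sdp)))
  dplyr::bind_cols(
    tibble::tibble(trial = trials),
    tibble::as_tibble(mu), tibble::as_tibble(sdp),
    tibble::tibble(kalman_gain = res$kalman_gain,
                   prediction_error = res$pe,
                   prev_choice = res$prev_choice)
  )
}

# validate + normalize one subject-condition sequence
check_sequence <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("trial", "choice", "reward") %in% names(data)))
  if (!"responded" %in% names(data)) data$responded <- TRUE
  data$responded <- as.logical(data$responded) & !is.na(data$choice)
  if (is.unsorted(data$trial, strictly = TRUE)) {
    stop("`trial` must be strictly increasing within a sequence.",
         call. = FALSE)
  }
  resp <- data$responded
  if (any(resp & !is.finite(data$reward))) {
    stop("responded trials must carry a finite reward.", call. = FALSE)
  }
  if (any(resp & (data$choice < 1 | data$choice > 4))) {
    stop("`choice` must be in 1..4 on responded trials.", call. = FALSE)
  }
  data$choice[!resp] <- 1L # placeholder, never used by the filter
  data$reward[!resp] <- 0
  data
}
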