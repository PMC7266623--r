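#' Softmax choice rules
#'
#' The four choice rules map per-bandit beliefs to choice probabilities via a
#' softmax over an augmented value, with the inverse temperature \eqn{\beta}
#' applied to the full bracket:
#' \itemize{
#'   \item SM: \eqn{v_i = \mu_i^{pre}} (random exploration via \eqn{\beta});
#'   \item SME: \eqn{v_i = \mu_i^{pre} + \phi \sigma_i^{pre}} (directed
#'     exploration bonus);
#'   \item SMEP: adds a constant perseveration bonus \eqn{\rho} to the bandit
#'     chosen on the previous trial;
#'   \item SMERP: adds \eqn{\gamma \mu_i^{pre} / \Sigma\sigma^{pre}}, a
#'     random-exploration term discounted by total uncertainty (the sum of
#'     all bandits' prior sds on that trial).
#' }
#' All rules are computed with log-sum-exp stabilization. On a session's
#' first trial (or after a missed trial) there is no previous choice and the
#' perseveration bonus is absent (`previous_choice = NULL`).
#'
#' @param means Per-bandit prior means \eqn{\mu^{pre}} (points).
#' @param sds Per-bandit prior sds \eqn{\sigma^{pre}} (points, > 0).
#' @param beta Inverse temperature \eqn{\beta \ge 0}.
#' @param phi Exploration-bonus weight \eqn{\phi} (signed).
#' @param rho Perseveration bonus \eqn{\rho} (signed, points).
#' @param gamma Total-uncertainty random-exploration weight \eqn{\gamma}.
#' @param previous_choice 1-based index of the previous trial's choice, or
#'   `NULL` if none.
#' @return A probability vector over bandits (sums to 1).
#' @export
#' @examples
#' choice_prob_sm(c(60, 50, 50, 50), beta = 0.1)
choice_prob_sm <- function(means, beta) {
  softmax_checked(beta, means)
}

#' @rdname choice_prob_sm
#' @export
choice_prob_sme <- function(means, sds, beta, phi) {
  check_sds(sds, means)
  softmax_checked(beta, means + phi * sds)
}

#' @rdname choice_prob_sm
#' @export
choice_prob_smep <- function(means, sds, beta, phi, rho,
                             previous_choice = NULL) {
  check_sds(sds, means)
  v <- means + phi * sds
  v <- v + rho * persev_indicator(previous_choice, length(means))
  softmax_checked(beta, v)
}

#' @rdname choice_prob_sm
#' @export
choice_prob_smerp <- function(means, sds, beta, phi, rho, gamma,
                              previous_choice = NULL) {
  check_sds(sds, means)
  total_sd <- sum(sds)
  if (total_sd <= 0) stop("total uncertainty must be positive.",
                          call. = FALSE)
  v <- means + phi * sds + gamma * means / total_sd
  v <- v + rho * persev_indicator(previous_choice, length(means))
  softmax_checked(beta, v)
}

persev_indicator <- function(previous_choice, k) {
  ind <- numeric(k)
  if (!is.null(previous_choice) && !is.na(previous_choice) &&
      previous_choice >= 1) {
    stopifnot(previous_choice <= k)
    ind[previous_choice] <- 1
  }
  ind
}

check_sds <- function(sds, means) {
  stopifnot(length(sds) == length(means))
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("`sds` must be finite and > 0.", call. = FALSE)
  }
}

softmax_checked <- function(beta, values) {
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0.",
                                         call. = FALSE)
  if (any(!is.finite(values))) stop("augmented values must be finite.",
                                    call. = FALSE)
  x <- beta * values
  e <- exp(x - max(x))
  e / sum(e)
}

#' Registry of the eight cognitive models
#'
#' Two learning rules (Kalman-filter Bayesian learner, Delta rule) crossed
#' with four softmax choice rules.
#'
#' @return A tibble with columns `model`, `learner`, `choice_rule` (1-4),
#'   `rule_label`, and `free_params` (list column).
#' @export
model_registry <- function() {
  rules <- tibble::tibble(
    choice_rule = 1:4,
    rule_label = c("sm", "sme", "smep", "smerp"),
    rule_params = list("beta", c("beta", "phi"), c("beta", "phi", "rho"),
                       c("beta", "phi", "rho", "gamma"))
  )
  out <- tidyr::expand_grid(learner = c("delta", "bayes"), rules)
  out$model <- paste(out$learner, out$rule_label, sep = "_")
  out$free_params <- purrr::map2(out$learner, out$rule_params, function(l, p) {
    if (l == "delta") c("alpha", p) else p
  })
  dplyr::select(out, "model", "learner", "choice_rule", "rule_label",
                "free_params")
}

model_info <- function(model) {
  reg <- model_registry()
  i <- match(model, reg$model)
  if (is.na(i)) {
    stop("unknown model `", model, "`; see model_registry().", call. = FALSE)
  }
  as.list(reg[i, ])
}

# full 5-slot parameter vector (alpha, beta, phi, rho, gamma) from a named
# list/vector of free parameters
full_param_vector <- function(params, model) {
  info <- model_info(model)
  free <- info$free_params[[1]]
  p <- unlist(params)
  missing <- setdiff(free, names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- c(alpha = 0, beta = 0, phi = 0, rho = 0, gamma = 0)
  out[free] <- p[free]
  out
}

#' Log-likelihood of a choice sequence under a cognitive model
#'
#' Sum of log choice probabilities of the chosen bandits over responded
#' trials, with beliefs filtered sequentially (observe, then drift). Choice
#' probabilities are floored at machine epsilon inside the likelihood only.
#'
#' @param data One subject-condition sequence (see [run_learner()]).
#' @param model Model name from [model_registry()], e.g. `"bayes_smep"`.
#' @param params Named list or vector of the model's free parameters.
#' @param learner_params A [learner_params()] object.
#' @return The log-likelihood (scalar).
#' @export
#' @examples
#' d <- tibble::tibble(trial = 1:3, choice = c(1, 2, 1), reward = c(55, 40, 60))
#' choice_log_likelihood(d, "bayes_smep",
#'                       list(beta = 0.29, phi = 1.34, rho = 4.11))
choice_log_likelihood <- function(data, model, params,
                                  learner_params = restlessbandit::learner_params()) {
  data <- check_sequence(data)
  info <- model_info(model)
  pv <- full_param_vector(params, model)
  res <- .filter_cpp(as.integer(data$choice), as.numeric(data$reward),
                     data$responded,
                     learner = if (info$learner == "bayes") 0L else 1L,
                     rule = info$choice_rule,
                     alpha = pv[["alpha"]], beta = pv[["beta"]],
                     phi = pv[["phi"]], rho = pv[["rho"]],
                     gamma = pv[["gamma"]],
                     lambda = learner_params$est_lambda,
                     center = learner_params$est_center,
                     obs_var = learner_params$est_obs_var,
                     diff_var = learner_params$est_diff_var,
                     init_mean = learner_params$init_mean,
                     init_var = learner_params$init_sd^2,
                     v1 = learner_params$v1, trajectory = FALSE)
  res$loglik
}

# trial-wise trajectory under a full choice model (beliefs + probabilities)
model_trajectory <- function(data, model, params,
                             learner_params = restlessbandit::learner_params()) {
  data <- check_sequence(data)
  info <- model_info(model)
  pv <- full_param_vector(params, model)
  res <- .filter_cpp(as.integer(data$choice), as.numeric(data$reward),
                     data$responded,
                     learner = if (info$learner == "bayes") 0L else 1L,
                     rule = info$choice_rule,
                     alpha = pv[["alpha"]], beta = pv[["beta"]],
                     phi = pv[["phi"]], rho = pv[["rho"]],
                     gamma = pv[["gamma"]],
                     lambda = learner_params$est_lambda,
                     center = learner_params$est_center,
                     obs_var = learner_params$est_obs_var,
                     diff_var = learner_params$est_diff_var,
                     init_mean = learner_params$init_mean,
                     init_var = learner_params$init_sd^2,
                     v1 = learner_params$v1, trajectory = TRUE)
  out <- traj_tibble(data$trial, res)
  pr <- res$prob
  colnames(pr) <- paste0("p_", seq_len(ncol(pr)))
  dplyr::bind_cols(out, tibble::as_tibble(pr))
}
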