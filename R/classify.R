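#' Classify a single trial as exploitation or exploration
#'
#' A trial is an exploitation when the chosen bandit belongs to the argmax
#' set of the prior expected values (ties count as exploitation, which also
#' covers trial 1 where all beliefs are equal); otherwise it is an
#' exploration.
#'
#' @param means Per-bandit prior means \eqn{\mu^{pre}} on that trial.
#' @param chosen 1-based chosen bandit.
#' @return `"exploit"` or `"explore"`.
#' @export
#' @examples
#' classify_binary(c(10, 20, 15, 5), 2) # exploit
classify_binary <- function(means, chosen) {
  stopifnot(chosen >= 1, chosen <= length(means))
  if (means[chosen] >= max(means) - 1e-12) "exploit" else "explore"
}

#' Refine an exploration trial into directed vs. random exploration
#'
#' Exploitation takes precedence: a bandit that is both max-value and
#' max-uncertainty is an exploitation. Among exploration trials, the choice
#' is a directed exploration when the chosen bandit has the highest prior
#' uncertainty \eqn{\sigma^{pre}}, and a random exploration otherwise.
#'
#' @param means,sds Per-bandit prior means and sds on that trial.
#' @param chosen 1-based chosen bandit.
#' @return `"exploit"`, `"directed"` or `"random"`.
#' @export
classify_trinary <- function(means, sds, chosen) {
  if (classify_binary(means, chosen) == "exploit") return("exploit")
  if (sds[chosen] >= max(sds) - 1e-12) "directed" else "random"
}

#' Trial-wise model-based regressors and trial classification
#'
#' Replays each subject-condition sequence through a cognitive model and
#' returns, per trial: the chosen bandit's prior expected value and
#' uncertainty, the prediction error, the model's choice probability of the
#' chosen bandit, the total uncertainty \eqn{\Sigma\sigma^{pre}} (sum over
#' all four bandits), the perseveration indicator, and the binary/trinary
#' trial classes. Missed trials carry NA for choice-dependent fields.
#'
#' @param data A `choice_dataset` or compatible tibble.
#' @param model Model name from [model_registry()].
#' @param params Either a named vector/list of parameters shared by all
#'   subjects, or a tibble with columns `subject`, `condition` and one column
#'   per free parameter (e.g. the `true_params` attribute of a simulated
#'   cohort, or [fit_subject_map()] output).
#' @param learner_params A [learner_params()].
#' @return A tibble with one row per trial and columns `subject`,
#'   `condition`, `trial`, `choice`, `reward`, `responded`,
#'   `mu_pre_chosen`, `sigma_pre_chosen`, `delta`, `p_chosen`,
#'   `sum_sigma_pre`, `persev_indicator`, `class_binary`, `class_trinary`.
#' @export
compute_regressors <- function(data, model = "bayes_smep", params,
                               learner_params = restlessbandit::learner_params()) {
  seqs <- split_sequences(tibble::as_tibble(data))
  param_tbl <- NULL
  if (is.data.frame(params)) {
    param_tbl <- tibble::as_tibble(params)
    stopifnot(all(c("subject", "condition") %in% names(param_tbl)))
  }
  free <- model_info(model)$free_params[[1]]
  purrr::map_dfr(seqs, function(sq) {
    p <- if (is.null(param_tbl)) params else {
      row <- dplyr::filter(param_tbl, .data$subject == sq$subject[1],
                           .data$condition == sq$condition[1])
      if (nrow(row) != 1) {
        stop("no unique parameter row for subject ", sq$subject[1],
             ", condition ", sq$condition[1], ".", call. = FALSE)
      }
      as.list(row[free])
    }
    traj <- model_trajectory(sq, model, p, learner_params)
    regressors_one(sq, traj)
  })
}

regressors_one <- function(sq, traj) {
  nb <- sum(startsWith(names(traj), "mu_pre_"))
  mu <- as.matrix(traj[paste0("mu_pre_", seq_len(nb))])
  sdp <- as.matrix(traj[paste0("sd_pre_", seq_len(nb))])
  pr <- as.matrix(traj[paste0("p_", seq_len(nb))])
  nt <- nrow(traj)
  idx <- cbind(seq_len(nt), ifelse(sq$responded, sq$choice, NA_integer_))
  cls_b <- cls_t <- rep(NA_character_, nt)
  for (t in seq_len(nt)) {
    if (!sq$responded[t]) next
    cls_b[t] <- classify_binary(mu[t, ], sq$choice[t])
    cls_t[t] <- classify_trinary(mu[t, ], sdp[t, ], sq$choice[t])
  }
  tibble::tibble(
    subject = sq$subject[1], condition = sq$condition[1],
    trial = sq$trial, choice = ifelse(sq$responded, sq$choice, NA_integer_),
    reward = ifelse(sq$responded, sq$reward, NA_real_),
    responded = sq$responded,
    mu_pre_chosen = mu[idx], sigma_pre_chosen = sdp[idx],
    delta = traj$prediction_error, p_chosen = pr[idx],
    sum_sigma_pre = rowSums(sdp),
    persev_indicator = as.integer(sq$responded & sq$choice ==
                                    traj$prev_choice & traj$prev_choice > 0),
    class_binary = cls_b, class_trinary = cls_t
  )
}

#' Percentage of best-bandit choices per block
#'
#' "Best" is the bandit with the highest latent mean payoff on each trial.
#' The default block scheme follows the study's learning-curve summary:
#' trials 1-10, 11-50, then 50-trial blocks to the end of the session.
#' Missed trials are excluded from denominators.
#'
#' @param data A `choice_dataset` (its per-condition walks are used) or a
#'   tibble plus an explicit `walks` named list of `payoff_walk`s.
#' @param walks Optional named list of walks per condition.
#' @return A tibble: `subject`, `condition`, `block`, `n_trials`,
#'   `pct_best_bandit`.
#' @export
best_bandit_rate <- function(data, walks = NULL) {
  walks <- walks %||% attr(data, "walks")
  if (is.null(walks)) stop("`walks` must be supplied when the dataset does ",
                           "not carry them.", call. = FALSE)
  d <- tibble::as_tibble(data)
  if (!"responded" %in% names(d)) d$responded <- TRUE
  best <- purrr::map_dfr(names(walks), function(cnd) {
    lm <- walk_matrix(walks[[cnd]], "latent_mean")
    tibble::tibble(condition = cnd, trial = seq_len(nrow(lm)),
                   best_bandit = max.col(lm))
  })
  nt <- max(d$trial)
  d <- dplyr::left_join(d, best, by = c("condition", "trial"))
  d$block <- block_label(d$trial, nt)
  d <- dplyr::filter(d, .data$responded)
  dplyr::summarise(
    dplyr::group_by(d, .data$subject, .data$condition, .data$block),
    n_trials = dplyr::n(),
    pct_best_bandit = 100 * mean(.data$choice == .data$best_bandit),
    .groups = "drop")
}

block_label <- function(trial, n_trials) {
  breaks <- unique(c(0, 10, 50, seq(100, max(n_trials, 100), by = 50)))
  labs <- paste0(head(breaks, -1) + 1, "-", tail(breaks, -1))
  cut(trial, breaks = breaks, labels = labs)
}

#' Percentage of choice switches
#'
#' Fraction of responded trials (from the second responded trial of each
#' subject-condition sequence on) whose choice differs from the previous
#' responded choice.
#'
#' @param data A `choice_dataset` or compatible tibble.
#' @return A tibble: `subject`, `condition`, `pct_switches`.
#' @export
switch_rate <- function(data) {
  seqs <- split_sequences(tibble::as_tibble(data))
  purrr::map_dfr(seqs, function(sq) {
    ch <- sq$choice[sq$responded]
    if (length(ch) < 2) {
      return(tibble::tibble(subject = sq$subject[1],
                            condition = sq$condition[1],
                            pct_switches = NA_real_))
    }
    tibble::tibble(subject = sq$subject[1], condition = sq$condition[1],
                   pct_switches = 100 * mean(diff(ch) != 0))
  })
}

#' Model-free and model-based behavioural summary
#'
#' Per subject and condition: total points and payout in cents, percentage
#' of switches, and the exploit/directed/random percentages from the trinary
#' classification — overall and per 50-trial block. Missed trials are
#' excluded from all denominators; the three class percentages sum to 100
#' over responded trials.
#'
#' @param regressors Output of [compute_regressors()].
#' @param cents_per_100_points Payout conversion.
#' @return A list of tibbles: `overall` (one row per subject x condition)
#'   and `by_block` (class percentages per 50-trial block).
#' @export
behavioral_summary <- function(regressors, cents_per_100_points = 5) {
  r <- dplyr::filter(tibble::as_tibble(regressors), .data$responded)
  overall <- dplyr::summarise(
    dplyr::group_by(r, .data$subject, .data$condition),
    total_points = sum(.data$reward),
    payout_cents = points_to_payout(sum(.data$reward),
                                    cents_per_100_points),
    pct_exploit = 100 * mean(.data$class_trinary == "exploit"),
    pct_directed = 100 * mean(.data$class_trinary == "directed"),
    pct_random = 100 * mean(.data$class_trinary == "random"),
    .groups = "drop")
  overall <- dplyr::left_join(overall, switch_rate(regressors),
                              by = c("subject", "condition"))
  r$block50 <- ceiling(r$trial / 50)
  by_block <- dplyr::summarise(
    dplyr::group_by(r, .data$subject, .data$condition, .data$block50),
    n_trials = dplyr::n(),
    pct_exploit = 100 * mean(.data$class_trinary == "exploit"),
    pct_directed = 100 * mean(.data$class_trinary == "directed"),
    pct_random = 100 * mean(.data$class_trinary == "random"),
    .groups = "drop")
  list(overall = overall, by_block = by_block)
}

#' Export trial-wise regressors as TSV
#'
#' One row per trial with all model-based regressor fields, suitable as
#' design-matrix input for downstream (e.g. neuroimaging) models.
#'
#' @param regressors Output of [compute_regressors()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_regressors <- function(regressors, path) {
  write.table(as.data.frame(regressors), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Plot trial-wise regressors of one subject-condition sequence
#'
#' @param regressors Output of [compute_regressors()] filtered to one
#'   subject and condition.
#' @return A ggplot object with total uncertainty and choice probability over
#'   trials, exploration trials marked.
#' @export
plot_regressors <- function(regressors) {
  r <- tibble::as_tibble(regressors)
  stopifnot(dplyr::n_distinct(r$subject) == 1,
            dplyr::n_distinct(r$condition) == 1)
  long <- tidyr::pivot_longer(
    dplyr::select(r, "trial", "sum_sigma_pre", "p_chosen", "class_binary"),
    c("sum_sigma_pre", "p_chosen"), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$trial, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = dplyr::filter(r, .data$class_binary ==
                                               "explore"),
                        ggplot2::aes(xintercept = .data$trial),
                        alpha = 0.2, colour = "grey40") +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial", y = NULL)
}
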