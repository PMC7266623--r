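#' Specification of a synthetic cohort
#'
#' Describes a within-subjects study: every subject completes one 300-trial
#' session per condition, each condition with its own payoff walk. Subject
#' parameters are drawn from condition-specific group-level normal
#' distributions \eqn{N(M_x, \Lambda_x)} (truncated to the parameter's
#' support: \eqn{\beta \ge 0}, \eqn{\alpha \in [0,1]}; \eqn{\phi, \rho,
#' \gamma} unbounded). Default group means reuse one representative subject's
#' posterior medians (\eqn{\beta = 0.29}, \eqn{\phi = 1.34},
#' \eqn{\rho = 4.11}) as plausible values — they are synthetic stand-ins, not
#' fitted group estimates.
#'
#' @param n_subjects Subjects (default 31).
#' @param conditions Condition labels (default placebo, ldopa, haloperidol).
#' @param group_means Named list: for each condition, a named vector of
#'   group-level means for the model's free parameters. A single named vector
#'   is recycled across conditions.
#' @param group_sds Named vector of group-level sds (shared across
#'   conditions).
#' @param omission_rate Probability that a trial is missed (default 0).
#' @param seed Master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 31,
                        conditions = c("placebo", "ldopa", "haloperidol"),
                        group_means = c(beta = 0.29, phi = 1.34, rho = 4.11),
                        group_sds = c(beta = 0.1, phi = 0.5, rho = 1.5),
                        omission_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 1, length(conditions) >= 1,
            omission_rate >= 0, omission_rate < 1)
  if (!is.list(group_means)) {
    group_means <- setNames(rep(list(group_means), length(conditions)),
                            conditions)
  }
  stopifnot(setequal(names(group_means), conditions))
  if (any(group_sds <= 0)) stop("`group_sds` must be > 0.", call. = FALSE)
  for (cnd in conditions) {
    if (!setequal(names(group_means[[cnd]]), names(group_sds))) {
      stop("group means and sds must name the same parameters.",
           call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 group_means = group_means[conditions], group_sds = group_sds,
                 omission_rate = omission_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build a cohort spec with a drug-like directed-exploration effect
#'
#' Returns a [cohort_spec()] identical across conditions except that the
#' group-level mean of the exploration-bonus parameter \eqn{\phi} is reduced
#' in the `ldopa` condition, emulating a dopaminergic attenuation of directed
#' exploration.
#'
#' @param spec A baseline [cohort_spec()].
#' @param phi_reduction Fractional reduction of \eqn{M_\phi} under `ldopa`
#'   (0.5 halves it).
#' @return A `cohort_spec`.
#' @export
emulate_study_effect <- function(spec = cohort_spec(), phi_reduction = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"), "ldopa" %in% spec$conditions,
            is.finite(phi_reduction))
  gm <- spec$group_means
  gm[["ldopa"]]["phi"] <- gm[["ldopa"]]["phi"] * (1 - phi_reduction)
  spec$group_means <- gm
  spec
}

param_support <- function(param) {
  switch(param,
         alpha = c(0, 1),
         beta = c(0, Inf),
         c(-Inf, Inf))
}

rtnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mean, sd)
}

#' Draw subject-level parameters from the group-level distributions
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject`, `condition`, and one column per
#'   parameter.
#' @export
draw_subject_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, 3L)
  pars <- names(spec$group_sds)
  withr_seed(seeds[1L], {
    purrr::map_dfr(spec$conditions, function(cnd) {
      m <- spec$group_means[[cnd]]
      out <- tibble::tibble(subject = seq_len(spec$n_subjects),
                            condition = cnd)
      for (p in pars) {
        sup <- param_support(p)
        out[[p]] <- rtnorm(spec$n_subjects, m[[p]], spec$group_sds[[p]],
                           sup[1], sup[2])
      }
      out
    })
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws subject-level parameters, generates one payoff walk per condition
#' (identical across subjects within a condition, as with the task's fixed
#' payoff instantiations), and simulates trial-by-trial choices from the
#' cognitive model's choice probabilities.
#'
#' @param spec A [cohort_spec()].
#' @param model Generating model name (default `"bayes_smep"`).
#' @param params A [walk_params()] object for the payoff walks.
#' @param config A [session_config()] object.
#' @param learner_params A [learner_params()] object.
#' @return A tibble of class `choice_dataset` with columns `subject`,
#'   `condition`, `trial`, `choice`, `reward`, `responded`; attributes
#'   `walks` (named list of `payoff_walk`), `true_params` (tibble), `model`
#'   and `spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 2, conditions = "placebo", seed = 42)
#' d <- simulate_cohort(spec, config = session_config(n_trials = 50,
#'                                                    block_length = 25))
#' dplyr::count(d, subject)
simulate_cohort <- function(spec, model = "bayes_smep",
                            params = walk_params(),
                            config = session_config(),
                            learner_params = restlessbandit::learner_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (length(spec$conditions) == 0) stop("spec has no conditions.",
                                         call. = FALSE)
  info <- model_info(model)
  truth <- draw_subject_params(spec)
  seeds <- derive_seeds(spec$seed, 2L + length(spec$conditions))

  walks <- setNames(vector("list", length(spec$conditions)), spec$conditions)
  for (i in seq_along(spec$conditions)) {
    walks[[i]] <- generate_walk(params, config, seed = seeds[2L + i])
  }

  sim_seed <- seeds[1L]
  rows <- withr_seed(sim_seed, {
    purrr::map_dfr(seq_len(nrow(truth)), function(r) {
      tp <- truth[r, ]
      simulate_session(walks[[tp$condition]], model,
                       as.list(tp[names(spec$group_sds)]),
                       learner_params, spec$omission_rate,
                       subject = tp$subject, condition = tp$condition)
    })
  })
  structure(rows, walks = walks, true_params = truth, model = model,
            spec = spec,
            class = c("choice_dataset", class(tibble::tibble())))
}

# simulate one subject-condition session against a fixed walk
simulate_session <- function(walk, model, params, learner_params,
                             omission_rate, subject, condition) {
  info <- model_info(model)
  pv <- full_param_vector(params, model)
  cfg <- attr(walk, "config")
  nt <- cfg$n_trials
  nb <- cfg$n_bandits
  payoff <- walk_matrix(walk, "payoff")

  mu <- rep(learner_params$init_mean, nb)
  varv <- rep(learner_params$init_sd^2, nb)
  val <- rep(learner_params$v1, nb)
  lam <- learner_params$est_lambda
  prev <- NULL
  choice <- integer(nt)
  reward <- numeric(nt)
  responded <- if (omission_rate > 0) runif(nt) >= omission_rate else
    rep(TRUE, nt)

  for (t in seq_len(nt)) {
    if (responded[t]) {
      m <- if (info$learner == "bayes") mu else val
      sds <- sqrt(varv)
      p <- switch(info$choice_rule,
                  choice_prob_sm(m, pv[["beta"]]),
                  choice_prob_sme(m, sds, pv[["beta"]], pv[["phi"]]),
                  choice_prob_smep(m, sds, pv[["beta"]], pv[["phi"]],
                                   pv[["rho"]], prev),
                  choice_prob_smerp(m, sds, pv[["beta"]], pv[["phi"]],
                                    pv[["rho"]], pv[["gamma"]], prev))
      c_t <- sample.int(nb, 1L, prob = p)
      r_t <- payoff[t, c_t]
      kap <- varv[c_t] / (varv[c_t] + learner_params$est_obs_var)
      mu[c_t] <- mu[c_t] + kap * (r_t - mu[c_t])
      val[c_t] <- val[c_t] + pv[["alpha"]] * (r_t - val[c_t])
      varv[c_t] <- (1 - kap) * varv[c_t]
      choice[t] <- c_t
      reward[t] <- r_t
      prev <- c_t
    } else {
      choice[t] <- NA_integer_
      reward[t] <- NA_real_
      prev <- NULL
    }
    mu <- lam * mu + (1 - lam) * learner_params$est_center
    varv <- lam^2 * varv + learner_params$est_diff_var
  }
  tibble::tibble(subject = subject, condition = condition,
                 trial = seq_len(nt), choice = choice, reward = reward,
                 responded = responded)
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("<choice_dataset: %d subjects x %d condition(s), model %s>\n",
              dplyr::n_distinct(x$subject),
              dplyr::n_distinct(x$condition),
              attr(x, "model") %||% "?"))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a choice dataset as TSV
#'
#' The dataset TSV holds `subject`, `condition`, `trial`, `choice`,
#' `reward`, `responded`; ground-truth parameters (when present) go to a
#' companion `<path>_truth.tsv`.
#'
#' @param data A `choice_dataset` (or plain tibble with the same columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_tsv <- function(data, path) {
  write.table(as.data.frame(data), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- attr(data, "true_params")
  if (!is.null(truth)) {
    write.table(as.data.frame(truth),
                sub("\\.tsv$", "_truth.tsv", path), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  d <- tibble::as_tibble(read.delim(path))
  stopifnot(all(c("subject", "condition", "trial", "choice", "reward")
                %in% names(d)))
  if (!"responded" %in% names(d)) d$responded <- TRUE
  truth_path <- sub("\\.tsv$", "_truth.tsv", path)
  truth <- if (file.exists(truth_path))
    tibble::as_tibble(read.delim(truth_path)) else NULL
  structure(d, true_params = truth,
            class = c("choice_dataset", class(tibble::tibble())))
}

# split a dataset into named per-sequence lists, preserving order
split_sequences <- function(data) {
  data <- tibble::as_tibble(data)
  key <- paste(data$subject, data$condition, sep = ".")
  lapply(split(data, factor(key, unique(key))), check_sequence)
}
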