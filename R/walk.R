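#' Parameters of the decaying Gaussian random-walk payoff process
#'
#' The latent mean payoff of each bandit evolves as
#' \eqn{\mu_{i,t+1} = \lambda \mu_{i,t} + (1-\lambda)\vartheta + v_t} with
#' diffusion noise \eqn{v_t \sim N(0, \sigma_d^2)}; the realized payoff on a
#' trial is \eqn{r \sim N(\mu_{i,t}, \sigma_o^2)}, rounded to integer points.
#' Defaults are the task's generative values: \eqn{\lambda = 0.9836},
#' \eqn{\vartheta = 50} points, \eqn{\sigma_o = 4}, \eqn{\sigma_d = 2.8}.
#'
#' @param decay_lambda Decay parameter \eqn{\lambda}, in (0, 1).
#' @param decay_center Decay center \eqn{\vartheta} in points.
#' @param obs_sd Observation noise sd \eqn{\sigma_o} in points (> 0).
#' @param diff_sd Diffusion noise sd \eqn{\sigma_d} in points (> 0).
#' @return A list of class `walk_params`.
#' @export
#' @examples
#' walk_params()
walk_params <- function(decay_lambda = 0.9836, decay_center = 50,
                        obs_sd = 4, diff_sd = 2.8) {
  for (nm in c("decay_lambda", "decay_center", "obs_sd", "diff_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number.", call. = FALSE)
    }
  }
  if (decay_lambda <= 0 || decay_lambda >= 1) {
    stop("`decay_lambda` must lie strictly in (0, 1).", call. = FALSE)
  }
  # zero is admitted (degenerate noise) so the recursion itself can be probed
  if (obs_sd < 0) stop("`obs_sd` must be >= 0.", call. = FALSE)
  if (diff_sd < 0) stop("`diff_sd` must be >= 0.", call. = FALSE)
  structure(list(decay_lambda = decay_lambda, decay_center = decay_center,
                 obs_sd = obs_sd, diff_sd = diff_sd),
            class = "walk_params")
}

#' Session structure of the bandit task
#'
#' The default session has 300 trials split by short breaks into four blocks
#' of 75 trials, four bandits, and a payout of 5 cents per 100 points.
#'
#' @param n_trials Trials per session.
#' @param n_bandits Number of bandits.
#' @param block_length Trials per block; must divide `n_trials`.
#' @param cents_per_100_points Payout conversion (default 5).
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_trials = 300, n_bandits = 4, block_length = 75,
                           cents_per_100_points = 5) {
  stopifnot(n_trials >= 1, n_bandits >= 2, block_length >= 1)
  if (n_trials %% block_length != 0) {
    stop("`n_trials` must be divisible by `block_length`.", call. = FALSE)
  }
  structure(list(n_trials = as.integer(n_trials),
                 n_bandits = as.integer(n_bandits),
                 block_length = as.integer(block_length),
                 cents_per_100_points = cents_per_100_points),
            class = "session_config")
}

#' Stationary standard deviation of the latent-mean process
#'
#' The latent mean is an AR(1) process around the decay center with
#' stationary variance \eqn{\sigma_d^2 / (1 - \lambda^2)}.
#'
#' @param params A [walk_params()] object.
#' @return Stationary sd in points (about 15.5 at the defaults).
#' @export
stationary_sd <- function(params = walk_params()) {
  sqrt(params$diff_sd^2 / (1 - params$decay_lambda^2))
}

#' Generate a restless-bandit payoff walk
#'
#' Simulates the latent mean payoff of every bandit under the decaying
#' Gaussian random walk and realizes integer payoffs by adding observation
#' noise, rounding to the nearest point and flooring at 0. Initial latent
#' means are drawn uniformly within two stationary standard deviations of the
#' decay center unless supplied.
#'
#' @param params A [walk_params()] object.
#' @param config A [session_config()] object.
#' @param seed Integer seed; identical seeds give identical walks. Each
#'   bandit gets its own derived RNG stream, so bandits are exchangeable:
#'   permuting `bandit_seeds` permutes the walk's columns.
#' @param init_means Optional numeric vector of initial latent means, one per
#'   bandit (drawn uniformly in the two-stationary-sd band otherwise).
#' @param bandit_seeds Optional integer vector of per-bandit stream seeds
#'   (derived from `seed` by default).
#' @return A tibble of class `payoff_walk` with columns `trial`, `bandit`
#'   (both 1-based), `latent_mean` and `payoff`, carrying `params` and
#'   `config` as attributes.
#' @export
#' @examples
#' w <- generate_walk(seed = 1)
#' dplyr::filter(w, trial <= 2)
generate_walk <- function(params = walk_params(), config = session_config(),
                          seed, init_means = NULL, bandit_seeds = NULL) {
  stopifnot(inherits(params, "walk_params"),
            inherits(config, "session_config"))
  if (missing(seed) && is.null(bandit_seeds)) {
    stop("`seed` is required for reproducibility.", call. = FALSE)
  }
  nt <- config$n_trials
  nb <- config$n_bandits
  if (is.null(bandit_seeds)) bandit_seeds <- derive_seeds(seed, nb)
  stopifnot(length(bandit_seeds) == nb)

  lam <- params$decay_lambda
  th <- params$decay_center
  sd_stat <- stationary_sd(params)

  latent <- matrix(NA_real_, nt, nb)
  payoff <- matrix(NA_real_, nt, nb)
  for (i in seq_len(nb)) {
    col <- withr_seed(bandit_seeds[i], {
      mu0 <- if (is.null(init_means)) {
        runif(1, th - 2 * sd_stat, th + 2 * sd_stat)
      } else init_means[i]
      stopifnot(is.finite(mu0))
      dn <- rnorm(nt, 0, params$diff_sd)
      on <- rnorm(nt, 0, params$obs_sd)
      mu <- numeric(nt)
      m <- mu0
      for (t in seq_len(nt)) {
        mu[t] <- m
        m <- lam * m + (1 - lam) * th + dn[t]
      }
      list(mu = mu, pay = pmax(0, round(mu + on)))
    })
    latent[, i] <- col$mu
    payoff[, i] <- col$pay
  }

  out <- tibble::tibble(
    trial = rep(seq_len(nt), times = nb),
    bandit = rep(seq_len(nb), each = nt),
    latent_mean = as.vector(latent),
    payoff = as.integer(payoff)
  )
  new_payoff_walk(out, params = params, config = config)
}

new_payoff_walk <- function(tbl, params, config) {
  structure(tbl, params = params, config = config,
            class = c("payoff_walk", class(tibble::tibble())))
}

#' @export
print.payoff_walk <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<payoff_walk: %d trials x %d bandits>\n",
              cfg$n_trials, cfg$n_bandits))
  NextMethod()
}

# trial x bandit matrices, used internally
walk_matrix <- function(walk, what = c("latent_mean", "payoff")) {
  what <- match.arg(what)
  cfg <- attr(walk, "config")
  matrix(walk[[what]], nrow = cfg$n_trials, ncol = cfg$n_bandits)
}

#' Look up a realized payoff
#'
#' @param walk A `payoff_walk`.
#' @param trial,bandit 1-based indices.
#' @return The stored integer payoff.
#' @export
sample_payoff <- function(walk, trial, bandit) {
  cfg <- attr(walk, "config")
  if (trial < 1 || trial > cfg$n_trials) {
    stop("`trial` out of range [1, ", cfg$n_trials, "].", call. = FALSE)
  }
  if (bandit < 1 || bandit > cfg$n_bandits) {
    stop("`bandit` out of range [1, ", cfg$n_bandits, "].", call. = FALSE)
  }
  walk$payoff[(bandit - 1L) * cfg$n_trials + trial]
}

#' Convert task points to payout in cents
#'
#' 100 points convert to 5 cents; cents are rounded half up.
#'
#' @param points Non-negative points earned.
#' @param cents_per_100_points Conversion rate.
#' @return Payout in whole cents.
#' @export
#' @examples
#' points_to_payout(100) # 5
points_to_payout <- function(points, cents_per_100_points = 5) {
  stopifnot(all(points >= 0))
  floor(points * cents_per_100_points / 100 + 0.5)
}

#' Write / read a payoff walk as TSV
#'
#' Columns: trial, bandit (1-based), latent_mean, payoff.
#'
#' @param walk A `payoff_walk`.
#' @param path File path.
#' @return `write_walk_tsv` returns `path` invisibly; `read_walk_tsv`
#'   returns a `payoff_walk` (with the default parameter attributes unless
#'   supplied).
#' @export
write_walk_tsv <- function(walk, path) {
  write.table(as.data.frame(walk), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_walk_tsv
#' @param params,config Attributes to attach on read.
#' @export
read_walk_tsv <- function(path, params = walk_params(), config = NULL) {
  d <- tibble::as_tibble(read.delim(path))
  stopifnot(all(c("trial", "bandit", "latent_mean", "payoff") %in% names(d)))
  nb <- max(d$bandit)
  nt <- max(d$trial)
  if (is.null(config)) {
    bl <- if (nt %% 75L == 0L) 75L else nt
    config <- session_config(n_trials = nt, n_bandits = nb, block_length = bl)
  }
  d <- dplyr::arrange(d, .data$bandit, .data$trial)
  new_payoff_walk(d, params = params, config = config)
}

# run expr under a local RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# one master seed -> n independent sub-stream seeds (all < 2^31)
derive_seeds <- function(seed, n) {
  withr_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Plot a payoff walk
#'
#' Latent mean trajectories (lines) with realized payoffs (points) per bandit.
#'
#' @param object A `payoff_walk`.
#' @param show_payoffs Overlay realized payoffs?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.payoff_walk <- function(object, show_payoffs = TRUE, ...) {
  d <- tibble::as_tibble(object)
  d$bandit <- factor(d$bandit)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$trial, y = .data$latent_mean,
                                       colour = .data$bandit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial", y = "Points", colour = "Bandit")
  if (show_payoffs) {
    p <- p + ggplot2::geom_point(ggplot2::aes(y = .data$payoff),
                                 alpha = 0.3, size = 0.6)
  }
  p
}
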