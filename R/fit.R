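#' Priors of the hierarchical model
#'
#' Group-level means get uniform priors within parameter-specific bounds;
#' group-level standard deviations get half-Cauchy(0, scale) priors;
#' subject-level parameters are normal \eqn{N(M_x, \Lambda_x)}, truncated to
#' the parameter's support (\eqn{\alpha \in [0,1]}, \eqn{\beta \ge 0};
#' \eqn{\phi, \rho, \gamma} unbounded).
#'
#' @param bounds Named list of `c(lower, upper)` uniform bounds for the
#'   group-level means.
#' @param hcauchy_scale Scale of the half-Cauchy prior on group sds.
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(bounds = list(alpha = c(0, 1), beta = c(0, 3),
                                     phi = c(-10, 10), rho = c(-15, 15),
                                     gamma = c(-10, 10)),
                       hcauchy_scale = 1) {
  for (p in names(bounds)) {
    b <- bounds[[p]]
    if (length(b) != 2 || b[1] >= b[2]) {
      stop("bounds for `", p, "` must be c(lower, upper) with lower < upper.",
           call. = FALSE)
    }
  }
  stopifnot(hcauchy_scale > 0)
  structure(list(bounds = bounds, hcauchy_scale = hcauchy_scale),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' Defaults mirror the study's sampling contract: four chains, 1000 warmup
#' and 1000 retained iterations each, no thinning. [ci_profile()] is the
#' reduced profile used by the test suite (2 chains, 250/250).
#'
#' @param n_chains,n_warmup,n_samples Counts (all >= 1).
#' @param seed Integer seed controlling all chains.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_warmup = 1000, n_samples = 1000,
                           seed = 1L) {
  stopifnot(n_chains >= 1, n_warmup >= 1, n_samples >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' @rdname sampler_config
#' @export
ci_profile <- function(seed = 1L) {
  sampler_config(n_chains = 2, n_warmup = 250, n_samples = 250, seed = seed)
}

ldtnorm <- function(x, m, s, lo, hi) {
  z <- pnorm(hi, m, s) - pnorm(lo, m, s)
  dnorm(x, m, s, log = TRUE) - log(pmax(z, 1e-300))
}

ldhalfcauchy <- function(x, scale) {
  ifelse(x > 0, dcauchy(x, 0, scale, log = TRUE) + log(2), -Inf)
}

#' Fit the hierarchical model
#'
#' Estimates posterior distributions of the model's free parameters for every
#' subject and condition. Each condition is fitted as an independent
#' hierarchical model: subject-level parameters are drawn from
#' condition-specific group normals \eqn{N(M_x, \Lambda_x)} with a uniform
#' prior on each \eqn{M_x} and a half-Cauchy(0, 1) prior on each
#' \eqn{\Lambda_x}. Sampling uses adaptive Metropolis-within-Gibbs
#' (random-walk proposals with diminishing adaptation during warmup only);
#' chains are initialized from per-subject penalized maximum-likelihood
#' estimates. Missed trials contribute nothing to the likelihood.
#'
#' Pointwise log-likelihoods (one unit = one subject under one condition,
#' compounded over trials) are stored for model comparison with
#' [psis_loo()]. Convergence is summarized by split-R-hat and effective
#' sample size; the fit carries a `converged` flag and warns (never fails
#' silently) when any group-level split-R-hat exceeds 1.1.
#'
#' @param data A `choice_dataset` or tibble with columns `subject`,
#'   `condition`, `trial`, `choice`, `reward`, optionally `responded`.
#' @param model Model name from [model_registry()].
#' @param priors A [prior_spec()].
#' @param sampler A [sampler_config()].
#' @param learner_params A [learner_params()].
#' @return An object of class `bandit_fit`.
#' @export
fit_hierarchical <- function(data, model = "bayes_smep",
                             priors = prior_spec(),
                             sampler = sampler_config(),
                             learner_params = restlessbandit::learner_params()) {
  info <- model_info(model)
  free <- info$free_params[[1]]
  data <- tibble::as_tibble(data)
  conditions <- unique(data$condition)
  cond_seeds <- derive_seeds(sampler$seed, length(conditions))

  fits <- purrr::map2(conditions, cond_seeds, function(cnd, cseed) {
    d <- dplyr::filter(data, .data$condition == cnd)
    sample_condition(d, model, free, priors, sampler, learner_params, cseed)
  })
  names(fits) <- conditions

  diag <- purrr::map_dfr(conditions, function(cnd) {
    f <- fits[[cnd]]
    purrr::map_dfr(seq_along(free), function(j) {
      tibble::tibble(
        condition = cnd,
        parameter = c(paste0("M_", free[j]), paste0("Lambda_", free[j])),
        rhat = c(split_rhat(f$M[, , j]), split_rhat(f$Lambda[, , j])),
        ess = c(ess_bulk(f$M[, , j]), ess_bulk(f$Lambda[, , j]))
      )
    })
  })
  converged <- all(diag$rhat <= 1.1, na.rm = TRUE)
  if (!converged) {
    warning("split-R-hat above 1.1 for some group-level parameters; ",
            "treat posterior summaries with caution.", call. = FALSE)
  }

  structure(list(model = model, free_params = free, conditions = conditions,
                 fits = fits, diagnostics = diag, converged = converged,
                 priors = priors, sampler = sampler,
                 learner_params = learner_params,
                 divergences = NA_integer_),
            class = "bandit_fit")
}

# fit one condition; returns arrays of draws
sample_condition <- function(d, model, free, priors, sampler, lp, seed) {
  seqs <- split_sequences(d)
  subjects <- vapply(seqs, function(s) s$subject[1], numeric(1))
  S <- length(seqs)
  P <- length(free)
  info <- model_info(model)
  learner_code <- if (info$learner == "bayes") 0L else 1L
  rule <- info$choice_rule
  n_resp <- vapply(seqs, function(s) sum(s$responded), numeric(1))

  loglik_s <- function(s, x) {
    pv <- c(alpha = 0, beta = 0, phi = 0, rho = 0, gamma = 0)
    pv[free] <- x
    r <- .filter_cpp(as.integer(seqs[[s]]$choice),
                     as.numeric(seqs[[s]]$reward), seqs[[s]]$responded,
                     learner_code, rule, pv[["alpha"]], pv[["beta"]],
                     pv[["phi"]], pv[["rho"]], pv[["gamma"]],
                     lp$est_lambda, lp$est_center, lp$est_obs_var,
                     lp$est_diff_var, lp$init_mean, lp$init_sd^2, lp$v1,
                     FALSE)
    r$loglik
  }

  lo_b <- vapply(free, function(p) priors$bounds[[p]][1], numeric(1))
  hi_b <- vapply(free, function(p) priors$bounds[[p]][2], numeric(1))
  lo_s <- vapply(free, function(p) param_support(p)[1], numeric(1))
  hi_s <- vapply(free, function(p) param_support(p)[2], numeric(1))

  n_chain <- sampler$n_chains
  n_warm <- sampler$n_warmup
  n_keep <- sampler$n_samples
  chain_seeds <- derive_seeds(seed, n_chain + 1L)

  # chain initialization from penalized ML point estimates
  map_est <- withr_seed(chain_seeds[n_chain + 1L], {
    est <- vapply(seq_len(S), function(s) {
      map_optim(function(x) loglik_s(s, x), free, lo_s, hi_s, lo_b, hi_b)$par
    }, numeric(P))
    if (P == 1L) matrix(est, ncol = 1L) else t(est)
  })

  M_arr <- array(NA_real_, c(n_keep, n_chain, P))
  L_arr <- array(NA_real_, c(n_keep, n_chain, P))
  X_arr <- array(NA_real_, c(n_keep, n_chain, S, P))
  ll_arr <- array(NA_real_, c(n_keep, n_chain, S))

  for (ch in seq_len(n_chain)) {
    res <- withr_seed(chain_seeds[ch], {
      run_mwg_chain(map_est, loglik_s, free, lo_b, hi_b, lo_s, hi_s,
                    priors$hcauchy_scale, n_warm, n_keep)
    })
    M_arr[, ch, ] <- res$M
    L_arr[, ch, ] <- res$L
    X_arr[, ch, , ] <- res$X
    ll_arr[, ch, ] <- res$ll
  }
  dimnames(M_arr)[[3]] <- free
  dimnames(L_arr)[[3]] <- free
  dimnames(X_arr)[[4]] <- free
  list(M = M_arr, Lambda = L_arr, X = X_arr, ll = ll_arr,
       subjects = subjects, n_resp = n_resp)
}

# one adaptive Metropolis-within-Gibbs chain
run_mwg_chain <- function(map_est, loglik_s, free, lo_b, hi_b, lo_s, hi_s,
                          hc_scale, n_warm, n_keep) {
  S <- nrow(map_est)
  P <- ncol(map_est)
  # jittered init, clamped to group-mean bounds and subject support
  X <- map_est + matrix(rnorm(S * P, 0, 0.05), S, P)
  for (j in seq_len(P)) {
    X[, j] <- pmin(pmax(X[, j], lo_s[j] + 1e-6),
                   ifelse(is.finite(hi_s[j]), hi_s[j] - 1e-6, Inf))
  }
  M <- pmin(pmax(colMeans(X), lo_b + 1e-3), hi_b - 1e-3)
  L <- pmax(apply(X, 2, sd), 0.05)
  ll <- vapply(seq_len(S), function(s) loglik_s(s, X[s, ]), numeric(1))

  sX <- matrix(rep(pmax(L, 0.1) / 2, each = S), S, P)
  sM <- pmax(L, 0.1) / 2
  sL <- rep(0.3, P)
  accX <- matrix(0, S, P); accM <- numeric(P); accL <- numeric(P)
  batch <- 25L; n_batch <- 0L

  M_out <- matrix(NA_real_, n_keep, P)
  L_out <- matrix(NA_real_, n_keep, P)
  X_out <- array(NA_real_, c(n_keep, S, P))
  ll_out <- matrix(NA_real_, n_keep, S)

  total <- n_warm + n_keep
  for (it in seq_len(total)) {
    # subject-level updates
    for (s in seq_len(S)) {
      for (j in seq_len(P)) {
        prop <- X[s, j] + rnorm(1, 0, sX[s, j])
        if (prop <= lo_s[j] || prop >= hi_s[j]) next
        xs <- X[s, ]; xs[j] <- prop
        ll_new <- loglik_s(s, xs)
        d <- (ll_new - ll[s]) +
          ldtnorm(prop, M[j], L[j], lo_s[j], hi_s[j]) -
          ldtnorm(X[s, j], M[j], L[j], lo_s[j], hi_s[j])
        if (is.finite(d) && log(runif(1)) < d) {
          X[s, j] <- prop; ll[s] <- ll_new; accX[s, j] <- accX[s, j] + 1
        }
      }
    }
    # group-level updates touch no data likelihood, so sweep them several
    # times per iteration to decorrelate (M, Lambda) given X
    for (sweep in 1:10) {
      for (j in seq_len(P)) {
        prop <- M[j] + rnorm(1, 0, sM[j])
        if (prop > lo_b[j] && prop < hi_b[j]) {
          d <- sum(ldtnorm(X[, j], prop, L[j], lo_s[j], hi_s[j])) -
            sum(ldtnorm(X[, j], M[j], L[j], lo_s[j], hi_s[j]))
          if (is.finite(d) && log(runif(1)) < d) {
            M[j] <- prop; accM[j] <- accM[j] + 1
          }
        }
        # group-level sd on the log scale (with Jacobian)
        propL <- L[j] * exp(rnorm(1, 0, sL[j]))
        d <- ldhalfcauchy(propL, hc_scale) - ldhalfcauchy(L[j], hc_scale) +
          sum(ldtnorm(X[, j], M[j], propL, lo_s[j], hi_s[j])) -
          sum(ldtnorm(X[, j], M[j], L[j], lo_s[j], hi_s[j])) +
          log(propL) - log(L[j])
        if (is.finite(d) && log(runif(1)) < d) {
          L[j] <- propL; accL[j] <- accL[j] + 1
        }
      }
    }
    # diminishing adaptation during warmup
    if (it <= n_warm && it %% batch == 0L) {
      n_batch <- n_batch + 1L
      step <- min(0.25, n_batch^-0.5)
      sX <- sX * exp(ifelse(accX / batch > 0.44, step, -step))
      sM <- sM * exp(ifelse(accM / (10 * batch) > 0.44, step, -step))
      sL <- sL * exp(ifelse(accL / (10 * batch) > 0.44, step, -step))
      accX[] <- 0; accM[] <- 0; accL[] <- 0
    }
    if (it > n_warm) {
      k <- it - n_warm
      M_out[k, ] <- M; L_out[k, ] <- L
      X_out[k, , ] <- X; ll_out[k, ] <- ll
    }
  }
  list(M = M_out, L = L_out, X = X_out, ll = ll_out)
}

# penalized ML for one subject: weak N(0, 10^2) ridge on each parameter,
# optimized within the intersection of support and group-mean bounds
map_optim <- function(ll_fun, free, lo_s, hi_s, lo_b, hi_b) {
  lo <- pmax(lo_s, lo_b) + 1e-4
  hi <- pmin(hi_s, hi_b) - 1e-4
  start <- setNames(pmin(pmax(c(alpha = 0.3, beta = 0.3, phi = 0.5,
                                rho = 0.5, gamma = 0)[free], lo), hi), free)
  obj <- function(x) -ll_fun(x) + sum((x / 10)^2) / 2
  fit <- tryCatch(
    optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi),
    error = function(e) list(par = start, value = obj(start),
                             convergence = 1L)
  )
  bound_hit <- any(abs(fit$par - lo) < 1e-3 | abs(fit$par - hi) < 1e-3)
  list(par = fit$par, value = -fit$value, bound_hit = bound_hit,
       convergence = fit$convergence)
}

#' Per-subject penalized maximum-likelihood estimates
#'
#' A fast non-hierarchical fallback (L-BFGS-B with a weak normal penalty) for
#' smoke tests and chain initialization; never a substitute for the
#' hierarchical posterior in headline contrasts.
#'
#' @inheritParams fit_hierarchical
#' @return A tibble with one row per subject x condition: parameter
#'   estimates, `loglik` at the optimum, and a `bound_hit` flag.
#' @export
fit_subject_map <- function(data, model = "bayes_smep",
                            priors = prior_spec(),
                            learner_params = restlessbandit::learner_params()) {
  info <- model_info(model)
  free <- info$free_params[[1]]
  seqs <- split_sequences(tibble::as_tibble(data))
  lo_b <- vapply(free, function(p) priors$bounds[[p]][1], numeric(1))
  hi_b <- vapply(free, function(p) priors$bounds[[p]][2], numeric(1))
  lo_s <- vapply(free, function(p) param_support(p)[1], numeric(1))
  hi_s <- vapply(free, function(p) param_support(p)[2], numeric(1))
  learner_code <- if (info$learner == "bayes") 0L else 1L
  purrr::map_dfr(seqs, function(sq) {
    ch <- as.integer(sq$choice); rw <- as.numeric(sq$reward)
    rs <- sq$responded
    est <- map_optim(function(x) {
      pv <- c(alpha = 0, beta = 0, phi = 0, rho = 0, gamma = 0)
      pv[free] <- x
      .filter_cpp(ch, rw, rs, learner_code, info$choice_rule,
                  pv[["alpha"]], pv[["beta"]], pv[["phi"]], pv[["rho"]],
                  pv[["gamma"]], learner_params$est_lambda,
                  learner_params$est_center, learner_params$est_obs_var,
                  learner_params$est_diff_var, learner_params$init_mean,
                  learner_params$init_sd^2, learner_params$v1,
                  FALSE)$loglik
    }, free, lo_s, hi_s, lo_b, hi_b)
    out <- tibble::tibble(subject = sq$subject[1],
                          condition = sq$condition[1])
    for (j in seq_along(free)) out[[free[j]]] <- est$par[[j]]
    out$loglik <- est$value
    out$bound_hit <- est$bound_hit
    out
  })
}

#' Extract posterior draws as a tidy tibble
#'
#' @param fit A `bandit_fit`.
#' @param level `"group"` for \eqn{M_x} and \eqn{\Lambda_x}, `"subject"` for
#'   subject-level parameters.
#' @return A tibble with columns `chain`, `draw`, `condition`, `parameter`
#'   (plus `subject` at subject level) and `value`.
#' @export
posterior_draws <- function(fit, level = c("group", "subject")) {
  level <- match.arg(level)
  stopifnot(inherits(fit, "bandit_fit"))
  purrr::map_dfr(fit$conditions, function(cnd) {
    f <- fit$fits[[cnd]]
    n_keep <- dim(f$M)[1]
    n_chain <- dim(f$M)[2]
    if (level == "group") {
      purrr::map_dfr(fit$free_params, function(p) {
        tibble::tibble(
          chain = rep(rep(seq_len(n_chain), each = n_keep), 2),
          draw = rep(rep(seq_len(n_keep), n_chain), 2),
          condition = cnd,
          parameter = rep(c(paste0("M_", p), paste0("Lambda_", p)),
                          each = n_keep * n_chain),
          value = c(as.vector(f$M[, , p]), as.vector(f$Lambda[, , p]))
        )
      })
    } else {
      purrr::map_dfr(fit$free_params, function(p) {
        purrr::map_dfr(seq_along(f$subjects), function(s) {
          tibble::tibble(
            chain = rep(seq_len(n_chain), each = n_keep),
            draw = rep(seq_len(n_keep), n_chain),
            condition = cnd, subject = f$subjects[s], parameter = p,
            value = as.vector(f$X[, , s, p])
          )
        })
      })
    }
  })
}

# flattened draws of one group-level quantity in one condition
group_draws <- function(fit, parameter, condition, what = c("M", "Lambda")) {
  what <- match.arg(what)
  stopifnot(parameter %in% fit$free_params,
            condition %in% fit$conditions)
  as.vector(fit$fits[[condition]][[what]][, , parameter])
}

#' Highest density interval
#'
#' Shortest interval containing a given posterior mass, computed by the
#' sorted-sample sliding-window method.
#'
#' @param x Numeric draws.
#' @param mass Probability mass in (0, 1\].
#' @return Named vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.90) {
  stopifnot(mass > 0, mass <= 1, length(x) >= 2)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Posterior contrast of a group-level mean between conditions
#'
#' Computes the highest density interval of the draw-wise difference
#' \eqn{M_x(a) - M_x(b)} between two independently fitted conditions and
#' flags whether zero lies outside it (the study's criterion for a credible
#' drug effect, at 90% mass).
#'
#' @param fit A `bandit_fit` covering both conditions.
#' @param parameter Free parameter name (e.g. `"phi"`).
#' @param cond_a,cond_b Condition labels.
#' @param mass HDI mass (default 0.90).
#' @return A one-row tibble with the interval, the posterior median
#'   difference, and `excludes_zero`.
#' @export
condition_contrast_hdi <- function(fit, parameter, cond_a, cond_b,
                                   mass = 0.90) {
  da <- group_draws(fit, parameter, cond_a)
  db <- group_draws(fit, parameter, cond_b)
  stopifnot(length(da) == length(db))
  diff <- da - db
  h <- hdi(diff, mass)
  tibble::tibble(parameter = parameter, cond_a = cond_a, cond_b = cond_b,
                 mass = mass, lower = h[["lower"]], upper = h[["upper"]],
                 median = median(diff),
                 excludes_zero = h[["lower"]] > 0 | h[["upper"]] < 0)
}

# --- convergence diagnostics -------------------------------------------------

# split-R-hat (Gelman et al.): draws is an iterations x chains matrix
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# bulk effective sample size via Geyer initial positive sequence
ess_bulk <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  ac <- sapply(seq_len(m), function(ch) {
    x <- draws[, ch] - mean(draws[, ch])
    v <- sum(x^2)
    if (v == 0) return(rep(0, n))
    a <- stats::acf(draws[, ch], lag.max = n - 1, plot = FALSE,
                    demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- rowMeans(ac)
  # sum consecutive pairs while positive
  tau <- 1
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2
  }
  max(1, n * m / tau)
}

# --- methods -----------------------------------------------------------------

#' @export
print.bandit_fit <- function(x, ...) {
  cat(sprintf("<bandit_fit: model %s, %d condition(s), %d chains x %d draws>\n",
              x$model, length(x$conditions), x$sampler$n_chains,
              x$sampler$n_samples))
  cat(if (x$converged) "converged (all group-level split-R-hat <= 1.1)\n"
      else "WARNING: convergence not reached\n")
  invisible(x)
}

#' Tidy posterior summary of a hierarchical fit
#'
#' @param x A `bandit_fit`.
#' @param level `"group"` or `"subject"`.
#' @param mass Central-interval mass for the reported bounds.
#' @param ... Unused.
#' @return A tibble with posterior median, mean, and central interval per
#'   parameter (and subject, at subject level) and condition.
#' @export
tidy.bandit_fit <- function(x, level = c("group", "subject"), mass = 0.95,
                            ...) {
  level <- match.arg(level)
  d <- posterior_draws(x, level)
  grp <- if (level == "group") c("condition", "parameter") else
    c("condition", "subject", "parameter")
  alpha <- (1 - mass) / 2
  dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(grp))),
    estimate = median(.data$value), mean = mean(.data$value),
    conf.low = quantile(.data$value, alpha),
    conf.high = quantile(.data$value, 1 - alpha), .groups = "drop")
}

#' One-row fit summary
#'
#' @param x A `bandit_fit`.
#' @param ... Unused.
#' @return A tibble with the model, sampling dimensions, worst split-R-hat,
#'   smallest ESS, divergence count (NA: not an HMC sampler) and the
#'   convergence flag.
#' @export
glance.bandit_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 n_conditions = length(x$conditions),
                 n_chains = x$sampler$n_chains,
                 n_draws = x$sampler$n_samples,
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE),
                 divergences = x$divergences,
                 converged = x$converged)
}

#' Plot group-level posterior distributions
#'
#' Density of each group-level mean \eqn{M_x} per condition, one facet per
#' parameter.
#'
#' @param object A `bandit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bandit_fit <- function(object, ...) {
  d <- posterior_draws(object, "group")
  d <- dplyr::filter(d, startsWith(.data$parameter, "M_"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "Group-level mean", y = "Posterior density",
                  colour = "Condition")
}

#' Export posterior draws and diagnostics as TSV
#'
#' @param fit A `bandit_fit`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fit_tsv <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(posterior_draws(fit, "group")),
              file.path(dir, "draws_group.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(posterior_draws(fit, "subject")),
              file.path(dir, "draws_subject.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(fit$diagnostics),
              file.path(dir, "diagnostics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
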