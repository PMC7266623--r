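#' Pointwise log-likelihood matrix of a fit
#'
#' One unit is the data of one subject under one condition, compounded over
#' its trials; entries are the unit's log-likelihood evaluated at each stored
#' posterior draw of the subject-level parameters.
#'
#' @param fit A `bandit_fit`.
#' @return A draws x units matrix of class `pointwise_loglik` with unit
#'   metadata (`units` tibble with `subject`, `condition`, `n_trials`)
#'   attached.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "bandit_fit"))
  mats <- list()
  units <- list()
  for (cnd in fit$conditions) {
    f <- fit$fits[[cnd]]
    n_keep <- dim(f$ll)[1]
    n_chain <- dim(f$ll)[2]
    S <- dim(f$ll)[3]
    m <- matrix(f$ll, n_keep * n_chain, S)
    mats[[cnd]] <- m
    units[[cnd]] <- tibble::tibble(subject = f$subjects, condition = cnd,
                                   n_trials = f$n_resp)
  }
  out <- do.call(cbind, mats)
  structure(out, units = dplyr::bind_rows(units),
            class = c("pointwise_loglik", "matrix", "array"))
}

# Zhang & Stephens (2009) estimator for the generalized Pareto distribution,
# fitted to exceedances x > 0. Internally uses their (k, sigma) convention;
# returns the modern shape xi = -k_ZS (positive xi = heavy tail, the "Pareto
# k" of PSIS diagnostics) and the common scale sigma.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) return(list(k = Inf, sigma = NA_real_))
  prior_bs <- 3
  m <- 30 + floor(sqrt(n))
  bs <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) /
    (prior_bs * x[floor(n / 4 + 0.5)])
  ks <- vapply(bs, function(b) -mean(log1p(-b * x)), numeric(1))
  ls <- n * (log(bs / ks) + ks - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(ls - ls[j])), numeric(1))
  b <- sum(bs * w)
  xi <- mean(log1p(-b * x))
  list(k = xi, sigma = -xi / b)
}

# inverse CDF of the generalized Pareto with location 0
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance weights for one unit's raw log-weights
psis_smooth <- function(lw) {
  n <- length(lw)
  lw <- lw - max(lw)
  ntail <- max(5L, ceiling(0.2 * n)) # largest 20% of ratios
  ord <- order(lw)
  tail_ids <- ord[(n - ntail + 1):n]
  cutpoint <- lw[ord[n - ntail]]
  exc <- exp(lw[tail_ids]) - exp(cutpoint)
  if (all(exc == 0)) return(list(lw = lw - logsumexp(lw), k = 0))
  fit <- gpd_fit(exc[exc > 0])
  k <- fit$k
  if (is.finite(k) && is.finite(fit$sigma) && fit$sigma > 0) {
    p <- (seq_len(ntail) - 0.5) / ntail
    smoothed <- log(qgpd(p, k, fit$sigma) + exp(cutpoint))
    smoothed <- pmin(smoothed, 0) # cap at the largest raw weight (max lw = 0)
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  list(lw = lw - logsumexp(lw), k = k)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO estimate of out-of-sample predictive accuracy
#'
#' Approximate leave-one-out cross-validation by Pareto-smoothed importance
#' sampling: for each unit the importance ratios (reciprocal pointwise
#' likelihoods) are tail-smoothed with a generalized Pareto fit to the
#' largest 20% of ratios, and the unit's expected log predictive density is
#' the smoothed-weight average of its likelihood. Units with Pareto k above
#' 0.7 are flagged as unreliable.
#'
#' @param pll A `pointwise_loglik` matrix (draws x units), e.g. from
#'   [pointwise_loglik()].
#' @return An object of class `bandit_loo`: per-unit tibble (`elpd`,
#'   `pareto_k`), `elpd_total`, `elpd_normalized` (per data point, when trial
#'   counts are known), and `se` of the total.
#' @export
psis_loo <- function(pll) {
  m <- as.matrix(pll)
  if (nrow(m) < 2) stop("need at least 2 posterior draws.", call. = FALSE)
  if (any(!is.finite(m))) stop("pointwise log-likelihood must be finite.",
                               call. = FALSE)
  if (all(apply(m, 2, function(x) max(x) - min(x)) < 1e-12)) {
    # degenerate posterior: all draws identical; LOO equals plain log-lik
    elpd_i <- m[1, ]
    k_i <- rep(0, ncol(m))
  } else {
    res <- lapply(seq_len(ncol(m)), function(i) {
      sm <- psis_smooth(-m[, i])
      list(elpd = logsumexp(sm$lw + m[, i]), k = sm$k)
    })
    elpd_i <- vapply(res, `[[`, numeric(1), "elpd")
    k_i <- vapply(res, `[[`, numeric(1), "k")
  }
  units <- attr(pll, "units")
  per_unit <- tibble::tibble(unit = seq_along(elpd_i), elpd = elpd_i,
                             pareto_k = k_i)
  n_points <- NA_real_
  if (!is.null(units)) {
    per_unit <- dplyr::bind_cols(units, per_unit["elpd"],
                                 per_unit["pareto_k"])
    n_points <- sum(units$n_trials)
  }
  total <- sum(elpd_i)
  structure(list(per_unit = per_unit, elpd_total = total,
                 se = sqrt(length(elpd_i) * var(elpd_i)),
                 n_units = length(elpd_i), n_points = n_points,
                 elpd_normalized = if (is.na(n_points)) NA_real_ else
                   total / n_points,
                 worst_pareto_k = max(k_i)),
            class = "bandit_loo")
}

#' @export
print.bandit_loo <- function(x, ...) {
  cat(sprintf("<bandit_loo: elpd %.2f (se %.2f) over %d units%s>\n",
              x$elpd_total, x$se, x$n_units,
              if (is.na(x$elpd_normalized)) "" else
                sprintf(", %.4f per data point", x$elpd_normalized)))
  if (x$worst_pareto_k > 0.7) {
    cat("note: some Pareto k > 0.7; estimates may be unreliable\n")
  }
  invisible(x)
}

#' Compare models by PSIS-LOO
#'
#' Ranks models fitted to the same data by normalized LOO log-likelihood
#' (per data point, as in the study's comparison figure; the ranking is
#' invariant to this linear rescaling). Pairwise differences to the best
#' model carry standard errors computed from the per-unit contributions.
#'
#' @param loos Named list of `bandit_loo` objects on identical data.
#' @return A tibble sorted best-first with columns `model`, `loo_total`,
#'   `loo_normalized`, `se`, `delta_to_best`, `delta_se`, `worst_pareto_k`.
#' @export
compare_models <- function(loos) {
  stopifnot(is.list(loos), length(loos) >= 1, !is.null(names(loos)))
  n_units <- vapply(loos, function(l) l$n_units, numeric(1))
  if (length(unique(n_units)) != 1) {
    stop("all models must be evaluated on the same units.", call. = FALSE)
  }
  tab <- purrr::map_dfr(names(loos), function(nm) {
    l <- loos[[nm]]
    tibble::tibble(model = nm, loo_total = l$elpd_total,
                   loo_normalized = l$elpd_normalized, se = l$se,
                   worst_pareto_k = l$worst_pareto_k)
  })
  tab <- dplyr::arrange(tab, dplyr::desc(.data$loo_total))
  best <- loos[[tab$model[1]]]
  tab$delta_to_best <- tab$loo_total - best$elpd_total
  tab$delta_se <- vapply(tab$model, function(nm) {
    d <- loos[[nm]]$per_unit$elpd - best$per_unit$elpd
    sqrt(length(d) * var(d))
  }, numeric(1))
  dplyr::select(tab, "model", "loo_total", "loo_normalized", "se",
                "delta_to_best", "delta_se", "worst_pareto_k")
}

#' Write a model-comparison table as TSV
#'
#' @param table Output of [compare_models()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
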