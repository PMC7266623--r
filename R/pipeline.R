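#' Read a declarative run configuration
#'
#' Plain `key: value` text, one pair per line; `#` starts a comment. Values
#' are parsed as numbers where possible, comma-separated lists become
#' vectors. Unknown keys are rejected by [run_pipeline()] before any compute.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln, call. = FALSE)
    val <- trimws(strsplit(m[3], ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!anyNA(num)) num else val
  }
  out
}

pipeline_defaults <- function() {
  list(input = "simulate", model = "bayes_smep", n_subjects = 31,
       conditions = c("placebo", "ldopa", "haloperidol"),
       phi_reduction = 0.5, n_trials = 300, block_length = 75,
       n_chains = 4, n_warmup = 1000, n_samples = 1000,
       seed = 1, out_dir = "bandit_run", log_level = "info")
}

#' Run the full simulate / fit / compare / classify pipeline
#'
#' Orchestrates the package end to end: simulate a synthetic cohort (or load
#' a dataset TSV), fit the requested cognitive model(s) hierarchically,
#' compare models by PSIS-LOO when more than one is fitted, classify trials
#' and export regressors and behavioural summaries. Every run writes the
#' resolved configuration, a seed manifest, and a log file to the output
#' directory; reruns with the same config and seed reproduce the dataset
#' files exactly.
#'
#' @param config Named list (see `pipeline_defaults` keys: `input`
#'   (`"simulate"` or a dataset TSV path), `model` (a model name or
#'   `"all8"`), `n_subjects`, `conditions`, `phi_reduction`, `n_trials`,
#'   `block_length`, `n_chains`, `n_warmup`, `n_samples`, `seed`, `out_dir`,
#'   `log_level`) or the path to a `key: value` config file readable by
#'   [read_run_config()].
#' @return The output directory path, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (identical(cfg$log_level, "info")) message(msg)
  }
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(v) paste(v, collapse = ", "),
                           character(1))),
             file.path(cfg$out_dir, "config_resolved.txt"))

  seeds <- derive_seeds(as.integer(cfg$seed), 3L)
  writeLines(paste0(c("master", "cohort", "sampler"), ": ",
                    c(cfg$seed, seeds[1], seeds[2])),
             file.path(cfg$out_dir, "seed_manifest.txt"))

  # stage 1: data
  if (identical(cfg$input, "simulate")) {
    logf("simulating cohort: %d subjects, %d conditions",
         cfg$n_subjects, length(cfg$conditions))
    spec <- cohort_spec(n_subjects = cfg$n_subjects,
                        conditions = cfg$conditions, seed = seeds[1])
    if ("ldopa" %in% cfg$conditions && cfg$phi_reduction != 0) {
      spec <- emulate_study_effect(spec, cfg$phi_reduction)
    }
    data <- simulate_cohort(spec, model = if (identical(cfg$model, "all8"))
      "bayes_smep" else cfg$model,
      config = session_config(n_trials = cfg$n_trials,
                              block_length = cfg$block_length))
    write_dataset_tsv(data, file.path(cfg$out_dir, "dataset.tsv"))
    for (cnd in names(attr(data, "walks"))) {
      write_walk_tsv(attr(data, "walks")[[cnd]],
                     file.path(cfg$out_dir, paste0("walk_", cnd, ".tsv")))
    }
  } else {
    logf("loading dataset from %s", cfg$input)
    data <- read_dataset_tsv(cfg$input)
    rep <- validate_dataset(data)
    if (nrow(rep)) {
      stop("input dataset failed validation; see validate_dataset().",
           call. = FALSE)
    }
  }

  # stage 2: fit
  models <- if (identical(cfg$model, "all8")) model_registry()$model else
    cfg$model
  sampler <- sampler_config(cfg$n_chains, cfg$n_warmup, cfg$n_samples,
                            seed = seeds[2])
  fits <- list()
  loos <- list()
  for (m in models) {
    logf("fitting %s (%d chains x %d draws)", m, sampler$n_chains,
         sampler$n_samples)
    fits[[m]] <- fit_hierarchical(data, model = m, sampler = sampler)
    write_fit_tsv(fits[[m]], file.path(cfg$out_dir, paste0("fit_", m)))
    loos[[m]] <- psis_loo(pointwise_loglik(fits[[m]]))
  }

  # stage 3: compare
  comparison <- compare_models(loos)
  write_comparison_tsv(comparison, file.path(cfg$out_dir, "loo_table.tsv"))
  best <- comparison$model[1]
  logf("best model by LOO: %s", best)

  # stage 4: classify and export regressors at subject-level posterior medians
  est <- tidy(fits[[best]], level = "subject")
  est <- tidyr::pivot_wider(
    dplyr::select(est, "condition", "subject", "parameter", "estimate"),
    names_from = "parameter", values_from = "estimate")
  regs <- compute_regressors(data, model = best, params = est)
  export_regressors(regs, file.path(cfg$out_dir, "regressors.tsv"))
  summ <- behavioral_summary(regs)
  write.table(as.data.frame(summ$overall),
              file.path(cfg$out_dir, "summary_overall.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(summ$by_block),
              file.path(cfg$out_dir, "summary_by_block.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ok <- all(vapply(fits, function(f) f$converged, logical(1)))
  logf("pipeline complete; convergence %s", if (ok) "ok" else "FLAGGED")
  invisible(cfg$out_dir)
}

#' Validate a choice-dataset table
#'
#' Checks schema, strictly increasing trials within each subject-condition
#' sequence, choices in 1-4 on responded trials, and integer rewards.
#'
#' @param data A tibble or a TSV path.
#' @return A tibble of violations (`rule`, `detail`, `row`); zero rows when
#'   the dataset is valid.
#' @export
validate_dataset <- function(data) {
  if (is.character(data)) data <- tibble::as_tibble(read.delim(data))
  d <- tibble::as_tibble(data)
  viol <- list()
  need <- c("subject", "condition", "trial", "choice", "reward")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    return(tibble::tibble(rule = "schema",
                          detail = paste("missing column(s):",
                                         paste(miss, collapse = ", ")),
                          row = NA_integer_))
  }
  if (!"responded" %in% names(d)) d$responded <- !is.na(d$choice)
  d$.row <- seq_len(nrow(d))
  bad_choice <- d$.row[d$responded &
                         (is.na(d$choice) | d$choice < 1 | d$choice > 4)]
  for (r in bad_choice) {
    viol[[length(viol) + 1]] <- tibble::tibble(
      rule = "choice_range", detail = "choice outside 1-4", row = r)
  }
  bad_reward <- d$.row[d$responded &
                         (!is.finite(d$reward) | d$reward %% 1 != 0)]
  for (r in bad_reward) {
    viol[[length(viol) + 1]] <- tibble::tibble(
      rule = "reward_integer", detail = "reward not a finite integer",
      row = r)
  }
  key <- paste(d$subject, d$condition, sep = ".")
  for (grp in split(d, factor(key, unique(key)))) {
    if (is.unsorted(grp$trial, strictly = TRUE)) {
      viol[[length(viol) + 1]] <- tibble::tibble(
        rule = "trial_order",
        detail = paste0("trials not strictly increasing for subject ",
                        grp$subject[1], ", condition ", grp$condition[1]),
        row = grp$.row[which(diff(grp$trial) <= 0)[1] + 1])
    }
  }
  if (!length(viol)) {
    return(tibble::tibble(rule = character(), detail = character(),
                          row = integer()))
  }
  dplyr::bind_rows(viol)
}
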