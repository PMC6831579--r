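#' Experiment configuration
#'
#' Validated configuration for the reproducible sweep harness. The
#' `scale` presets encode the two problem sizes the package works at:
#' `"paper"` mirrors the full-scale published settings (1000 simulations
#' of 1000 trials for the perceptron; 1000 repeats of 5000 trials for the
#' two-layer network; 7200 MT neurons with learning rate 1e-7 and 100
#' runs per target), `"desk"` the scaled-down sizes used throughout the
#' test suite (100 simulations; 20 replications x 3 repeats; 720 neurons
#' with learning rate 1e-6 -- neuron count and learning rate are
#' co-scaled so the per-trial weight change stays comparable -- and 20
#' runs).
#'
#' @param experiment One of `"theory-table"`, `"perceptron-sweep"`,
#'   `"twolayer-sweep"`, `"lawgold-sweep"`, `"flow-surface"`.
#' @param noise Noise-model name for the theory experiments.
#' @param er_grid Error-rate grid for perceptron/lawgold sweeps (must lie
#'   in `(0, 0.5)`).
#' @param acc_grid Accuracy-target grid for the two-layer sweep (must lie
#'   in `(0.5, 1)`).
#' @param n_sims,n_trials Simulation counts; `NULL` means "use the scale
#'   preset".
#' @param scale `"paper"` or `"desk"`.
#' @param seed Master seed.
#' @param output Output directory.
#' @return A validated list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("theory-table",
                                             "perceptron-sweep",
                                             "twolayer-sweep",
                                             "lawgold-sweep",
                                             "flow-surface"),
                              noise = "gaussian",
                              er_grid = NULL, acc_grid = NULL,
                              n_sims = NULL, n_trials = NULL,
                              scale = c("desk", "paper"),
                              seed = 1, output = ".") {
  experiment <- tryCatch(match.arg(experiment), error = function(e) {
    stop(sprintf("unknown experiment '%s'", experiment[1]), call. = FALSE)
  })
  scale <- match.arg(scale)
  problems <- character(0)
  if (!noise %in% c("gaussian", "laplace", "cauchy")) {
    problems <- c(problems, sprintf("noise: unknown model '%s'", noise))
  }
  if (!is.null(er_grid) && (any(er_grid <= 0) || any(er_grid >= 0.5))) {
    problems <- c(problems, "er_grid: error rates must lie in (0, 0.5)")
  }
  if (!is.null(acc_grid) && (any(acc_grid <= 0.5) || any(acc_grid >= 1))) {
    problems <- c(problems, "acc_grid: accuracy targets must lie in (0.5, 1)")
  }
  if (!is.numeric(seed) || length(seed) != 1) {
    problems <- c(problems, "seed: must be a single number")
  }
  if (length(problems) > 0) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  structure(list(experiment = experiment, noise = noise,
                 er_grid = er_grid, acc_grid = acc_grid,
                 n_sims = n_sims, n_trials = n_trials,
                 scale = scale, seed = seed, output = output),
            class = "experiment_config")
}

# Polynomial rolling hash of the serialized configuration; cheap content
# fingerprint for the metadata sidecar (not cryptographic).
config_hash <- function(config) {
  bytes <- as.integer(serialize(config[setdiff(names(config), "output")],
                                NULL, version = 2))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483629
    h2 <- (h2 * 37 + b) %% 2147483587
  }
  sprintf("%08x%08x", h1, h2)
}

scale_defaults <- function(config) {
  desk <- config$scale == "desk"
  list(
    perceptron = list(n_sims = if (desk) 100 else 1000, n_trials = 1000),
    twolayer = list(n_reps = if (desk) 20 else 1000,
                    n_repeats = if (desk) 3 else 1, n_trials = 5000),
    lawgold = list(n_runs = if (desk) 20 else 100,
                   n_trials = if (desk) 3000 else 30000,
                   n_neurons = if (desk) 720 else 7200,
                   eta = if (desk) 1e-6 else 1e-7)
  )
}

#' Run a configured experiment and write its result table
#'
#' Dispatches to the appropriate module, collects a long-format result
#' table (columns `experiment`, `condition`, `replicate`, `index`,
#' `metric`, `value`), writes it as CSV together with a JSON metadata
#' sidecar (configuration echo, configuration hash, master seed, package
#' version, wall time), and returns the table invisibly. Identical
#' configuration and seed reproduce the result table byte for byte.
#'
#' @param config An [experiment_config()].
#' @return The result tibble, invisibly. Files
#'   `<output>/<experiment>-results.csv` and
#'   `<output>/<experiment>-meta.json` are written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t_start <- Sys.time()
  sc <- scale_defaults(config)
  nm <- noise_model(config$noise)
  tab <- switch(config$experiment,
    "theory-table" = {
      tt <- theory_table()
      dplyr::bind_rows(
        tibble::tibble(condition = tt$noise, replicate = NA_integer_,
                       index = NA_real_, metric = "er_star",
                       value = tt$er_star),
        tibble::tibble(condition = tt$noise, replicate = NA_integer_,
                       index = NA_real_, metric = "acc_star",
                       value = tt$acc_star),
        tibble::tibble(condition = tt$noise, replicate = NA_integer_,
                       index = NA_real_, metric = "acc_pct",
                       value = tt$acc_pct))
    },
    "perceptron-sweep" = {
      grid <- if (is.null(config$er_grid)) seq(0.01, 0.5, by = 0.01)
              else config$er_grid
      sw <- perceptron_sweep(
        er_grid = grid,
        n_sims = config$n_sims %||% sc$perceptron$n_sims,
        n_trials = config$n_trials %||% sc$perceptron$n_trials,
        seed = config$seed, noise = nm)
      dplyr::bind_rows(
        tidyr_longer_final(sw$final_beta, sw$summary$er_target),
        tibble::tibble(condition = format(sw$summary$er_target),
                       replicate = NA_integer_, index = NA_real_,
                       metric = "empirical_er",
                       value = sw$summary$empirical_er))
    },
    "twolayer-sweep" = {
      grid <- if (is.null(config$acc_grid)) seq(0.70, 0.95, by = 0.05)
              else config$acc_grid
      sw <- twolayer_sweep(A_grid = grid,
                           n_reps = sc$twolayer$n_reps,
                           n_repeats = sc$twolayer$n_repeats,
                           n_trials = config$n_trials %||%
                             sc$twolayer$n_trials,
                           seed = config$seed)
      dplyr::bind_rows(
        tibble::tibble(condition = format(sw$A_target),
                       replicate = as.integer(sw$replication),
                       index = as.numeric(sw$repeat_idx),
                       metric = "test_accuracy", value = sw$test_accuracy),
        tibble::tibble(condition = format(sw$A_target),
                       replicate = as.integer(sw$replication),
                       index = as.numeric(sw$repeat_idx),
                       metric = "train_accuracy_last",
                       value = sw$train_accuracy_last))
    },
    "lawgold-sweep" = {
      grid <- if (is.null(config$er_grid))
        c(0.06, 0.11, 0.16, 0.21, 0.26, 0.31, 0.38, 0.44)
      else config$er_grid
      sw <- lawgold_sweep(er_grid = grid,
                          n_runs = config$n_sims %||% sc$lawgold$n_runs,
                          n_trials = config$n_trials %||%
                            sc$lawgold$n_trials,
                          n_neurons = sc$lawgold$n_neurons,
                          eta = sc$lawgold$eta, seed = config$seed)
      dplyr::bind_rows(
        tibble::tibble(condition = format(sw$er_target),
                       replicate = as.integer(sw$run), index = NA_real_,
                       metric = "beta", value = sw$beta),
        tibble::tibble(condition = format(sw$er_target),
                       replicate = as.integer(sw$run), index = NA_real_,
                       metric = "empirical_er", value = sw$empirical_er))
    },
    "flow-surface" = {
      skill <- 10^seq(-0.5, 1, length.out = 40)
      challenge <- 10^seq(-0.5, 1, length.out = 40)
      fs <- flow_surfaces(skill, challenge, nm)
      grid_idx <- expand.grid(i = seq_along(skill), j = seq_along(challenge))
      dplyr::bind_rows(
        tibble::tibble(condition = sprintf("skill=%.4g,challenge=%.4g",
                                           skill[grid_idx$i],
                                           challenge[grid_idx$j]),
                       replicate = NA_integer_, index = NA_real_,
                       metric = "learning",
                       value = fs$learning[cbind(grid_idx$i, grid_idx$j)]),
        tibble::tibble(condition = sprintf("skill=%.4g,challenge=%.4g",
                                           skill[grid_idx$i],
                                           challenge[grid_idx$j]),
                       replicate = NA_integer_, index = NA_real_,
                       metric = "accuracy",
                       value = fs$accuracy[cbind(grid_idx$i, grid_idx$j)]))
    })
  tab <- dplyr::bind_cols(
    tibble::tibble(experiment = rep(config$experiment, nrow(tab))), tab)
  dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(config$output, config$experiment)
  readr::write_csv(tab, paste0(stem, "-results.csv"))
  meta <- list(
    experiment = config$experiment,
    config = config[setdiff(names(config), "output")],
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("traindiff")),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(meta, paste0(stem, "-meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tidyr_longer_final <- function(final_beta, er_grid) {
  n_sims <- nrow(final_beta)
  tibble::tibble(
    condition = rep(format(er_grid), each = n_sims),
    replicate = rep(seq_len(n_sims), times = length(er_grid)),
    index = NA_real_,
    metric = "final_beta",
    value = as.vector(final_beta))
}

#' Read a result table written by [run_experiment()]
#'
#' @param path Path to a `*-results.csv` file.
#' @return The result tibble.
#' @export
read_result_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    experiment = readr::col_character(),
    condition = readr::col_character(),
    replicate = readr::col_integer(),
    index = readr::col_double(),
    metric = readr::col_character(),
    value = readr::col_double()))
}

#' Summarize a sweep result table
#'
#' Per-condition aggregates (mean, standard deviation, replicate count)
#' of one metric, the argmax condition, and a bootstrap distribution of
#' the argmax over replicate resampling.
#'
#' @param tab A result tibble (from [run_experiment()] or
#'   [read_result_table()]), or a path to a results CSV.
#' @param metric Metric to aggregate (default the first in the table).
#' @param n_boot Bootstrap resamples for the argmax interval.
#' @return A list with `summary` (tibble: condition, mean, sd, n),
#'   `argmax` (condition with the largest mean), and `argmax_boot`
#'   (tibble of bootstrap argmax proportions per condition).
#' @export
summarize_results <- function(tab, metric = NULL, n_boot = 1000) {
  if (is.character(tab) && length(tab) == 1) tab <- read_result_table(tab)
  if (nrow(tab) == 0) stop("empty result table", call. = FALSE)
  if (is.null(metric)) metric <- tab$metric[1]
  m <- metric
  sub <- dplyr::filter(tab, .data$metric == m)
  if (nrow(sub) == 0) {
    stop(sprintf("metric '%s' not present in the table", m), call. = FALSE)
  }
  summary <- sub |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  argmax <- summary$condition[which.max(summary$mean)]
  by_cond <- split(sub$value, sub$condition)
  conds <- names(by_cond)
  picks <- vapply(seq_len(n_boot), function(b) {
    means <- vapply(by_cond, function(v) {
      mean(v[sample.int(length(v), replace = TRUE)])
    }, numeric(1))
    conds[which.max(means)]
  }, character(1))
  boot <- tibble::tibble(condition = conds,
                         argmax_prop = vapply(conds, function(cn) {
                           mean(picks == cn)
                         }, numeric(1)))
  list(summary = summary, argmax = argmax, argmax_boot = boot)
}
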