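## Run driver -----------------------------------------------------------------
##
## Configuration-driven entry points mirroring the simulation studies: a
## single scenario x learner x N cell (`cara_run`) and a grid sweep
## (`cara_sweep`) producing the tidy table behind the figures' numeric
## content.  Configs are plain named lists and can be read from JSON or YAML.

#' Assemble and validate a run configuration
#'
#' @param scenario scenario id (`"s1"`..`"s6"`, `"cs1"`..`"cs4"`).
#' @param learner learner family, `"fixed"` or `"oracle"`.
#' @param n total sample size.
#' @param reps number of replicates.
#' @param seed root seed.
#' @param pi_start,pi_end randomization-sequence endpoints (defaults `1/K`,
#'   0.1).
#' @param burn_in_per_arm burn-in patients per arm (default 5).
#' @param burn_in_scheme `"balanced"` or `"bernoulli"`.
#' @param noise_c,followup_days,arrival_mean scenario overrides (see
#'   [cara_scenario()]).
#' @param learner_opts learner hyperparameter overrides (see
#'   [trial_config()]).
#' @return validated list of class `cara_run_config`.
#' @export
run_config <- function(scenario, learner, n, reps = 100L, seed = 1L,
                       pi_start = NULL, pi_end = 0.1,
                       burn_in_per_arm = 5L, burn_in_scheme = "balanced",
                       noise_c = 0.1, followup_days = 180L, arrival_mean = 5,
                       learner_opts = list()) {
  sc <- cara_scenario(scenario, noise_c = noise_c,
                      followup_days = followup_days,
                      arrival_mean = arrival_mean)
  cfg <- trial_config(N = n, learner = learner, K = sc$K,
                      L = burn_in_per_arm,
                      pi_start = pi_start %||% (1 / sc$K), pi_end = pi_end,
                      burn_in = burn_in_scheme,
                      learner_opts = learner_opts)
  if (!cfg$learner %in% c("fixed", "oracle") &&
      !cfg$learner %in% learner_families(sc$setting)) {
    stop(sprintf("learner '%s' is not usable with scenario '%s' (%s outcome)",
                 learner, scenario, sc$setting))
  }
  structure(list(scenario = sc, config = cfg, reps = as.integer(reps),
                 seed = as.integer(seed)),
            class = "cara_run_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' The file holds the [run_config()] arguments by name.
#'
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return a `cara_run_config`.
#' @export
read_run_config <- function(path) {
  args <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    stop("config file must be .json or .yaml/.yml")
  }
  do.call(run_config, args)
}

#' Execute one run configuration and write its artifacts
#'
#' Simulates the configured replicates, aggregates operating characteristics,
#' and writes `oc_<scenario>_<learner>_<N>.json` (all aggregate metrics plus
#' the configuration and seed) and `metrics_<...>.csv` (tidy one-row-per-metric
#' table) to `out_dir`; optionally also the per-patient CSV of each trial.
#'
#' @param rc a `cara_run_config` (or a config file path).
#' @param out_dir output directory (created if missing); `NULL` to skip all
#'   file output.
#' @param keep_trials write per-trial patient CSVs as well?
#' @return the `cara_oc` object, invisibly if files were written.
#' @export
cara_run <- function(rc, out_dir = NULL, keep_trials = FALSE) {
  if (is.character(rc)) rc <- read_run_config(rc)
  stopifnot(inherits(rc, "cara_run_config"))
  oc <- operating_characteristics(rc$scenario, rc$config,
                                  replicates = rc$reps, seed = rc$seed)
  if (is.null(out_dir)) return(oc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s_%d", oc$scenario, oc$learner, oc$N)
  payload <- list(
    package = "caratrial",
    version = as.character(utils::packageVersion("caratrial")),
    scenario = oc$scenario, learner = oc$learner, N = oc$N,
    replicates = oc$replicates, seed = oc$seed,
    config = rc$config[setdiff(names(rc$config), "learner_opts")],
    proportion_best = oc$proportion_best,
    proportion_best_se = oc$proportion_best_se,
    proportion_best_mean_def = oc$proportion_best_mean_def,
    proportion_on_arm = oc$proportion_on_arm,
    performance_ratio = oc$performance_ratio,
    rejection = oc$rejection)
  jsonlite::write_json(payload, file.path(out_dir, paste0("oc_", stem, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(oc),
                   file.path(out_dir, paste0("metrics_", stem, ".csv")),
                   row.names = FALSE)
  if (keep_trials) {
    tdir <- file.path(out_dir, paste0("trials_", stem))
    dir.create(tdir, showWarnings = FALSE)
    for (r in seq_len(rc$reps)) {
      tr <- run_trial(rc$scenario, rc$config, seed = rc$seed, replicate = r)
      write_trial_csv(tr, file.path(tdir, sprintf("trial_%04d.csv", r)))
    }
  }
  invisible(oc)
}

#' Sweep a scenario x learner x sample-size grid
#'
#' Runs [cara_run()] for every cell of the grid and row-binds the tidy metric
#' tables; a failing cell is recorded (`ok = FALSE`) without aborting the
#' sweep.
#'
#' @param scenarios,learners,Ns character / integer vectors spanning the grid.
#' @param reps replicates per cell.
#' @param seed root seed (every cell uses its own derived stream).
#' @param out_dir optional directory for the combined CSV
#'   (`sweep_metrics.csv`).
#' @param ... further arguments passed to [run_config()].
#' @return data.frame of tidy metrics for all cells, with columns `ok` and
#'   `error` recording per-cell failures.
#' @export
cara_sweep <- function(scenarios, learners, Ns, reps = 100L, seed = 1L,
                       out_dir = NULL, ...) {
  grid <- expand.grid(scenario = scenarios, learner = learners, N = Ns,
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cell_seed <- derive_seed(seed, i, 3L)
    out[[i]] <- tryCatch({
      oc <- cara_run(run_config(g$scenario, g$learner, g$N, reps = reps,
                                seed = cell_seed, ...))
      cbind(as.data.frame(oc), ok = TRUE, error = NA_character_)
    }, error = function(e) {
      data.frame(scenario = g$scenario, learner = g$learner, N = g$N,
                 replicates = reps, metric = NA, test = NA, level = NA,
                 value = NA, mc_se = NA, ok = FALSE,
                 error = conditionMessage(e))
    })
  }
  res <- do.call(rbind, out)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "sweep_metrics.csv"),
                     row.names = FALSE)
  }
  res
}

#' Emit a small demonstration cohort
#'
#' Simulates a single trial and writes its per-patient CSV — handy for
#' inspecting the record layout or seeding examples.
#'
#' @param scenario scenario id.
#' @param learner learner family.
#' @param n sample size.
#' @param seed root seed.
#' @param path output CSV path.
#' @return the `cara_trial`, invisibly.
#' @export
cara_fixture <- function(scenario, learner, n, seed, path) {
  rc <- run_config(scenario, learner, n, reps = 1L, seed = seed)
  tr <- run_trial(rc$scenario, rc$config, seed = rc$seed, replicate = 1L)
  write_trial_csv(tr, path)
  invisible(tr)
}
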