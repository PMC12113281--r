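# Orchestration: a seeded, config-driven run of the analysis chain writing
# per-stage tables plus a manifest.

#' Run configuration
#'
#' Bundles the knobs of a pipeline run. Defaults follow the study design:
#' alpha 0.05, 100 decoding resamplings, 200 permutation runs, 60 units
#' (subject-balanced), 8 trials per stimulus, SVM cost 1.
#'
#' @param seed master seed for the whole run.
#' @param alpha significance level used by screening and ANOVA stages.
#' @param n_resamples decoding resamplings.
#' @param n_permutation_runs permutation-null runs.
#' @param n_units units drawn per decoding resampling (`NULL` = all).
#' @param n_trials trials per stimulus in the generator.
#' @param n_sim_units units simulated by the `simulate` stage.
#' @param cost SVM regularization parameter.
#' @param n_splits reliability splits.
#' @param generator named list of [sample_tuning_params()] arguments.
#' @return list of class `"hbo_config"`.
#' @export
run_config <- function(seed = 1, alpha = 0.05, n_resamples = 100,
                       n_permutation_runs = 200, n_units = 60, n_trials = 8,
                       n_sim_units = 60, cost = 1, n_splits = 100,
                       generator = list()) {
  structure(list(seed = seed, alpha = alpha, n_resamples = n_resamples,
                 n_permutation_runs = n_permutation_runs, n_units = n_units,
                 n_trials = n_trials, n_sim_units = n_sim_units, cost = cost,
                 n_splits = n_splits, generator = generator),
            class = "hbo_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return an `"hbo_config"` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, reading each stage's inputs from
#' `outdir` (or from the in-memory results of earlier stages in the same
#' call) and writing per-stage CSV/TSV/JSON outputs plus a run manifest.
#' The run is deterministic under the config seed.
#'
#' Stages: `simulate` (synthetic experiment-1 population, both centerings),
#' `screen` (responsiveness screen), `msi` (monkey-sum indices), `anova`
#' (head-by-body interaction, centering and residual correlations),
#' `reliability` (split-half), `decode` (zero-versus-straight pooled angle
#' decoding with permutation null), `symmetry` (mirror distance matrices).
#'
#' @param config an [run_config()] object.
#' @param stages character vector of stages (in any order; executed in
#'   canonical order).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "screen", "msi", "anova",
                                    "reliability", "decode", "symmetry"),
                         outdir = "hborient-run") {
  all_stages <- c("simulate", "screen", "msi", "anova", "reliability",
                  "decode", "symmetry")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  timings <- list()

  trials_path <- file.path(outdir, "trials.tsv")
  get_trials <- function(stage) {
    if (!is.null(results$trials)) return(results$trials)
    if (!file.exists(trials_path)) {
      stop("stage '", stage, "' needs trial data: run the 'simulate' stage ",
           "first or place trials.tsv in the output directory")
    }
    results$trials <<- compute_rates(read_trials(trials_path))
    results$trials
  }

  for (stage in stages) {
    t0 <- Sys.time()
    if (stage == "simulate") {
      grid <- rbind(make_stimulus_grid("E1", "P1", "MC"),
                    make_stimulus_grid("E1", "P1", "HC"))
      trials <- do.call(simulate_population,
                        c(list(n_units = config$n_sim_units, grid = grid,
                               n_trials = config$n_trials,
                               seed = config$seed),
                          config$generator))
      write_trials(trials, trials_path)
      results$trials <- compute_rates(trials)
    } else if (stage == "screen") {
      trials <- get_trials(stage)
      results$screen <- screen_units(trials, "E1", alpha = config$alpha)
      utils::write.csv(results$screen, file.path(outdir, "screening.csv"),
                       row.names = FALSE)
    } else if (stage == "msi") {
      trials <- get_trials(stage)
      results$msi <- msi_table(trials, alpha = config$alpha)
      if (is.null(results$msi)) {
        results$msi <- data.frame(unit_id = character(), pose = character(),
                                  centering = character(), msi = numeric())
      }
      utils::write.csv(results$msi, file.path(outdir, "msi.csv"),
                       row.names = FALSE)
    } else if (stage == "anova") {
      trials <- get_trials(stage)
      units <- unique(trials$unit_id)
      rows <- lapply(units, function(u) {
        tr <- trials[trials$unit_id == u, , drop = FALSE]
        res <- lapply(c("MC", "HC"), function(ct)
          headbody_anova(tr, pose = "P1", centering = ct))
        data.frame(unit_id = u,
                   p_head_mc = res[[1]]$p_head, p_body_mc = res[[1]]$p_body,
                   p_interaction_mc = res[[1]]$p_interaction,
                   p_head_hc = res[[2]]$p_head, p_body_hc = res[[2]]$p_body,
                   p_interaction_hc = res[[2]]$p_interaction,
                   centering_r = centering_correlation(tr, pose = "P1"),
                   residual_r = residual_correlation(tr, pose = "P1"),
                   stringsAsFactors = FALSE)
      })
      results$anova <- do.call(rbind, rows)
      utils::write.csv(results$anova, file.path(outdir, "anova.csv"),
                       row.names = FALSE)
    } else if (stage == "reliability") {
      trials <- get_trials(stage)
      units <- unique(trials$unit_id)
      rows <- lapply(units, function(u) {
        tr <- trials[trials$unit_id == u, , drop = FALSE]
        vals <- vapply(c("MC", "HC"), function(ct) {
          sub <- tr[tr$centering == ct & tr$part == "monkey", , drop = FALSE]
          split_half_reliability(sub, n_splits = config$n_splits,
                                 seed = sub_seed(config$seed, match(u, units)))
        }, numeric(1))
        data.frame(unit_id = u, reliability_mc = vals[1],
                   reliability_hc = vals[2], stringsAsFactors = FALSE)
      })
      results$reliability <- do.call(rbind, rows)
      utils::write.csv(results$reliability,
                       file.path(outdir, "reliability.csv"),
                       row.names = FALSE)
    } else if (stage == "decode") {
      trials <- get_trials(stage)
      res <- decode_angle_pair(trials, angles = c(0, 180), pose = "P1",
                               n_units = config$n_units,
                               n_resamples = config$n_resamples,
                               null_runs = config$n_permutation_runs,
                               seed = config$seed, cost = config$cost)
      results$decode <- res
      utils::write.csv(data.frame(resampling = seq_along(res$accuracies),
                                  accuracy = res$accuracies),
                       file.path(outdir, "decode_accuracies.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(contrast = "0_vs_180_pooled",
                                mean = res$mean, sd = res$sd,
                                null_band = res$null_band),
                           file.path(outdir, "decode_summary.json"),
                           auto_unbox = TRUE, digits = NA)
    } else if (stage == "symmetry") {
      trials <- get_trials(stage)
      for (ax in c("head", "body")) {
        d <- mirror_distance_matrix(
          population_marginals(trials, axis = ax, pose = "P1",
                               centering = "MC"))
        utils::write.csv(d, file.path(outdir,
                                      paste0("symmetry_", ax, ".csv")))
        results[[paste0("symmetry_", ax)]] <- d
      }
    }
    timings[[stage]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("hborient")),
                   config = unclass(config),
                   stages = stages,
                   timings_s = timings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}
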