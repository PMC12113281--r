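#' Simulate trial-wise spike counts for one unit
#'
#' Counts are drawn independently per trial and window from Poisson laws with
#' mean `rate * duration`: the 100-ms and 200-ms baseline windows use the
#' baseline rate only, the 250-ms response window (50-300 ms after stimulus
#' onset) uses the condition's [expected_rate()].
#'
#' @param params a [tuning_params()] object.
#' @param grid stimulus conditions from [make_stimulus_grid()].
#' @param n_trials trials per condition (the experiments used 8).
#' @param seed optional integer seed for reproducibility.
#' @return a trial table (one row per trial) with the condition columns plus
#'   `trial_index`, `baseline100_count`, `baseline200_count`,
#'   `response_count`.
#' @export
simulate_unit <- function(params, grid, n_trials = 8, seed = NULL) {
  stopifnot(n_trials >= 1)
  with_seed(seed, {
    rate <- expected_rate(params, grid)
    n <- nrow(grid)
    trials <- grid[rep(seq_len(n), each = n_trials), , drop = FALSE]
    trials$trial_index <- rep(seq_len(n_trials), times = n)
    trials$baseline100_count <- stats::rpois(n * n_trials,
                                             params$baseline * WIN_BASE100)
    trials$baseline200_count <- stats::rpois(n * n_trials,
                                             params$baseline * WIN_BASE200)
    trials$response_count <- stats::rpois(n * n_trials,
                                          rep(rate, each = n_trials) * WIN_RESPONSE)
    rownames(trials) <- NULL
    trials
  })
}

#' Simulate a population of independently tuned units
#'
#' Units are drawn i.i.d. from `param_sampler` and labelled with alternating
#' subjects (`M1`, `M2`) and a region, so subject-balanced subsampling is
#' testable downstream. Units are statistically independent, which matches
#' the pseudo-population construction used for decoding.
#'
#' @param n_units number of units (>= 1).
#' @param grid stimulus conditions from [make_stimulus_grid()]; several grids
#'   may be row-bound (e.g. both centerings of experiment 1).
#' @param n_trials trials per condition.
#' @param seed optional integer seed.
#' @param param_sampler function of `n` returning a list of
#'   [tuning_params()]; defaults to [sample_tuning_params()] with `...`
#'   forwarded.
#' @param region region label for all units.
#' @param subjects subject labels cycled over units.
#' @param ... forwarded to `param_sampler`.
#' @return a trial table covering all units, with columns `unit_id`,
#'   `region`, `subject` prepended; the generating parameter list is attached
#'   as attribute `"params"`.
#' @export
simulate_population <- function(n_units, grid, n_trials = 8, seed = NULL,
                                param_sampler = sample_tuning_params,
                                region = "aSTS", subjects = c("M1", "M2"),
                                ...) {
  if (n_units < 1) stop("n_units must be >= 1")
  with_seed(seed, {
    params <- param_sampler(n_units, ...)
    ids <- sprintf("u%03d", seq_len(n_units))
    subj <- rep_len(subjects, n_units)
    out <- vector("list", n_units)
    for (i in seq_len(n_units)) {
      tr <- simulate_unit(params[[i]], grid, n_trials = n_trials)
      tr <- cbind(unit_id = ids[i], region = region, subject = subj[i], tr,
                  stringsAsFactors = FALSE)
      out[[i]] <- tr
    }
    trials <- do.call(rbind, out)
    rownames(trials) <- NULL
    attr(trials, "params") <- params
    trials
  })
}
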