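# Unit responsiveness / selectivity screening.
#
# Experiment 1 uses a split-plot responsiveness ANOVA plus an excitatory
# check; experiments 2 and 3 additionally require a Kruskal-Wallis
# selectivity test and a z-score criterion, reflecting the less curated
# multi-unit recordings.

#' Split-plot responsiveness ANOVA for one unit
#'
#' Mixed two-factor ANOVA on per-trial window rates with within-trial factor
#' window (200-ms baseline vs response window) and between-trial factor
#' stimulus; trials are the error stratum for the between factor. A unit
#' counts as responsive when the main effect of window or the
#' stimulus-by-window interaction is significant and the response is
#' excitatory (best-stimulus mean response above its baseline).
#'
#' @param unit_trials trial table of a single unit (any number of stimulus
#'   conditions with >= 2 trials each).
#' @return list with `p_main` (window effect), `p_interaction`, and
#'   `excitatory`; p-values are `NA` when the fit is degenerate (the unit
#'   then fails the screen).
#' @export
splitplot_responsiveness <- function(unit_trials) {
  tr <- .with_rates(unit_trials)
  stim <- condition_key(tr)
  if (length(unique(stim)) < 2 || min(table(stim)) < 2) {
    stop("need >= 2 conditions with >= 2 trials each")
  }
  long <- data.frame(
    rate = c(tr$baseline200_rate, tr$response_rate),
    window = factor(rep(c("baseline", "response"), each = nrow(tr))),
    stimulus = factor(c(stim, stim)),
    trial = factor(rep(paste(stim, tr$trial_index), 2))
  )
  p_main <- p_int <- NA_real_
  fit <- try(stats::aov(rate ~ stimulus * window + Error(trial), data = long),
             silent = TRUE)
  if (!inherits(fit, "try-error")) {
    s <- summary(fit)
    within <- s[["Error: Within"]][[1]]
    rn <- trimws(rownames(within))
    p_main <- within[match("window", rn), "Pr(>F)"]
    p_int <- within[match("stimulus:window", rn), "Pr(>F)"]
  }
  resp_by_stim <- tapply(tr$response_rate, stim, mean)
  base_by_stim <- tapply(tr$baseline200_rate, stim, mean)
  best <- which.max(resp_by_stim)
  excitatory <- isTRUE(resp_by_stim[best] > base_by_stim[best])
  list(p_main = unname(p_main), p_interaction = unname(p_int),
       excitatory = excitatory)
}

#' Kruskal-Wallis stimulus selectivity test for one unit
#'
#' One Kruskal-Wallis test across stimuli on the per-trial raw
#' response-window rates.
#'
#' @inheritParams splitplot_responsiveness
#' @return the p-value; `NA` when the rates are all identical (the unit then
#'   fails the screen).
#' @export
kruskal_selectivity <- function(unit_trials) {
  tr <- .with_rates(unit_trials)
  stim <- factor(condition_key(tr))
  if (nlevels(stim) < 2) stop("need >= 2 stimuli for a selectivity test")
  if (stats::var(tr$response_rate) == 0) return(NA_real_)
  stats::kruskal.test(tr$response_rate, stim)$p.value
}

#' Maximum response z-score of one unit
#'
#' For each stimulus, averages the response-window rate over its trials
#' (`meanRespStim`) and the 100-ms baseline rate (`meanBaseStim`); then
#' computes `z = (meanRespStim - meanBaseAll) / stdBaseAll` where
#' `meanBaseAll` and `stdBaseAll` are the mean and standard deviation of the
#' per-stimulus baseline means across all stimuli. Returns the maximum z
#' over stimuli; the screen requires `max_z > 3`.
#'
#' @inheritParams splitplot_responsiveness
#' @return the maximum z-score (`NA` if `stdBaseAll` is 0; the unit then
#'   fails).
#' @export
zscore_screen <- function(unit_trials) {
  tr <- .with_rates(unit_trials)
  stim <- condition_key(tr)
  mean_resp <- tapply(tr$response_rate, stim, mean)
  mean_base <- tapply(tr$baseline100_rate, stim, mean)
  std_base_all <- stats::sd(mean_base)
  if (is.na(std_base_all) || std_base_all == 0) return(NA_real_)
  max((mean_resp - mean(mean_base)) / std_base_all)
}

#' Category-selectivity filter
#'
#' Passes a unit whose mean net response to the monkey, face or body category
#' is at least twice the mean net response to the matched object controls
#' (the criterion is inclusive: exactly twice passes).
#'
#' @param category_nets named numeric vector of mean net responses with names
#'   among `monkey`, `face`, `body`.
#' @param control_nets named numeric vector of the matched object-control
#'   mean net responses (same names).
#' @return `TRUE` if at least one category meets the criterion.
#' @export
category_filter <- function(category_nets, control_nets) {
  cats <- intersect(names(category_nets), names(control_nets))
  if (length(cats) == 0) stop("no shared category names")
  any(category_nets[cats] >= 2 * control_nets[cats])
}

#' Screen all units of a population
#'
#' Applies the experiment's conjunctive screening criteria to each unit:
#' experiment 1 requires split-plot responsiveness with an excitatory
#' response; experiments 2 and 3 additionally require Kruskal-Wallis
#' selectivity (p < alpha) and a maximum response z-score above 3.
#'
#' @param trials trial table of the population (already restricted to the
#'   conditions relevant for the screen).
#' @param experiment `"E1"`, `"E2"` or `"E3"`.
#' @param alpha significance level for the ANOVA and Kruskal-Wallis tests.
#' @return data frame with one row per unit: the test statistics and the
#'   conjunctive `passed` flag.
#' @export
screen_units <- function(trials, experiment = c("E1", "E2", "E3"),
                         alpha = 0.05) {
  experiment <- match.arg(experiment)
  trials <- .with_rates(trials)
  units <- unique(trials$unit_id)
  rows <- lapply(units, function(u) {
    tr <- trials[trials$unit_id == u, , drop = FALSE]
    sp <- splitplot_responsiveness(tr)
    responsive <- (isTRUE(sp$p_main < alpha) ||
                     isTRUE(sp$p_interaction < alpha)) && sp$excitatory
    kp <- NA_real_
    mz <- NA_real_
    passed <- responsive
    if (experiment != "E1") {
      kp <- kruskal_selectivity(tr)
      mz <- zscore_screen(tr)
      passed <- responsive && isTRUE(kp < alpha) && isTRUE(mz > 3)
    }
    data.frame(unit_id = u,
               region = tr$region[1] %||% NA_character_,
               subject = tr$subject[1] %||% NA_character_,
               splitplot_p_main = sp$p_main,
               splitplot_p_interaction = sp$p_interaction,
               excitatory = sp$excitatory,
               kruskal_p = kp, max_z = mz, passed = passed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
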