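# Neuron-dropping: rank units by their contribution to a population
# decoding and characterize the top contributors.

.angle_effect_p <- function(unit_trials, pose = "P1", centering = "MC") {
  tr <- .with_rates(unit_trials)
  tr <- tr[tr$part == "monkey" & tr$pose == pose &
             tr$centering == centering & tr$inversion == "upright", ,
           drop = FALSE]
  if (length(unique(tr$angle)) < 2) return(NA_real_)
  tab <- summary(stats::aov(response_rate ~ factor(angle), data = tr))[[1]]
  tab[1, "Pr(>F)"]
}

#' Neuron-dropping analysis of an angle decoding
#'
#' Ranks units by a leave-one-out contribution: the drop in mean decoding
#' accuracy when the unit is removed from the population (same sub-seeds, so
#' resamplings are paired). Reports the contribution ranking, an accuracy
#' curve over top-k subsets of the ranking, the `top_k` best units, and the
#' fraction of those units with a significant head-by-body interaction
#' ([headbody_anova()]) and with a significant one-way effect of head-body
#' angle on their responses.
#'
#' The ranking procedure is a documented stand-in: leave-one-out deltas are
#' one reasonable operationalization of "contribution to decoding".
#'
#' @inheritParams decode_angle_pair
#' @param top_k size of the reported best-unit roster.
#' @param curve_sizes population sizes at which the top-k accuracy curve is
#'   evaluated; defaults to a small grid up to the full roster.
#' @param alpha significance level for the per-unit ANOVAs.
#' @return list with `ranking` (data frame: unit, contribution), `curve`
#'   (data frame: k, accuracy), `top_units`, `frac_interaction`,
#'   `frac_angle_effect`, `full_accuracy`.
#' @export
neuron_dropping <- function(trials, angles = c(0, 180), pose = "P1",
                            train_centering = "MC",
                            test_centering = train_centering,
                            response_kind = "raw", n_resamples = 10,
                            seed = 1, cost = 1, top_k = 10,
                            curve_sizes = NULL, alpha = 0.05) {
  units <- unique(trials$unit_id)
  run <- function(subset_ids) {
    decode_angle_pair(trials[trials$unit_id %in% subset_ids, , drop = FALSE],
                      angles = angles, pose = pose,
                      train_centering = train_centering,
                      test_centering = test_centering,
                      response_kind = response_kind,
                      n_resamples = n_resamples, seed = seed, cost = cost)
  }
  full <- run(units)
  contrib <- vapply(units, function(u) {
    full$mean - run(setdiff(units, u))$mean
  }, numeric(1))
  ord <- order(contrib, decreasing = TRUE)
  ranking <- data.frame(unit_id = units[ord], contribution = contrib[ord],
                        stringsAsFactors = FALSE)

  if (is.null(curve_sizes)) {
    curve_sizes <- unique(pmin(c(2, 5, 10, 20, 40, length(units)),
                               length(units)))
    curve_sizes <- curve_sizes[curve_sizes >= 2]
  }
  curve <- data.frame(k = curve_sizes,
                      accuracy = vapply(curve_sizes, function(k) {
                        run(ranking$unit_id[seq_len(k)])$mean
                      }, numeric(1)))

  top_units <- ranking$unit_id[seq_len(min(top_k, nrow(ranking)))]
  p_int <- vapply(top_units, function(u) {
    res <- try(headbody_anova(trials[trials$unit_id == u, , drop = FALSE],
                              pose = pose, centering = train_centering),
               silent = TRUE)
    if (inherits(res, "try-error")) NA_real_ else res$p_interaction
  }, numeric(1))
  p_ang <- vapply(top_units, function(u) {
    .angle_effect_p(trials[trials$unit_id == u, , drop = FALSE],
                    pose = pose, centering = train_centering)
  }, numeric(1))

  list(ranking = ranking, curve = curve, top_units = top_units,
       frac_interaction = mean(p_int < alpha, na.rm = TRUE),
       frac_angle_effect = mean(p_ang < alpha, na.rm = TRUE),
       full_accuracy = full$mean)
}
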