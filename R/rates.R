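#' Firing rates from window spike counts
#'
#' Converts the three window counts of each trial into rates (spikes/s) and
#' the net rate used throughout the analyses: the response-window rate minus
#' the rate in the 100-ms baseline window immediately before stimulus onset.
#'
#' @param trials a trial table with `baseline100_count`, `baseline200_count`
#'   and `response_count` columns.
#' @return the table with `baseline100_rate`, `baseline200_rate`,
#'   `response_rate` and `net_rate` columns appended.
#' @examples
#' tr <- data.frame(baseline100_count = 2, baseline200_count = 4,
#'                  response_count = 5)
#' compute_rates(tr)$net_rate  # 5/0.25 - 2/0.1 = 0
#' @export
compute_rates <- function(trials) {
  cols <- c("baseline100_count", "baseline200_count", "response_count")
  if (!all(cols %in% names(trials))) {
    stop("trials must contain columns ", paste(cols, collapse = ", "))
  }
  counts <- as.matrix(trials[cols])
  if (any(counts < 0, na.rm = TRUE)) stop("negative spike counts")
  trials$baseline100_rate <- trials$baseline100_count / WIN_BASE100
  trials$baseline200_rate <- trials$baseline200_count / WIN_BASE200
  trials$response_rate <- trials$response_count / WIN_RESPONSE
  trials$net_rate <- trials$response_rate - trials$baseline100_rate
  trials
}

# Ensure rate columns exist, computing them if necessary.
.with_rates <- function(trials) {
  if (!"net_rate" %in% names(trials)) compute_rates(trials) else trials
}

# Mean of `value` per condition (keyed by condition_key), returned in the
# order of `conds`.
.cond_means <- function(trials, conds, value = "net_rate") {
  key <- condition_key(trials)
  m <- tapply(trials[[value]], key, mean)
  unname(m[condition_key(conds)])
}
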