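# Split-half reliability and reliability-corrected correlations.

#' Spearman-Brown corrected split-half reliability of one unit
#'
#' The eight trials of each stimulus are split at random into two groups of
#' four; the mean raw response-window rates of the halves are correlated
#' across stimuli (Pearson) and corrected to full length with the
#' Spearman-Brown formula `2r / (1 + r)`. The reliability is the mean over
#' `n_splits` random splits; degenerate splits (zero variance in a half) are
#' skipped.
#'
#' @param unit_trials trial table of one unit, 8 trials per condition.
#' @param n_splits number of random splits.
#' @param seed optional seed.
#' @return mean corrected correlation (`NA` if every split is degenerate).
#' @export
split_half_reliability <- function(unit_trials, n_splits = 100, seed = NULL) {
  tr <- .with_rates(unit_trials)
  key <- condition_key(tr)
  tr <- tr[order(key, tr$trial_index), , drop = FALSE]
  counts <- table(key)
  if (any(counts != 8)) stop("split-half reliability expects 8 trials per condition")
  n_stim <- length(counts)
  rate <- matrix(tr$response_rate, nrow = 8)  # trials x stimuli
  with_seed(seed, {
    rs <- vapply(seq_len(n_splits), function(s) {
      pick <- apply(matrix(stats::runif(8 * n_stim), nrow = 8), 2,
                    function(u) rank(u, ties.method = "first") <= 4)
      h1 <- colSums(rate * pick) / 4
      h2 <- colSums(rate * !pick) / 4
      if (stats::sd(h1) == 0 || stats::sd(h2) == 0) return(NA_real_)
      r <- stats::cor(h1, h2)
      2 * r / (1 + r)
    }, numeric(1))
    if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
  })
}

#' Reliability-normalized correlation
#'
#' Divides a correlation between two response sets by the geometric mean of
#' their split-half reliabilities. Values above 1 can occur for noisy small
#' samples and are deliberately not clipped.
#'
#' @param r observed correlation.
#' @param rel_a,rel_b reliabilities of the two response sets (must be > 0;
#'   nonpositive reliabilities return `NA`, dropping the case).
#' @return the corrected correlation.
#' @examples
#' reliability_normalized_correlation(0.45, 0.9, 0.9)  # 0.5
#' @export
reliability_normalized_correlation <- function(r, rel_a, rel_b) {
  out <- r / sqrt(rel_a * rel_b)
  out[!(rel_a > 0 & rel_b > 0)] <- NA_real_
  out
}
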