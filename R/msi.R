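# Monkey-sum index: contrast between the net response to a whole monkey and
# the sum of the net responses to its isolated head and body at matched
# locations.

#' Monkey-sum index
#'
#' `MSI = (M - (B + H)) / (|M| + |B + H|)` for net responses to the whole
#' monkey (`M`), the isolated headless body (`B`) and the isolated head
#' (`H`). `-1` means the unit responds to the parts but not the whole;
#' `+1` the reverse; `0` exact additivity.
#'
#' @param M_net,B_net,H_net mean net responses (spikes/s); vectorized.
#' @return the index in `[-1, 1]`; `NA` when the denominator is 0 (the case
#'   is excluded).
#' @examples
#' msi(10, 4, 2)  # 0.25
#' @export
msi <- function(M_net, B_net, H_net) {
  denom <- abs(M_net) + abs(B_net + H_net)
  out <- (M_net - (B_net + H_net)) / denom
  out[denom == 0] <- NA_real_
  out
}

# Matched isolated head/body rows for a whole-monkey condition.  Under MC the
# head image follows the avatar configuration (anchor = the configuration's
# angle) and the body location is configuration-independent; under HC the
# roles are swapped.
.msi_matches <- function(conds, monkey_row) {
  a <- monkey_row$angle
  h <- monkey_row$head_orientation
  b <- monkey_row$body_orientation
  mc <- monkey_row$centering == "MC"
  same <- conds$pose == monkey_row$pose &
    conds$centering == monkey_row$centering &
    conds$inversion == monkey_row$inversion
  head_ok <- same & conds$part == "head" & conds$head_orientation == h &
    (if (mc) !is.na(conds$anchor_angle) & conds$anchor_angle == a
     else is.na(conds$anchor_angle))
  body_ok <- same & conds$part == "body" & conds$body_orientation == b &
    (if (mc) is.na(conds$anchor_angle)
     else !is.na(conds$anchor_angle) & conds$anchor_angle == a)
  list(head = which(head_ok), body = which(body_ok))
}

#' Case selection for the monkey-sum index
#'
#' A monkey/head/body case enters the MSI analysis when at least one of the
#' three images evokes a significant excitatory response: Wilcoxon rank-sum
#' test comparing the trial rates in the 100-ms baseline window against the
#' response window (p < alpha), with the mean response exceeding the mean
#' baseline.
#'
#' @param case_trials list with elements `monkey`, `head`, `body`, each a
#'   trial table (rates are computed if absent).
#' @param alpha significance level.
#' @return `TRUE` if the case is selected.
#' @export
msi_case_select <- function(case_trials, alpha = 0.05) {
  sig <- vapply(case_trials[c("monkey", "head", "body")], function(tr) {
    tr <- .with_rates(tr)
    if (nrow(tr) == 0) return(FALSE)
    if (stats::var(c(tr$baseline100_rate, tr$response_rate)) == 0) return(FALSE)
    p <- suppressWarnings(
      stats::wilcox.test(tr$response_rate, tr$baseline100_rate)$p.value)
    isTRUE(p < alpha) && mean(tr$response_rate) > mean(tr$baseline100_rate)
  }, logical(1))
  any(sig)
}

#' Monkey-sum indices for all matched cases of a population
#'
#' Finds every whole-monkey condition with matched isolated head and body
#' images (same pose, centering and locations), applies [msi_case_select()],
#' and computes the MSI from the mean net responses of the selected cases.
#'
#' @param trials trial table (one or more units).
#' @param alpha significance level of the case-selection Wilcoxon tests.
#' @return data frame with one row per selected unit/case: identifiers, the
#'   `M`, `B`, `H` mean net responses and `msi`. Cases with a zero MSI
#'   denominator are dropped.
#' @export
msi_table <- function(trials, alpha = 0.05) {
  trials <- .with_rates(trials)
  conds <- unique(trials[, c("pose", "part", "body_orientation",
                             "head_orientation", "anchor_angle",
                             "centering", "inversion", "angle")])
  rownames(conds) <- NULL
  monkeys <- which(conds$part == "monkey")
  matches <- lapply(monkeys, function(i) .msi_matches(conds, conds[i, ]))
  keep <- vapply(matches, function(m) {
    length(m$head) == 1 && length(m$body) == 1
  }, logical(1))
  monkeys <- monkeys[keep]
  matches <- matches[keep]
  if (length(monkeys) == 0) return(NULL)

  ckey <- condition_key(conds)
  tkey <- condition_key(trials)
  out <- list()
  for (u in unique(trials$unit_id)) {
    tru <- trials[trials$unit_id == u, , drop = FALSE]
    ku <- tkey[trials$unit_id == u]
    for (j in seq_along(monkeys)) {
      i <- monkeys[j]
      trs <- list(monkey = tru[ku == ckey[i], , drop = FALSE],
                  head = tru[ku == ckey[matches[[j]]$head], , drop = FALSE],
                  body = tru[ku == ckey[matches[[j]]$body], , drop = FALSE])
      if (any(vapply(trs, nrow, integer(1)) == 0)) next
      if (!msi_case_select(trs, alpha = alpha)) next
      M <- mean(trs$monkey$net_rate)
      H <- mean(trs$head$net_rate)
      B <- mean(trs$body$net_rate)
      out[[length(out) + 1]] <- data.frame(
        unit_id = u, pose = conds$pose[i], centering = conds$centering[i],
        inversion = conds$inversion[i],
        body_orientation = conds$body_orientation[i],
        angle = conds$angle[i],
        M = M, B = B, H = H, msi = msi(M, B, H),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res <- res[!is.na(res$msi), , drop = FALSE]
  rownames(res) <- NULL
  res
}
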