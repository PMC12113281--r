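# Sum-versus-configuration decoding: can the head-body angle be read out
# from the summed responses to the isolated head and body, or does it need
# their simultaneous presentation?

# Net-rate array over the whole-monkey conditions in `conds_monkey`, where
# each "trial" is the sum of the matched isolated-head and isolated-body net
# responses of the same trial index.
.summed_array <- function(trials, conds_monkey) {
  heads <- conds_monkey
  heads$part <- "head"
  heads$head_orientation <- (conds_monkey$body_orientation +
                               conds_monkey$angle) %% 360L
  heads$body_orientation <- NA_integer_
  heads$anchor_angle <- as.integer(wrap_signed(conds_monkey$angle))
  heads$angle <- NA_integer_
  # isolated bodies are shared across angles (their location does not depend
  # on the head), so build the array over the unique body conditions and
  # expand to one slice per configuration
  bodies <- conds_monkey
  bodies$part <- "body"
  bodies$head_orientation <- NA_integer_
  bodies$anchor_angle <- NA_integer_
  bodies$angle <- NA_integer_
  ub <- bodies[!duplicated(condition_key(bodies)), , drop = FALSE]
  ih <- .response_array(trials, heads, "net")
  ib <- .response_array(trials, ub, "net")
  body_of <- match(condition_key(bodies), condition_key(ub))
  list(heads = ih$A, bodies = ib$A, body_of = body_of, units = ih$units)
}

# Assemble one pseudo-population of head-body sums: trial slots are permuted
# at the level of the unique isolated-part stimuli (a body image shared by
# several configurations keeps one permutation), then matched head and body
# vectors are summed slot by slot.  Permuting per configuration instead
# would put a shared body trial in the training set of one class while it is
# being tested in the other, biasing accuracy below chance.
.assemble_sums <- function(sa, sel) {
  H <- .permute_slots(sa$heads[sel, , , drop = FALSE])
  B <- .permute_slots(sa$bodies[sel, , , drop = FALSE])
  H + B[, sa$body_of, , drop = FALSE]
}

#' Decode head-body angle from summed isolated-part responses
#'
#' For each head-body configuration, sums the net responses to the matched
#' isolated head and isolated body (presented at the same locations as in
#' the whole-monkey image) trial by trial, giving 8 head-body sums per
#' orientation and angle, and decodes the angle from these sums with the
#' same orientation-balanced procedure as [decode_angle_pair()]. Net rates
#' are used to avoid inflating the summed response with two baselines.
#'
#' @inheritParams decode_angle_pair
#' @return an `"hbo_decoding"` object.
#' @export
decode_from_sums <- function(trials, angles = c(0, 180), pose = "P1",
                             n_units = NULL, n_resamples = 100,
                             null_runs = 0, null_resamples = 1,
                             seed = NULL, cost = 1) {
  stopifnot(length(angles) == 2)
  tr <- trials[trials$pose == pose & trials$inversion == "upright", ,
               drop = FALSE]
  mono <- tr[tr$part == "monkey" & tr$angle %in% wrap_signed(angles), ,
             drop = FALSE]
  orientations <- sort(unique(mono$body_orientation))
  conds <- .angle_conds(pose, tr$centering[1], angles, orientations)
  sa <- .summed_array(tr, conds)
  class_idx <- lapply(wrap_signed(angles), function(a) which(conds$angle == a))

  run_once <- function(permute) {
    sel <- .draw_units(sa$units, n_units)
    A <- .assemble_sums(sa, sel)
    .decode_cv(A, A, class_idx, conds, same_assembly = TRUE,
               balanced = TRUE, permute = permute, cost = cost,
               check_balance = TRUE, identity_folds = TRUE)
  }
  acc <- vapply(seq_len(n_resamples), function(r) {
    if (!is.null(seed)) set.seed(sub_seed(seed, r))
    run_once(FALSE)
  }, numeric(1))
  null_acc <- numeric(0)
  if (null_runs > 0) {
    null_acc <- vapply(seq_len(null_runs), function(j) {
      mean(vapply(seq_len(null_resamples), function(m) {
        if (!is.null(seed)) set.seed(sub_seed(seed, 100000 + j * 97 + m))
        run_once(TRUE)
      }, numeric(1)))
    }, numeric(1))
  }
  .new_decoding(acc, null_acc, n_classes = 2,
                spec = list(angles = angles, pose = pose,
                            response_kind = "summed_net",
                            n_units = n_units, seed = seed))
}

#' Paired sum-versus-configuration decoding contrast
#'
#' Decodes a head-body angle pair from (a) the net responses to the
#' whole-monkey configurations and (b) the summed net responses to the
#' matched isolated parts, drawing the same units per resampling, and
#' compares the paired accuracies with [compare_decodings()].
#'
#' @inheritParams decode_angle_pair
#' @return list with the two `"hbo_decoding"` objects (`config`, `sum`),
#'   the paired difference vector, and `p` (percentile of a zero
#'   difference; configuration > sum gives p near 0).
#' @export
decode_sum_vs_config <- function(trials, angles = c(0, 180), pose = "P1",
                                 n_units = NULL, n_resamples = 100,
                                 seed = NULL, cost = 1) {
  cfg <- decode_angle_pair(trials, angles = angles, pose = pose,
                           response_kind = "net", n_units = n_units,
                           n_resamples = n_resamples, seed = seed,
                           cost = cost)
  sm <- decode_from_sums(trials, angles = angles, pose = pose,
                         n_units = n_units, n_resamples = n_resamples,
                         seed = seed, cost = cost)
  cmp <- compare_decodings(cfg, sm)
  list(config = cfg, sum = sm, diffs = cmp$diffs, p = cmp$p)
}
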