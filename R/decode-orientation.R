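# Multiclass decoding of whole-monkey orientation and the body-inversion
# contrast.

#' Decode the orientation of the whole monkey
#'
#' Eight-way classification of the avatar's orientation from
#' pseudo-population vectors of the zero-angle head-body configurations,
#' separately for upright or inverted stimuli. Eightfold cross-validation
#' uses 7 trials per orientation for training and one for testing; the
#' multiclass linear SVM uses one-vs-one voting. Units (default 60,
#' subject-balanced) are redrawn per resampling.
#'
#' @param trials trial table.
#' @param pose avatar pose.
#' @param inversion `"upright"` or `"inverted"`.
#' @param angle head-body angle of the decoded configurations (default 0).
#' @param n_units units per resampling (subject-balanced); `NULL` = all.
#' @param n_resamples number of resamplings.
#' @param null_runs,null_resamples optional permutation null (chance is
#'   1/8).
#' @param response_kind `"raw"` or `"net"`.
#' @param seed master seed.
#' @param cost SVM regularization parameter.
#' @return an `"hbo_decoding"` object (`n_classes = 8`).
#' @export
decode_orientation <- function(trials, pose = "P1", inversion = "upright",
                               angle = 0, n_units = 60, n_resamples = 100,
                               null_runs = 0, null_resamples = 1,
                               response_kind = "raw", seed = NULL, cost = 1) {
  tr <- trials[trials$part == "monkey" & trials$pose == pose &
                 trials$inversion == inversion &
                 trials$angle == wrap_signed(angle), , drop = FALSE]
  if (nrow(tr) == 0) stop("no trials for the requested configuration")
  orientations <- sort(unique(tr$body_orientation))
  conds <- .angle_conds(pose, tr$centering[1], angle, orientations, inversion)
  ra <- .response_array(tr, conds, response_kind)
  if (!is.null(n_units) && nrow(ra$units) < n_units) {
    stop("fewer units than n_units")
  }
  class_idx <- as.list(seq_len(nrow(conds)))

  run_once <- function(permute) {
    sel <- .draw_units(ra$units, n_units)
    A <- .permute_slots(ra$A[sel, , , drop = FALSE])
    .decode_cv(A, A, class_idx, conds, same_assembly = TRUE,
               balanced = TRUE, permute = permute, cost = cost,
               check_balance = FALSE)
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
  .new_decoding(acc, null_acc, n_classes = length(class_idx),
                spec = list(pose = pose, inversion = inversion,
                            angle = angle, n_units = n_units,
                            response_kind = response_kind, seed = seed))
}

#' Upright versus inverted orientation-decoding contrast
#'
#' Runs the eight-way orientation decoding of [decode_orientation()] for
#' upright and inverted stimuli with the same unit draw per resampling, and
#' summarizes the inversion effect with the distribution of differences of
#' mean accuracies computed over groups of `group_size` resamplings (the
#' study used means of 10). An inversion effect is supported when zero lies
#' outside that difference distribution.
#'
#' @inheritParams decode_orientation
#' @param group_size resamplings averaged per difference value.
#' @return list with the two accuracy vectors, their means, the grouped
#'   `diff_distribution`, and `zero_outside` (is 0 outside its range?).
#' @export
decode_inversion_effect <- function(trials, pose = "P1", angle = 0,
                                    n_units = 60, n_resamples = 100,
                                    group_size = 10, response_kind = "raw",
                                    seed = NULL, cost = 1) {
  res_up <- decode_orientation(trials, pose, "upright", angle, n_units,
                               n_resamples, response_kind = response_kind,
                               seed = seed, cost = cost)
  res_inv <- decode_orientation(trials, pose, "inverted", angle, n_units,
                                n_resamples, response_kind = response_kind,
                                seed = seed, cost = cost)
  d <- res_up$accuracies - res_inv$accuracies
  n_groups <- length(d) %/% group_size
  gm <- vapply(seq_len(n_groups), function(g) {
    mean(d[((g - 1) * group_size + 1):(g * group_size)])
  }, numeric(1))
  list(upright = res_up, inverted = res_inv,
       mean_upright = res_up$mean, mean_inverted = res_inv$mean,
       diff_distribution = gm,
       zero_outside = all(gm > 0) || all(gm < 0))
}
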