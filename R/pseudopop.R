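# Pseudo-population assembly: population response vectors built from
# non-simultaneously recorded units by independently permuting each unit's
# trials per stimulus.

# Dense response array [unit x stimulus x trial] from a trial table.
# `value` is the raw response rate or the net rate.
.response_array <- function(trials, conds, response_kind = c("raw", "net"),
                            n_trials = 8) {
  response_kind <- match.arg(response_kind)
  trials <- .with_rates(trials)
  value <- if (response_kind == "raw") trials$response_rate else trials$net_rate
  units <- unique(trials[, intersect(c("unit_id", "subject", "region"),
                                     names(trials)), drop = FALSE])
  units <- units[!duplicated(units$unit_id), , drop = FALSE]
  rownames(units) <- NULL
  ckey <- condition_key(conds)
  si <- match(condition_key(trials), ckey)
  ui <- match(trials$unit_id, units$unit_id)
  keep <- !is.na(si)
  if (any(trials$trial_index[keep] > n_trials)) {
    stop("more than ", n_trials, " trials per condition")
  }
  A <- array(NA_real_, dim = c(nrow(units), length(ckey), n_trials))
  A[cbind(ui[keep], si[keep], trials$trial_index[keep])] <- value[keep]
  if (anyNA(A)) stop("every unit needs ", n_trials, " trials for every condition")
  list(A = A, units = units, conds = conds)
}

# Independently permute the trial slots of each (unit, stimulus) cell: after
# this, slot t across units is one pseudo-population vector per stimulus.
.permute_slots <- function(A) {
  d <- dim(A)
  for (s in seq_len(d[2])) {
    for (u in seq_len(d[1])) {
      A[u, s, ] <- A[u, s, sample.int(d[3])]
    }
  }
  A
}

# Rows matrix for a stimulus subset: [(n_stims * n_slots) x n_units], with
# the stimulus index varying fastest, then the slot.
.rows_matrix <- function(A, stims) {
  sub <- A[, stims, , drop = FALSE]
  t(matrix(sub, nrow = dim(A)[1]))
}

#' Assemble a pseudo-population from a trial table
#'
#' For every stimulus condition, builds 8 population response vectors by
#' permuting the order of each unit's 8 trials independently, so that every
#' unit contributes exactly one trial to each vector. A fresh assembly is
#' drawn per decoding resampling; this function exposes one assembly for
#' inspection and testing.
#'
#' @param trials trial table (all units must have 8 trials per condition).
#' @param conditions data frame of stimulus conditions to include; defaults
#'   to all conditions present.
#' @param response_kind `"raw"` response rates or `"net"` rates.
#' @param seed optional seed.
#' @return object of class `"pseudopopulation"`: list with `vectors` (array
#'   unit x stimulus x vector-slot), `units` and `conditions`.
#' @export
build_pseudopopulation <- function(trials, conditions = NULL,
                                   response_kind = "raw", seed = NULL) {
  if (is.null(conditions)) {
    conditions <- unique(trials[, c("pose", "part", "body_orientation",
                                    "head_orientation", "anchor_angle",
                                    "centering", "inversion", "angle")])
    rownames(conditions) <- NULL
  }
  ra <- .response_array(trials, conditions, response_kind)
  with_seed(seed, {
    structure(list(vectors = .permute_slots(ra$A), units = ra$units,
                   conditions = ra$conds),
              class = "pseudopopulation")
  })
}

#' @export
print.pseudopopulation <- function(x, ...) {
  cat(sprintf("pseudo-population: %d units x %d stimuli x %d vectors\n",
              dim(x$vectors)[1], dim(x$vectors)[2], dim(x$vectors)[3]))
  invisible(x)
}

#' Orientation-balanced cross-validation folds
#'
#' Builds the eightfold cross-validation used for head-body angle decoding:
#' for each class, every stimulus (orientation) contributes exactly one of
#' its 8 trials to each fold's test set, so each fold trains on 7 trials per
#' orientation per class (56 with 8 orientations, 28 with 4) and tests on
#' one. The function first enforces the anti-artifact guard: the two classes
#' must contain identical multisets of head orientations and of body
#' orientations, otherwise orientation imbalance can produce spurious
#' (including below-chance) accuracies.
#'
#' @param class_stims list of two data frames (one per class) with
#'   `head_orientation` and `body_orientation` columns, one row per stimulus.
#' @param n_trials trials per stimulus (folds = `n_trials`).
#' @return list of two integer matrices `[n_stimuli x n_trials]`; entry
#'   `(i, t)` is the fold in which trial slot `t` of stimulus `i` is tested.
#'   Each row is a permutation of `1:n_trials`.
#' @export
balanced_folds <- function(class_stims, n_trials = 8) {
  stopifnot(length(class_stims) == 2)
  h1 <- sort(class_stims[[1]]$head_orientation)
  h2 <- sort(class_stims[[2]]$head_orientation)
  b1 <- sort(class_stims[[1]]$body_orientation)
  b2 <- sort(class_stims[[2]]$body_orientation)
  if (!identical(h1, h2) || !identical(b1, b2)) {
    stop("unbalanced classes: head and body orientations must form ",
         "identical multisets in both classes")
  }
  lapply(class_stims, function(s) {
    t(vapply(seq_len(nrow(s)), function(i) sample.int(n_trials),
             integer(n_trials)))
  })
}
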