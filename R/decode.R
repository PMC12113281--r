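# Pseudo-population decoding of head-body configuration angle and of
# whole-monkey orientation with a linear SVM (cost C = 1), orientation-
# balanced eightfold cross-validation, and permutation null distributions.

.svm_predict <- function(Xtr, ytr, Xte, cost) {
  ytr <- factor(ytr)
  # features are standardized within the training set (numerical
  # conditioning; the SMO solver converges orders of magnitude faster on
  # near-inseparable problems); the learned scaling is applied to the test
  # vectors by predict()
  fit <- try(suppressWarnings(
    e1071::svm(Xtr, ytr, kernel = "linear", cost = cost,
               scale = TRUE, type = "C-classification")),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate training set (e.g. identical classes): deterministic
    # first-class prediction; accuracy then sits at chance by symmetry
    factor(rep(levels(ytr)[1], nrow(Xte)), levels = levels(ytr))
  } else {
    predict(fit, Xte)
  }
}

# Per-class fold vector for rows ordered (stimulus fastest, then slot).
.fold_vector <- function(fold_mats, n_per_class, n_slots) {
  unlist(lapply(fold_mats, as.vector), use.names = FALSE)
}

# Eightfold cross-validated accuracy for K classes of stimuli.
# A_tr / A_te: [unit x stim x slot] arrays, already unit-subset and
# slot-permuted; identical objects for within-centering decoding (the folds
# are then shared so no assembled vector is both trained and tested on).
.decode_cv <- function(A_tr, A_te, class_idx, conds, same_assembly,
                       balanced = TRUE, permute = FALSE, cost = 1,
                       check_balance = TRUE, identity_folds = FALSE) {
  n_slots <- dim(A_tr)[3]
  K <- length(class_idx)
  Xtr <- do.call(rbind, lapply(class_idx, function(ix) .rows_matrix(A_tr, ix)))
  Xte <- if (same_assembly) Xtr else
    do.call(rbind, lapply(class_idx, function(ix) .rows_matrix(A_te, ix)))
  n_stims <- vapply(class_idx, length, integer(1))
  y <- factor(rep(paste0("c", seq_len(K)), n_stims * n_slots))

  draw_folds <- function(y_use) {
    folds <- integer(length(y_use))
    if (permute) {
      for (lv in levels(y_use)) {
        rows <- which(y_use == lv)
        folds[rows] <- sample(rep_len(seq_len(n_slots), length(rows)))
      }
    } else if (balanced) {
      if (identity_folds) {
        # fold = assembly slot, shared across classes; required when the
        # classes reuse trials of shared stimuli (head-body sums), so that a
        # shared trial is never trained on in one class while being tested
        # in the other
        if (check_balance) {
          balanced_folds(lapply(class_idx, function(ix) conds[ix, ]),
                         n_trials = n_slots)
        }
        fm <- lapply(n_stims, function(ns) {
          matrix(rep(seq_len(n_slots), each = ns), nrow = ns)
        })
      } else if (check_balance) {
        fm <- balanced_folds(lapply(class_idx, function(ix) conds[ix, ]),
                             n_trials = n_slots)
      } else {
        fm <- lapply(n_stims, function(ns) {
          t(vapply(seq_len(ns), function(i) sample.int(n_slots),
                   integer(n_slots)))
        })
      }
      folds <- .fold_vector(fm, n_stims * n_slots, n_slots)
    } else {
      # deliberately unbalanced folds (artifact demonstration): each fold
      # holds out one whole orientation per class, staggered between the
      # classes, so the training sets over-represent different orientations
      # in the two classes
      off <- 0L
      for (k in seq_len(K)) {
        ns <- n_stims[k]
        shift <- ((k - 1) * (ns %/% 2))
        block <- n_slots %/% ns   # 1 when 8 orientations, 2 when 4
        fm <- matrix(0L, nrow = ns, ncol = n_slots)
        for (t in seq_len(n_slots)) {
          for (i in seq_len(ns)) {
            b <- (t - 1) %/% ns
            fm[i, t] <- (((i - 1 + shift) %% ns) + b * ns + 1L)
          }
        }
        if (block < 1) fm <- t(vapply(seq_len(ns), function(i)
          sample.int(n_slots), integer(n_slots)))
        folds[off + seq_len(ns * n_slots)] <- as.vector(fm)
        off <- off + ns * n_slots
      }
    }
    folds
  }

  y_use <- if (permute) sample(y) else y
  folds_tr <- draw_folds(y_use)
  folds_te <- if (same_assembly) folds_tr else draw_folds(y_use)

  correct <- 0L
  total <- 0L
  for (k in seq_len(n_slots)) {
    tr <- folds_tr != k
    te <- folds_te == k
    pred <- .svm_predict(Xtr[tr, , drop = FALSE], y_use[tr],
                         Xte[te, , drop = FALSE], cost)
    correct <- correct + sum(pred == y_use[te])
    total <- total + sum(te)
  }
  correct / total
}

# Single-fit transfer decoding: train on one stimulus set, test on a
# disjoint one (cross-orientation and/or cross-centering generalization).
.decode_transfer <- function(A_tr, A_te, train_idx, test_idx, conds,
                             permute = FALSE, cost = 1,
                             check_balance = TRUE) {
  n_slots <- dim(A_tr)[3]
  if (check_balance) {
    balanced_folds(lapply(train_idx, function(ix) conds[ix, ]), n_slots)
    balanced_folds(lapply(test_idx, function(ix) conds[ix, ]), n_slots)
  }
  K <- length(train_idx)
  Xtr <- do.call(rbind, lapply(train_idx, function(ix) .rows_matrix(A_tr, ix)))
  Xte <- do.call(rbind, lapply(test_idx, function(ix) .rows_matrix(A_te, ix)))
  ytr <- factor(rep(paste0("c", seq_len(K)),
                    vapply(train_idx, length, integer(1)) * n_slots))
  yte <- factor(rep(paste0("c", seq_len(K)),
                    vapply(test_idx, length, integer(1)) * n_slots),
                levels = levels(ytr))
  if (permute) ytr <- sample(ytr)
  mean(.svm_predict(Xtr, ytr, Xte, cost) == yte)
}

# Subject-balanced unit draw; returns row indices into `units`.
.draw_units <- function(units, n_units) {
  if (is.null(n_units)) return(seq_len(nrow(units)))
  subjects <- unique(units$subject)
  per <- n_units / length(subjects)
  if (per != round(per)) stop("n_units must be divisible by the number of subjects")
  idx <- unlist(lapply(subjects, function(s) {
    pool <- which(units$subject == s)
    if (length(pool) < per) stop("not enough units for subject ", s)
    sample(pool, per)
  }))
  sort(idx)
}

.new_decoding <- function(accuracies, null_accuracies, n_classes, spec) {
  structure(list(accuracies = accuracies,
                 mean = mean(accuracies),
                 sd = stats::sd(accuracies),
                 null_accuracies = null_accuracies,
                 null_band = if (length(null_accuracies)) range(null_accuracies) else NULL,
                 n_classes = n_classes,
                 spec = spec),
            class = "hbo_decoding")
}

#' @export
print.hbo_decoding <- function(x, ...) {
  cat(sprintf("decoding accuracy: %.3f (sd %.3f, %d resamplings, chance %.3f)\n",
              x$mean, x$sd, length(x$accuracies), 1 / x$n_classes))
  if (!is.null(x$null_band)) {
    cat(sprintf("  permutation null band (%d runs): [%.3f, %.3f]\n",
                length(x$null_accuracies), x$null_band[1], x$null_band[2]))
  }
  invisible(x)
}

# Whole-monkey condition frame for a set of angles/orientations.
.angle_conds <- function(pose, centering, angles, orientations,
                         inversion = "upright") {
  g <- expand.grid(body_orientation = orientations, angle = angles,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(pose = pose, part = "monkey",
             body_orientation = as.integer(g$body_orientation),
             head_orientation = as.integer((g$body_orientation + g$angle) %% 360),
             anchor_angle = NA_integer_,
             centering = centering, inversion = inversion,
             angle = as.integer(wrap_signed(g$angle)))
}

#' Decode a pair of head-body configuration angles
#'
#' Linear-SVM (cost 1) classification of two head-body angle classes from
#' pseudo-population vectors, pooling all available orientations of each
#' angle so that only the head-body conjunction - not either part's
#' orientation alone - separates the classes. Uses orientation-balanced
#' eightfold cross-validation ([balanced_folds()]); training can use one
#' centering and testing the other (`test_centering`), and training and
#' testing can use disjoint orientation sets (`train_orientations` /
#' `test_orientations`, e.g. the '+' versus 'x' views), in which case a
#' single classifier is trained on all trials of the training set and
#' evaluated on all trials of the test set.
#'
#' Setting `null_runs > 0` additionally computes a permutation null
#' distribution: per run, class labels of the pooled trials are permuted and
#' the identical pipeline is re-run (units re-drawn per run); each run
#' reports the mean of `null_resamples` resamplings.
#'
#' @param trials trial table (upright whole-monkey conditions are used).
#' @param angles length-2 vector of signed angles (degrees).
#' @param pose avatar pose.
#' @param train_centering,test_centering centering used for the training and
#'   test vectors.
#' @param train_orientations,test_orientations optional disjoint orientation
#'   sets for transfer decoding; `NULL` pools all orientations with
#'   cross-validation.
#' @param response_kind `"raw"` rates (experiment-1 convention) or `"net"`
#'   rates (experiment-2 convention).
#' @param n_units units drawn per resampling, balanced across subjects;
#'   `NULL` uses every unit.
#' @param n_resamples number of resamplings (fresh unit draw and
#'   pseudo-population assembly each).
#' @param null_runs,null_resamples permutation-null settings (see above).
#' @param balanced use orientation-balanced folds; `FALSE` deliberately
#'   ignores orientation when folding, demonstrating the unbalancing
#'   artifact.
#' @param seed master seed; per-resampling sub-seeds are derived from it so
#'   unit draws are shared across decodings run with the same seed.
#' @param cost SVM regularization parameter.
#' @return an object of class `"hbo_decoding"` with per-resampling
#'   accuracies, their mean/sd, and (optionally) the null accuracies and
#'   their min-max band.
#' @export
decode_angle_pair <- function(trials, angles = c(0, 180), pose = "P1",
                              train_centering = "MC",
                              test_centering = train_centering,
                              train_orientations = NULL,
                              test_orientations = NULL,
                              response_kind = "raw",
                              n_units = NULL, n_resamples = 100,
                              null_runs = 0, null_resamples = 1,
                              balanced = TRUE, seed = NULL, cost = 1) {
  stopifnot(length(angles) == 2)
  if (is.null(train_orientations) != is.null(test_orientations)) {
    stop("train_orientations and test_orientations must be given together")
  }
  transfer <- !is.null(train_orientations)
  tr <- trials[trials$part == "monkey" & trials$pose == pose &
                 trials$inversion == "upright" &
                 trials$angle %in% wrap_signed(angles), , drop = FALSE]
  orientations <- sort(unique(tr$body_orientation))
  centerings <- unique(c(train_centering, test_centering))
  conds_list <- lapply(centerings, function(ct)
    .angle_conds(pose, ct, angles, orientations))
  arrays <- lapply(seq_along(centerings), function(i)
    .response_array(tr[tr$centering == centerings[i], , drop = FALSE],
                    conds_list[[i]], response_kind))
  units <- arrays[[1]]$units
  conds <- conds_list[[1]]
  i_tr <- match(train_centering, centerings)
  i_te <- match(test_centering, centerings)
  same <- train_centering == test_centering

  class_sets <- function(orients) {
    lapply(wrap_signed(angles), function(a)
      which(conds$angle == a & conds$body_orientation %in% orients))
  }

  run_once <- function(permute) {
    sel <- .draw_units(units, n_units)
    A1 <- .permute_slots(arrays[[i_tr]]$A[sel, , , drop = FALSE])
    A2 <- if (same) A1 else .permute_slots(arrays[[i_te]]$A[sel, , , drop = FALSE])
    if (transfer) {
      .decode_transfer(A1, A2, class_sets(train_orientations),
                       class_sets(test_orientations), conds,
                       permute = permute, cost = cost,
                       check_balance = balanced)
    } else {
      .decode_cv(A1, A2, class_sets(orientations), conds,
                 same_assembly = same, balanced = balanced,
                 permute = permute, cost = cost, check_balance = balanced)
    }
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
                            train_centering = train_centering,
                            test_centering = test_centering,
                            train_orientations = train_orientations,
                            test_orientations = test_orientations,
                            response_kind = response_kind,
                            n_units = n_units, balanced = balanced,
                            seed = seed))
}

#' Permutation null distribution for a decoding specification
#'
#' Re-runs a decoding with the class labels of the pooled trials permuted
#' before training, `n_runs` times; each run's value is the mean accuracy of
#' `n_resamples` resamplings. The min-max range of the run means is the
#' null band drawn as the shaded area in the study's figures.
#'
#' @param trials trial table.
#' @param ... passed to `decoder` (contrast, centerings, `n_units`, ...).
#' @param n_runs number of permutation runs.
#' @param n_resamples resamplings averaged within each run.
#' @param seed master seed.
#' @param decoder decoding function supporting `null_runs` /
#'   `null_resamples` ([decode_angle_pair()] or [decode_orientation()]).
#' @return object of class `"hbo_null"`: the run means and their `band`.
#' @export
permutation_null <- function(trials, ..., n_runs = 200, n_resamples = 1,
                             seed = NULL, decoder = decode_angle_pair) {
  res <- decoder(trials, ..., n_resamples = 1, null_runs = n_runs,
                 null_resamples = n_resamples, seed = seed)
  structure(list(null_accuracies = res$null_accuracies,
                 band = res$null_band, n_runs = n_runs),
            class = "hbo_null")
}

#' @export
print.hbo_null <- function(x, ...) {
  cat(sprintf("permutation null: %d runs, mean %.3f, band [%.3f, %.3f]\n",
              x$n_runs, mean(x$null_accuracies), x$band[1], x$band[2]))
  invisible(x)
}

#' Resampling-based comparison of two decodings
#'
#' Computes the per-resampling accuracy differences between two decodings
#' run with the same unit draws per resampling (same master seed and
#' roster), and returns the percentile of a zero difference, which serves as
#' the p-value; two-tailed significance requires p below 0.025 (or above
#' 0.975).
#'
#' @param result_a,result_b `"hbo_decoding"` objects with paired
#'   resamplings.
#' @return list with the difference vector `diffs` and `p`.
#' @export
compare_decodings <- function(result_a, result_b) {
  if (length(result_a$accuracies) != length(result_b$accuracies)) {
    stop("decodings must have the same number of (paired) resamplings")
  }
  sa <- result_a$spec$seed
  sb <- result_b$spec$seed
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("decodings were not run with the same master seed; resamplings are not paired")
  }
  d <- result_a$accuracies - result_b$accuracies
  p <- mean(d < 0) + 0.5 * mean(d == 0)
  list(diffs = d, p = p)
}
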