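# Head-by-body interaction ANOVA and the additive-model residuals that
# isolate the interaction structure of a unit's 8 x 8 orientation tuning.

#' Variance-stabilizing transform for Poisson-like spike counts
#'
#' `sqrt(count + 3/8)` (Anscombe), applied to per-trial response-window
#' counts before the two-way ANOVA so the error variance is approximately
#' constant across conditions.
#'
#' @param count nonnegative spike counts.
#' @return transformed values.
#' @examples
#' variance_stabilize(13 / 8)  # sqrt(2)
#' @export
variance_stabilize <- function(count) {
  if (any(count < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  sqrt(count + 3 / 8)
}

#' Additive-model residuals of an orientation response matrix
#'
#' For a matrix of mean responses with body orientation in rows and head
#' orientation in columns, the additive model predicts cell `(i, j)` as
#' `body mean(i) + head mean(j) - grand mean`. The residuals quantify the
#' conjunctive (interaction) structure; their row and column means are zero
#' by construction and the operator is idempotent.
#'
#' @param mean_matrix numeric matrix (8 x 8 in the orientation experiments).
#' @return matrix of residuals with the same dimensions.
#' @export
additive_residuals <- function(mean_matrix) {
  m <- as.matrix(mean_matrix)
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}

#' Two-way head-by-body orientation ANOVA for one unit
#'
#' Fits a two-way fixed-effects ANOVA on the per-trial response-window spike
#' counts of the 64 whole-monkey conditions of one pose and centering, with
#' factors head and body orientation. Counts are variance-stabilized with
#' [variance_stabilize()] by default (set `transform = FALSE` for raw
#' counts). Also returns the 8 x 8 matrix of mean (transformed) responses
#' and its additive-model residuals.
#'
#' @param unit_trials trial table of one unit.
#' @param pose,centering condition selectors.
#' @param transform apply the square-root transform before the ANOVA.
#' @return object of class `"headbody_anova"`: list with `p_body`, `p_head`,
#'   `p_interaction`, `means` (body orientation in rows, head in columns) and
#'   `residuals`.
#' @export
headbody_anova <- function(unit_trials, pose = "P1", centering = "MC",
                           transform = TRUE) {
  tr <- unit_trials[unit_trials$part == "monkey" &
                      unit_trials$pose == pose &
                      unit_trials$centering == centering &
                      unit_trials$inversion == "upright", , drop = FALSE]
  cells <- table(tr$body_orientation, tr$head_orientation)
  if (!all(dim(cells) == c(8, 8)) || any(cells == 0)) {
    stop("need trials for all 64 head-body conditions of the pose/centering")
  }
  y <- if (transform) variance_stabilize(tr$response_count) else tr$response_count
  head_f <- factor(tr$head_orientation, levels = ORIENTATIONS8)
  body_f <- factor(tr$body_orientation, levels = ORIENTATIONS8)
  tab <- summary(stats::aov(y ~ head_f * body_f))[[1]]
  rn <- trimws(rownames(tab))
  means <- tapply(y, list(body_f, head_f), mean)
  res <- list(p_head = tab[match("head_f", rn), "Pr(>F)"],
              p_body = tab[match("body_f", rn), "Pr(>F)"],
              p_interaction = tab[match("head_f:body_f", rn), "Pr(>F)"],
              means = means,
              residuals = additive_residuals(means),
              pose = pose, centering = centering, transform = transform)
  class(res) <- "headbody_anova"
  res
}

#' @export
print.headbody_anova <- function(x, ...) {
  cat(sprintf("head x body orientation ANOVA (%s, %s, %s counts)\n",
              x$pose, x$centering,
              if (x$transform) "sqrt-transformed" else "raw"))
  cat(sprintf("  p(head) = %.4g, p(body) = %.4g, p(interaction) = %.4g\n",
              x$p_head, x$p_body, x$p_interaction))
  invisible(x)
}

#' Correlation of orientation tuning across centerings
#'
#' Pearson correlation, across the 64 head-body conditions of one pose,
#' between the per-condition mean net responses under monkey- and
#' head-centered presentation. High values indicate position-tolerant
#' orientation tuning.
#'
#' @param unit_trials trial table of one unit (both centerings present).
#' @param pose condition selector.
#' @return the correlation, or `NA` if either centering's responses have
#'   zero variance (the case is dropped).
#' @export
centering_correlation <- function(unit_trials, pose = "P1") {
  tr <- .with_rates(unit_trials)
  tr <- tr[tr$part == "monkey" & tr$pose == pose &
             tr$inversion == "upright", , drop = FALSE]
  vecs <- lapply(c("MC", "HC"), function(ct) {
    sub <- tr[tr$centering == ct, , drop = FALSE]
    m <- tapply(sub$net_rate, list(factor(sub$body_orientation, ORIENTATIONS8),
                                   factor(sub$head_orientation, ORIENTATIONS8)),
                mean)
    as.vector(m)
  })
  if (anyNA(vecs[[1]]) || anyNA(vecs[[2]])) {
    stop("both centerings must cover all 64 conditions")
  }
  if (stats::sd(vecs[[1]]) == 0 || stats::sd(vecs[[2]]) == 0) return(NA_real_)
  stats::cor(vecs[[1]], vecs[[2]])
}

#' Correlation of additive-model residuals across centerings
#'
#' Pearson correlation between the 64-element additive-model residual
#' vectors of the two centerings, isolating whether the conjunctive part of
#' the tuning is position tolerant. Intended for units with a significant
#' head-by-body interaction in both centerings.
#'
#' @inheritParams centering_correlation
#' @param transform passed to [headbody_anova()].
#' @return the correlation (`NA` if either residual vector is degenerate).
#' @export
residual_correlation <- function(unit_trials, pose = "P1", transform = TRUE) {
  r_mc <- headbody_anova(unit_trials, pose, "MC", transform)$residuals
  r_hc <- headbody_anova(unit_trials, pose, "HC", transform)$residuals
  if (stats::sd(r_mc) == 0 || stats::sd(r_hc) == 0) return(NA_real_)
  stats::cor(as.vector(r_mc), as.vector(r_hc))
}
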