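# Mirror-symmetry analysis of marginal head and body orientation tuning via
# correlation-distance matrices.

#' Max-normalized marginal orientation tuning of one unit
#'
#' From a unit's 8 x 8 matrix of mean responses (body orientation in rows,
#' head orientation in columns), first normalizes by the unit's maximum over
#' the 64 stimuli and then averages the 8 conditions sharing each head (or
#' body) orientation. The order - normalize, then average - is fixed;
#' averaging first gives different values for non-uniform responses.
#'
#' @param unit_matrix 8 x 8 mean-response matrix.
#' @param axis `"head"` (average over body orientations) or `"body"`.
#' @return length-8 vector of marginal tuning values (`<= 1`), or `NULL`
#'   when the unit's maximum response is not positive (unit excluded).
#' @export
marginal_tuning <- function(unit_matrix, axis = c("head", "body")) {
  axis <- match.arg(axis)
  m <- as.matrix(unit_matrix)
  stopifnot(all(dim(m) == c(8, 8)))
  mx <- max(m)
  if (!(mx > 0)) return(NULL)
  m <- m / mx
  if (axis == "head") colMeans(m) else rowMeans(m)
}

#' Population marginal tuning matrix
#'
#' Computes the per-unit mean net responses to the 64 head-body conditions
#' of one pose and centering, and stacks the [marginal_tuning()] vectors of
#' all includable units.
#'
#' @param trials trial table (several units).
#' @param axis `"head"` or `"body"`.
#' @param pose,centering condition selectors.
#' @return matrix `[units x 8]` with orientation (degrees) as column names;
#'   units with nonpositive maximum response are dropped.
#' @export
population_marginals <- function(trials, axis = c("head", "body"),
                                 pose = "P1", centering = "MC") {
  axis <- match.arg(axis)
  trials <- .with_rates(trials)
  tr <- trials[trials$part == "monkey" & trials$pose == pose &
                 trials$centering == centering &
                 trials$inversion == "upright", , drop = FALSE]
  units <- unique(tr$unit_id)
  rows <- lapply(units, function(u) {
    sub <- tr[tr$unit_id == u, , drop = FALSE]
    m <- tapply(sub$net_rate,
                list(factor(sub$body_orientation, ORIENTATIONS8),
                     factor(sub$head_orientation, ORIENTATIONS8)),
                mean)
    if (anyNA(m)) stop("unit ", u, " lacks some of the 64 conditions")
    marginal_tuning(m, axis)
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  rownames(out) <- units[keep]
  colnames(out) <- ORIENTATIONS8
  out
}

#' Mirror-symmetry distance matrix over orientations
#'
#' For each pair of orientations, computes `1 - Pearson r` between the
#' population vectors (one marginal-tuning value per unit) of the two
#' orientations. Mirror-symmetric tuning shows up as small distances
#' between left/right reflected orientations (e.g. 90 and 270 degrees).
#'
#' @param population_marginals matrix `[units x 8]` from
#'   [population_marginals()].
#' @return symmetric 8 x 8 matrix with zero diagonal and entries in
#'   `[0, 2]`; entries are `NA` when a column has zero variance across
#'   units.
#' @export
mirror_distance_matrix <- function(population_marginals) {
  m <- as.matrix(population_marginals)
  if (nrow(m) < 2) stop("need at least 2 units")
  sds <- apply(m, 2, stats::sd)
  d <- 1 - suppressWarnings(stats::cor(m))
  d[sds == 0, ] <- NA_real_
  d[, sds == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(colnames(population_marginals),
                      colnames(population_marginals))
  d
}
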