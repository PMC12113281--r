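#' Signed head-body angle
#'
#' The head-body configuration angle is the angular difference between the
#' head and the body orientation about the vertical axis, wrapped into
#' `(-180, 180]` degrees. `0` is an aligned (zero-angle) configuration,
#' `180` the anatomically impossible straight angle, and `+90`/`-90` the
#' rightward and leftward right angles.
#'
#' @param head_orientation,body_orientation orientations in degrees; both
#'   must be multiples of 45 (the stimulus grid step).
#' @return signed angle in degrees, in `(-180, 180]`; `180`, never `-180`,
#'   is returned for the straight angle.
#' @examples
#' signed_angle(90, 0)   # rightward right angle
#' signed_angle(0, 45)   # -45
#' @export
signed_angle <- function(head_orientation, body_orientation) {
  if (!all(is_grid_orientation(head_orientation)) ||
      !all(is_grid_orientation(body_orientation))) {
    stop("orientations must be non-missing multiples of 45 degrees")
  }
  wrap_signed(head_orientation - body_orientation)
}

# Isolated-part rows for the monkey-centered designs: four headless bodies
# (location independent of the head) plus heads taken from the configurations
# with the given angles, positioned to match their source avatar.  The
# `anchor_angle` column records the source configuration's head-body angle and
# stands in for the screen location that distinguishes otherwise identical
# part images.
.isolated_mc <- function(angles) {
  bodies <- data.frame(part = "body",
                       body_orientation = ORIENTATIONS4,
                       head_orientation = NA_integer_,
                       anchor_angle = NA_integer_)
  grid <- expand.grid(anchor_angle = angles, o = ORIENTATIONS4,
                      KEEP.OUT.ATTRS = FALSE)
  heads <- data.frame(part = "head",
                      body_orientation = NA_integer_,
                      head_orientation = (grid$o + grid$anchor_angle) %% 360L,
                      anchor_angle = grid$anchor_angle)
  rbind(bodies, heads)
}

# Head-centered counterpart: four heads (at the fixated location) and bodies
# from the zero- and straight-angle configurations of each head orientation.
.isolated_hc <- function(angles) {
  heads <- data.frame(part = "head",
                      body_orientation = NA_integer_,
                      head_orientation = ORIENTATIONS4,
                      anchor_angle = NA_integer_)
  grid <- expand.grid(anchor_angle = angles, o = ORIENTATIONS4,
                      KEEP.OUT.ATTRS = FALSE)
  bodies <- data.frame(part = "body",
                       body_orientation = (grid$o + grid$anchor_angle) %% 360L,
                       head_orientation = NA_integer_,
                       anchor_angle = grid$anchor_angle)
  rbind(heads, bodies)
}

.monkey_rows <- function(body, head) {
  data.frame(part = "monkey",
             body_orientation = as.integer(body) %% 360L,
             head_orientation = as.integer(head) %% 360L,
             anchor_angle = NA_integer_)
}

#' Stimulus grids of the three head-body orientation experiments
#'
#' Builds the full condition set of one experiment for one pose and centering:
#'
#' * `E1` (head-body orientation test): 64 whole-monkey conditions crossing
#'   eight head with eight body orientations (45 degree steps), plus 12
#'   isolated-part conditions (four headless bodies and eight heads when
#'   monkey-centered; four heads and eight bodies when head-centered).
#' * `E2` (sum versus configuration test): 16 whole-monkey conditions (four
#'   angles 0/90/180/-90 at four orientations), 16 standalone heads, and four
#'   headless bodies; monkey-centered only.
#' * `E3` (upright versus inverted test): four angles at eight orientations
#'   plus the E1-style isolated parts, each upright and inverted;
#'   monkey-centered only.
#'
#' Isolated-part conditions carry an `anchor_angle`: the head-body angle of
#' the avatar configuration whose location the part image occupies. It keeps
#' conditions that share an orientation but not a screen position distinct.
#'
#' @param experiment `"E1"`, `"E2"` or `"E3"`.
#' @param pose avatar pose, `"P1"` (sitting) or `"P2"` (standing).
#' @param centering `"MC"` (monkey-centered) or `"HC"` (head-centered);
#'   experiments 2 and 3 exist only monkey-centered.
#' @return a data frame with one row per condition and columns
#'   `experiment`, `pose`, `part`, `body_orientation`, `head_orientation`,
#'   `anchor_angle`, `centering`, `inversion` and the derived signed `angle`
#'   (whole-monkey rows only), in a deterministic order.
#' @examples
#' nrow(make_stimulus_grid("E1", "P1", "MC"))  # 76
#' nrow(make_stimulus_grid("E2", "P1", "MC"))  # 36
#' @export
make_stimulus_grid <- function(experiment = c("E1", "E2", "E3"),
                               pose = c("P1", "P2"),
                               centering = c("MC", "HC")) {
  experiment <- match.arg(experiment)
  pose <- match.arg(pose)
  centering <- match.arg(centering)
  if (experiment != "E1" && centering != "MC") {
    stop("experiments E2 and E3 were run monkey-centered only")
  }
  angles_e23 <- c(0L, 90L, 180L, -90L)

  if (experiment == "E1") {
    m <- expand.grid(body_orientation = ORIENTATIONS8,
                     head_orientation = ORIENTATIONS8,
                     KEEP.OUT.ATTRS = FALSE)
    monkey <- .monkey_rows(m$body_orientation, m$head_orientation)
    iso <- if (centering == "MC") .isolated_mc(c(0L, 180L)) else .isolated_hc(c(0L, 180L))
    grid <- rbind(monkey, iso)
    grid$inversion <- "upright"
  } else if (experiment == "E2") {
    m <- expand.grid(body_orientation = ORIENTATIONS4, angle = angles_e23,
                     KEEP.OUT.ATTRS = FALSE)
    monkey <- .monkey_rows(m$body_orientation, m$body_orientation + m$angle)
    grid4 <- expand.grid(anchor_angle = angles_e23, o = ORIENTATIONS4,
                         KEEP.OUT.ATTRS = FALSE)
    heads <- data.frame(part = "head",
                        body_orientation = NA_integer_,
                        head_orientation = (grid4$o + grid4$anchor_angle) %% 360L,
                        anchor_angle = wrap_signed(grid4$anchor_angle))
    bodies <- data.frame(part = "body",
                         body_orientation = ORIENTATIONS4,
                         head_orientation = NA_integer_,
                         anchor_angle = NA_integer_)
    grid <- rbind(monkey, heads, bodies)
    grid$inversion <- "upright"
  } else {
    m <- expand.grid(body_orientation = ORIENTATIONS8, angle = angles_e23,
                     KEEP.OUT.ATTRS = FALSE)
    one <- rbind(.monkey_rows(m$body_orientation, m$body_orientation + m$angle),
                 .isolated_mc(c(0L, 180L)))
    grid <- rbind(transform(one, inversion = "upright"),
                  transform(one, inversion = "inverted"))
  }

  grid$experiment <- experiment
  grid$pose <- pose
  grid$centering <- centering
  grid$angle <- NA_integer_
  is_m <- grid$part == "monkey"
  grid$angle[is_m] <- as.integer(
    signed_angle(grid$head_orientation[is_m], grid$body_orientation[is_m]))
  grid$anchor_angle <- as.integer(grid$anchor_angle)

  grid <- grid[, c("experiment", "pose", "part", "body_orientation",
                   "head_orientation", "anchor_angle", "centering",
                   "inversion", "angle")]
  part_rank <- match(grid$part, c("monkey", "head", "body"))
  ord <- order(part_rank, grid$body_orientation, grid$head_orientation,
               grid$anchor_angle, grid$inversion,
               na.last = FALSE, method = "radix")
  grid <- grid[ord, ]
  rownames(grid) <- NULL
  if (anyDuplicated(condition_key(grid))) {
    stop("internal error: duplicate stimulus conditions in grid")  # nocov
  }
  grid
}
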