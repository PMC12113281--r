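# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Orientation grids (degrees, rotation about the vertical axis).
ORIENTATIONS8 <- seq(0L, 315L, by = 45L)
ORIENTATIONS4 <- seq(0L, 270L, by = 90L)   # frontal, right lateral, back, left lateral
PLUS_ORIENTATIONS <- c(0L, 90L, 180L, 270L)
X_ORIENTATIONS <- c(45L, 135L, 225L, 315L)

# Window durations (s): 100-ms and 200-ms pre-stimulus baselines, 250-ms
# response window (50-300 ms after stimulus onset).
WIN_BASE100 <- 0.1
WIN_BASE200 <- 0.2
WIN_RESPONSE <- 0.25

wrap_signed <- function(a) {
  r <- a %% 360
  r[r > 180] <- r[r > 180] - 360
  r
}

is_grid_orientation <- function(x) {
  is.numeric(x) & !is.na(x) & (x %% 45 == 0)
}

# Deterministic pseudo-uniform value in [0, 1) from an integer seed and a
# numeric key; used for the fixed per-unit non-reference-centering pattern.
hash01 <- function(seed, key) {
  x <- sin(seed * 12.9898 + key * 78.233 + 0.5) * 43758.5453
  x - floor(x)
}

# One string per condition row; NA fields are encoded so that distinct
# conditions never collide.
condition_key <- function(df) {
  enc <- function(x) ifelse(is.na(x), ".", as.character(x))
  paste(enc(df$pose), enc(df$part), enc(df$body_orientation),
        enc(df$head_orientation), enc(df$anchor_angle),
        enc(df$centering), enc(df$inversion), sep = "|")
}

# Deterministic sub-seed stream below 2^31.
sub_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 1009) %% 2147483629
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}
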