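#' Generative tuning parameters for a synthetic unit
#'
#' A synthetic unit responds with a baseline Poisson rate plus a driven
#' component built from peak-normalized von Mises bumps over head and body
#' orientation. The driven component mixes an additive term,
#' `(f_H(h) + f_B(b)) / 2`, with a conjunctive term `f_H(h) * f_B(b)`
#' (weight `w_conj`); each marginal bump can be symmetrized across the
#' vertical midline (weight `m_mirror`), mimicking mirror-symmetric view
#' tuning. Because the bumps peak at 1, `gain` is in spikes/s and the
#' additive and conjunctive components are commensurable.
#'
#' @param mu_head,mu_body preferred head/body orientations (degrees).
#' @param kappa_head,kappa_body von Mises concentrations (>= 0; 0 = untuned).
#' @param w_conj conjunctive weight in `[0, 1]`; 0 gives an exactly additive
#'   expected response to whole-monkey stimuli.
#' @param m_mirror mirror-symmetry weight in `[0, 1]`; 1 makes the expected
#'   rate invariant under reflection of both orientations.
#' @param c_tol centering tolerance in `[0, 1]`: for the non-reference
#'   centering the tuned component is scaled by `c_tol` and a fixed,
#'   unit-specific pseudo-random pattern is mixed in with weight
#'   `1 - c_tol`. 1 = identical tuning in both centerings.
#' @param a_inv multiplicative attenuation of the driven component for
#'   inverted stimuli, in `[0, 1]`.
#' @param gain peak driven rate (spikes/s).
#' @param baseline baseline rate (spikes/s).
#' @param part_weights named numeric weights in `[0, 1]` giving the relative
#'   drive of whole-monkey, isolated-head and isolated-body stimuli. The
#'   defaults (monkey 1, head 0.5, body 0.5) make the expected whole-monkey
#'   net response equal the sum of the expected part nets when `w_conj = 0`.
#' @param pattern_seed integer seed of the fixed non-reference-centering
#'   pattern (drawn once per unit by [sample_tuning_params()]).
#' @return an object of class `"tuning_params"`.
#' @seealso [expected_rate()], [simulate_unit()], [sample_tuning_params()]
#' @export
tuning_params <- function(mu_head = 0, mu_body = 0,
                          kappa_head = 2, kappa_body = 2,
                          w_conj = 0, m_mirror = 0,
                          c_tol = 1, a_inv = 1,
                          gain = 20, baseline = 10,
                          part_weights = c(monkey = 1, head = 0.5, body = 0.5),
                          pattern_seed = 1L) {
  stopifnot(kappa_head >= 0, kappa_body >= 0,
            w_conj >= 0, w_conj <= 1,
            m_mirror >= 0, m_mirror <= 1,
            c_tol >= 0, c_tol <= 1,
            a_inv >= 0, a_inv <= 1,
            gain >= 0, baseline >= 0)
  if (!all(c("monkey", "head", "body") %in% names(part_weights))) {
    stop("part_weights must be named with 'monkey', 'head' and 'body'")
  }
  if (any(part_weights < 0 | part_weights > 1)) {
    stop("part_weights must lie in [0, 1]")
  }
  structure(list(mu_head = mu_head, mu_body = mu_body,
                 kappa_head = kappa_head, kappa_body = kappa_body,
                 w_conj = w_conj, m_mirror = m_mirror,
                 c_tol = c_tol, a_inv = a_inv,
                 gain = gain, baseline = baseline,
                 part_weights = part_weights,
                 pattern_seed = as.integer(pattern_seed)),
            class = "tuning_params")
}

#' Draw i.i.d. tuning parameters for a synthetic population
#'
#' Preferred orientations are uniform on `[0, 360)` and concentrations
#' uniform over `kappa_range`; all remaining parameters are shared across
#' units, so sweeps over e.g. `w_conj` change only the quantity under study.
#'
#' @param n number of units.
#' @param kappa_range range of the von Mises concentrations.
#' @param kappa_head_range,kappa_body_range optional per-factor
#'   concentration ranges (default `kappa_range`); e.g.
#'   `kappa_head_range = c(0, 0)` yields units tuned purely to the overall
#'   orientation of the configuration via the body.
#' @inheritParams tuning_params
#' @return a list of `n` [tuning_params()] objects.
#' @export
sample_tuning_params <- function(n, w_conj = 0, m_mirror = 0,
                                 c_tol = 1, a_inv = 1,
                                 gain = 20, baseline = 10,
                                 kappa_range = c(1, 3),
                                 kappa_head_range = kappa_range,
                                 kappa_body_range = kappa_range,
                                 part_weights = c(monkey = 1, head = 0.5, body = 0.5)) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    tuning_params(mu_head = stats::runif(1, 0, 360),
                  mu_body = stats::runif(1, 0, 360),
                  kappa_head = stats::runif(1, kappa_head_range[1],
                                            kappa_head_range[2]),
                  kappa_body = stats::runif(1, kappa_body_range[1],
                                            kappa_body_range[2]),
                  w_conj = w_conj, m_mirror = m_mirror,
                  c_tol = c_tol, a_inv = a_inv,
                  gain = gain, baseline = baseline,
                  part_weights = part_weights,
                  pattern_seed = sample.int(2^30, 1))
  })
}

# Peak-normalized von Mises bump (value 1 at theta == mu).
vm_bump <- function(theta, mu, kappa) {
  exp(kappa * (cos((theta - mu) * pi / 180) - 1))
}

# Marginal tuning factor with optional mirror symmetrization.
part_factor <- function(theta, mu, kappa, m_mirror) {
  (1 - m_mirror) * vm_bump(theta, mu, kappa) +
    m_mirror * (vm_bump(theta, mu, kappa) + vm_bump(-theta, mu, kappa)) / 2
}

#' Expected firing rate of a synthetic unit for stimulus conditions
#'
#' Computes `baseline + part_weight * a * gain * D(condition)` where `D` is
#' the driven tuning component described in [tuning_params()], `a` is the
#' inversion attenuation for inverted stimuli, and for the non-reference
#' centering (`HC`) the tuned component is mixed with the unit's fixed
#' pseudo-random pattern according to `c_tol`. Isolated parts are driven by
#' their own marginal factor only.
#'
#' @param params a [tuning_params()] object.
#' @param conditions a stimulus-condition data frame as produced by
#'   [make_stimulus_grid()] (vectorized over rows).
#' @param reference_centering centering in which the tuning is defined.
#' @return numeric vector of expected rates (spikes/s), one per row.
#' @export
expected_rate <- function(params, conditions, reference_centering = "MC") {
  stopifnot(inherits(params, "tuning_params"))
  h <- conditions$head_orientation
  b <- conditions$body_orientation
  fH <- part_factor(h, params$mu_head, params$kappa_head, params$m_mirror)
  fB <- part_factor(b, params$mu_body, params$kappa_body, params$m_mirror)

  driven <- numeric(nrow(conditions))
  im <- conditions$part == "monkey"
  ih <- conditions$part == "head"
  ib <- conditions$part == "body"
  driven[im] <- (1 - params$w_conj) * (fH[im] + fB[im]) / 2 +
    params$w_conj * fH[im] * fB[im]
  driven[ih] <- fH[ih]
  driven[ib] <- fB[ib]

  off <- conditions$centering != reference_centering
  if (any(off)) {
    key <- (ifelse(is.na(b), 991, b) * 131 + ifelse(is.na(h), 991, h) * 17 +
              ifelse(is.na(conditions$anchor_angle), 991,
                     conditions$anchor_angle %% 360) * 7 +
              match(conditions$part, c("monkey", "head", "body")) * 3001 +
              (conditions$inversion == "inverted") * 13)
    pattern <- hash01(params$pattern_seed, key)
    driven[off] <- params$c_tol * driven[off] + (1 - params$c_tol) * pattern[off]
  }

  a <- ifelse(conditions$inversion == "inverted", params$a_inv, 1)
  pw <- unname(params$part_weights[conditions$part])
  rate <- params$baseline + pw * a * params$gain * driven
  if (any(rate < 0)) stop("negative expected rate")  # cannot occur by construction
  rate
}
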