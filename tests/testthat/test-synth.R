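test_that("additive units decompose exactly into head and body terms", {
  p <- tuning_params(mu_head = 45, mu_body = 200, kappa_head = 2,
                     kappa_body = 1.5, w_conj = 0, gain = 20)
  g <- e1_grid_mc
  r <- expected_rate(p, g)
  m <- g$part == "monkey"
  fH <- exp(p$kappa_head * (cos((g$head_orientation[m] - p$mu_head) * pi / 180) - 1))
  fB <- exp(p$kappa_body * (cos((g$body_orientation[m] - p$mu_body) * pi / 180) - 1))
  expect_equal(r[m] - p$baseline, (fH + fB) / 2 * p$gain * 1)
  # zero additive-model residuals on the 8 x 8 expected-rate matrix
  M <- matrix(r[m][order(g$body_orientation[m], g$head_orientation[m])],
              8, 8, byrow = TRUE)
  expect_lt(max(abs(additive_residuals(M))), 1e-10)
})

test_that("mirror weight 1 makes the expected rate reflection invariant", {
  p <- tuning_params(m_mirror = 1, mu_head = 30, mu_body = 100, w_conj = 1)
  g <- e1_monkey_mc
  r <- expected_rate(p, g)
  refl <- data.frame(h = (-g$head_orientation) %% 360,
                     b = (-g$body_orientation) %% 360)
  idx <- match(paste(refl$h, refl$b),
               paste(g$head_orientation, g$body_orientation))
  expect_equal(r, r[idx])
})

test_that("flat tuning yields identical rates across the 64 conditions", {
  p <- tuning_params(kappa_head = 0, kappa_body = 0)
  r <- expected_rate(p, e1_monkey_mc)
  expect_equal(max(r) - min(r), 0)
})

test_that("Poisson counts have the right means and dispersion", {
  p <- tuning_params(baseline = 20, gain = 0)
  one <- e1_monkey_mc[1, ]
  big <- one[rep(1, 1250), ]   # 1250 conditions x 8 trials = 1e4 draws
  big$head_orientation <- big$head_orientation  # keep schema
  tr <- simulate_unit(p, big, n_trials = 8, seed = 99)
  # baseline100 mean = 20 * 0.1 = 2.0, within 3 SE
  se <- sqrt(2 / nrow(tr))
  expect_lt(abs(mean(tr$baseline100_count) - 2), 3 * se)
  # response window mean = baseline only when gain = 0
  expect_lt(abs(mean(tr$response_count) - 5), 3 * sqrt(5 / nrow(tr)))
  # variance/mean close to 1 (Poisson)
  expect_gt(var(tr$response_count) / mean(tr$response_count), 0.9)
  expect_lt(var(tr$response_count) / mean(tr$response_count), 1.1)
})

test_that("simulation is reproducible and labels subjects evenly", {
  p <- tuning_params()
  a <- simulate_unit(p, e1_grid_mc, seed = 7)
  b <- simulate_unit(p, e1_grid_mc, seed = 7)
  expect_identical(a, b)
  pop <- simulate_population(60, e1_grid_mc, seed = 8)
  info <- unique(pop[, c("unit_id", "subject")])
  expect_equal(as.vector(table(info$subject)), c(30, 30))
  pop2 <- simulate_population(60, e1_grid_mc, seed = 8)
  expect_identical(as.data.frame(pop), as.data.frame(pop2))
  expect_error(simulate_population(0, e1_grid_mc), "n_units")
})

test_that("centering tolerance controls MC-HC tuning correspondence", {
  # c_tol = 1: identical expected tuning in both centerings
  p <- tuning_params(c_tol = 1)
  g_hc <- make_stimulus_grid("E1", "P1", "HC")
  m_mc <- expected_rate(p, e1_monkey_mc)
  m_hc <- expected_rate(p, g_hc[g_hc$part == "monkey", ])
  expect_equal(cor(m_mc, m_hc), 1)
  # c_tol = 0: an unrelated fixed pattern; correlations spread around 0
  rs <- vapply(1:30, function(i) {
    p0 <- tuning_params(c_tol = 0, mu_head = i * 11, mu_body = i * 29,
                        pattern_seed = i)
    cor(expected_rate(p0, e1_monkey_mc),
        expected_rate(p0, g_hc[g_hc$part == "monkey", ]))
  }, numeric(1))
  expect_lt(abs(median(rs)), 0.35)
  expect_lt(abs(median(rs)), abs(1))  # strictly below the c_tol = 1 case
})

test_that("inversion attenuation scales only the driven component", {
  p <- tuning_params(a_inv = 0.5, gain = 20, baseline = 10)
  g3 <- e3_grid
  up <- g3[g3$part == "monkey" & g3$inversion == "upright", ]
  inv <- g3[g3$part == "monkey" & g3$inversion == "inverted", ]
  # same conditions in both inversions, matched order
  key <- function(d) paste(d$body_orientation, d$head_orientation)
  inv <- inv[match(key(up), key(inv)), ]
  r_up <- expected_rate(p, up)
  r_inv <- expected_rate(p, inv)
  expect_equal(r_inv - p$baseline, (r_up - p$baseline) * 0.5)
})
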