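test_that("monkey-sum index matches its closed form and boundary cases", {
  expect_equal(msi(10, 4, 2), 0.25)
  expect_equal(msi(0, 3, 2), -1)
  expect_equal(msi(7, 0, 0), 1)
  expect_true(is.na(msi(0, 0, 0)))
  # antisymmetry: swapping M with (B + H) flips the sign
  expect_equal(msi(3, 5, 4), -msi(9, 2, 1))
  for (i in 1:20) {
    m <- rnorm(1, 5, 3); b <- rnorm(1, 3, 2); h <- rnorm(1, 2, 2)
    expect_equal(msi(m, b, h), -msi(b + h, m, 0))
  }
})

test_that("MSI case selection keys on significant excitatory responses", {
  g <- e1_grid_mc
  case_of <- function(unit) {
    list(monkey = unit[unit$part == "monkey" & unit$body_orientation == 0 &
                         unit$head_orientation == 0, ],
         head = unit[unit$part == "head" & unit$head_orientation == 0 &
                       unit$anchor_angle %in% 0, ],
         body = unit[unit$part == "body" & unit$body_orientation == 0, ])
  }
  driven <- simulate_unit(tuning_params(gain = 80, kappa_head = 0.5,
                                        kappa_body = 0.5), g, 8, seed = 11)
  expect_true(msi_case_select(case_of(driven)))
  silent <- simulate_unit(tuning_params(gain = 0), g, 8, seed = 12)
  expect_false(msi_case_select(case_of(silent)))
  # head-only drive still selects the case (enables MSI near -1)
  head_only <- simulate_unit(
    tuning_params(gain = 80, part_weights = c(monkey = 0, head = 1, body = 0)),
    g, 8, seed = 13)
  expect_true(msi_case_select(case_of(head_only)))
})

test_that("null case-selection rate matches three independent tests", {
  # three untuned images, alpha 0.05: P(select) ~ 1 - (1 - a')^3 where a' is
  # the one-sided-excitatory share of rejections (~ alpha/2 each)
  g <- e1_grid_mc
  sel <- vapply(1:300, function(i) {
    u <- simulate_unit(tuning_params(gain = 0, baseline = 15), g[c(1, 65, 69), ],
                       8, seed = 7000 + i)
    msi_case_select(list(monkey = u[1:8, ], head = u[9:16, ], body = u[17:24, ]))
  }, logical(1))
  p_hat <- mean(sel)
  expect_gt(p_hat, 0.01)
  expect_lt(p_hat, 0.15)
})

test_that("variance stabilization is sqrt(count + 3/8)", {
  expect_equal(variance_stabilize(0), sqrt(0.375))
  expect_equal(variance_stabilize(1), sqrt(1.375))
  expect_equal(variance_stabilize(13 / 8), sqrt(2))
  expect_error(variance_stabilize(-1), "nonnegative")
})

test_that("additive residuals satisfy the centering identities", {
  set.seed(5)
  m <- matrix(rnorm(64), 8, 8)
  r <- additive_residuals(m)
  expect_lt(max(abs(rowMeans(r))), 1e-12)
  expect_lt(max(abs(colMeans(r))), 1e-12)
  # idempotent
  expect_equal(additive_residuals(r), r)
  # model-exact input: zero residuals
  add <- outer(rnorm(8), rep(1, 8)) + outer(rep(1, 8), rnorm(8))
  expect_lt(max(abs(additive_residuals(add))), 1e-12)
  # single-cell bump of +8: residual 8 * (1 - 1/8 - 1/8 + 1/64)
  bump <- matrix(0, 8, 8); bump[3, 5] <- 8
  expect_equal(additive_residuals(bump)[3, 5], 8 * (1 - 1 / 8 - 1 / 8 + 1 / 64))
})

test_that("interaction ANOVA separates conjunctive from additive units", {
  conj <- simulate_unit(tuning_params(w_conj = 1, gain = 60,
                                      kappa_head = 3, kappa_body = 3),
                        e1_monkey_mc, 8, seed = 21)
  a <- headbody_anova(conj)
  expect_lt(a$p_interaction, 0.05)
  expect_equal(dim(a$residuals), c(8, 8))
  expect_lt(max(abs(rowMeans(a$residuals))), 1e-10)
  # additive units: interaction rejection near alpha (seed-frozen small sim)
  rej <- vapply(1:60, function(i) {
    u <- simulate_unit(tuning_params(w_conj = 0, mu_head = i * 37,
                                     mu_body = i * 53), e1_monkey_mc, 8,
                       seed = 900 + i)
    isTRUE(headbody_anova(u)$p_interaction < 0.05)
  }, logical(1))
  expect_lt(mean(rej), 0.2)
  expect_error(headbody_anova(conj[conj$body_orientation != 0, ]), "64")
})

test_that("centering and residual correlations track c_tol and w_conj", {
  both <- rbind(make_stimulus_grid("E1", "P1", "MC"),
                make_stimulus_grid("E1", "P1", "HC"))
  stable <- simulate_unit(tuning_params(c_tol = 1, w_conj = 1, gain = 60,
                                        kappa_head = 3, kappa_body = 3),
                          both, 8, seed = 31)
  expect_gt(centering_correlation(stable), 0.5)
  expect_gt(residual_correlation(stable), 0.2)
  rs <- vapply(1:20, function(i) {
    u <- simulate_unit(tuning_params(c_tol = 0, gain = 60, mu_head = i * 31,
                                     mu_body = i * 17, pattern_seed = i),
                       both, 8, seed = 40 + i)
    centering_correlation(u)
  }, numeric(1))
  expect_lt(abs(median(rs)), 0.4)
})

test_that("split-half reliability is high for reliable units and corrected by Spearman-Brown", {
  expect_equal(reliability_normalized_correlation(0.5, 1, 1), 0.5)
  expect_equal(reliability_normalized_correlation(0.45, 0.9, 0.9), 0.5)
  expect_true(is.na(reliability_normalized_correlation(0.5, 0, 0.9)))
  # 2r/(1+r) on a synthetic half-correlation
  r_half <- 0.5
  expect_equal(2 * r_half / (1 + r_half), 2 / 3)

  reliable <- simulate_unit(tuning_params(gain = 80, baseline = 2,
                                          kappa_head = 3, kappa_body = 3),
                            e1_monkey_mc, 8, seed = 51)
  expect_gt(split_half_reliability(reliable, n_splits = 30, seed = 1), 0.8)
  noise <- simulate_unit(tuning_params(gain = 0), e1_monkey_mc, 8, seed = 52)
  expect_lt(abs(split_half_reliability(noise, n_splits = 30, seed = 1)), 0.35)
})

test_that("msi_table pools matched cases and reports net responses", {
  pop <- simulate_population(4, e1_grid_mc, seed = 61, gain = 60,
                             kappa_range = c(0.5, 1))
  tab <- msi_table(pop)
  expect_true(nrow(tab) > 0)
  expect_true(all(tab$msi >= -1 & tab$msi <= 1))
  expect_true(all(tab$angle %in% c(0, 180)))
  expect_equal(tab$msi, msi(tab$M, tab$B, tab$H))
})
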