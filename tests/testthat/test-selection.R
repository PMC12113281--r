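test_that("window counts convert to the documented rates", {
  tr <- data.frame(baseline100_count = c(2, 0), baseline200_count = c(4, 0),
                   response_count = c(5, 0))
  out <- compute_rates(tr)
  expect_equal(out$response_rate, c(20, 0))
  expect_equal(out$baseline100_rate, c(20, 0))
  expect_equal(out$baseline200_rate, c(20, 0))
  expect_equal(out$net_rate, c(0, 0))
  expect_error(compute_rates(transform(tr, response_count = -1)), "negative")
})

small_grid <- e1_monkey_mc[e1_monkey_mc$body_orientation %in% c(0, 90, 180, 270) &
                             e1_monkey_mc$head_orientation %in% c(0, 90, 180, 270), ]

test_that("split-plot ANOVA detects responsive units and the excitatory sign", {
  strong <- simulate_unit(tuning_params(gain = 60, baseline = 5), small_grid,
                          8, seed = 1)
  sp <- splitplot_responsiveness(strong)
  expect_lt(sp$p_main, 0.05)
  expect_true(sp$excitatory)
  # inhibitory unit: response window silent, baseline active
  inhib <- strong
  inhib$response_count <- rpois(nrow(inhib), 0.2)
  sp2 <- splitplot_responsiveness(inhib)
  expect_false(sp2$excitatory)
  expect_error(splitplot_responsiveness(strong[1:3, ]), ">= 2")
})

test_that("split-plot window effect is calibrated on undriven units", {
  rej <- vapply(1:150, function(i) {
    tr <- simulate_unit(tuning_params(gain = 0), small_grid, 8, seed = 1000 + i)
    isTRUE(splitplot_responsiveness(tr)$p_main < 0.05)
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("Kruskal-Wallis selectivity has power and approximate type-I control", {
  tuned <- simulate_unit(tuning_params(gain = 60, kappa_head = 3,
                                       kappa_body = 3), small_grid, 8, seed = 2)
  expect_lt(kruskal_selectivity(tuned), 0.05)
  rej <- vapply(1:150, function(i) {
    tr <- simulate_unit(tuning_params(gain = 0), small_grid, 8, seed = 5000 + i)
    isTRUE(kruskal_selectivity(tr) < 0.05)
  }, logical(1))
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.10)
  expect_error(kruskal_selectivity(simulate_unit(tuning_params(),
                                                 small_grid[1, ], 8, seed = 3)),
               ">= 2 stimuli")
})

test_that("z-score screen follows the meanRespStim/stdBaseAll formula", {
  # hand-built unit: 2 stimuli x 8 trials with known window rates
  mk <- function(resp100ms) data.frame(
    pose = "P1", part = "monkey", body_orientation = 0L,
    head_orientation = 0L, anchor_angle = NA_integer_,
    centering = "MC", inversion = "upright", trial_index = 1:8,
    baseline100_count = 0L, baseline200_count = 0L,
    response_count = as.integer(resp100ms))
  a <- mk(rep(5, 8)); a$baseline100_count <- rep(1L, 8)
  b <- mk(rep(1, 8)); b$head_orientation <- 45L; b$baseline100_count <- rep(2L, 8)
  tr <- rbind(a, b)
  # meanResp: (20, 4); meanBase per stim: (10, 20); meanBaseAll 15, sd 7.0711
  z <- zscore_screen(tr)
  expect_equal(z, (20 - 15) / sd(c(10, 20)))
  # identical baselines across stimuli: sd = 0 -> NA (unit fails)
  a$baseline100_count <- b$baseline100_count <- rep(1L, 8)
  expect_true(is.na(zscore_screen(rbind(a, b))))
})

test_that("category filter applies the inclusive twice-the-control rule", {
  expect_true(category_filter(c(monkey = 10, face = 1, body = 1),
                              c(monkey = 4, face = 3, body = 3)))
  expect_false(category_filter(c(monkey = 5, face = 5, body = 5),
                               c(monkey = 5, face = 5, body = 5)))
  expect_true(category_filter(c(monkey = 1, face = 1, body = 6),
                              c(monkey = 3, face = 3, body = 3)))  # boundary 2x
})

test_that("the full screen passes driven units and rejects undriven ones", {
  pop <- rbind(
    cbind(unit_id = "driven", region = "aSTS", subject = "M1",
          simulate_unit(tuning_params(gain = 60, kappa_head = 3), small_grid,
                        8, seed = 4)),
    cbind(unit_id = "flat", region = "aSTS", subject = "M1",
          simulate_unit(tuning_params(gain = 0), small_grid, 8, seed = 5)))
  v <- screen_units(pop, "E2")
  expect_true(v$passed[v$unit_id == "driven"])
  expect_false(v$passed[v$unit_id == "flat"])
  # E1 screen ignores the selectivity criteria
  v1 <- screen_units(pop, "E1")
  expect_true(v1$passed[v1$unit_id == "driven"])
  expect_true(all(is.na(v1$kruskal_p)))
})
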