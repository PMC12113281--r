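test_that("pseudo-population assembly preserves trials and roster shape", {
  pop <- conj_pop()
  m <- pop[pop$part == "monkey" & pop$angle %in% c(0, 180), ]
  pp <- build_pseudopopulation(m, seed = 1)
  expect_equal(dim(pp$vectors), c(60, 16, 8))
  # each unit-stimulus cell is a permutation of its 8 trial rates
  tr <- compute_rates(m)
  u1 <- sort(tr$response_rate[tr$unit_id == "u001" & tr$angle == 0 &
                                tr$body_orientation == 0])
  expect_equal(sort(pp$vectors[1, which(pp$conditions$angle == 0 &
                                          pp$conditions$body_orientation == 0), ]),
               u1)
  expect_identical(build_pseudopopulation(m, seed = 1)$vectors, pp$vectors)
})

test_that("balanced folds give 56/28 training trials per class and partition all trials", {
  cls8 <- list(data.frame(head_orientation = 0:7 * 45, body_orientation = 0:7 * 45),
               data.frame(head_orientation = 0:7 * 45, body_orientation = 0:7 * 45))
  set.seed(1)
  fm <- balanced_folds(cls8)
  for (f in fm) {
    expect_equal(dim(f), c(8, 8))
    expect_true(all(apply(f, 1, sort) == 1:8))  # each row a permutation
  }
  # per fold: one test trial per orientation -> 8 test, 56 training per class
  for (k in 1:8) expect_equal(sum(fm[[1]] == k), 8)
  cls4 <- lapply(cls8, function(d) d[1:4, ])
  fm4 <- balanced_folds(cls4)
  for (k in 1:8) expect_equal(sum(fm4[[1]] == k), 4)   # 28 training
  # guard: unbalanced multisets rejected
  bad <- list(cls8[[1]], transform(cls8[[2]], head_orientation = c(0, 0, 90, 135, 180, 225, 270, 315)))
  expect_error(balanced_folds(bad), "unbalanced")
})

test_that("conjunctive populations decode pooled angles; additive ones cannot", {
  r_conj <- decode_angle_pair(conj_pop(), c(0, 180), n_units = 60,
                              n_resamples = 5, seed = 1)
  r_add <- decode_angle_pair(add_pop(), c(0, 180), n_units = 60,
                             n_resamples = 5, seed = 1)
  expect_gt(r_conj$mean, 0.75)
  expect_lt(abs(r_add$mean - 0.5), 0.12)
  # determinism under the master seed
  r_again <- decode_angle_pair(conj_pop(), c(0, 180), n_units = 60,
                               n_resamples = 5, seed = 1)
  expect_identical(r_conj$accuracies, r_again$accuracies)
})

test_that("mirror-symmetric populations confuse sign-only angle pairs", {
  r_sign <- decode_angle_pair(mirror_pop(), c(90, -90), n_units = 60,
                              n_resamples = 5, seed = 2)
  r_abs <- decode_angle_pair(mirror_pop(), c(0, 180), n_units = 60,
                             n_resamples = 5, seed = 2)
  expect_lt(r_sign$mean, r_abs$mean)
  expect_lt(abs(r_sign$mean - 0.5), 0.15)
})

test_that("permutation null sits at chance for binary and 8-way decoding", {
  nul <- permutation_null(add_pop(), angles = c(0, 180), n_units = 60,
                          n_runs = 30, seed = 3)
  expect_lt(abs(mean(nul$null_accuracies) - 0.5), 0.05)
  expect_equal(length(nul$null_accuracies), 30)
  pop3 <- simulate_population(20, e3_grid, seed = 54, w_conj = 0.5,
                              gain = 40, kappa_range = c(2, 4))
  ro <- decode_orientation(pop3, n_units = 20, n_resamples = 3,
                           null_runs = 20, seed = 7)
  expect_lt(abs(mean(ro$null_accuracies) - 0.125), 0.04)
  expect_gt(ro$mean, 0.5)   # strongly tuned upright population
})

test_that("decoding comparisons are paired and sign-symmetric", {
  a <- decode_angle_pair(conj_pop(), c(0, 180), n_units = 60,
                         n_resamples = 6, seed = 4)
  b <- decode_angle_pair(conj_pop(), c(90, -90), n_units = 60,
                         n_resamples = 6, seed = 4)
  cmp <- compare_decodings(a, b)
  cmp_rev <- compare_decodings(b, a)
  expect_equal(cmp$p + cmp_rev$p, 1)
  same <- compare_decodings(a, a)
  expect_equal(same$p, 0.5)
  mismatched <- decode_angle_pair(conj_pop(), c(0, 180), n_units = 60,
                                  n_resamples = 6, seed = 99)
  expect_error(compare_decodings(a, mismatched), "seed")
})

test_that("cross-centering generalization is below within-centering on average", {
  both <- rbind(make_stimulus_grid("E1", "P1", "MC"),
                make_stimulus_grid("E1", "P1", "HC"))
  pop <- simulate_population(40, both, seed = 51, w_conj = 1, gain = 40,
                             c_tol = 0.8, kappa_range = c(2, 4))
  r_within <- decode_angle_pair(pop, c(0, 180), n_units = 40,
                                n_resamples = 5, seed = 2)
  r_cross <- decode_angle_pair(pop, c(0, 180), train_centering = "MC",
                               test_centering = "HC", n_units = 40,
                               n_resamples = 5, seed = 2)
  expect_lte(r_cross$mean, r_within$mean + 0.02)
  expect_gt(r_cross$mean, 0.6)   # c_tol 0.8 keeps transfer decodable
})

test_that("cross-orientation transfer decodes angle and the guard rejects unbalanced contrasts", {
  plus <- c(0, 90, 180, 270); cross <- c(45, 135, 225, 315)
  r_xo <- decode_angle_pair(conj_pop(), c(0, 180), train_orientations = plus,
                            test_orientations = cross, n_units = 60,
                            n_resamples = 5, seed = 5)
  expect_gt(r_xo$mean, 0.6)
  expect_error(
    decode_angle_pair(conj_pop(), c(0, 45), train_orientations = plus,
                      test_orientations = cross, n_resamples = 2, seed = 5),
    "unbalanced")
})

test_that("angle decoding accuracy grows with conjunctive weight and population size", {
  accs <- vapply(c(0, 0.5, 1), function(w) {
    pop <- simulate_population(30, e1_grid_mc, seed = 71, w_conj = w,
                               gain = 40, kappa_range = c(2, 4))
    decode_angle_pair(pop, c(0, 180), n_units = 30, n_resamples = 4,
                      seed = 6)$mean
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.03))
  expect_gt(accs[3], accs[1] + 0.2)
  # more units help, on average
  a_small <- decode_angle_pair(conj_pop(), c(0, 180), n_units = 10,
                               n_resamples = 5, seed = 7)
  a_large <- decode_angle_pair(conj_pop(), c(0, 180), n_units = 60,
                               n_resamples = 5, seed = 7)
  expect_gte(a_large$mean, a_small$mean - 0.02)
})

test_that("sum decoding stays at chance for independent parts and the paired contrast detects conjunctions", {
  popc <- simulate_population(40, e2_grid, seed = 21, w_conj = 1, gain = 40,
                              kappa_range = c(2, 4))
  sv <- decode_sum_vs_config(popc, c(0, 180), n_units = 40,
                             n_resamples = 10, seed = 8)
  expect_gt(sv$config$mean, sv$sum$mean)
  expect_lt(sv$p, 0.025)
  expect_lt(abs(sv$sum$mean - 0.5), 0.12)
})

test_that("inversion attenuation lowers orientation decoding for inverted stimuli", {
  pop3 <- simulate_population(30, e3_grid, seed = 31, w_conj = 0.5,
                              a_inv = 0.4, gain = 40, kappa_range = c(2, 4))
  inv <- decode_inversion_effect(pop3, n_units = 30, n_resamples = 10,
                                 group_size = 5, seed = 9)
  expect_gt(inv$mean_upright, inv$mean_inverted)
  expect_true(inv$zero_outside)
})

test_that("neuron dropping ranks informative units first", {
  # 10 conjunctive units among 20 untuned ones
  g <- e1_grid_mc
  conj_units <- simulate_population(10, g, seed = 81, w_conj = 1, gain = 50,
                                    kappa_range = c(2, 4))
  flat_units <- simulate_population(20, g, seed = 82, gain = 0)
  flat_units$unit_id <- sprintf("f%03d", match(flat_units$unit_id,
                                               unique(flat_units$unit_id)))
  pop <- rbind(as.data.frame(conj_units), as.data.frame(flat_units))
  nd <- neuron_dropping(pop, n_resamples = 4, seed = 10,
                        curve_sizes = c(5, 10, 30))
  informative <- unique(conj_units$unit_id)
  expect_gte(sum(nd$top_units %in% informative), 6)
  expect_gte(nd$frac_interaction, 0.5)
  expect_equal(nrow(nd$curve), 3)
})
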