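# Shared fixtures: small synthetic populations built once per test run.
# All fixtures are generated in code under fixed seeds; sizes are kept small
# so the default test run stays fast.

e1_grid_mc <- make_stimulus_grid("E1", "P1", "MC")
e1_grid_both <- rbind(make_stimulus_grid("E1", "P1", "MC"),
                      make_stimulus_grid("E1", "P1", "HC"))
e1_monkey_mc <- e1_grid_mc[e1_grid_mc$part == "monkey", ]
e2_grid <- make_stimulus_grid("E2", "P1", "MC")
e3_grid <- make_stimulus_grid("E3", "P1", "MC")

# Strongly tuned populations used across decoding tests (gain well above
# baseline, sharp tuning, so the qualitative signatures are unambiguous at
# small simulation sizes).
pop_cache <- new.env(parent = emptyenv())
cached_pop <- function(name, builder) {
  if (is.null(pop_cache[[name]])) pop_cache[[name]] <- builder()
  pop_cache[[name]]
}

conj_pop <- function() cached_pop("conj", function()
  simulate_population(60, e1_grid_mc, seed = 11, w_conj = 1, gain = 40,
                      kappa_range = c(2, 4)))
add_pop <- function() cached_pop("add", function()
  simulate_population(60, e1_grid_mc, seed = 12, w_conj = 0, gain = 40,
                      kappa_range = c(2, 4)))
mirror_pop <- function() cached_pop("mirror", function()
  simulate_population(60, e1_grid_mc, seed = 13, w_conj = 1, m_mirror = 1,
                      gain = 40, kappa_range = c(2, 4)))
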