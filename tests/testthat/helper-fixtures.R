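# Shared fixture builders. Small voxel counts keep unit tests fast; the
# acceptance tests use the full default configuration.

default_design8 <- function(repeats = 27) {
  stimulus_design((0:7) * 22.5, repeats = repeats)
}

# population + train/validation pair at a given noise level
sim_pair <- function(sigma, seed = 1, v = 100, m = 180, h = 40,
                     design = default_design8()) {
  pop <- simulate_population(v = v, m = m, h = h, seed = seed)
  list(
    pop = pop,
    train = simulate_dataset(pop, design, sigma, seed = 2L * seed,
                             role = "train"),
    val = simulate_dataset(pop, design, sigma, seed = 2L * seed + 1L,
                           role = "validation"),
    design = design
  )
}
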