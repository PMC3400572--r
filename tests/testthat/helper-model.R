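# Shared model fixtures. Expensive grid maps are memoized by the package's
# in-session cache, so repeated calls across test files cost one simulation
# pass in total.

test_model <- basal_model()

# the calibrated model's default two-input map (21x21, double pulse, 90/150)
default_map <- function() map_two_input(test_model)

# coarser within/between-branch maps for interaction tests
coarse_map_within <- function() map_two_input(test_model, n_max = 40, step = 4)
coarse_map_between <- function() {
  map_two_input(test_model, n_max = 40, step = 4,
                branch_dist = dendarith:::nth_basal(test_model, 2))
}

.ramp_cache <- new.env(parent = emptyenv())
cached_ramp <- function(distance, nmda_gmax = 3.56) {
  key <- sprintf("d%g_g%g", distance, nmda_gmax)
  if (is.null(.ramp_cache[[key]])) {
    .ramp_cache[[key]] <- uncaging_ramp(test_model, distance, seq(2, 40, 2),
                                        nmda_gmax = nmda_gmax)
  }
  .ramp_cache[[key]]
}
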