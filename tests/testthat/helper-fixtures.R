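# Shared Monte Carlo fixtures, built once per test run and cached.
# Unit tests use a small 5e4-motion world; the acceptance tests build
# their own 2e5-motion world (see test-acceptance.R).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_samples <- function() cached("small_samples", function()
  simulate_motions(5e4, seed = 101))

small_tables <- function() cached("small_tables", function()
  build_posterior_tables(small_samples()))

# coarse co-occurrence grid: order-100 bins per signal axis (see the
# methods vignette on the threshold scale of the conflict detector)
coarse_grids <- function() signal_grids(cd_bin = 2, cs_bin = 0.004)

small_cotable <- function() cached("small_cotable", function()
  build_cooccurrence(small_samples(), coarse_grids()))

std_stimulus <- function(surface_size = 40, amplitude = 80, duration = 1.5)
  consistent_stimulus(triangular_trajectory(amplitude, duration, 60),
                      surface_size)
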