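# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_layout <- function() memo("small_layout", function() sensor_layout(32))

small_leadfield <- function() memo("small_leadfield", function() {
  build_leadfield(small_layout()$positions, n_sources = 140)
})

full_leadfield <- function() memo("full_leadfield", function() {
  build_leadfield(sensor_layout(62)$positions)
})

# Compact two-patch scenario on the 32-channel montage: same patch structure
# as the default scenario, shorter recording for fast module tests.
small_two_arc_scenario <- function(seed = 5) {
  simulation_scenario(default_two_arc_scenario()$patches, n_channels = 32,
                      duration = 80, n_segments = 2, seed = seed)
}

small_config <- function(seed = 99) {
  arc_config(K_max = 3, n_starts = 4, n_sources = 140, seed = seed)
}

# One simulated + decomposed small subject, reused read-only across tests.
small_case <- function() memo("small_case", function() {
  sim <- simulate_recording(small_two_arc_scenario(), small_leadfield())
  dec <- decompose_subject(sim$recording, small_config(),
                           leadfield = small_leadfield())
  list(sim = sim, dec = dec)
})

white_recording <- function(n_ch = 4, seconds = 30, fs = 250, sd = 1,
                            seed = 7, segment_starts = 1L) {
  pos <- sensor_layout(n_ch)$positions
  set.seed(seed)
  eeg_recording(matrix(rnorm(n_ch * seconds * fs, sd = sd), n_ch),
                fs, channel_positions = pos, segment_starts = segment_starts)
}
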