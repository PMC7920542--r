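# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Miniature study: 40 parcels, 12 subjects.
tiny_config <- function(...) {
  synthetic_config(n_parcels = 40L, n_subjects = 12L, seed = 42L, ...)
}

tiny_ds <- function() cached("tiny_ds", generate_dataset(tiny_config()))

# Mid-size study used where block structure needs room: 120 parcels.
mid_ds <- function() cached("mid_ds", {
  generate_dataset(synthetic_config(n_parcels = 120L, n_subjects = 12L,
                                    seed = 7L))
})

# Random raw-count connectome matrix.
random_counts <- function(n, max_count = 50) {
  m <- matrix(sample.int(max_count + 1L, n * n, replace = TRUE) - 1L, n, n)
  diag(m) <- NA
  connectome_matrix(m, scale = "raw_counts")
}
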