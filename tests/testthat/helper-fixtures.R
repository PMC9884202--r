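# Shared fixtures, generated in code and cached for the duration of the test
# session (several files reuse the same small labelled field and its
# features).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small labelled field: 4 double-line objects plus noise, ~9k localizations
small_field <- function() {
  cached("small_field", {
    simulate_field(
      double_line_spec(n_pairs = 4, epitope_density = 40),
      noise_spec(field_width = 15600, field_height = 8000),
      seed = 101
    )
  })
}

small_features <- function() {
  cached("small_features", {
    locs <- small_field()
    feats <- featurize_corpus(locs, seed = 102)
    list(locs = locs, feats = feats, labels = locs$label[feats$.row])
  })
}

# sparse-background strand: off-structure localizations are dominated by the
# neighbouring double-line objects along the strand, the regime in which the
# direction histogram's 90-degree minor peak emerges
strand_features <- function() {
  cached("strand_features", {
    locs <- simulate_field(
      double_line_spec(n_pairs = 5, epitope_density = 40),
      noise_spec(
        uniform_density = 2, vesicle_density = 0.2,
        field_width = 19000, field_height = 8000
      ),
      seed = 103
    )
    feats <- featurize_corpus(locs, seed = 104)
    list(locs = locs, feats = feats, labels = locs$label[feats$.row])
  })
}

# deterministic object-only strand used by geometry checks
straight_pair <- function(d = 120, n = 400, jitter = 10, seed = 7) {
  withr::with_seed(seed, {
    tibble::tibble(
      x = rep(c(-d / 2, d / 2), each = n / 2) + rnorm(n, 0, jitter),
      y = runif(n, -750, 750)
    )
  })
}
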