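# Shared fixtures: everything is generated in code at test time.

# small, fast section spec used throughout the unit tests
tiny_spec <- function(true_fraction = 0, seed = 1L, size = 64L, ...) {
  image_spec(width = size, height = size, true_fraction = true_fraction,
             seed = seed, ...)
}

# cohort with a given seed under the default study configuration
test_cohort <- function(seed = 1L, ...) {
  generate_cohort(cohort_config(seed = seed, ...))
}

# the hand-computable bimodal histogram: symmetric background (1,3,5,3,1)
# at intensities 0..4 plus a 10-pixel signal bin at intensity 200
worked_bimodal_hist <- function() {
  counts <- c(1, 3, 5, 3, 1, rep(0, 195), 10)
  intensity_histogram(counts, bin_values = 0:200)
}

expect_cohorts_equal <- function(a, b) {
  expect_equal(a$animals, b$animals, tolerance = 1e-8,
               ignore_attr = "row.names")
  expect_equal(a$epochs, b$epochs, tolerance = 1e-8,
               ignore_attr = "row.names")
}
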