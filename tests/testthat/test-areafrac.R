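test_that("histograms enumerate ROI pixels per integer intensity", {
  img <- intensity_image(matrix(c(10, 10, 10, 200), 2, 2))
  h <- compute_histogram(img)
  expect_equal(h$counts[h$bin_values == 10], 3)
  expect_equal(h$counts[h$bin_values == 200], 1)
  expect_equal(h$total, 4)
  expect_equal(sum(h$counts), h$total)

  roi <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  h2 <- compute_histogram(intensity_image(matrix(c(10, 10, 10, 200), 2, 2),
                                          roi_mask = roi))
  expect_equal(h2$total, 3)
  expect_equal(h2$counts[h2$bin_values == 200], 0)

  h3 <- compute_histogram(intensity_image(matrix(7L, 3, 3)))
  expect_equal(sum(h3$counts > 0), 1)
  expect_equal(max(h3$counts), h3$total)
})

test_that("background peak: centroid of the three-bin mode, ties low, degenerate fallback", {
  expect_equal(locate_background_peak(intensity_histogram(c(1, 3, 5, 3, 1)))$peak_intensity,
               (1 * 3 + 2 * 5 + 3 * 3) / 11)
  # a flat stretch ties on window mass; the lower-intensity window wins
  pk <- locate_background_peak(intensity_histogram(c(5, 5, 5, 5)))
  expect_equal(pk$peak_intensity, 1)
  sg <- locate_background_peak(intensity_histogram(c(0, 0, 9, 0, 0),
                                                   bin_values = 28:32))
  expect_true(sg$degenerate)
  expect_equal(sg$peak_intensity, 30)
  # symmetric Gaussian background: peak lands within one bin of the mean
  peaks <- vapply(1:40, function(s) {
    img <- generate_section_image(tiny_spec(seed = s, bg_mean = 50))
    locate_background_peak(compute_histogram(img))$peak_intensity
  }, numeric(1))
  expect_true(all(abs(peaks - 50) <= 1))
})

test_that("background reflection doubles the low side and counts the peak bin once", {
  h <- intensity_histogram(c(1, 3, 5, 3, 1))
  est <- estimate_background_area(h, 2)
  expect_equal(est$background_count, 13)
  expect_false(est$clamp_applied)
  # with a signal bin the background estimate is unchanged
  hb <- worked_bimodal_hist()
  estb <- estimate_background_area(hb, 2)
  expect_equal(estb$background_count, 13)
  # single-bin histogram: background equals total without clamping
  h1 <- intensity_histogram(c(0, 0, 100), bin_values = 28:30)
  e1 <- estimate_background_area(h1, 30)
  expect_equal(e1$background_count, 100)
  expect_false(e1$clamp_applied)
  # asymmetric histogram overshoots and is clamped at the total
  h2 <- intensity_histogram(c(10, 6, 5, 1, 1))
  e2 <- estimate_background_area(h2, 1)
  expect_true(e2$clamp_applied)
  expect_equal(e2$background_count, h2$total)
  expect_error(estimate_background_area(h, 99), "range")
})

test_that("worked bimodal histogram yields fraction 10/23 exactly", {
  r <- labeled_area_fraction(worked_bimodal_hist())
  expect_equal(r$peak_intensity, 2.0)
  expect_equal(r$background_count, 13)
  expect_equal(r$fraction, 10 / 23)
})

test_that("doubling is exact on symmetric unimodal count vectors", {
  set.seed(42)
  for (k in 1:20) {
    half <- sort(sample.int(50, 4))            # increasing low side
    counts <- c(half, max(half) + sample.int(10, 1), rev(half))
    r <- labeled_area_fraction(intensity_histogram(counts))
    expect_equal(r$background_count, sum(counts))
    expect_equal(r$fraction, 0)
  }
})

test_that("fractions stay in [0,1] at both extremes and degenerate inputs", {
  all_bg <- generate_section_image(tiny_spec(true_fraction = 0, seed = 4))
  all_sig <- generate_section_image(tiny_spec(true_fraction = 1, seed = 4,
                                              bg_mean = 30, bg_sd = 2))
  for (img in list(all_bg, all_sig)) {
    f <- labeled_area_fraction(img)$fraction
    expect_gte(f, 0); expect_lte(f, 1)
  }
  expect_warning(r <- labeled_area_fraction(intensity_image(matrix(7L, 4, 4))),
                 "degenerate")
  expect_equal(r$fraction, 0)
  expect_true(r$degenerate)
})

test_that("replacing background with signal never decreases the estimate", {
  set.seed(11)
  n <- 64L
  bg <- matrix(as.integer(pmax(0, round(rnorm(n * n, 30, 2)))), n, n)
  sig_vals <- as.integer(round(rnorm(n * n, 160, 20)))
  ord <- sample.int(n * n)                     # nested replacement order
  prev <- -Inf
  for (f in seq(0, 0.8, by = 0.1)) {
    px <- bg
    k <- round(f * n * n)
    if (k > 0) px[ord[seq_len(k)]] <- sig_vals[ord[seq_len(k)]]
    est <- labeled_area_fraction(intensity_image(px))$fraction
    expect_gte(est, prev - 1e-12)
    prev <- est
  }
})

test_that("estimator recovers truth on ideal well-separated images", {
  sp <- tiny_spec(true_fraction = 0.4, seed = 1)
  expect_true(is_well_separated(sp))
  errs <- vapply(1:30, function(s) {
    img <- generate_section_image(tiny_spec(true_fraction = 0.4, seed = s))
    labeled_area_fraction(img)$fraction - 0.4
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.03)
})

test_that("animal aggregation averages sections and is order invariant", {
  r <- animal_area_fraction(c(0.30, 0.35, 0.40), marker = "GFAP")
  expect_equal(r$animal_fraction, 0.35)
  expect_equal(animal_area_fraction(0.5, "Iba1")$animal_fraction, 0.5)
  expect_equal(animal_area_fraction(c(0.40, 0.30, 0.35))$animal_fraction, 0.35)
  expect_error(animal_area_fraction(numeric(0)), "no section")
})

test_that("batch quantification aggregates triplicates per animal", {
  imgs <- lapply(1:6, function(s) generate_section_image(
    tiny_spec(true_fraction = ifelse(s <= 3, 0.1, 0.5), seed = s, size = 48L)))
  man <- data.frame(animal_id = rep(c("A", "B"), each = 3),
                    marker = "GFAP", section_index = rep(1:3, 2))
  man$image <- I(imgs)
  out <- quantify_images(man)
  expect_equal(nrow(out), 6)
  expect_equal(out$animal_fraction[1], mean(out$fraction[1:3]))
  expect_lt(abs(out$animal_fraction[1] - 0.1), 0.03)
  expect_lt(abs(out$animal_fraction[4] - 0.5), 0.03)
  expect_error(quantify_images(man[, -1]), "missing columns")
})
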