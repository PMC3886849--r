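test_that("arterial oxygen content reproduces the printed epoch means", {
  expect_equal(compute_cao2(9.2, 66.4, 25.0), 1.34 * 9.2 * 0.664 + 0.075)
  expect_lt(abs(compute_cao2(9.2, 66.4, 25.0) - 8.2), 0.1)   # baseline
  expect_lt(abs(compute_cao2(9.2, 35.0, 16.0) - 4.3), 0.1)   # hypoxia
  expect_equal(compute_cao2(0, 50, 20), 0.003 * 20)
  expect_error(compute_cao2(9, 120, 20))
})

test_that("covariance builder honors signed r-squared targets", {
  tg <- data.frame(var1 = "a", var2 = "b", r2 = 0.74, sign = -1)
  S <- build_covariance(tg, c(a = 2, b = 3))
  expect_equal(S["a", "b"] / (2 * 3), -sqrt(0.74))
  S0 <- build_covariance(tg[0, ], c(a = 2, b = 3))
  expect_equal(unname(S0), diag(c(4, 9)), ignore_attr = TRUE)
  # default target set is PD (or within a 0.05 projection)
  sds <- c(BP = 2.2, CaO2 = 2.3, glucose = 0.2, lactate = 0.6)
  Sd <- build_covariance(default_r2_targets(), sds)
  expect_lt(attr(Sd, "projection_distance"), 0.05)
  expect_true(all(eigen(Sd, symmetric = TRUE, only.values = TRUE)$values > 0))
  # a frustrated triangle cannot be repaired within tolerance
  bad <- data.frame(var1 = c("a", "a", "b"), var2 = c("b", "c", "c"),
                    r2 = c(0.98, 0.98, 0.98), sign = c(1, 1, -1))
  expect_error(build_covariance(bad, c(a = 1, b = 1, c = 1)), "infeasible")
})

test_that("cohort structure matches the study design", {
  ch <- test_cohort(seed = 4)
  an <- ch$animals
  expect_equal(sum(an$group == "HI"), 17)
  expect_equal(sum(an$group == "control"), 17)
  expect_equal(sum(an$survival_week[an$group == "HI"] == 1), 10)
  ep <- ch$epochs
  expect_equal(sort(unique(ep$epoch[ep$group == "HI"])),
               sort(c("baseline", "hypoxia", "hypoxia_ischemia", "recovery")))
  expect_equal(unique(ep$epoch[ep$group == "control"]), "baseline")
  expect_true(all(is.na(ep$HR[ep$epoch == "hypoxia_ischemia"])))
  expect_true(all(!is.na(ep$HR[ep$epoch != "hypoxia_ischemia"])))
  expect_true(all(an$gfap_fraction >= 0 & an$gfap_fraction <= 1))
  expect_true(all(an$pathology_score %in% 0:4))
  expect_true(all(an$pathology_score[an$group == "control"] == 0L))
})

test_that("each record's CaO2 is consistent with Hb, SatO2 and PO2", {
  ep <- test_cohort(seed = 5)$epochs
  expect_true(all(abs(ep$CaO2 - compute_cao2(ep$Hb, ep$SatO2, ep$PO2)) < 0.01))
  expect_true(all(ep$SatO2 >= 0 & ep$SatO2 <= 100))
})

test_that("cohort generation is deterministic and seed-sensitive", {
  expect_cohorts_equal(test_cohort(seed = 8), test_cohort(seed = 8))
  a <- test_cohort(seed = 8); b <- test_cohort(seed = 9)
  expect_false(isTRUE(all.equal(a$animals$gfap_fraction,
                                b$animals$gfap_fraction)))
})

test_that("degenerate noise collapses the occlusion epoch onto its targets", {
  phys <- epoch_physiology_defaults()
  phys$sd <- ifelse(is.na(phys$sd), NA, 1e-9)
  ch <- generate_cohort(cohort_config(physiology = phys, seed = 2))
  hi <- ch$epochs[ch$epochs$epoch == "hypoxia_ischemia", ]
  expect_equal(hi$BP, rep(7.1, 17), tolerance = 1e-6)
  expect_equal(hi$glucose, rep(1.7, 17), tolerance = 1e-6)
  expect_equal(hi$lactate, rep(3.6, 17), tolerance = 1e-6)
})

test_that("recovery glucose and lactate inherit occlusion-epoch ranks", {
  ep <- test_cohort(seed = 12)$epochs
  hi <- ep[ep$epoch == "hypoxia_ischemia", ]
  rec <- ep[ep$epoch == "recovery", ]
  rec <- rec[match(hi$animal_id, rec$animal_id), ]
  expect_equal(rank(rec$glucose), rank(hi$glucose))
  expect_equal(rank(rec$lactate), rank(hi$lactate))
})

test_that("GFAP fraction falls across H-I glucose terciles", {
  gl <- gf <- numeric(0)
  for (s in 1:30) {
    ch <- test_cohort(seed = 100 + s)
    hi <- ch$epochs[ch$epochs$epoch == "hypoxia_ischemia", ]
    an <- ch$animals[ch$animals$group == "HI", ]
    gl <- c(gl, hi$glucose[match(an$animal_id, hi$animal_id)])
    gf <- c(gf, an$gfap_fraction)
  }
  terc <- cut(gl, quantile(gl, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  m <- tapply(gf, terc, mean)
  expect_true(all(diff(m) < 0))
})

test_that("control fractions are independent of the H-I covariance block", {
  tg <- default_r2_targets()
  tg$r2[tg$var1 == "lactate"] <- 0.5   # outside the severity composite
  a <- test_cohort(seed = 21)
  b <- generate_cohort(cohort_config(r2_targets = tg, seed = 21))
  expect_equal(a$animals$gfap_fraction[a$animals$group == "control"],
               b$animals$gfap_fraction[b$animals$group == "control"])
})

test_that("cohort CSV round trip is lossless and schema-checked", {
  dir <- withr::local_tempdir()
  ch <- test_cohort(seed = 6)
  write_cohort_csv(ch, dir)
  back <- read_cohort_csv(dir)
  expect_cohorts_equal(ch, back)
  # empty cohort writes header-only files
  empty <- structure(list(animals = ch$animals[0, ], epochs = ch$epochs[0, ],
                          clips = NULL, projection_distance = 0, config = NULL),
                     class = "glia_cohort")
  dir2 <- withr::local_tempdir()
  write_cohort_csv(empty, dir2)
  expect_equal(nrow(read.csv(file.path(dir2, "animals.csv"))), 0)
  # missing column is named in the error
  ep <- read.csv(file.path(dir, "epochs.csv"))
  write.csv(ep[setdiff(names(ep), "glucose")], file.path(dir, "epochs.csv"),
            row.names = FALSE)
  expect_error(read_cohort_csv(dir), "glucose")
})

test_that("replicate calibration check passes under the default config", {
  m <- check_calibration(cohort_config(seed = 31), n_cohorts = 25,
                         max_rel_err = 0.20)
  expect_true(all(c("quantity", "target", "recovered") %in% names(m)))
  expect_true(any(grepl("^cor:", m$quantity)))
})

test_that("per-cohort self-check triggers on a miscalibrated configuration", {
  links <- default_marker_links()
  links$GFAP$c0 <- links$GFAP$c0 - 1.5   # GFAP mean far off its target
  expect_error(generate_cohort(cohort_config(marker_links = links, seed = 3),
                               self_check = TRUE), "self-check")
  expect_silent(generate_cohort(cohort_config(seed = 3), self_check = TRUE))
})
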