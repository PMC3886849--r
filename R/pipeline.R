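# End-to-end desk-scale study: simulate cohort -> synthesize section images
# -> quantify stained fractions -> score pathology -> run associations ->
# emit a recovered-vs-target report. Every stage is seeded from one top-level
# seed by fixed offsets, so reruns are byte-identical.

#' Pipeline configuration
#'
#' @param seed top-level seed; fans out to per-stage child seeds.
#' @param cohort a [cohort_config()] (its seed is overridden by `seed`).
#' @param image_width,image_height section geometry in pixels.
#' @param bit_depth image bit depth.
#' @param n_sections sections per animal and marker (triplicate).
#' @param skip_images if `TRUE` the quantification stage uses the simulated
#'   per-animal fractions directly (no imaging); associations are unchanged
#'   in expectation because the image estimator is unbiased.
#' @param write_images write TIFFs to disk (in-memory quantification
#'   otherwise; the manifest then records empty paths).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_config(),
                            image_width = 512L, image_height = 512L,
                            bit_depth = 8L, n_sections = 3L,
                            skip_images = FALSE, write_images = FALSE) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 bit_depth = as.integer(bit_depth),
                 n_sections = as.integer(n_sections),
                 skip_images = isTRUE(skip_images),
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML document
#'
#' Recognized top-level keys: `seed`, `image_width`, `image_height`,
#' `bit_depth`, `n_sections`, `skip_images`, `write_images`, and a `cohort`
#' block with `n_hi`, `n_week1`, `n_controls`, `necrosis_threshold`,
#' `necrosis_gain`, `necrosis_noise_sd`, `jitter_sd`. Omitted keys keep
#' their defaults. See `system.file("extdata", "example-config.yaml",
#' package = "gliaquant")`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  co <- do.call(cohort_config, y$cohort %||% list())
  args <- y[setdiff(names(y), "cohort")]
  args$cohort <- co
  do.call(pipeline_config, args)
}

quantify_cohort_images <- function(cohort, config, seed) {
  an <- cohort$animals
  rows <- list()
  for (i in seq_len(nrow(an))) {
    for (mk in c("GFAP", "Iba1")) {
      frac <- if (mk == "GFAP") an$gfap_fraction[i] else an$iba1_fraction[i]
      sec <- generate_animal_sections(
        severity = an$severity[i], marker = mk,
        n_sections = config$n_sections, calib = frac,
        seed = child_seed(seed, 31L * i + (mk == "Iba1")),
        jitter_sd = cohort$config$jitter_sd %||% 0.02,
        width = config$image_width, height = config$image_height,
        bit_depth = config$bit_depth)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = an$animal_id[i], marker = mk,
        section_index = seq_len(config$n_sections),
        true_fraction = sec$true_fractions,
        image = I(sec$images), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full desk-scale study
#'
#' Simulates a cohort, synthesizes and quantifies section images (unless
#' `skip_images`), scores pathology, computes the association profile over
#' the measured fractions, and writes all stage outputs plus a run manifest
#' with per-file checksums.
#'
#' @param config a [pipeline_config()] or path to a YAML config.
#' @param out_dir output directory (created).
#' @param seed optional override of the config seed.
#' @return the run manifest (list), invisibly written as `manifest.json`:
#'   config snapshot, seed, per-stage output paths and checksums, warnings
#'   (clip events, degenerate histograms, PD projection distance).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # -- simulate ---------------------------------------------------------
  cohort <- stage("simulate", {
    cc <- config$cohort
    cc$seed <- child_seed(config$seed, 1L)
    generate_cohort(cc)
  })
  write_cohort_csv(cohort, out_dir)
  if (nrow(cohort$clips))
    warnings <- c(warnings, sprintf("clip:%s(n=%d)", cohort$clips$what,
                                    cohort$clips$n))
  if (cohort$projection_distance > 0)
    warnings <- c(warnings, sprintf("PD projection distance %.4f",
                                    cohort$projection_distance))

  # -- images + quantify ------------------------------------------------
  fr_path <- file.path(out_dir, "fractions.csv")
  man_path <- file.path(out_dir, "image_manifest.csv")
  if (config$skip_images) {
    an <- cohort$animals
    fractions <- data.frame(
      animal_id = rep(an$animal_id, 2),
      marker = rep(c("GFAP", "Iba1"), each = nrow(an)),
      section_index = NA_integer_,
      fraction = c(an$gfap_fraction, an$iba1_fraction),
      animal_fraction = c(an$gfap_fraction, an$iba1_fraction),
      degenerate_flag = FALSE, clamp_flag = FALSE)
    manifest_df <- NULL
  } else {
    manifest_df <- stage("images",
      quantify_cohort_images(cohort, config, child_seed(config$seed, 2L)))
    if (config$write_images) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      # manifest stores paths relative to the output dir so runs are portable
      manifest_df$path <- file.path("images", sprintf(
        "%s_%s_s%d.tif", manifest_df$animal_id, manifest_df$marker,
        manifest_df$section_index))
      for (i in seq_len(nrow(manifest_df)))
        write_image_tiff(manifest_df$image[[i]],
                         file.path(out_dir, manifest_df$path[i]))
    } else manifest_df$path <- ""
    fractions <- stage("quantify",
      quantify_images(manifest_df, bit_depth = config$bit_depth))
    nd <- sum(fractions$degenerate_flag)
    if (nd) warnings <- c(warnings, sprintf("degenerate histograms: %d", nd))
    write.csv(manifest_df[c("animal_id", "marker", "section_index",
                            "true_fraction", "path")],
              man_path, row.names = FALSE)
  }
  write.csv(fractions, fr_path, row.names = FALSE)

  # -- analyze ----------------------------------------------------------
  results <- stage("analyze", {
    measured <- cohort
    agg <- unique(fractions[c("animal_id", "marker", "animal_fraction")])
    for (mk in c("GFAP", "Iba1")) {
      col <- if (mk == "GFAP") "gfap_fraction" else "iba1_fraction"
      sub <- agg[agg$marker == mk, ]
      measured$animals[[col]] <-
        sub$animal_fraction[match(measured$animals$animal_id, sub$animal_id)]
    }
    prof <- multi_predictor_profile(measured)
    an <- measured$animals
    grp <- lapply(c(GFAP = "gfap_fraction", Iba1 = "iba1_fraction"), function(col)
      two_group_f_test(an[[col]][an$group == "HI"],
                       an[[col]][an$group == "control"]))
    list(profile = prof, group_tests = grp, measured = measured)
  })
  write.csv(results$profile, file.path(out_dir, "associations.csv"),
            row.names = FALSE)
  n_hi_eff <- sum(results$measured$animals$group == "HI")
  summary_json <- list(
    n_hi = n_hi_eff,
    low_n = n_hi_eff < 8,
    ranking = lapply(split(results$profile, results$profile$outcome),
                     function(d) d$predictor[order(d$rank)]),
    group_tests = lapply(results$group_tests, function(g)
      list(F = g$F, p = g$p, mean_diff = g$mean_diff)))
  jsonlite::write_json(summary_json, file.path(out_dir, "associations.json"),
                       auto_unbox = TRUE, digits = NA)
  if (summary_json$low_n)
    warnings <- c(warnings, sprintf("low n (%d H-I animals)", n_hi_eff))

  # -- manifest ---------------------------------------------------------
  out_files <- c("animals.csv", "epochs.csv", "fractions.csv",
                 "associations.csv", "associations.json",
                 if (!config$skip_images) "image_manifest.csv")
  paths <- file.path(out_dir, out_files)
  manifest <- list(
    seed = config$seed,
    config = list(n_hi = config$cohort$n_hi, n_week1 = config$cohort$n_week1,
                  image_width = config$image_width,
                  image_height = config$image_height,
                  n_sections = config$n_sections,
                  skip_images = config$skip_images),
    outputs = as.list(setNames(paths, out_files)),
    checksums = as.list(tools::md5sum(paths)),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- report_summary(manifest)
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(manifest)
}

#' Human-readable recovered-vs-target report for a completed run
#'
#' Tabulates the run's recovered quantities (group mean fractions, the
#' week-adjusted r-squared profile, the lactate~CaO2 association, score-0
#' count and the score-0 GFAP span) against their calibration targets.
#' Stages whose outputs are missing are marked as gaps rather than failing.
#'
#' @param manifest a run manifest from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @return character vector of report lines.
#' @export
report_summary <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  if (is.null(manifest$outputs) || !length(manifest$outputs))
    stopf("empty run manifest")
  get_csv <- function(name) {
    p <- manifest$outputs[[name]]
    if (is.null(p) || !file.exists(p)) return(NULL)
    read.csv(p, stringsAsFactors = FALSE)
  }
  lines <- c("gliaquant run report",
             sprintf("seed: %s", manifest$seed),
             sprintf("%-38s %10s %10s", "quantity", "target", "recovered"))
  row <- function(name, target, value)
    sprintf("%-38s %10s %10s", name,
            ifelse(is.na(target), "-", format(round(target, 3))),
            ifelse(is.na(value), "MISSING", format(round(value, 3))))
  an <- get_csv("animals.csv")
  fr <- get_csv("fractions.csv")
  if (!is.null(an) && !is.null(fr)) {
    agg <- unique(fr[c("animal_id", "marker", "animal_fraction")])
    m <- merge(agg, an[c("animal_id", "group")], by = "animal_id")
    tg <- c(GFAP.HI = 0.40, GFAP.control = 0.22, Iba1.HI = 0.33,
            Iba1.control = 0.16)
    for (k in names(tg)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      v <- mean(m$animal_fraction[m$marker == parts[1] & m$group == parts[2]])
      lines <- c(lines, row(paste0("mean fraction ", k), tg[[k]], v))
    }
    z <- an$pathology_score == 0 & an$group == "HI"
    lines <- c(lines, row("score-0 H-I animals", 12, sum(z)))
    gf <- agg$animal_fraction[agg$marker == "GFAP"][
      match(an$animal_id[an$group == "HI"], agg$animal_id[agg$marker == "GFAP"])]
    if (sum(z) > 1) {
      span <- diff(range(gf[z[an$group == "HI"]])) / diff(range(gf))
      lines <- c(lines, row("score-0 GFAP span / range", 2 / 3, span))
    }
  } else {
    lines <- c(lines, row("mean fractions", NA, NA))
  }
  assoc <- get_csv("associations.csv")
  if (!is.null(assoc)) {
    tg_r2 <- rbind(
      data.frame(outcome = "GFAP", predictor = c("glucose", "CaO2", "BP"),
                 target = c(0.499, 0.21, 0.15)),
      data.frame(outcome = "Iba1", predictor = c("glucose", "CaO2", "BP"),
                 target = c(0.298, 0.08, 0.057)))
    for (i in seq_len(nrow(tg_r2))) {
      v <- assoc$r2[assoc$outcome == tg_r2$outcome[i] &
                      assoc$predictor == tg_r2$predictor[i]]
      lines <- c(lines, row(sprintf("r2 %s ~ %s", tg_r2$outcome[i],
                                    tg_r2$predictor[i]),
                            tg_r2$target[i], if (length(v)) v else NA))
    }
  } else {
    lines <- c(lines, row("association profile", NA, NA))
  }
  ep <- get_csv("epochs.csv")
  if (!is.null(ep)) {
    hi <- ep[ep$epoch == "hypoxia_ischemia", ]
    a <- adjusted_linear_assoc(hi$lactate, hi$CaO2, hi$survival_week,
                               "lactate", "CaO2")
    lines <- c(lines, row("r2 lactate ~ CaO2", 0.74, a$r2),
               row("mean H-I cephalic BP (mmHg)", 7.1, mean(hi$BP)),
               row("mean baseline glucose (mM)", 1.3,
                   mean(ep$glucose[ep$epoch == "baseline"])))
  } else {
    lines <- c(lines, row("epoch physiology", NA, NA))
  }
  if (length(manifest$warnings))
    lines <- c(lines, "", "warnings:",
               paste0("  ", unlist(manifest$warnings)))
  lines
}
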