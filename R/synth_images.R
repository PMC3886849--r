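# Synthetic immunofluorescence section images with known ground truth.
#
# Each image emulates one montaged white-matter section stained for GFAP or
# Iba1: a dominant low-intensity background mode plus brighter stained pixels
# laid down as tissue-like blobs. The generator controls the stained fraction
# exactly (by pixel count), which is what makes estimator-recovery studies
# possible.

#' Specify a synthetic section image
#'
#' Parameters of a single synthetic grayscale section: geometry, bit depth,
#' the true stained-area fraction, and the background/signal intensity
#' distributions (truncated Gaussians, clipped to the bit range).
#'
#' @param width,height image size in pixels.
#' @param bit_depth bits per pixel, 8 or 16.
#' @param true_fraction ground-truth stained fraction of the ROI, in [0, 1].
#' @param bg_mean,bg_sd background intensity mean and SD (intensity units).
#' @param signal_mean,signal_sd stained-pixel intensity mean and SD.
#' @param seed integer seed; the image is a deterministic function of the spec.
#' @return an object of class `image_spec`.
#' @examples
#' sp <- image_spec(true_fraction = 0.4, seed = 1)
#' img <- generate_section_image(sp)
#' mean(img$truth_mask[img$roi_mask])
#' @export
image_spec <- function(width = 512L, height = 512L, bit_depth = 8L,
                       true_fraction = 0, bg_mean = 30, bg_sd = 2,
                       signal_mean = 160, signal_sd = 20, seed = 1L) {
  stopifnot(width >= 8, height >= 8, bit_depth %in% c(8L, 16L))
  if (!is.numeric(true_fraction) || length(true_fraction) != 1L ||
      is.na(true_fraction) || true_fraction < 0 || true_fraction > 1)
    stopf("true_fraction must be a single value in [0, 1]")
  maxI <- 2^bit_depth - 1
  # fraction of draws expected to clip outside the bit range; reject leaky specs
  p_clip_bg <- pnorm(0, bg_mean, bg_sd) +
    pnorm(maxI, bg_mean, bg_sd, lower.tail = FALSE)
  p_clip_sig <- pnorm(0, signal_mean, signal_sd) +
    pnorm(maxI, signal_mean, signal_sd, lower.tail = FALSE)
  p_clip <- (1 - true_fraction) * p_clip_bg + true_fraction * p_clip_sig
  if (p_clip > 0.001)
    stopf("intensity distributions overflow the %d-bit range for %.2f%% of pixels (limit 0.1%%)",
          bit_depth, 100 * p_clip)
  structure(list(width = as.integer(width), height = as.integer(height),
                 bit_depth = as.integer(bit_depth),
                 true_fraction = true_fraction,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 signal_mean = signal_mean, signal_sd = signal_sd,
                 seed = as.integer(seed)),
            class = "image_spec")
}

#' Test whether a spec's background and signal modes are well separated
#'
#' Separation by at least four SDs on each side, the regime in which the
#' histogram-reflection estimator is expected to be unbiased.
#'
#' @param spec an [image_spec()].
#' @return logical.
#' @export
is_well_separated <- function(spec) {
  spec$bg_mean + 4 * spec$bg_sd < spec$signal_mean - 4 * spec$signal_sd
}

# Stamp random disks into `mask` (restricted to roi) until `target` pixels are
# covered, then trim the surplus of the final disk at random. Exactness by
# pixel count is the contract; blobs only shape the spatial layout.
place_blobs <- function(roi, target, radius_range, nr, nc) {
  mask <- matrix(FALSE, nr, nc)
  if (target <= 0) return(mask)
  roi_idx <- which(roi)
  covered <- 0L
  guard <- 0L
  while (covered < target) {
    guard <- guard + 1L
    if (guard > 200000L) stopf("blob placement failed to reach target coverage")
    r <- sample.int(radius_range[2] - radius_range[1] + 1L, 1L) + radius_range[1] - 1L
    ctr <- roi_idx[sample.int(length(roi_idx), 1L)]
    ci <- ((ctr - 1L) %% nr) + 1L
    cj <- ((ctr - 1L) %/% nr) + 1L
    di <- seq.int(max(1L, ci - r), min(nr, ci + r))
    dj <- seq.int(max(1L, cj - r), min(nc, cj + r))
    circ <- outer(di - ci, dj - cj, function(a, b) a * a + b * b <= r * r)
    idx <- cbind(rep(di, times = length(dj))[as.vector(circ)],
                 rep(dj, each = length(di))[as.vector(circ)])
    lin <- idx[, 1L] + (idx[, 2L] - 1L) * nr
    lin <- lin[roi[lin] & !mask[lin]]
    if (!length(lin)) next
    need <- target - covered
    if (length(lin) > need) lin <- lin[sample.int(length(lin), need)]
    mask[lin] <- TRUE
    covered <- covered + length(lin)
  }
  mask
}

#' Generate one synthetic section image
#'
#' Draws exactly `round(true_fraction * |ROI|)` stained pixels (placed as
#' random disk blobs so the image is tissue-like) from the signal
#' distribution; all remaining ROI pixels come from the background
#' distribution. Intensities are rounded and clipped to the bit range.
#' Deterministic for a fixed spec.
#'
#' @param spec an [image_spec()].
#' @param roi_mask optional logical matrix (height x width); defaults to the
#'   full frame, emulating a traced white-matter region when supplied.
#' @param blob_radius_range integer range of blob radii in pixels.
#' @return an object of class `intensity_image`: list with integer matrix
#'   `pixels`, logical `roi_mask` and `truth_mask`, and `bit_depth`.
#' @export
generate_section_image <- function(spec, roi_mask = NULL,
                                   blob_radius_range = c(3L, 8L)) {
  stopifnot(inherits(spec, "image_spec"))
  nr <- spec$height; nc <- spec$width
  roi <- roi_mask %||% matrix(TRUE, nr, nc)
  stopifnot(is.logical(roi), nrow(roi) == nr, ncol(roi) == nc)
  n_roi <- sum(roi)
  if (n_roi == 0L) stopf("empty ROI")
  set.seed(spec$seed)
  n_sig <- as.integer(round(spec$true_fraction * n_roi))
  truth <- place_blobs(roi, n_sig, as.integer(blob_radius_range), nr, nc)
  px <- matrix(0L, nr, nc)
  bg_idx <- which(roi & !truth)
  px[bg_idx] <- as.integer(round(rnorm(length(bg_idx), spec$bg_mean, spec$bg_sd)))
  sig_idx <- which(truth)
  px[sig_idx] <- as.integer(round(rnorm(length(sig_idx), spec$signal_mean, spec$signal_sd)))
  px <- matrix(clamp(px, 0L, as.integer(2^spec$bit_depth - 1)), nr, nc)
  structure(list(pixels = px, roi_mask = roi, truth_mask = truth,
                 bit_depth = spec$bit_depth),
            class = "intensity_image")
}

#' Construct an intensity image from raw components
#'
#' @param pixels integer matrix of intensities.
#' @param roi_mask optional logical matrix; defaults to the full frame.
#' @param bit_depth bits per pixel.
#' @return an `intensity_image`.
#' @export
intensity_image <- function(pixels, roi_mask = NULL, bit_depth = 8L) {
  pixels <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  roi <- roi_mask %||% matrix(TRUE, nrow(pixels), ncol(pixels))
  stopifnot(identical(dim(pixels), dim(roi)), is.logical(roi))
  if (any(pixels < 0 | pixels > 2^bit_depth - 1, na.rm = TRUE))
    stopf("pixel intensities outside the %d-bit range", bit_depth)
  structure(list(pixels = pixels, roi_mask = roi, truth_mask = NULL,
                 bit_depth = as.integer(bit_depth)),
            class = "intensity_image")
}

#' Map latent injury severity to a stained fraction
#'
#' Linear calibration mapping with a floor at the marker's control mean; used
#' by [generate_animal_sections()]. The mapping must be non-decreasing in
#' severity (checked on construction).
#'
#' @param floor_fraction stained fraction at (and below) `severity_floor`,
#'   the marker's uninjured mean.
#' @param slope fraction units per severity unit, must be > 0.
#' @param severity_floor severity at which injury-related staining begins.
#' @return a function severity -> fraction, clamped to [0, 0.85].
#' @export
severity_calibration <- function(floor_fraction, slope, severity_floor = 0) {
  stopifnot(slope > 0, floor_fraction >= 0, floor_fraction < 1)
  f <- function(severity)
    clamp(floor_fraction + slope * pmax(0, severity - severity_floor), 0, 0.85)
  grid <- seq(-4, 4, length.out = 41)
  if (any(diff(f(grid)) < 0)) stopf("calibration mapping is not monotone")
  f
}

#' Generate the triplicate sections for one animal and marker
#'
#' Produces `n_sections` images whose true fractions are `calib(severity)`
#' plus small per-section jitter, emulating the triplicate sections that are
#' alternately stained for each marker.
#'
#' @param severity latent injury severity (unitless).
#' @param marker `"GFAP"` or `"Iba1"`.
#' @param n_sections number of sections (default 3, triplicate).
#' @param calib a monotone severity-to-fraction mapping, e.g.
#'   [severity_calibration()], or a fixed fraction to use directly.
#' @param seed integer seed.
#' @param jitter_sd SD of per-section jitter on the true fraction.
#' @param width,height,bit_depth,bg_mean,bg_sd,signal_mean,signal_sd passed to
#'   [image_spec()].
#' @return list with `images` (list of `intensity_image`) and numeric
#'   `true_fractions`.
#' @export
generate_animal_sections <- function(severity, marker = c("GFAP", "Iba1"),
                                     n_sections = 3L, calib, seed,
                                     jitter_sd = 0.02,
                                     width = 512L, height = 512L,
                                     bit_depth = 8L, bg_mean = 30, bg_sd = 2,
                                     signal_mean = 160, signal_sd = 20) {
  marker <- match.arg(marker)
  base_fraction <- if (is.function(calib)) calib(severity) else {
    stopifnot(is.numeric(calib), length(calib) == 1L)
    calib
  }
  set.seed(child_seed(seed, 7L))
  fr <- clamp(base_fraction + rnorm(n_sections, 0, jitter_sd), 0, 0.90)
  images <- lapply(seq_len(n_sections), function(k) {
    generate_section_image(image_spec(
      width = width, height = height, bit_depth = bit_depth,
      true_fraction = fr[k], bg_mean = bg_mean, bg_sd = bg_sd,
      signal_mean = signal_mean, signal_sd = signal_sd,
      seed = child_seed(seed, 100L + k)))
  })
  list(images = images, true_fractions = fr, marker = marker)
}

#' Write an intensity image (and masks) to TIFF
#'
#' Pixels are stored at native bit depth; ROI and truth masks as 0/255
#' single-channel images alongside, with `.roi.tif` / `.truth.tif` suffixes.
#'
#' @param image an `intensity_image`.
#' @param path output path for the pixel TIFF.
#' @param write_masks write ROI/truth mask companions.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path, write_masks = FALSE) {
  stopifnot(inherits(image, "intensity_image"))
  maxI <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$pixels / maxI, path,
                  bits.per.sample = image$bit_depth, compression = "none")
  if (write_masks) {
    base <- sub("\\.tiff?$", "", path)
    tiff::writeTIFF(ifelse(image$roi_mask, 1, 0), paste0(base, ".roi.tif"),
                    bits.per.sample = 8L, compression = "none")
    if (!is.null(image$truth_mask))
      tiff::writeTIFF(ifelse(image$truth_mask, 1, 0), paste0(base, ".truth.tif"),
                      bits.per.sample = 8L, compression = "none")
  }
  invisible(path)
}

#' Read an intensity image from TIFF
#'
#' @param path pixel TIFF written by [write_image_tiff()].
#' @param bit_depth bit depth the file was written at.
#' @param roi_path optional companion ROI mask TIFF.
#' @return an `intensity_image`.
#' @export
read_image_tiff <- function(path, bit_depth = 8L, roi_path = NULL) {
  maxI <- 2^bit_depth - 1
  px <- round(tiff::readTIFF(path) * maxI)
  roi <- NULL
  if (!is.null(roi_path)) roi <- tiff::readTIFF(roi_path) > 0.5
  intensity_image(px, roi_mask = roi, bit_depth = bit_depth)
}
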