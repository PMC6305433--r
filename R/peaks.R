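#' Parameters of the perineurial peak analysis
#'
#' Defaults are the published settings of the algorithm: minimal peak
#' amplitude 1.5 x the perineurial gray-level standard deviation
#' (interpreted as topographic prominence), minimal peak distance 1 um,
#' minimal value of a maximum 40, background elimination by subtracting
#' 1.5 x the perineurial mean gray value followed by a Gaussian blur of
#' radius 2 px (mapped to the Gaussian sigma), peak calling along 5 profile
#' lines, and a quality-control discard of samples whose perineurial mean
#' gray value is >= 143.33 -- exactly the solvability boundary of the
#' defaults, since `255 - 1.5 * 143.33` is (approximately) 40, the minimal
#' admissible maximum.
#'
#' @param amp_factor prominence threshold multiplier on `sd_gray`.
#' @param min_distance_um minimal spacing between accepted peaks (um).
#' @param min_value minimal height of a maximum (post-subtraction scale).
#' @param subtract_factor multiplier on `mean_gray` for the threshold
#'   subtraction.
#' @param blur_radius_px Gaussian blur sigma in pixels.
#' @param qc_mean_max perineurial mean gray value at or above which a sample
#'   is discarded.
#' @param n_lines number of profile lines per sample.
#' @param prominence_mode `"prominence"` (topographic, default) or
#'   `"height"` (amplitude above the profile minimum); the published
#'   description does not fix the routine's exact semantics.
#' @param stats_on how the thresholds' mean/SD are computed: on the `"raw"`
#'   perineurial pixels (default; the statistics are described before the
#'   subtraction step) or on the `"preprocessed"` image.
#' @return list of class `peak_params`.
#' @export
peak_params <- function(amp_factor = 1.5, min_distance_um = 1,
                        min_value = 40, subtract_factor = 1.5,
                        blur_radius_px = 2, qc_mean_max = 143.33,
                        n_lines = 5L,
                        prominence_mode = c("prominence", "height"),
                        stats_on = c("raw", "preprocessed")) {
  p <- list(amp_factor = amp_factor, min_distance_um = min_distance_um,
            min_value = min_value, subtract_factor = subtract_factor,
            blur_radius_px = blur_radius_px, qc_mean_max = qc_mean_max,
            n_lines = as.integer(n_lines),
            prominence_mode = match.arg(prominence_mode),
            stats_on = match.arg(stats_on))
  num <- p[c("amp_factor", "min_distance_um", "min_value", "subtract_factor",
             "blur_radius_px", "qc_mean_max", "n_lines")]
  if (any(unlist(num) <= 0))
    stop("parameter error: all peak parameters must be positive",
         call. = FALSE)
  class(p) <- "peak_params"
  p
}

#' Gray-level statistics of the perineurium ROI
#'
#' Mean and sample standard deviation (n - 1 denominator) of all pixels
#' under the perineurium mask of the unprocessed channel image; these drive
#' the subtraction threshold, the prominence criterion, and the QC filter.
#'
#' @param image 2-D numeric matrix (raw channel plane).
#' @param perineurium_mask logical mask.
#' @return list of class `roi_gray_stats` with `mean_gray, sd_gray, n_px`.
#' @export
roi_gray_stats <- function(image, perineurium_mask) {
  m <- roi_mean(image, perineurium_mask)
  if (m$area_px < 2L)
    stop("sd undefined error: need >= 2 pixels in the perineurium ROI",
         call. = FALSE)
  structure(list(mean_gray = m$mean,
                 sd_gray = stats::sd(image[perineurium_mask]),
                 n_px = m$area_px),
            class = "roi_gray_stats")
}

#' Quality-control filter on perineurial contrast
#'
#' Returns `FALSE` (discard) exactly when `mean_gray >= qc_mean_max`
#' (143.33 by default): such samples cannot produce enough contrast for any
#' admissible peak under the default subtraction and minimum-value settings.
#'
#' @param stats a [roi_gray_stats()].
#' @param params a [peak_params()].
#' @return logical `qc_pass`.
#' @export
qc_filter <- function(stats, params = peak_params()) {
  stats$mean_gray < params$qc_mean_max
}

.subtract_threshold <- function(image, stats, params) {
  pmax(image - params$subtract_factor * stats$mean_gray, 0)
}

#' Threshold subtraction and Gaussian blur
#'
#' Eliminates unspecific signal by clamping `pixel - subtract_factor *
#' mean_gray` at zero (the 8-bit subtraction floor), then applies a Gaussian
#' blur with `sigma = blur_radius_px` to the whole image. The output stays
#' in real precision; no re-quantization.
#'
#' @param image 2-D numeric matrix (raw channel plane).
#' @param stats a [roi_gray_stats()]; must pass [qc_filter()].
#' @param params a [peak_params()].
#' @return real-valued matrix of the same dimensions.
#' @export
preprocess_image <- function(image, stats, params = peak_params()) {
  if (!qc_filter(stats, params))
    stop("QC error: sample is discarded (mean gray ", round(stats$mean_gray,
         2), " >= ", params$qc_mean_max, ")", call. = FALSE)
  sub <- .subtract_threshold(image, stats, params)
  as.matrix(EBImage::gblur(sub, sigma = params$blur_radius_px))
}

.bilinear <- function(image, x, y) {
  h <- nrow(image); w <- ncol(image)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- image[cbind(y0 + 1, x0 + 1)]
  i01 <- image[cbind(y0 + 1, x0 + 2)]
  i10 <- image[cbind(y0 + 2, x0 + 1)]
  i11 <- image[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Sample an intensity profile along a drawn line
#'
#' Intensities are sampled by bilinear interpolation at arc-length steps of
#' 1 px along the (poly)line; positions are reported in micrometers.
#'
#' @param image 2-D numeric matrix (typically the preprocessed image).
#' @param line an open [polygon_roi()] with label `"profile_line"`.
#' @param pixel_size_um pixel size in micrometers.
#' @return list of class `line_profile` with `position_um` and `value`.
#' @export
sample_profile <- function(image, line, pixel_size_um) {
  stopifnot(inherits(line, "polygon_roi"))
  if (line$closed) stop("profile lines must be open polylines",
                        call. = FALSE)
  v <- line$vertices
  h <- nrow(image); w <- ncol(image)
  if (any(v[, 1] < 0 | v[, 1] > w - 1 | v[, 2] < 0 | v[, 2] > h - 1))
    stop("geometry error: profile line leaves the image bounds",
         call. = FALSE)
  seglen <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  t <- c(0, cumsum(seglen))
  s <- seq(0, floor(t[length(t)]), by = 1)
  xs <- stats::approx(t, v[, 1], xout = s)$y
  ys <- stats::approx(t, v[, 2], xout = s)$y
  structure(list(position_um = s * pixel_size_um,
                 value = .bilinear(image, xs, ys)),
            class = "line_profile")
}

# local maxima with plateaus collapsed to their center index
.local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(r$values)
  out <- integer(0)
  if (n >= 3L) {
    for (j in 2:(n - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
        out <- c(out, floor((starts[j] + ends[j]) / 2))
    }
  }
  out
}

# topographic prominence: on each side walk to the nearest strictly higher
# value (or the signal end); prominence = height - max(left min, right min)
.prominence <- function(v, i) {
  h <- v[i]
  lmin <- h
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (v[j] > h) break
    if (v[j] < lmin) lmin <- v[j]
  }
  rmin <- h
  j <- i
  n <- length(v)
  while (j < n) {
    j <- j + 1L
    if (v[j] > h) break
    if (v[j] < rmin) rmin <- v[j]
  }
  h - max(lmin, rmin)
}

#' Find peaks in a line profile
#'
#' A peak is a local maximum (plateaus contribute one peak at their center)
#' that (a) has height at least `min_value`, (b) has topographic prominence
#' at least `amp_factor * sd_gray`, and (c) survives greedy suppression in
#' descending height order (ties broken leftmost) so that accepted peaks are
#' pairwise at least `min_distance_um` apart.
#'
#' @param profile a [sample_profile()] result (or list with `position_um`,
#'   `value`).
#' @param stats a [roi_gray_stats()] supplying `sd_gray`.
#' @param params a [peak_params()].
#' @return list `(position_um, height, count)` with positions sorted.
#' @export
find_peaks <- function(profile, stats, params = peak_params()) {
  v <- profile$value
  pos <- profile$position_um
  if (length(v) < 3L)
    stop("degenerate-profile error: need at least 3 samples", call. = FALSE)
  cand <- .local_maxima(v)
  cand <- cand[v[cand] >= params$min_value]
  amp_min <- params$amp_factor * stats$sd_gray
  if (length(cand)) {
    amp <- if (params$prominence_mode == "prominence")
      vapply(cand, function(i) .prominence(v, i), numeric(1))
    else v[cand] - min(v)
    cand <- cand[amp >= amp_min]
  }
  keep <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-v[cand], pos[cand])]
    for (i in ord) {
      if (!length(keep) ||
          all(abs(pos[keep] - pos[i]) >= params$min_distance_um))
        keep <- c(keep, i)
    }
    keep <- sort(keep)
  }
  list(position_um = pos[keep], height = v[keep], count = length(keep))
}

#' Full peak analysis of one sample
#'
#' Runs the complete chain: perineurial gray statistics on the raw channel
#' image, QC filter, threshold subtraction and blur, profile sampling along
#' exactly `n_lines` drawn lines, peak calling per line, and the per-sample
#' mean peak count (the arithmetic mean of the per-line counts). Discarded
#' samples carry `qc_pass = FALSE` and no counts.
#'
#' @param image 2-D numeric matrix: raw channel plane of the analyzed slice.
#' @param rois list of [polygon_roi()] with the perineurium (outline) and
#'   endoneurium compartments and the profile lines.
#' @param pixel_size_um pixel size in micrometers.
#' @param params a [peak_params()].
#' @param sample_id sample identifier.
#' @param masks optional precomputed [compartment_masks()] for the ROIs.
#' @return list of class `peak_report`: `sample_id, qc_pass, stats,
#'   per_line` (positions/heights/count per line), `mean_peak_count`
#'   (`NA` when discarded).
#' @export
peak_report <- function(image, rois, pixel_size_um, params = peak_params(),
                        sample_id = NA_character_, masks = NULL) {
  labs <- vapply(rois, function(r) r$label, character(1))
  lines <- rois[labs == "profile_line"]
  if (length(lines) != params$n_lines)
    stop("arity error: expected ", params$n_lines, " profile lines, got ",
         length(lines), call. = FALSE)
  if (is.null(masks))
    masks <- compartment_masks(rois, nrow(image), ncol(image))
  st <- roi_gray_stats(image, masks$perineurium)
  if (!qc_filter(st, params))
    return(structure(list(sample_id = sample_id, qc_pass = FALSE,
                          stats = st, per_line = NULL,
                          mean_peak_count = NA_real_),
                     class = "peak_report"))
  pre <- preprocess_image(image, st, params)
  if (params$stats_on == "preprocessed")
    st_thr <- structure(list(mean_gray = mean(pre[masks$perineurium]),
                             sd_gray = stats::sd(pre[masks$perineurium]),
                             n_px = st$n_px), class = "roi_gray_stats")
  else st_thr <- st
  per_line <- lapply(lines, function(ln)
    find_peaks(sample_profile(pre, ln, pixel_size_um), st_thr, params))
  counts <- vapply(per_line, `[[`, numeric(1), "count")
  structure(list(sample_id = sample_id, qc_pass = TRUE, stats = st,
                 per_line = per_line, mean_peak_count = mean(counts)),
            class = "peak_report")
}

#' Peak reports for a synthetic cohort
#'
#' Applies [peak_report()] to the first z-slice of the stained channel of
#' every cohort sample, using the ground-truth ROIs.
#'
#' @param cohort output of [generate_cohort()].
#' @param params a [peak_params()].
#' @param slice which z-slice to analyze.
#' @param masks optional precomputed [compartment_masks()] shared by all
#'   samples (cohort samples share their ROI geometry).
#' @return data.frame `sample_id, group, qc_pass, mean_peak_count`.
#' @export
cohort_peaks <- function(cohort, params = peak_params(), slice = 1L,
                         masks = NULL) {
  if (is.null(masks) && length(cohort)) {
    d <- dim(cohort[[1]]$stack$slices[[1]])
    masks <- compartment_masks(cohort[[1]]$truth$rois, d[1], d[2])
  }
  rows <- lapply(cohort, function(s) {
    chan <- match(s$truth$channel, c("R", "G", "B"))
    img <- s$stack$slices[[slice]][, , chan]
    rep <- peak_report(img, s$truth$rois, s$stack$pixel_size_um, params,
                       sample_id = s$sample_id, masks = masks)
    data.frame(sample_id = s$sample_id, group = s$group,
               qc_pass = rep$qc_pass, mean_peak_count = rep$mean_peak_count)
  })
  do.call(rbind, rows)
}
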