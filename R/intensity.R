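#' Mean intensity under a mask
#'
#' Arithmetic mean of the pixel intensities whose mask entry is `TRUE`
#' (exact sum/area semantics up to double precision).
#'
#' @param image 2-D numeric matrix (a single channel plane).
#' @param mask logical matrix of the same dimensions.
#' @return list `(area_px, mean)`.
#' @export
roi_mean <- function(image, mask) {
  stopifnot(is.matrix(image), is.logical(mask),
            identical(dim(image), dim(mask)))
  area <- sum(mask)
  if (area == 0L) stop("empty-ROI error: mask selects no pixels",
                       call. = FALSE)
  list(area_px = area, mean = sum(as.numeric(image[mask])) / area)
}

#' Normalized immunofluorescence intensity (NIFI) of a compartment
#'
#' Computes the semiquantification chain
#' `IntD = area * mean_intensity`,
#' `IntC = IntD - area * bg_mean`, and
#' `NIFI = IntC / area = mean_intensity - bg_mean`,
#' where `bg_mean` is the unweighted mean of the mean intensities of exactly
#' three background areas. Negative NIFI values are retained; they indicate a
#' compartment dimmer than the background.
#'
#' @param image 2-D numeric matrix.
#' @param compartment_mask logical mask of the measured compartment.
#' @param background_masks list of exactly 3 logical masks, disjoint from
#'   the compartment mask.
#' @param sample_id,compartment metadata carried into the result.
#' @return list of class `nifi_result` with fields `sample_id, compartment,
#'   area_px, mean_intensity, IntD, bg_mean, IntC, NIFI`.
#' @export
nifi <- function(image, compartment_mask, background_masks,
                 sample_id = NA_character_, compartment = NA_character_) {
  if (!is.list(background_masks) || length(background_masks) != 3L)
    stop("arity error: exactly 3 background masks are required",
         call. = FALSE)
  for (bm in background_masks)
    if (any(bm & compartment_mask))
      stop("geometry error: background masks must be disjoint from the ",
           "compartment mask", call. = FALSE)
  comp <- roi_mean(image, compartment_mask)
  bg_means <- vapply(background_masks,
                     function(bm) roi_mean(image, bm)$mean, numeric(1))
  bg_mean <- mean(bg_means)
  int_d <- comp$area_px * comp$mean
  int_c <- int_d - comp$area_px * bg_mean
  structure(list(sample_id = sample_id, compartment = compartment,
                 area_px = comp$area_px, mean_intensity = comp$mean,
                 IntD = int_d, bg_mean = bg_mean, IntC = int_c,
                 NIFI = int_c / comp$area_px),
            class = "nifi_result")
}

#' Aggregate slice-level NIFI to an animal-level value
#'
#' Animal NIFI is the mean over fascicles of the mean over slices (nested
#' means, not a pooled mean), with at most 3 slices per fascicle and at most
#' 3 fascicles per animal.
#'
#' @param nifi_values numeric vector of per-slice NIFI values.
#' @param fascicle fascicle identifier per value (defaults to a single
#'   fascicle).
#' @return single numeric animal-level NIFI.
#' @export
aggregate_nifi <- function(nifi_values, fascicle = rep(1L,
                                                       length(nifi_values))) {
  if (length(nifi_values) == 0L)
    stop("empty-input error: no NIFI values to aggregate", call. = FALSE)
  stopifnot(length(fascicle) == length(nifi_values))
  per_fascicle <- tapply(nifi_values, fascicle, mean)
  if (length(per_fascicle) > 3L)
    stop("at most 3 fascicles per animal", call. = FALSE)
  if (any(table(fascicle) > 3L))
    stop("at most 3 slices per fascicle", call. = FALSE)
  mean(per_fascicle)
}

#' Percent change of a test group relative to a reference group
#'
#' Returns `100 * (1 - test / reference)`; positive values are reductions,
#' negative values increases.
#'
#' @param reference_group_mean positive reference mean.
#' @param test_group_mean test group mean.
#' @return percent change.
#' @export
percent_change <- function(reference_group_mean, test_group_mean) {
  if (!is.finite(reference_group_mean) || reference_group_mean <= 0)
    stop("domain error: reference group mean must be positive",
         call. = FALSE)
  100 * (1 - test_group_mean / reference_group_mean)
}

#' Animal-level NIFI table for a synthetic cohort
#'
#' Runs the NIFI chain on every sample of a generated cohort: extracts the
#' stained channel, rasterizes the ground-truth ROIs, computes per-slice
#' NIFI for the requested compartment with 3-area background correction, and
#' aggregates slices to one value per animal.
#'
#' @param cohort output of [generate_cohort()].
#' @param compartment `"perineurium"`, `"endoneurium"` or
#'   `"whole_fascicle"`.
#' @param masks optional precomputed [compartment_masks()] shared by all
#'   samples (all samples of a cohort share their ROI geometry).
#' @return data.frame `sample_id, group, nifi`.
#' @export
cohort_nifi <- function(cohort, compartment = "perineurium", masks = NULL) {
  compartment <- match.arg(compartment,
                           c("perineurium", "endoneurium", "whole_fascicle"))
  rows <- lapply(cohort, function(s) {
    d <- dim(s$stack$slices[[1]])
    m <- if (is.null(masks)) compartment_masks(s$truth$rois, d[1], d[2])
         else masks
    chan <- match(s$truth$channel, c("R", "G", "B"))
    vals <- vapply(s$stack$slices, function(sl)
      nifi(sl[, , chan], m[[compartment]], m$background)$NIFI, numeric(1))
    data.frame(sample_id = s$sample_id, group = s$group,
               nifi = aggregate_nifi(vals))
  })
  do.call(rbind, rows)
}

#' Tidy NIFI table across proteins and compartments
#'
#' @param stack a [zstack()].
#' @param rois list of [polygon_roi()] for the stack (one perineurium, one
#'   endoneurium, three background areas).
#' @param map a [channel_map()].
#' @param assignments named list mapping protein to the compartments in
#'   which it is quantified.
#' @return data.frame `sample_id, group, protein, compartment, slice,
#'   area_px, mean, IntD, IntC, NIFI`.
#' @export
nifi_table <- function(stack, rois, map,
                       assignments = list(
                         "claudin-1" = "perineurium",
                         "ZO-1" = c("perineurium", "endoneurium",
                                    "whole_fascicle"))) {
  d <- dim(stack$slices[[1]])
  m <- compartment_masks(rois, d[1], d[2])
  if (length(m$background) != 3L)
    stop("arity error: exactly 3 background ROIs are required per image",
         call. = FALSE)
  rows <- list()
  for (protein in names(assignments)) {
    planes <- extract_channel(stack, map, protein)
    for (comp in assignments[[protein]]) {
      for (s in seq_along(planes)) {
        r <- nifi(planes[[s]], m[[comp]], m$background,
                  sample_id = stack$sample_id, compartment = comp)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = stack$sample_id, group = stack$group,
          protein = protein, compartment = comp, slice = s,
          area_px = r$area_px, mean = r$mean_intensity, IntD = r$IntD,
          IntC = r$IntC, NIFI = r$NIFI)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
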