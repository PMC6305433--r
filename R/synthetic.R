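#' Parameters of a synthetic nerve fascicle image
#'
#' Defines the image model used for closed-loop validation: a perineurial
#' annulus carrying diffuse staining plus bright Gaussian spots at cell-cell
#' contact positions on the annulus midline (the sharp "zig-zag" junctional
#' signal), an endoneurial interior at background level, additive Gaussian
#' read noise on the analyzed channel, and optional DAPI-channel nuclei.
#' `internalization_fraction` redistributes contact signal into the diffuse
#' band component while conserving the total deposited signal, emulating
#' junctional protein moving to the cytoplasm after injury.
#'
#' @param image_size `(height, width)` in pixels.
#' @param pixel_size_um pixel edge length in micrometers.
#' @param center annulus center `(x, y)` in pixel coordinates; defaults to
#'   the image center.
#' @param inner_radius_px inner radius of the perineurial annulus (px).
#' @param band_width_px radial width of the annulus (px).
#' @param contact_density cell-cell contacts per 100 um of perineurial
#'   midline length.
#' @param contact_peak_height 8-bit amplitude of a contact spot before
#'   internalization.
#' @param contact_sd_px isotropic Gaussian spot standard deviation (px).
#' @param internalization_fraction share in `[0, 1]` of contact signal
#'   redistributed as diffuse band signal.
#' @param diffuse_level 8-bit diffuse staining level of the band.
#' @param background_level 8-bit baseline outside the band.
#' @param noise_sd standard deviation of additive Gaussian noise (gray
#'   levels), clipped to `[0, 255]`.
#' @param nuclei_count number of DAPI-channel nuclei dots in the endoneurium.
#' @param channel channel carrying the stain, `"R"` or `"G"` (`"B"` is
#'   reserved for nuclei).
#' @param seed integer seed; renders are bit-identical for a fixed seed.
#' @param sample_id,group sample metadata.
#' @return A list of class `fascicle_params`.
#' @export
fascicle_params <- function(image_size = c(208L, 208L),
                            pixel_size_um = 0.5,
                            center = NULL,
                            inner_radius_px = 84,
                            band_width_px = 8,
                            contact_density = 4,
                            contact_peak_height = 235,
                            contact_sd_px = 1.5,
                            internalization_fraction = 0,
                            diffuse_level = 10,
                            background_level = 5,
                            noise_sd = 4,
                            nuclei_count = 30L,
                            channel = "R",
                            seed = 1L,
                            sample_id = "synthetic",
                            group = "sham") {
  p <- list(image_size = as.integer(image_size), pixel_size_um = pixel_size_um,
            center = center, inner_radius_px = inner_radius_px,
            band_width_px = band_width_px, contact_density = contact_density,
            contact_peak_height = contact_peak_height,
            contact_sd_px = contact_sd_px,
            internalization_fraction = internalization_fraction,
            diffuse_level = diffuse_level, background_level = background_level,
            noise_sd = noise_sd, nuclei_count = as.integer(nuclei_count),
            channel = match.arg(channel, c("R", "G")), seed = as.integer(seed),
            sample_id = sample_id, group = group)
  if (is.null(p$center))
    p$center <- c((p$image_size[2] - 1) / 2, (p$image_size[1] - 1) / 2)
  if (p$contact_peak_height + p$diffuse_level + p$background_level > 255)
    stop("parameter error: contact_peak_height + diffuse_level + ",
         "background_level must be <= 255", call. = FALSE)
  if (p$inner_radius_px + p$band_width_px >= min(p$image_size) / 2)
    stop("parameter error: annulus must fit inside the image ",
         "(inner radius + band width < min(h, w)/2)", call. = FALSE)
  if (p$internalization_fraction < 0 || p$internalization_fraction > 1)
    stop("parameter error: internalization_fraction must be in [0, 1]",
         call. = FALSE)
  if (p$contact_density < 0 || p$noise_sd < 0 || p$pixel_size_um <= 0)
    stop("parameter error: nonnegative density/noise, positive pixel size",
         call. = FALSE)
  class(p) <- "fascicle_params"
  p
}

# geometry (distance map, band/endo masks) is deterministic per parameter
# set; cache it because cohorts render thousands of identically shaped images
.geom_cache <- new.env(parent = emptyenv())

.fascicle_geometry <- function(p) {
  key <- paste(p$image_size[1], p$image_size[2], p$center[1], p$center[2],
               p$inner_radius_px, p$band_width_px, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  h <- p$image_size[1]; w <- p$image_size[2]
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), w), h, w)
  r <- sqrt((x - p$center[1])^2 + (y - p$center[2])^2)
  band <- r >= p$inner_radius_px & r < p$inner_radius_px + p$band_width_px
  endo <- r < p$inner_radius_px
  g <- list(x = x, y = y, r = r, band = band, endo = endo,
            n_band = sum(band),
            mid_radius = p$inner_radius_px + p$band_width_px / 2)
  .geom_cache[[key]] <- g
  g
}

# noise-free stain field (double matrix) above background, plus contact info
.render_signal_field <- function(p, geom, phase) {
  h <- p$image_size[1]; w <- p$image_size[2]
  rm_px <- geom$mid_radius
  length_um <- 2 * pi * rm_px * p$pixel_size_um
  n_contacts <- round(p$contact_density * length_um / 100)
  field <- matrix(0, h, w)
  field[geom$band] <- p$diffuse_level
  spot_sum <- 0
  positions_um <- numeric(0)
  if (n_contacts > 0) {
    theta <- (phase + 2 * pi * (seq_len(n_contacts) - 1) / n_contacts) %%
      (2 * pi)
    positions_um <- sort(theta * rm_px * p$pixel_size_um)
    spots <- matrix(0, h, w)
    half <- ceiling(4 * p$contact_sd_px) + 1L
    for (k in seq_len(n_contacts)) {
      cx <- p$center[1] + rm_px * cos(theta[k])
      cy <- p$center[2] + rm_px * sin(theta[k])
      xr <- max(0L, floor(cx) - half):min(w - 1L, ceiling(cx) + half)
      yr <- max(0L, floor(cy) - half):min(h - 1L, ceiling(cy) + half)
      d2 <- outer((yr - cy)^2, (xr - cx)^2, "+")
      spots[yr + 1L, xr + 1L] <- spots[yr + 1L, xr + 1L] +
        p$contact_peak_height * exp(-d2 / (2 * p$contact_sd_px^2))
    }
    spots[!geom$band] <- 0 # contact signal is deposited within the band only
    spot_sum <- sum(spots)
    f <- p$internalization_fraction
    field <- field + (1 - f) * spots
    field[geom$band] <- field[geom$band] + f * spot_sum / geom$n_band
  }
  list(field = field, positions_um = positions_um, n_contacts = n_contacts,
       length_um = length_um)
}

.circle_polygon <- function(center, radius, n = 144L) {
  th <- 2 * pi * (0:(n - 1)) / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

.midline_arcs <- function(p, geom, n_lines = 5L, vertex_step_px = 2) {
  rm_px <- geom$mid_radius
  arc <- 2 * pi / n_lines
  lapply(seq_len(n_lines) - 1L, function(k) {
    nv <- max(2L, ceiling(arc * rm_px / vertex_step_px) + 1L)
    th <- seq(k * arc, (k + 1) * arc, length.out = nv)
    polygon_roi("profile_line",
                cbind(p$center[1] + rm_px * cos(th),
                      p$center[2] + rm_px * sin(th)),
                closed = FALSE)
  })
}

.background_squares <- function(p, side = 18L, margin = 4L) {
  h <- p$image_size[1]; w <- p$image_size[2]
  corners <- list(c(margin, margin), c(w - margin - side, margin),
                  c(margin, h - margin - side))
  lapply(corners, function(cc)
    polygon_roi("background",
                rbind(cc, cc + c(side, 0), cc + c(side, side),
                      cc + c(0, side))))
}

#' Generate a synthetic fascicle z-stack with ground truth
#'
#' Renders three z-slices with independent noise realizations of the image
#' model described in [fascicle_params()]. The total signal deposited in the
#' perineurial band is conserved under `internalization_fraction`. The
#' returned ground truth carries the compartment ROIs (fascicle outline,
#' endoneurium), exactly 3 background areas, 5 profile lines tracing the
#' perineurial midline in 5 disjoint arcs, the contact arc-length positions,
#' and the noise-free mean intensity per compartment.
#'
#' @param params a [fascicle_params()].
#' @param n_slices number of z slices (default 3, as measurements average
#'   three adjacent z planes).
#' @return list with elements `stack` (a [zstack()]) and `truth`.
#' @export
generate_fascicle <- function(params, n_slices = 3L) {
  stopifnot(inherits(params, "fascicle_params"))
  p <- params
  geom <- .fascicle_geometry(p)
  h <- p$image_size[1]; w <- p$image_size[2]
  withr::with_seed(p$seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- .render_signal_field(p, geom, phase)
    clean <- p$background_level + sig$field
    nuclei <- matrix(0, h, w)
    if (p$nuclei_count > 0) {
      idx <- sample(which(geom$endo & geom$r < p$inner_radius_px - 4),
                    p$nuclei_count, replace = TRUE)
      for (i in idx) {
        cy <- (i - 1L) %% h; cx <- (i - 1L) %/% h
        xr <- max(0L, cx - 5L):min(w - 1L, cx + 5L)
        yr <- max(0L, cy - 5L):min(h - 1L, cy + 5L)
        d2 <- outer((yr - cy)^2, (xr - cx)^2, "+")
        nuclei[yr + 1L, xr + 1L] <- pmin(200, nuclei[yr + 1L, xr + 1L] +
                                           150 * exp(-d2 / 8))
      }
    }
    chan <- match(p$channel, c("R", "G", "B"))
    slices <- lapply(seq_len(n_slices), function(s) {
      a <- array(0L, c(h, w, 3))
      img <- clean
      if (p$noise_sd > 0)
        img <- img + matrix(stats::rnorm(h * w, 0, p$noise_sd), h, w)
      a[, , chan] <- as.integer(round(pmin(255, pmax(0, img))))
      a[, , 3] <- as.integer(round(pmin(255, pmax(0, nuclei))))
      a
    })
  })
  rois <- c(list(polygon_roi("perineurium",
                             .circle_polygon(p$center, p$inner_radius_px +
                                               p$band_width_px)),
                 polygon_roi("endoneurium",
                             .circle_polygon(p$center, p$inner_radius_px))),
            .background_squares(p),
            .midline_arcs(p, geom))
  truth <- list(
    channel = p$channel,
    contact_positions_um = sig$positions_um,
    n_contacts = sig$n_contacts,
    perineurium_length_um = sig$length_um,
    rois = rois,
    true_mean_intensity = c(
      perineurium = mean(clean[geom$band]),
      endoneurium = mean(clean[geom$endo]),
      whole_fascicle = mean(clean[geom$band | geom$endo]),
      background = p$background_level))
  list(stack = zstack(slices, p$pixel_size_um, sample_id = p$sample_id,
                      group = if (p$group %in% .group_levels) p$group
                              else NA_character_),
       truth = truth)
}

#' Cohort design for synthetic group comparisons
#'
#' Per-group effect multipliers scale the contact density (the peak-analysis
#' effect) and the compartment staining intensity (the NIFI effect); the sham
#' multipliers are fixed at 1.
#'
#' @param n_per_group animals per group.
#' @param multipliers named list of `c(contact_density =, intensity =)`
#'   per group; must contain `sham = c(1, 1)`.
#' @param seed integer master seed.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 7L,
                          multipliers = list(
                            sham = c(contact_density = 1, intensity = 1),
                            cci_proximal = c(contact_density = 1,
                                             intensity = 1),
                            cci_distal = c(contact_density = 1,
                                           intensity = 1)),
                          seed = 1L) {
  if (!"sham" %in% names(multipliers) ||
      !isTRUE(all(multipliers$sham == 1)))
    stop("parameter error: sham multipliers must be exactly 1.0",
         call. = FALSE)
  for (m in multipliers)
    if (any(m < 0) || !all(c("contact_density", "intensity") %in% names(m)))
      stop("parameter error: multipliers need nonnegative contact_density ",
           "and intensity entries", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group),
                 multipliers = multipliers, seed = as.integer(seed)),
            class = "cohort_design")
}

# documented stable per-sample seed hash: reproducible independent of
# generation order; kept below 2^31 - 1
.sample_seed <- function(design_seed, group_index, sample_index) {
  as.integer((as.numeric(design_seed) + 100003 * group_index +
                1009 * sample_index) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' @param design a [cohort_design()].
#' @param base a [fascicle_params()] used as the sham template.
#' @param n_slices slices per stack.
#' @return list of per-sample lists `(stack, truth, group, sample_id)`.
#' @export
generate_cohort <- function(design, base = fascicle_params(), n_slices = 3L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(base, "fascicle_params"))
  out <- list()
  groups <- names(design$multipliers)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    m <- design$multipliers[[g]]
    for (i in seq_len(design$n_per_group)) {
      p <- base
      p$contact_density <- base$contact_density * m[["contact_density"]]
      p$diffuse_level <- base$diffuse_level * m[["intensity"]]
      p$contact_peak_height <- base$contact_peak_height * m[["intensity"]]
      p$seed <- .sample_seed(design$seed, gi, i)
      p$sample_id <- sprintf("%s_%02d", g, i)
      p$group <- g
      fas <- generate_fascicle(p, n_slices = n_slices)
      out[[length(out) + 1L]] <- list(stack = fas$stack, truth = fas$truth,
                                      group = g, sample_id = p$sample_id)
    }
  }
  out
}

#' Generate a synthetic qPCR Ct table
#'
#' Emits target-gene and reference-gene (GAPDH) Ct values for `n` animals per
#' group such that the expected group difference in reference-normalized
#' delta-Ct equals `group_shift` for each gene; independent Gaussian noise of
#' standard deviation `noise_sd` is added to every Ct measurement.
#'
#' @param genes character vector of target gene names.
#' @param n animals per group (>= 2).
#' @param reference_delta per-gene baseline delta-Ct versus the reference
#'   gene in sham (recycled).
#' @param group_shift per-gene additive Ct shift of the CCI group (recycled);
#'   positive values mean downregulation.
#' @param noise_sd Ct measurement noise standard deviation.
#' @param seed integer seed.
#' @param n_replicates technical replicates per (animal, gene).
#' @param reference_gene,reference_base_ct reference gene name and its mean
#'   Ct.
#' @return data.frame with columns `animal_id, group, gene, replicate, ct`
#'   and attribute `reference_gene`.
#' @export
generate_ct_table <- function(genes, n, reference_delta = 6,
                              group_shift = 0, noise_sd = 0.3, seed = 1L,
                              n_replicates = 3L, reference_gene = "GAPDH",
                              reference_base_ct = 18) {
  genes <- unlist(genes)
  if (n < 2) stop("parameter error: n >= 2 animals per group", call. = FALSE)
  if (noise_sd < 0) stop("parameter error: noise_sd >= 0", call. = FALSE)
  reference_delta <- rep_len(reference_delta, length(genes))
  group_shift <- rep_len(group_shift, length(genes))
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (grp in c("sham", "cci")) {
      for (a in seq_len(n)) {
        id <- sprintf("%s_%02d", grp, a)
        ref_ct <- reference_base_ct
        for (gene_i in c(0L, seq_along(genes))) {
          if (gene_i == 0L) {
            gene <- reference_gene; mu <- ref_ct
          } else {
            gene <- genes[gene_i]
            mu <- ref_ct + reference_delta[gene_i] +
              if (grp == "cci") group_shift[gene_i] else 0
          }
          ct <- mu + stats::rnorm(n_replicates, 0, noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, group = grp, gene = gene,
            replicate = seq_len(n_replicates), ct = ct)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_gene") <- reference_gene
  out
}

#' Generate a synthetic blinded-rater score table
#'
#' Integer questionnaire scores on a 1 (none) to 4 (strong/high) scale for
#' the four assessed categories, with per-group shifts on selected
#' categories and optional missing answers (omission was optional for
#' raters).
#'
#' @param n_samples rated samples per group.
#' @param reviewers reviewer identifiers.
#' @param group_effects named list mapping category to a named numeric
#'   vector of score shifts per group (sham shift 0).
#' @param score_sd rater noise standard deviation before rounding/clamping.
#' @param miss_prob probability that an answer is omitted.
#' @param seed integer seed.
#' @return data.frame `reviewer, sample_id, group, category, score`.
#' @export
generate_rater_table <- function(n_samples = 7L,
                                 reviewers = c("R1", "R2"),
                                 group_effects = list(
                                   structure = c(cci_proximal = -2,
                                                 cci_distal = -2),
                                   contrast = c(cci_proximal = -1.5,
                                                cci_distal = -1.5)),
                                 score_sd = 0.4, miss_prob = 0,
                                 seed = 1L) {
  cats <- c("structure", "contrast", "homogeneity", "quality")
  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (rev in reviewers) {
      for (g in .group_levels) {
        for (s in seq_len(n_samples)) {
          for (cat in cats) {
            shift <- 0
            if (cat %in% names(group_effects) &&
                g %in% names(group_effects[[cat]]))
              shift <- group_effects[[cat]][[g]]
            score <- round(3.5 + shift + stats::rnorm(1, 0, score_sd))
            score <- min(4L, max(1L, as.integer(score)))
            if (miss_prob > 0 && stats::runif(1) < miss_prob)
              score <- NA_integer_
            rows[[length(rows) + 1L]] <- data.frame(
              reviewer = rev, sample_id = sprintf("%s_%02d", g, s),
              group = g, category = cat, score = score)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
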