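.roi_labels <- c("perineurium", "endoneurium", "background", "profile_line")
.group_levels <- c("sham", "cci_proximal", "cci_distal")

#' Z-stack of 8-bit RGB nerve-section images
#'
#' Container for an ordered series of 8-bit RGB image slices (a z-stack)
#' together with the pixel size and sample metadata. Slices are stored as
#' integer arrays of dimension `height x width x 3` with values in 0..255;
#' row index is y (downward), column index is x (rightward), both 0-based in
#' all coordinate interfaces.
#'
#' @param slices list of `h x w x 3` integer arrays with values in 0..255.
#' @param pixel_size_um positive pixel edge length in micrometers.
#' @param sample_id sample identifier.
#' @param group experimental group, one of `"sham"`, `"cci_proximal"`,
#'   `"cci_distal"`, or `NA` when unknown.
#' @return An object of class `zstack`.
#' @export
zstack <- function(slices, pixel_size_um, sample_id = "sample",
                   group = NA_character_) {
  if (!is.list(slices) || length(slices) == 0L)
    stop("empty input: a zstack needs at least one slice", call. = FALSE)
  dims <- lapply(slices, dim)
  d0 <- dims[[1]]
  if (length(d0) != 3L || d0[3] != 3L)
    stop("format error: slices must be h x w x 3 RGB arrays", call. = FALSE)
  if (!all(vapply(dims, identical, logical(1), d0)))
    stop("format error: all slices must share identical dimensions",
         call. = FALSE)
  for (s in slices) {
    if (any(s < 0L) || any(s > 255L) ||
        (!is.integer(s) && any(s != round(s))))
      stop("format error: intensities must be integers in [0, 255]",
           call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive number", call. = FALSE)
  if (!is.na(group)) group <- match.arg(group, .group_levels)
  structure(list(slices = lapply(slices, function(s) {
    storage.mode(s) <- "integer"
    s
  }),
  pixel_size_um = pixel_size_um,
  sample_id = as.character(sample_id),
  group = group), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<zstack> %s [%s]: %d slice(s) %dx%d px, %.3g um/px\n",
              x$sample_id, ifelse(is.na(x$group), "?", x$group),
              length(x$slices), d[1], d[2], x$pixel_size_um))
  invisible(x)
}

#' Read a multi-page 8-bit RGB TIFF as a z-stack
#'
#' Reads a single- or multi-page TIFF and returns one slice per page, in page
#' order. The file must contain 8-bit RGB pages. Pixel size is taken from the
#' `pixel_size_um` argument; if absent, TIFF resolution tags are used when
#' present (an explicit argument always wins, so that distances specified in
#' micrometers downstream cannot be corrupted by silent metadata errors).
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um optional pixel size in micrometers; overrides TIFF
#'   resolution metadata.
#' @param sample_id,group passed to [zstack()].
#' @return A [zstack()].
#' @export
read_zstack <- function(path, pixel_size_um = NULL, sample_id = NULL,
                        group = NA_character_) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = TRUE),
    error = function(e) stop("format error: not a readable TIFF file (",
                             conditionMessage(e), ")", call. = FALSE))
  if (length(pages) == 0L)
    stop("empty input: TIFF has zero pages", call. = FALSE)
  first <- pages[[1]]
  bps <- attr(first, "bits.per.sample")
  if (!is.null(bps) && bps != 8L)
    stop("format error: expected 8 bits per sample, found ", bps,
         call. = FALSE)
  if (length(dim(first)) != 3L || dim(first)[3] != 3L)
    stop("format error: expected RGB pages (3 samples per pixel), found ",
         if (length(dim(first)) == 2L) 1L else dim(first)[3], call. = FALSE)
  if (is.null(pixel_size_um)) {
    xres <- attr(first, "x.resolution")
    unit <- attr(first, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      per_um <- switch(ifelse(is.null(unit), "inch", unit),
                       cm = xres / 1e4, inch = xres / 25400, xres / 25400)
      pixel_size_um <- 1 / per_um
    } else {
      stop("pixel_size_um not given and no TIFF resolution metadata present",
           call. = FALSE)
    }
  }
  slices <- lapply(pages, function(p) {
    a <- round(p * 255)
    storage.mode(a) <- "integer"
    attributes(a) <- list(dim = dim(p))
    a
  })
  if (is.null(sample_id))
    sample_id <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  zstack(slices, pixel_size_um, sample_id = sample_id, group = group)
}

#' Write a z-stack to a multi-page 8-bit RGB TIFF
#'
#' @param stack a [zstack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  tiff::writeTIFF(lapply(stack$slices, function(s) s / 255), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' Map stained proteins to RGB channels
#'
#' @param ... named channel assignments, e.g.
#'   `channel_map("claudin-1" = "R", "ZO-1" = "G", "DAPI" = "B")`.
#' @return A named character vector of class `channel_map`.
#' @export
channel_map <- function(...) {
  m <- c(...)
  if (length(m) == 0L || is.null(names(m)) || any(names(m) == ""))
    stop("channel_map entries must be named by protein", call. = FALSE)
  if (!all(m %in% c("R", "G", "B")))
    stop("channels must be one of R, G, B", call. = FALSE)
  if (anyDuplicated(names(m)))
    stop("each protein maps to exactly one channel", call. = FALSE)
  structure(m, class = "channel_map")
}

#' Extract the color plane of a stained protein
#'
#' Returns the selected color plane of every slice, unmodified (no rescaling
#' is ever applied).
#'
#' @param stack a [zstack()].
#' @param map a [channel_map()].
#' @param protein protein name present in `map`.
#' @return list of `h x w` integer matrices, one per slice.
#' @export
extract_channel <- function(stack, map, protein) {
  stopifnot(inherits(stack, "zstack"))
  if (!protein %in% names(map))
    stop("lookup error: protein '", protein, "' not present in channel map",
         call. = FALSE)
  k <- match(map[[protein]], c("R", "G", "B"))
  lapply(stack$slices, function(s) s[, , k])
}

#' Labeled polygon region of interest
#'
#' Polygons are in 0-based pixel coordinates, x rightward and y downward.
#' Closed ROIs delimit compartments or background areas; open polylines
#' (label `"profile_line"`) are sampling paths for peak analysis.
#'
#' @param label one of `"perineurium"`, `"endoneurium"`, `"background"`,
#'   `"profile_line"`.
#' @param vertices numeric `n x 2` matrix of (x, y) coordinates.
#' @param closed logical; must be `FALSE` exactly for `"profile_line"`.
#' @return An object of class `polygon_roi`.
#' @export
polygon_roi <- function(label, vertices, closed = label != "profile_line") {
  label <- match.arg(label, .roi_labels)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || anyNA(vertices))
    stop("schema error: vertices must be a numeric n x 2 matrix",
         call. = FALSE)
  if (isTRUE(closed) != (label != "profile_line"))
    stop("schema error: closed must be FALSE exactly for profile_line ROIs",
         call. = FALSE)
  if (closed && nrow(vertices) < 3L)
    stop("schema error: closed ROIs need >= 3 vertices", call. = FALSE)
  if (!closed && nrow(vertices) < 2L)
    stop("schema error: open ROIs need >= 2 vertices", call. = FALSE)
  if (closed && .self_intersects(vertices))
    stop("schema error: closed ROIs must be simple (non-self-intersecting)",
         call. = FALSE)
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(label = label, vertices = vertices, closed = closed),
            class = "polygon_roi")
}

# proper-crossing test over all non-adjacent edge pairs, vectorized
.self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  nx <- c(2:n, 1L)
  ax <- v[, 1]; ay <- v[, 2]; bx <- v[nx, 1]; by <- v[nx, 2]
  i <- rep(seq_len(n), times = n); j <- rep(seq_len(n), each = n)
  keep <- j > i + 1L & !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  ex <- bx[i] - ax[i]; ey <- by[i] - ay[i]
  fx <- bx[j] - ax[j]; fy <- by[j] - ay[j]
  d1 <- ex * (ay[j] - ay[i]) - ey * (ax[j] - ax[i])
  d2 <- ex * (by[j] - ay[i]) - ey * (bx[j] - ax[i])
  d3 <- fx * (ay[i] - ay[j]) - fy * (ax[i] - ax[j])
  d4 <- fx * (by[i] - ay[j]) - fy * (bx[i] - ax[j])
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
        ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Rasterize a closed polygon ROI to a pixel mask
#'
#' A pixel belongs to the mask exactly when its center lies inside the
#' polygon under the even-odd rule. Pixel centers sit at integer coordinates;
#' points on a left/top boundary are inside, right/bottom outside (half-open
#' scanline convention), so an axis-aligned `d x d` square covers `d^2`
#' pixels.
#'
#' @param roi a closed [polygon_roi()].
#' @param height,width image dimensions in pixels.
#' @return Logical `height x width` matrix with attribute `area_px`.
#' @export
rasterize_roi <- function(roi, height, width) {
  stopifnot(inherits(roi, "polygon_roi"))
  if (!roi$closed)
    stop("type error: cannot rasterize an open profile_line ROI",
         call. = FALSE)
  v <- roi$vertices
  area2 <- abs(sum(v[, 1] * v[c(2:nrow(v), 1L), 2] -
                   v[c(2:nrow(v), 1L), 1] * v[, 2]))
  if (area2 == 0)
    stop("degenerate-ROI error: polygon has zero area", call. = FALSE)
  mask <- matrix(FALSE, height, width)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:length(xs), 1L)]; ye <- ys[c(2:length(ys), 1L)]
  ymin <- max(0L, floor(min(ys)))
  ymax <- min(height - 1L, ceiling(max(ys)))
  if (ymin <= ymax) {
    for (y in ymin:ymax) {
      hit <- ((ys <= y & y < ye) | (ye <= y & y < ys))
      if (!any(hit)) next
      xi <- xs[hit] + (y - ys[hit]) * (xe[hit] - xs[hit]) / (ye[hit] - ys[hit])
      xi <- sort(xi)
      for (k in seq(1L, length(xi) - 1L, by = 2L)) {
        lo <- max(0L, ceiling(xi[k]))
        hi <- min(width - 1L, ceiling(xi[k + 1L]) - 1L)
        if (lo <= hi) mask[y + 1L, (lo:hi) + 1L] <- TRUE
      }
    }
  }
  area <- sum(mask)
  if (area == 0L)
    stop("degenerate-ROI error: polygon covers no pixel centers after ",
         "clipping to the image", call. = FALSE)
  attr(mask, "area_px") <- area
  mask
}

#' Read and write polygon ROIs as JSON
#'
#' The interchange format is a top-level JSON list of objects
#' `{"label": str, "closed": bool, "vertices": [[x, y], ...]}` with 0-based
#' pixel coordinates. `write_rois()` followed by `read_rois()` is the
#' identity on (label, vertices, closed).
#'
#' @param path path to a `.json` file.
#' @return `read_rois()`: list of [polygon_roi()].
#' @export
read_rois <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (is.null(r$label) || is.null(r$vertices))
      stop("schema error in ROI record ", i, ": missing label or vertices",
           call. = FALSE)
    if (!r$label %in% .roi_labels)
      stop("schema error in ROI record ", i, ": unknown label '", r$label,
           "'", call. = FALSE)
    ok <- vapply(r$vertices, function(p)
      is.numeric(unlist(p)) && length(unlist(p)) == 2L, logical(1))
    if (length(r$vertices) == 0L || !all(ok))
      stop("schema error in ROI record ", i, ": malformed vertex list",
           call. = FALSE)
    vmat <- do.call(rbind, lapply(r$vertices, unlist))
    closed <- if (is.null(r$closed)) r$label != "profile_line" else
      isTRUE(r$closed)
    out[[i]] <- tryCatch(polygon_roi(r$label, vmat, closed),
                         error = function(e)
                           stop("schema error in ROI record ", i, ": ",
                                conditionMessage(e), call. = FALSE))
  }
  out
}

#' @param rois list of [polygon_roi()].
#' @rdname read_rois
#' @export
write_rois <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    stopifnot(inherits(r, "polygon_roi"))
    list(label = jsonlite::unbox(r$label),
         closed = jsonlite::unbox(r$closed),
         vertices = unname(lapply(seq_len(nrow(r$vertices)),
                                  function(i) as.numeric(r$vertices[i, ]))))
  })
  jsonlite::write_json(recs, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Compartment masks from a set of ROIs
#'
#' The perineurium ROI delimits the fascicle outline; the perineurial band is
#' its mask minus the endoneurium mask, mirroring the two-circle scheme used
#' when compartments are drawn on brightfield images. The whole fascicle is
#' the union (i.e. the outline mask).
#'
#' @param rois list of [polygon_roi()] containing one `perineurium` and one
#'   `endoneurium` ROI.
#' @param height,width image dimensions.
#' @return list with logical masks `perineurium`, `endoneurium`,
#'   `whole_fascicle`, and a list `background` of the background-area masks.
#' @export
compartment_masks <- function(rois, height, width) {
  labs <- vapply(rois, function(r) r$label, character(1))
  outer <- rois[labs == "perineurium"]
  endo <- rois[labs == "endoneurium"]
  if (length(outer) != 1L || length(endo) != 1L)
    stop("need exactly one perineurium and one endoneurium ROI",
         call. = FALSE)
  m_out <- rasterize_roi(outer[[1]], height, width)
  m_end <- rasterize_roi(endo[[1]], height, width)
  bg <- lapply(rois[labs == "background"], rasterize_roi, height = height,
               width = width)
  peri <- m_out & !m_end
  attr(peri, "area_px") <- sum(peri)
  list(perineurium = peri, endoneurium = m_end, whole_fascicle = m_out,
       background = bg)
}
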