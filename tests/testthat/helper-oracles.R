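# Independent brute-force oracles; deliberately written with plain loops and
# a different algorithmic route than the package implementations.

# per-point even-odd crossing test (half-open rule: a crossing is counted
# when the edge spans [y1, y2) and intersects strictly right of the point)
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  crossings <- 0L
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]
    f <- if (e == n) 1L else e + 1L
    x2 <- v[f, 1]; y2 <- v[f, 2]
    if (y1 == y2) next
    if ((y1 <= py && py < y2) || (y2 <= py && py < y1)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (xi > px) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

oracle_rasterize <- function(v, h, w) {
  m <- matrix(FALSE, h, w)
  for (y in 0:(h - 1)) for (x in 0:(w - 1))
    m[y + 1, x + 1] <- oracle_point_in_polygon(x, y, v)
  m
}

# exhaustive peak enumerator: every candidate maximum is listed, the three
# acceptance criteria are applied one by one, then greedy suppression
oracle_find_peaks <- function(value, position_um, sd_gray, params) {
  n <- length(value)
  # candidate local maxima, plateaus collapsed to the center index
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && value[j + 1] == value[i]) j <- j + 1L
    if (i > 1L && j < n && value[i - 1] < value[i] && value[j + 1] < value[i])
      cand <- c(cand, floor((i + j) / 2))
    i <- j + 1L
  }
  cand <- cand[value[cand] >= params$min_value]
  # prominence by direct subrange search for the nearest higher samples
  ok <- logical(length(cand))
  for (k in seq_along(cand)) {
    idx <- cand[k]; h <- value[idx]
    higher_left <- which(value[seq_len(idx - 1)] > h)
    lo <- if (length(higher_left)) max(higher_left) else 1L
    lmin <- min(value[lo:idx])
    higher_right <- which(value[idx:n] > h)
    hi <- if (length(higher_right)) idx + min(higher_right) - 1L else n
    rmin <- min(value[idx:hi])
    ok[k] <- (h - max(lmin, rmin)) >= params$amp_factor * sd_gray
  }
  cand <- cand[ok]
  # greedy suppression, tallest first, leftmost on ties
  kept <- integer(0)
  for (idx in cand[order(-value[cand], position_um[cand])]) {
    if (all(abs(position_um[kept] - position_um[idx]) >=
            params$min_distance_um))
      kept <- c(kept, idx)
  }
  kept <- sort(kept)
  list(position_um = position_um[kept], height = value[kept],
       count = length(kept))
}

# convex polygon with vertices on a random ellipse: simple by construction
random_convex_polygon <- function(n_vertices, cx, cy, rx, ry) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

make_profile <- function(values, pixel_size_um = 0.5) {
  list(position_um = (seq_along(values) - 1) * pixel_size_um,
       value = values)
}

gray_stats <- function(mean_gray, sd_gray, n_px = 100L) {
  structure(list(mean_gray = mean_gray, sd_gray = sd_gray, n_px = n_px),
            class = "roi_gray_stats")
}

# small, fast fascicle geometry for pipeline-level tests
small_fascicle <- function(...) {
  args <- utils::modifyList(list(image_size = c(96L, 96L),
                                 inner_radius_px = 30, band_width_px = 6,
                                 nuclei_count = 5L),
                            list(...))
  do.call(fascicle_params, args)
}
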