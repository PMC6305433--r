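test_that("TIFF round trip preserves page count, values and pixel size", {
  set.seed(42)
  slices <- lapply(1:3, function(i)
    array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3)))
  st <- zstack(slices, pixel_size_um = 0.5, sample_id = "rt",
               group = "sham")
  path <- withr::local_tempfile(fileext = ".tif")
  write_zstack(st, path)
  back <- read_zstack(path, pixel_size_um = 0.5)
  expect_length(back$slices, 3L)
  expect_identical(dim(back$slices[[1]]), c(64L, 64L, 3L))
  for (i in 1:3)
    expect_true(all(back$slices[[i]] == st$slices[[i]]))
  expect_equal(back$pixel_size_um, 0.5)

  one <- zstack(slices[1], pixel_size_um = 1)
  write_zstack(one, path)
  expect_length(read_zstack(path, pixel_size_um = 0.5)$slices, 1L)
})

test_that("non-8-bit, non-RGB and non-TIFF inputs are rejected by name", {
  p16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(16 * 16 * 3), c(16, 16, 3)), p16,
                  bits.per.sample = 16L)
  expect_error(read_zstack(p16, 1), "8 bits")

  pg <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), pg, bits.per.sample = 8L)
  expect_error(read_zstack(pg, 1), "RGB")

  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(read_zstack(bad, 1), "format error")
})

test_that("zstack validation enforces shared dimensions and 8-bit range", {
  a <- array(0L, c(8, 8, 3))
  b <- array(0L, c(9, 8, 3))
  expect_error(zstack(list(a, b), 1), "identical dimensions")
  bad <- a; bad[1] <- 300L
  expect_error(zstack(list(bad), 1), "0, 255")
  expect_error(zstack(list(), 1), "empty")
  expect_error(zstack(list(a), -1), "positive")
})

test_that("channel extraction returns the stored plane unmodified", {
  a <- array(0L, c(4, 4, 3))
  a[1, 1, ] <- c(10L, 20L, 30L)
  st <- zstack(list(a), 1)
  map <- channel_map("claudin-1" = "R", "ZO-1" = "G", "DAPI" = "B")
  expect_equal(extract_channel(st, map, "ZO-1")[[1]][1, 1], 20L)
  expect_equal(extract_channel(st, map, "claudin-1")[[1]][1, 1], 10L)
  expect_true(all(extract_channel(st, map, "DAPI")[[1]][-1] == 0L))
  black <- zstack(list(array(0L, c(4, 4, 3))), 1)
  expect_true(all(extract_channel(black, map, "ZO-1")[[1]] == 0L))
  expect_error(extract_channel(st, map, "occludin"), "lookup error")
  expect_error(channel_map("a" = "R", "a" = "G"), "exactly one")
})

test_that("ROI JSON round trip is the identity on label, vertices, closed", {
  rois <- list(
    polygon_roi("perineurium", rbind(c(0, 0), c(30, 2), c(28, 25),
                                     c(1, 22))),
    polygon_roi("background", rbind(c(2.5, 2.5), c(7.5, 2.5), c(5, 9))),
    polygon_roi("profile_line", rbind(c(1, 1), c(10, 5), c(20, 3)),
                closed = FALSE))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_length(back, 3L)
  for (i in seq_along(rois)) {
    expect_identical(back[[i]]$label, rois[[i]]$label)
    expect_identical(back[[i]]$closed, rois[[i]]$closed)
    expect_equal(back[[i]]$vertices, rois[[i]]$vertices)
  }
  write_rois(list(), path)
  expect_length(read_rois(path), 0L)
})

test_that("malformed ROI files fail with a schema error naming the record", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0('[{"label": "perineurium", "closed": true,',
                    ' "vertices": [[0,0],[5,0],[5,5],[0,5]]},',
                    ' {"label": "perineurum", "closed": true,',
                    ' "vertices": [[0,0],[5,0],[5,5]]}]'), path)
  expect_error(read_rois(path), "record 2")
  writeLines('[{"closed": true, "vertices": [[0,0],[1,0],[1,1]]}]', path)
  expect_error(read_rois(path), "missing label")
  writeLines('[{"label": "background", "vertices": [[0,0],[1]]}]', path)
  expect_error(read_rois(path), "malformed vertex")
})

test_that("rasterization follows the pixel-center half-open even-odd rule", {
  sq <- polygon_roi("background",
                    rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  m <- rasterize_roi(sq, 20, 20)
  expect_equal(sum(m), 100L)
  expect_equal(attr(m, "area_px"), 100L)
  expect_true(all(m[1:10, 1:10]))

  # identity under a null translation
  m2 <- rasterize_roi(sq, 20, 20)
  expect_identical(m, m2)

  line <- polygon_roi("profile_line", rbind(c(0, 0), c(5, 5)),
                      closed = FALSE)
  expect_error(rasterize_roi(line, 20, 20), "type error")
  deg <- polygon_roi("background", rbind(c(0, 0), c(5, 5), c(10, 10)))
  expect_error(rasterize_roi(deg, 20, 20), "degenerate")
  out <- polygon_roi("background", rbind(c(50, 50), c(60, 50), c(55, 60)))
  expect_error(rasterize_roi(out, 20, 20), "degenerate")
})

test_that("rasterization agrees with the per-pixel point-in-polygon oracle", {
  set.seed(7)
  for (rep in 1:25) {
    h <- sample(8:32, 1); w <- sample(8:32, 1)
    v <- random_convex_polygon(sample(3:9, 1),
                               cx = runif(1, 2, w - 3),
                               cy = runif(1, 2, h - 3),
                               rx = runif(1, 1.5, w / 2),
                               ry = runif(1, 1.5, h / 2))
    roi <- polygon_roi("background", v)
    got <- tryCatch(rasterize_roi(roi, h, w), error = function(e) NULL)
    want <- oracle_rasterize(v, h, w)
    if (is.null(got)) {
      expect_equal(sum(want), 0L)
    } else {
      attr(got, "area_px") <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("self-intersecting closed polygons are rejected", {
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(polygon_roi("background", bowtie), "simple")
})
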