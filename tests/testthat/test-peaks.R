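test_that("perineurial gray statistics use the sample standard deviation", {
  img <- matrix(50, 6, 6)
  mask <- matrix(TRUE, 6, 6)
  st <- roi_gray_stats(img, mask)
  expect_equal(st$mean_gray, 50)
  expect_equal(st$sd_gray, 0)
  expect_equal(st$n_px, 36L)

  two <- matrix(FALSE, 6, 6); two[1, 1] <- TRUE; two[2, 2] <- TRUE
  img[1, 1] <- 40; img[2, 2] <- 60
  st2 <- roi_gray_stats(img, two)
  expect_equal(st2$mean_gray, 50)
  expect_equal(st2$sd_gray, sqrt(200 / 1), tolerance = 1e-12)

  set.seed(5)
  rnd <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
  st3 <- roi_gray_stats(rnd, mask)
  expect_equal(st3$mean_gray, sum(rnd) / 36)
  expect_equal(st3$sd_gray, sqrt(sum((rnd - mean(rnd))^2) / 35))

  one <- matrix(FALSE, 6, 6); one[1, 1] <- TRUE
  expect_error(roi_gray_stats(img, one), "sd undefined")
  expect_error(roi_gray_stats(img, matrix(FALSE, 6, 6)), "empty-ROI")
})

test_that("the QC filter discards at and above the contrast boundary", {
  expect_false(qc_filter(gray_stats(143.33, 10)))
  expect_true(qc_filter(gray_stats(143.32, 10)))
  expect_false(qc_filter(gray_stats(255, 10)))
  expect_true(qc_filter(gray_stats(0, 10)))
})

test_that("preprocessing subtracts with an 8-bit floor, then blurs", {
  st <- gray_stats(100, 10)
  img <- matrix(90, 32, 32)
  img[16, 16] <- 200
  sub <- bnbquant:::.subtract_threshold(img, st, peak_params())
  expect_equal(sub[16, 16], 50)       # 200 - 1.5 * 100
  expect_equal(sub[1, 1], 0)          # clamped at the 8-bit floor
  # everything below threshold -> identically zero output
  low <- matrix(120, 16, 16)
  expect_true(all(preprocess_image(low, st) == 0))
  # a uniform post-subtraction image is unchanged by the blur
  uni <- matrix(180, 16, 16)
  pre <- preprocess_image(uni, st)
  expect_equal(max(abs(pre - 30)), 0, tolerance = 1e-9)
  expect_error(preprocess_image(img, gray_stats(150, 10)), "QC error")
})

test_that("profile sampling is bilinear at 1 px arc steps", {
  img <- matrix(7, 20, 20)
  line <- polygon_roi("profile_line", rbind(c(2, 10), c(12, 10)),
                      closed = FALSE)
  pr <- sample_profile(img, line, pixel_size_um = 0.5)
  expect_equal(pr$value, rep(7, 11))
  expect_equal(pr$position_um, seq(0, 5, by = 0.5))

  # bilinear interpolation reproduces a plane exactly along a diagonal
  plane <- outer(0:19, 0:19, function(y, x) 2 * x + 3 * y + 1)
  diag_line <- polygon_roi("profile_line", rbind(c(1, 2), c(13, 11)),
                           closed = FALSE)
  pr2 <- sample_profile(plane, diag_line, 1)
  len <- sqrt(12^2 + 9^2)
  s <- seq(0, floor(len))
  xs <- 1 + 12 * s / len; ys <- 2 + 9 * s / len
  expect_equal(pr2$value, 2 * xs + 3 * ys + 1, tolerance = 1e-9)

  oob <- polygon_roi("profile_line", rbind(c(-3, 5), c(10, 5)),
                     closed = FALSE)
  expect_error(sample_profile(img, oob, 1), "geometry error")
})

test_that("find_peaks applies height, prominence and spacing criteria", {
  st <- gray_stats(0, 10)
  pp <- peak_params()

  flat <- make_profile(rep(5, 20))
  expect_equal(find_peaks(flat, st, pp)$count, 0L)

  bump <- make_profile(c(rep(0, 5), 20, 40, 60, 40, 20, rep(0, 5)))
  r <- find_peaks(bump, st, pp)
  expect_equal(r$count, 1L)
  expect_equal(r$height, 60)

  # two bumps 0.6 um apart: the taller wins the greedy suppression
  v <- rep(0, 16)
  v[5] <- 60; v[8] <- 50
  close_pair <- make_profile(v, pixel_size_um = 0.2)
  r2 <- find_peaks(close_pair, st, pp)
  expect_equal(r2$count, 1L)
  expect_equal(r2$height, 60)
  expect_equal(r2$position_um, 4 * 0.2)

  # same pair beyond the minimal distance: both kept, sorted positions
  far_pair <- make_profile(v, pixel_size_um = 0.5)
  r3 <- find_peaks(far_pair, st, pp)
  expect_equal(r3$count, 2L)
  expect_equal(r3$position_um, c(2, 3.5))

  # plateau contributes a single centered peak
  pv <- c(rep(0, 4), rep(80, 3), rep(0, 4))
  r4 <- find_peaks(make_profile(pv, 1), st, pp)
  expect_equal(r4$count, 1L)
  expect_equal(r4$position_um, 5)

  expect_error(find_peaks(make_profile(c(1, 2)), st, pp), "degenerate")
})

test_that("find_peaks matches the exhaustive oracle on random profiles", {
  set.seed(99)
  pp_list <- list(peak_params(), peak_params(min_distance_um = 2),
                  peak_params(min_value = 20))
  for (i in 1:300) {
    n <- sample(3:50, 1)
    v <- sample(seq(0, 240, by = 20), n, replace = TRUE)
    px <- sample(c(0.5, 1), 1)
    sd_gray <- sample(c(5, 10, 30), 1)
    pp <- pp_list[[sample(3, 1)]]
    prof <- make_profile(v, px)
    got <- find_peaks(prof, gray_stats(100, sd_gray), pp)
    want <- oracle_find_peaks(v, prof$position_um, sd_gray, pp)
    expect_identical(got$position_um, want$position_um)
    expect_identical(got$height, as.numeric(want$height))
  }
})

test_that("peak counts are monotone in the stringency parameters", {
  set.seed(17)
  v <- pmax(0, round(stats::filter(sample(c(rep(0, 8), 200), 120,
                                          replace = TRUE),
                                   rep(1 / 3, 3), circular = TRUE)))
  prof <- make_profile(as.numeric(v), 0.5)
  st <- gray_stats(0, 10)
  count <- function(...) find_peaks(prof, st, peak_params(...))$count
  expect_true(count(min_value = 20) >= count(min_value = 40))
  expect_true(count(min_value = 40) >= count(min_value = 80))
  expect_true(count(amp_factor = 1) >= count(amp_factor = 1.5))
  expect_true(count(amp_factor = 1.5) >= count(amp_factor = 4))
  expect_true(count(min_distance_um = 0.5) >= count(min_distance_um = 1))
  expect_true(count(min_distance_um = 1) >= count(min_distance_um = 3))
})

test_that("the full report recovers ground-truth contacts on a clean render", {
  # pick a seed whose contacts all lie well inside a profile arc: contacts
  # too close to an arc end fall on a profile endpoint and are not interior
  # local maxima of any line
  seed <- NA
  for (s in 1:50) {
    tr <- generate_fascicle(small_fascicle(noise_sd = 0, seed = s))$truth
    arc <- tr$perineurium_length_um / 5
    off <- tr$contact_positions_um %% arc
    if (min(off, arc - off) > 2) { seed <- s; break }
  }
  expect_false(is.na(seed))
  fas <- generate_fascicle(small_fascicle(noise_sd = 0, seed = seed))
  chan <- match(fas$truth$channel, c("R", "G", "B"))
  img <- fas$stack$slices[[1]][, , chan]
  rep <- peak_report(img, fas$truth$rois, 0.5, sample_id = "clean")
  expect_true(rep$qc_pass)
  expect_equal(rep$mean_peak_count * 5, fas$truth$n_contacts)
  counts <- vapply(rep$per_line, `[[`, numeric(1), "count")
  expect_equal(mean(counts), rep$mean_peak_count)
  for (pl in rep$per_line) {
    if (pl$count > 1)
      expect_true(all(diff(pl$position_um) >= peak_params()$min_distance_um))
  }
})

test_that("low-contrast samples are discarded with no counts", {
  p <- small_fascicle(diffuse_level = 150, background_level = 10,
                      contact_peak_height = 40, seed = 2L)
  fas <- generate_fascicle(p)
  img <- fas$stack$slices[[1]][, , 1]
  rep <- peak_report(img, fas$truth$rois, 0.5)
  expect_false(rep$qc_pass)
  expect_true(is.na(rep$mean_peak_count))
  expect_null(rep$per_line)
  expect_gte(rep$stats$mean_gray, 143.33)
})

test_that("peak_report enforces the five-line design", {
  fas <- generate_fascicle(small_fascicle(seed = 2L))
  rois <- fas$truth$rois
  labs <- vapply(rois, function(r) r$label, character(1))
  short <- rois[-(which(labs == "profile_line")[1])]
  img <- fas$stack$slices[[1]][, , 1]
  expect_error(peak_report(img, short, 0.5), "arity error")
})
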