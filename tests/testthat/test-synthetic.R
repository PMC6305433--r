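test_that("fascicle generation is bit-identical for a fixed seed", {
  p <- small_fascicle(seed = 12L)
  a <- generate_fascicle(p)
  b <- generate_fascicle(p)
  expect_identical(a$stack$slices, b$stack$slices)
  expect_identical(a$truth$contact_positions_um,
                   b$truth$contact_positions_um)
  c <- generate_fascicle(small_fascicle(seed = 13L))
  expect_false(identical(a$stack$slices, c$stack$slices))
})

test_that("contact count follows round(density x length / 100 um)", {
  p0 <- small_fascicle(contact_density = 0)
  t0 <- generate_fascicle(p0)$truth
  expect_length(t0$contact_positions_um, 0L)
  expect_equal(t0$n_contacts, 0L)
  for (dens in c(2, 4, 7.5)) {
    tr <- generate_fascicle(small_fascicle(contact_density = dens))$truth
    expect_equal(tr$n_contacts,
                 round(dens * tr$perineurium_length_um / 100))
    expect_length(tr$contact_positions_um, tr$n_contacts)
    expect_true(all(diff(sort(tr$contact_positions_um)) > 0))
  }
})

test_that("total band signal is conserved under internalization", {
  # exact on the continuous signal field, for every fraction
  p <- small_fascicle(noise_sd = 0, nuclei_count = 0L, seed = 3L)
  geom <- bnbquant:::.fascicle_geometry(p)
  sums <- vapply(c(0, 0.3, 0.7, 1), function(f) {
    p$internalization_fraction <- f
    sum(bnbquant:::.render_signal_field(p, geom, phase = 1.1)$field)
  }, numeric(1))
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-8 * sums[1])

  # and within per-pixel quantization error on the rendered 8-bit images
  f0 <- generate_fascicle(p)
  p1 <- p; p1$internalization_fraction <- 1
  f1 <- generate_fascicle(p1)
  d <- dim(f0$stack$slices[[1]])
  band <- compartment_masks(f0$truth$rois, d[1], d[2])$perineurium
  s0 <- sum(f0$stack$slices[[1]][, , 1][band]) - sum(band) * 5
  s1 <- sum(f1$stack$slices[[1]][, , 1][band]) - sum(band) * 5
  expect_lt(abs(s0 - s1), 0.5 * sum(band))
  expect_false(identical(f0$stack$slices[[1]], f1$stack$slices[[1]]))
})

test_that("all rendered intensities are 8-bit and ROIs are complete", {
  fas <- generate_fascicle(small_fascicle(seed = 5L))
  for (s in fas$stack$slices) {
    expect_true(all(s >= 0L & s <= 255L))
    expect_type(s, "integer")
  }
  labs <- vapply(fas$truth$rois, function(r) r$label, character(1))
  expect_equal(sum(labs == "background"), 3L)
  expect_equal(sum(labs == "profile_line"), 5L)
  expect_equal(sum(labs == "perineurium"), 1L)
  expect_equal(sum(labs == "endoneurium"), 1L)
})

test_that("detected peaks rise with contact density, fall with internalization", {
  counts_by_density <- vapply(c(1, 2, 4), function(dens) {
    fas <- generate_fascicle(small_fascicle(contact_density = dens,
                                            noise_sd = 0, seed = 9L))
    cohort_peaks(list(list(stack = fas$stack, truth = fas$truth,
                           group = "sham",
                           sample_id = "s")))$mean_peak_count
  }, numeric(1))
  expect_true(all(diff(counts_by_density) >= 0))
  expect_gt(counts_by_density[3], counts_by_density[1])

  counts_by_internal <- vapply(c(0, 0.5, 0.9), function(f) {
    fas <- generate_fascicle(small_fascicle(internalization_fraction = f,
                                            noise_sd = 0, seed = 9L))
    cohort_peaks(list(list(stack = fas$stack, truth = fas$truth,
                           group = "sham",
                           sample_id = "s")))$mean_peak_count
  }, numeric(1))
  expect_true(all(diff(counts_by_internal) <= 0))
  expect_lt(counts_by_internal[3], counts_by_internal[1])
})

test_that("cohort generation applies group multipliers to the ground truth", {
  des <- cohort_design(
    3L,
    list(sham = c(contact_density = 1, intensity = 1),
         cci_proximal = c(contact_density = 0.27, intensity = 1)),
    seed = 4L)
  coh <- generate_cohort(des, small_fascicle())
  expect_length(coh, 6L)
  truth_counts <- tapply(
    vapply(coh, function(s) s$truth$n_contacts, numeric(1)),
    vapply(coh, function(s) s$group, character(1)), mean)
  sham_n <- truth_counts[["sham"]]
  expect_equal(truth_counts[["cci_proximal"]],
               round(0.27 * 4 * coh[[1]]$truth$perineurium_length_um / 100))
  expect_lt(truth_counts[["cci_proximal"]], sham_n)
  expect_identical(generate_cohort(des, small_fascicle()), coh)

  # intensity multiplier scales the band signal above background
  des_i <- cohort_design(
    3L,
    list(sham = c(contact_density = 1, intensity = 1),
         cci_proximal = c(contact_density = 1, intensity = 0.6)),
    seed = 4L)
  coh_i <- generate_cohort(des_i, small_fascicle())
  mu <- tapply(
    vapply(coh_i, function(s)
      s$truth$true_mean_intensity[["perineurium"]] - 5, numeric(1)),
    vapply(coh_i, function(s) s$group, character(1)), mean)
  expect_equal(unname(mu[["cci_proximal"]] / mu[["sham"]]), 0.6,
               tolerance = 0.02)
})

test_that("cohort design validation rejects non-unit sham multipliers", {
  expect_error(cohort_design(3, list(sham = c(contact_density = 2,
                                              intensity = 1))),
               "sham multipliers")
  expect_error(cohort_design(3, list(sham = c(contact_density = 1,
                                              intensity = 1),
                                     cci = c(contact_density = -1,
                                             intensity = 1))),
               "nonnegative")
})

test_that("Ct tables encode the configured group shift exactly when noiseless", {
  tab <- generate_ct_table("cldn1", n = 4, group_shift = 0, noise_sd = 0)
  r <- delta_ct_expression(tab, "cldn1")
  expect_equal(r$fold_change, 1)
  expect_equal(r$percent_change, 0)

  tab2 <- generate_ct_table("cldn1", n = 4, group_shift = 2, noise_sd = 0)
  r2 <- delta_ct_expression(tab2, "cldn1")
  expect_equal(r2$fold_change, 0.25)
  expect_equal(r2$percent_change, 75)

  expect_identical(generate_ct_table("g", 3, seed = 8),
                   generate_ct_table("g", 3, seed = 8))
  expect_error(generate_ct_table("g", 1), "n >= 2")
})

test_that("rater tables stay on the 1-4 scale with the configured contrast", {
  tab <- generate_rater_table(seed = 2L)
  expect_true(all(tab$score %in% 1:4 | is.na(tab$score)))
  st <- tab[tab$category == "structure", ]
  mu <- tapply(st$score, st$group, mean, na.rm = TRUE)
  expect_gt(mu[["sham"]], mu[["cci_proximal"]])
  withmiss <- generate_rater_table(miss_prob = 0.2, seed = 2L)
  expect_gt(sum(is.na(withmiss$score)), 0L)
})
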