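#' Parameter recovery of an expression change from synthetic Ct tables
#'
#' Monte-Carlo benchmark of the delta-Ct pipeline: generates seeded Ct
#' tables with a known group shift, runs [delta_ct_expression()], and
#' returns the mean recovered percent change.
#'
#' @param group_shift true additive Ct shift of the CCI group (`ddCt`); the
#'   true percent change is `100 * (1 - 2^-group_shift)`.
#' @param n animals per group.
#' @param noise_sd Ct noise standard deviation.
#' @param n_replicates Monte-Carlo replicates.
#' @param seed integer master seed.
#' @return list `(percent_change, sd, n_replicates, true_percent)`.
#' @export
recover_expression_change <- function(group_shift, n = 8L, noise_sd = 0.3,
                                      n_replicates = 200L, seed = 1L) {
  vals <- vapply(seq_len(n_replicates), function(r) {
    tab <- generate_ct_table("target", n = n, group_shift = group_shift,
                             noise_sd = noise_sd,
                             seed = .sample_seed(seed, 1L, r))
    delta_ct_expression(tab, "target")$percent_change
  }, numeric(1))
  list(percent_change = mean(vals), sd = stats::sd(vals),
       n_replicates = n_replicates,
       true_percent = 100 * (1 - 2^(-group_shift)))
}

.cohort_group_percent <- function(df, value_col, groups) {
  ok <- !is.na(df[[value_col]])
  mu <- tapply(df[[value_col]][ok], df$group[ok], mean)
  vapply(groups, function(g) percent_change(mu[["sham"]], mu[[g]]),
         numeric(1))
}

#' Parameter recovery of peak-count reductions on synthetic cohorts
#'
#' Generates cohorts whose CCI groups have their true contact density scaled
#' by the given multipliers, runs the full peak pipeline with the supplied
#' parameters on every sample, and returns the mean percent reduction in
#' group mean peak count relative to sham across replicates.
#'
#' @param density_multipliers named numeric vector of contact-density
#'   multipliers for the non-sham groups.
#' @param n_per_group animals per group.
#' @param n_replicates Monte-Carlo replicates.
#' @param seed integer master seed.
#' @param base sham [fascicle_params()] template.
#' @param params a [peak_params()].
#' @return list `(percent_change` (named per group)`, per_replicate,
#'   n_replicates)`.
#' @export
recover_peak_change <- function(density_multipliers = c(cci_proximal = 0.27,
                                                        cci_distal = 0.18),
                                n_per_group = 7L, n_replicates = 100L,
                                seed = 1L, base = fascicle_params(),
                                params = peak_params()) {
  mults <- c(list(sham = c(contact_density = 1, intensity = 1)),
             lapply(density_multipliers, function(m)
               c(contact_density = m, intensity = 1)))
  per_rep <- vapply(seq_len(n_replicates), function(r) {
    des <- cohort_design(n_per_group, mults, seed = .sample_seed(seed, 2L, r))
    coh <- generate_cohort(des, base)
    pk <- cohort_peaks(coh, params)
    .cohort_group_percent(pk, "mean_peak_count", names(density_multipliers))
  }, numeric(length(density_multipliers)))
  per_rep <- matrix(per_rep, nrow = length(density_multipliers),
                    dimnames = list(names(density_multipliers), NULL))
  list(percent_change = rowMeans(per_rep), per_replicate = per_rep,
       n_replicates = n_replicates)
}

#' Parameter recovery of NIFI reductions on synthetic cohorts
#'
#' Generates cohorts whose CCI groups have their true staining intensity
#' scaled by the given multipliers, runs the NIFI pipeline (3 z-slices,
#' 3 background areas, animal-level aggregation) on the requested
#' compartment, and returns the mean percent reduction in group mean NIFI
#' relative to sham across replicates.
#'
#' @param intensity_multipliers named numeric vector of intensity
#'   multipliers for the non-sham groups.
#' @param compartment compartment passed to [cohort_nifi()].
#' @param n_per_group animals per group.
#' @param n_replicates Monte-Carlo replicates.
#' @param seed integer master seed.
#' @param base sham [fascicle_params()] template.
#' @return list `(percent_change, per_replicate, n_replicates)`.
#' @export
recover_nifi_change <- function(intensity_multipliers = c(
                                  cci_proximal = 0.61, cci_distal = 0.70),
                                compartment = "perineurium",
                                n_per_group = 7L, n_replicates = 100L,
                                seed = 1L, base = fascicle_params()) {
  mults <- c(list(sham = c(contact_density = 1, intensity = 1)),
             lapply(intensity_multipliers, function(m)
               c(contact_density = 1, intensity = m)))
  masks <- NULL
  per_rep <- vapply(seq_len(n_replicates), function(r) {
    des <- cohort_design(n_per_group, mults, seed = .sample_seed(seed, 3L, r))
    coh <- generate_cohort(des, base)
    if (is.null(masks)) {
      d <- dim(coh[[1]]$stack$slices[[1]])
      masks <<- compartment_masks(coh[[1]]$truth$rois, d[1], d[2])
    }
    nf <- cohort_nifi(coh, compartment, masks = masks)
    .cohort_group_percent(nf, "nifi", names(intensity_multipliers))
  }, numeric(length(intensity_multipliers)))
  per_rep <- matrix(per_rep, nrow = length(intensity_multipliers),
                    dimnames = list(names(intensity_multipliers), NULL))
  list(percent_change = rowMeans(per_rep), per_replicate = per_rep,
       n_replicates = n_replicates)
}

#' Empirical type-I error of the Kruskal-Wallis stage
#'
#' Simulates exchangeable null cohorts (no group effect) and reports the
#' fraction of cohorts with a Kruskal-Wallis p-value below `alpha`.
#'
#' @param n_cohorts number of simulated null cohorts.
#' @param n_per_group animals per group.
#' @param n_groups number of groups.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list `(type1, n_cohorts, alpha)`.
#' @export
null_type1_error <- function(n_cohorts = 2000L, n_per_group = 7L,
                             n_groups = 3L, alpha = 0.05, seed = 1L) {
  hits <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_cohorts), function(i) {
      g <- stats::setNames(
        lapply(seq_len(n_groups), function(k) stats::rnorm(n_per_group)),
        c("sham", paste0("g", seq_len(n_groups - 1L))))
      res <- kruskal_dunn(g)
      !is.na(res$p) && res$p < alpha
    }, logical(1))
  })
  list(type1 = mean(hits), n_cohorts = n_cohorts, alpha = alpha)
}

#' QC discard boundary by scanning the mean gray value
#'
#' Applies [qc_filter()] to gray statistics whose mean is swept over the
#' given range and returns the smallest discarded value.
#'
#' @param from,to,by sweep range and step of the mean gray value.
#' @param params a [peak_params()].
#' @return smallest mean gray value at which samples are discarded.
#' @export
qc_boundary_scan <- function(from = 140, to = 146, by = 0.01,
                             params = peak_params()) {
  grid <- seq(from, to, by = by)
  discarded <- vapply(grid, function(m)
    !qc_filter(structure(list(mean_gray = m, sd_gray = 1, n_px = 100L),
                         class = "roi_gray_stats"), params), logical(1))
  if (!any(discarded)) return(NA_real_)
  grid[which(discarded)[1]]
}
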