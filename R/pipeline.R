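.log <- function(level, threshold, ...) {
  lv <- c(debug = 1L, info = 2L, warn = 3L)
  if (lv[[level]] >= lv[[threshold]]) message("[", level, "] ", ...)
  paste0("[", level, "] ", paste0(..., collapse = ""))
}

.default_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    simulate = list(
      n_per_group = 7L,
      n_slices = 3L,
      multipliers = list(
        sham = c(contact_density = 1, intensity = 1),
        cci_proximal = c(contact_density = 0.27, intensity = 0.61),
        cci_distal = c(contact_density = 0.18, intensity = 0.70)),
      fascicle = list()),
    channel_map = list("claudin-1" = "R", "ZO-1" = "G", "DAPI" = "B"),
    nifi = list(protein = "claudin-1",
                compartments = c("perineurium", "endoneurium",
                                 "whole_fascicle")),
    peaks = list(protein = "claudin-1", params = list()),
    qpcr = NULL,
    stats = list(design = "independent", reference = "sham"))
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages simulate, nifi, peaks, qpcr and stats from a
#' single configuration: simulates a seeded synthetic cohort to disk (TIFF
#' stacks plus ROI JSON plus ground-truth CSV), reads the images back
#' through the regular I/O layer, computes per-slice NIFI tables and peak
#' reports, optionally a delta-Ct expression analysis, runs the group
#' statistics, and writes per-stage CSVs, a summary table of group means and
#' percent changes, and a machine-readable manifest of every parameter
#' actually used. The run is deterministic given the configuration
#' (including the seed).
#'
#' @param config path to a YAML configuration file, or a named list;
#'   omitted keys fall back to documented defaults (recorded in the
#'   manifest).
#' @param seed optional seed overriding the config.
#' @param outdir output directory (created if missing).
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return invisibly, a list with the per-stage tables, the summary
#'   data.frame, the manifest, and the log lines.
#' @export
run_pipeline <- function(config = list(), seed = NULL, outdir = tempfile(),
                         log_level = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(log_level)) cfg$log_level <- log_level
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lg <- cfg$log_level
  logs <- character(0)
  say <- function(...) logs <<- c(logs, .log("info", lg, ...))

  # --- simulate ------------------------------------------------------------
  fp <- do.call(fascicle_params, cfg$simulate$fascicle)
  design <- cohort_design(cfg$simulate$n_per_group,
                          lapply(cfg$simulate$multipliers, unlist),
                          seed = cfg$seed)
  cohort <- generate_cohort(design, fp, n_slices = cfg$simulate$n_slices)
  img_dir <- file.path(outdir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  truth_rows <- list()
  for (s in cohort) {
    write_zstack(s$stack, file.path(img_dir, paste0(s$sample_id, ".tif")))
    write_rois(s$truth$rois,
               file.path(img_dir, paste0(s$sample_id, "_rois.json")))
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      sample_id = s$sample_id, group = s$group,
      n_contacts = s$truth$n_contacts,
      perineurium_length_um = s$truth$perineurium_length_um,
      true_mean_perineurium = s$truth$true_mean_intensity[["perineurium"]])
  }
  truth <- do.call(rbind, truth_rows)
  utils::write.csv(truth, file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE)
  say("simulate: wrote ", length(cohort), " samples to ", img_dir)

  # --- nifi ----------------------------------------------------------------
  map <- do.call(channel_map, cfg$channel_map)
  protein <- cfg$nifi$protein
  stain_channel <- map[[protein]]
  nifi_rows <- list()
  for (s in cohort) {
    stk <- read_zstack(file.path(img_dir, paste0(s$sample_id, ".tif")),
                       pixel_size_um = fp$pixel_size_um,
                       sample_id = s$sample_id, group = s$group)
    rois <- read_rois(file.path(img_dir, paste0(s$sample_id, "_rois.json")))
    # simulated stacks carry the stain on the generator channel; map the
    # configured protein onto it for analysis
    amap <- channel_map(stats::setNames(fp$channel, protein))
    tab <- nifi_table(stk, rois, amap,
                      assignments = stats::setNames(
                        list(cfg$nifi$compartments), protein))
    nifi_rows[[length(nifi_rows) + 1L]] <- tab
  }
  nifi_tab <- do.call(rbind, nifi_rows)
  utils::write.csv(nifi_tab, file.path(outdir, "nifi.csv"),
                   row.names = FALSE)
  animal <- stats::aggregate(NIFI ~ sample_id + group + compartment,
                             nifi_tab, mean)
  say("nifi: ", nrow(nifi_tab), " slice measurements, ",
      nrow(animal), " animal values")

  # --- peaks ---------------------------------------------------------------
  pk_par <- do.call(peak_params, cfg$peaks$params)
  pk <- cohort_peaks(cohort, pk_par)
  utils::write.csv(pk, file.path(outdir, "peaks.csv"), row.names = FALSE)
  n_disc <- sum(!pk$qc_pass)
  say("peaks: ", nrow(pk), " samples analyzed, discarded (n = ", n_disc,
      ")")

  # --- qpcr ----------------------------------------------------------------
  qpcr_res <- NULL
  if (!is.null(cfg$qpcr)) {
    # key is n_per_group (not "n": a bare n is a YAML 1.1 boolean token)
    ct <- generate_ct_table(cfg$qpcr$genes, n = cfg$qpcr$n_per_group,
                            group_shift = unlist(cfg$qpcr$group_shift),
                            noise_sd = cfg$qpcr$noise_sd,
                            seed = cfg$seed)
    utils::write.csv(ct, file.path(outdir, "ct_table.csv"),
                     row.names = FALSE)
    qpcr_res <- do.call(rbind, lapply(cfg$qpcr$genes, function(g) {
      r <- delta_ct_expression(ct, g)
      data.frame(gene = g, fold_change = r$fold_change,
                 percent_change = r$percent_change)
    }))
    utils::write.csv(qpcr_res, file.path(outdir, "qpcr.csv"),
                     row.names = FALSE)
    say("qpcr: ", nrow(qpcr_res), " genes analyzed")
  }

  # --- stats + summary -----------------------------------------------------
  ref <- cfg$stats$reference
  summary_rows <- list(); stat_rows <- list()
  for (comp in unique(animal$compartment)) {
    sub <- animal[animal$compartment == comp, ]
    mu <- tapply(sub$NIFI, sub$group, mean)
    groups <- split(sub$NIFI, sub$group)
    groups <- groups[order(names(groups) != ref)]
    kd <- kruskal_dunn(groups)
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      measure = paste0("NIFI_", comp), test = kd$test,
      statistic = kd$statistic, p = kd$p)
    for (g in names(mu))
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        measure = paste0("NIFI_", comp), protein = protein, group = g,
        mean = mu[[g]],
        # percent change is undefined against a non-positive reference
        # (e.g. a signal-free compartment whose NIFI hovers around zero)
        percent_change_vs_ref = if (g == ref) 0
                                else if (!ref %in% names(mu) ||
                                         mu[[ref]] <= 0) NA_real_
                                else percent_change(mu[[ref]], mu[[g]]))
  }
  pk_ok <- pk[pk$qc_pass, ]
  if (nrow(pk_ok) > 0L) {
    mu_pk <- tapply(pk_ok$mean_peak_count, pk_ok$group, mean)
    pk_groups <- split(pk_ok$mean_peak_count, pk_ok$group)
    pk_groups <- pk_groups[order(names(pk_groups) != ref)]
    has_ref <- ref %in% names(mu_pk)
    if (length(pk_groups) >= 2L) {
      kd <- kruskal_dunn(pk_groups)
      stat_rows[[length(stat_rows) + 1L]] <- data.frame(
        measure = "mean_peak_count", test = kd$test,
        statistic = kd$statistic, p = kd$p)
    }
    for (g in names(mu_pk))
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        measure = "mean_peak_count", protein = cfg$peaks$protein,
        group = g, mean = mu_pk[[g]],
        percent_change_vs_ref = if (g == ref) 0
                                else if (!has_ref) NA_real_
                                else percent_change(mu_pk[[ref]],
                                                    mu_pk[[g]]))
  } else say("peaks: all samples discarded; peak statistics skipped")
  summary_tab <- do.call(rbind, summary_rows)
  stats_tab <- do.call(rbind, stat_rows)
  utils::write.csv(summary_tab, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_tab, file.path(outdir, "stats.csv"),
                   row.names = FALSE)
  say("stats: ", nrow(stats_tab), " tests run")

  manifest <- list(config = cfg, fascicle_params = unclass(fp),
                   peak_params = unclass(pk_par),
                   n_samples = length(cohort), n_qc_discarded = n_disc)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(logs, file.path(outdir, "run.log"))
  invisible(list(nifi = nifi_tab, animal_nifi = animal, peaks = pk,
                 qpcr = qpcr_res, summary = summary_tab, stats = stats_tab,
                 manifest = manifest, log = logs))
}
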