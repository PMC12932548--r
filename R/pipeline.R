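## End-to-end orchestration: simulate -> detect -> network metrics ->
## morphometry -> statistics, driven by a single validated configuration,
## deterministic for a fixed seed.

merge_settings <- function(defaults, user, where) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  stop_if(length(unknown) > 0, "unknown %s setting(s): %s", where,
          paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Pipeline configuration
#'
#' Assembles and validates the settings of every stage; unknown keys are
#' rejected so typos cannot silently fall back to defaults.  The returned
#' object serializes losslessly to JSON ([write_run_config()]).
#'
#' The default MEA scenario is a one-compound dose series (0/10/25/50
#' micrograms/mL, one well per group) recorded at 0, 24 and 72 h with a
#' dose- and time-dependent inhibitory effect; the default morphometry
#' scenario is a four-dose neurite-outgrowth assay with 4 replicate images
#' per group, fixed at the 48 h treatment endpoint.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param out_dir Output directory (`NULL`: return results only).
#' @param mea,morphometry,stats Named lists overriding the stage defaults
#'   (see the package vignette for the full key list).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, mea = list(),
                       morphometry = list(), stats = list()) {
  mea_def <- list(
    enabled = TRUE, render = TRUE,
    compound = "test-article",
    doses = c(0, 10, 25, 50), timepoints = c(0, 24, 72),
    wells_per_group = 1L, electrodes_per_well = 16L,
    sampling_rate = 12500, duration = 60,
    background_rate = 0.5, burst_rate = 6, spikes_per_burst_mean = 8,
    intra_burst_isi = 0.02, synchrony_coupling = 0.5,
    spike_amplitude = 50, noise_sd = 5,
    effect_factors = NULL)
  morph_def <- list(
    enabled = TRUE,
    doses = c(0, 10, 25, 50), timepoint = 48,
    images_per_group = 4L, n_somas = 5L,
    segment_length = c(25, 60), branch_probability = 0.35,
    image_size = c(256L, 256L),
    effect_factors = NULL)
  stats_def <- list(margin = 0.2, alpha = 0.05)
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              mea = merge_settings(mea_def, mea, "mea"),
              morphometry = merge_settings(morph_def, morphometry,
                                           "morphometry"),
              stats = merge_settings(stats_def, stats, "stats"))
  if (is.null(cfg$mea$effect_factors)) {
    d <- cfg$mea$doses; tp <- cfg$mea$timepoints
    grid <- expand.grid(dose = d, timepoint = tp)
    grid$factor <- ifelse(grid$dose == 0 | grid$timepoint == 0, 1,
                          pmax(0, 1 - 0.3 * (grid$timepoint / 24) *
                                 (match(grid$dose, sort(d)) - 1) / 2))
    cfg$mea$effect_factors <- grid
  }
  if (is.null(cfg$morphometry$effect_factors)) {
    d <- cfg$morphometry$doses
    cfg$morphometry$effect_factors <- data.frame(
      dose = d, timepoint = cfg$morphometry$timepoint,
      factor = ifelse(d == 0, 1,
                      pmax(0.4, 1 - 0.2 * (match(d, sort(d)) - 1))))
  }
  structure(cfg, class = "run_config")
}

#' Write / read a pipeline configuration
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `path` invisibly; [read_run_config()] returns the `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("mea", "morphometry")) {
    if (!is.null(raw[[k]]$effect_factors)) {
      raw[[k]]$effect_factors <- as.data.frame(raw[[k]]$effect_factors)
    }
  }
  run_config(seed = raw$seed, out_dir = raw$out_dir, mea = raw$mea,
             morphometry = raw$morphometry, stats = raw$stats)
}

mea_stage <- function(cfg) {
  m <- cfg$mea
  effect <- dose_effect_spec(m$effect_factors)
  doses <- m$doses
  plate <- plate_map(data.frame(
    well = well_names(length(doses) * m$wells_per_group),
    compound = m$compound,
    dose = rep(doses, each = m$wells_per_group)))
  metric_rows <- list()
  for (ti in seq_along(m$timepoints)) {
    tp <- m$timepoints[ti]
    for (di in seq_along(doses)) {
      dose <- doses[di]
      base <- spike_train_spec(
        background_rate = m$background_rate, burst_rate = m$burst_rate,
        spikes_per_burst_mean = m$spikes_per_burst_mean,
        intra_burst_isi = m$intra_burst_isi,
        synchrony_coupling = m$synchrony_coupling)
      spec <- apply_dose_effect(base, effect, dose, tp)
      layout <- plate_layout(n_wells = m$wells_per_group,
                             electrodes_per_well = m$electrodes_per_well,
                             sampling_rate = m$sampling_rate,
                             duration = m$duration)
      stage_seed <- cfg$seed + 101L * ti + 13L * di
      sim <- generate_spike_trains(layout, spec, seed = stage_seed)
      target_wells <- plate$well[plate$dose == dose]
      remap <- stats::setNames(target_wells, layout$wells)
      sts <- sim$trains
      sts$spikes$well <- unname(remap[sts$spikes$well])
      sts$wells <- unname(target_wells)
      if (isTRUE(m$render)) {
        tpl <- waveform_template(peak_amplitude = m$spike_amplitude,
                                 sampling_rate = m$sampling_rate)
        rec <- render_voltage_trace(sts, tpl, noise_sd = m$noise_sd,
                                    seed = stage_seed + 7L)
        sts <- detect_spikes(rec)
      }
      mm <- compute_plate_metrics(sts)
      mm$compound <- m$compound; mm$dose <- dose; mm$timepoint <- tp
      metric_rows[[length(metric_rows) + 1L]] <- mm
    }
  }
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  ## group-mean timeline of the headline metrics, then relatives and calls
  long <- list()
  for (metric in c("number_of_spikes", "mean_firing_rate",
                   "number_of_bursts", "synchrony_index")) {
    agg <- stats::aggregate(metrics[[metric]],
                            by = list(dose = metrics$dose,
                                      timepoint = metrics$timepoint),
                            FUN = mean)
    long[[metric]] <- data.frame(compound = m$compound, dose = agg$dose,
                                 timepoint = agg$timepoint, metric = metric,
                                 value = agg$x)
  }
  timeline <- do.call(rbind, long)
  rownames(timeline) <- NULL
  relative <- normalize_to_baseline(timeline)
  calls <- classify_effects(relative, margin = cfg$stats$margin)
  list(plate_map = plate, metrics = metrics, timeline = timeline,
       relative = relative, effects = calls)
}

morphometry_stage <- function(cfg) {
  mo <- cfg$morphometry
  effect <- dose_effect_spec(mo$effect_factors)
  per_cell <- list(); qc <- list()
  for (di in seq_along(mo$doses)) {
    dose <- mo$doses[di]
    base <- morphology_spec(n_somas = mo$n_somas,
                            segment_length = mo$segment_length,
                            branch_probability = mo$branch_probability,
                            image_size = mo$image_size)
    spec <- apply_dose_effect(base, effect, dose, mo$timepoint)
    for (im in seq_len(mo$images_per_group)) {
      sim <- generate_neuron_image(spec,
                                   seed = cfg$seed + 977L * di + im)
      res <- analyze_neuron_image(sim$image)
      if (nrow(res$phenotypes) > 0) {
        ph <- res$phenotypes
        ph$compound <- cfg$mea$compound
        ph$dose <- dose
        ph$well <- sprintf("d%g_r%d", dose, im)
        per_cell[[length(per_cell) + 1L]] <- ph
      }
      qc[[length(qc) + 1L]] <- data.frame(
        dose = dose, image = im, n_cells = res$qc$n_cells,
        marker_positive_fraction = res$qc$marker_positive_fraction)
    }
  }
  per_cell <- do.call(rbind, per_cell)
  rownames(per_cell) <- NULL
  wells <- aggregate_phenotypes(per_cell)
  wells$dose <- as.numeric(sub("^d([0-9.]+)_r.*$", "\\1", wells$well))
  ## relative-to-control well aggregates and the dose-group testing chain
  cols <- c("max_neurite_length", "total_neurite_length", "n_extremities",
            "n_roots", "n_segments", "n_nodes")
  ctrl <- colMeans(wells[wells$dose == 0, cols, drop = FALSE])
  rel <- wells
  for (cc in cols) rel[[cc]] <- wells[[cc]] / ifelse(ctrl[cc] > 0,
                                                     ctrl[cc], NA_real_)
  dose_table <- do.call(rbind, lapply(cols, function(cc) {
    data.frame(endpoint = cc, dose = wells$dose, value = wells[[cc]])
  }))
  tests <- test_dose_groups(dose_table, alpha = cfg$stats$alpha)
  list(per_cell = per_cell, wells = wells, relative = rel,
       qc = do.call(rbind, qc), tests = tests)
}

#' Run the full screening pipeline
#'
#' Executes (as enabled in the configuration) the MEA chain — simulate
#' spike trains under the configured dose-effect scenario, optionally
#' render voltage and re-detect spikes, compute per-well network metrics,
#' normalize to the 0 h baseline and classify effect directions — and the
#' morphometry chain — simulate neuron images per dose group, quantify the
#' six neurite phenotypes, aggregate per well and run the
#' ANOVA-plus-Dunnett testing chain.  With `out_dir` set (in the config or
#' as an argument) all tables are written as CSV plus a provenance JSON
#' carrying the config hash, seed and package version; a rerun with the
#' same config reproduces the outputs byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory, overriding the config's.
#' @return List with elements `mea`, `morphometry` (as produced by the two
#'   stages) and `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stop_if(!inherits(config, "run_config"),
          "`config` must come from run_config() or read_run_config()")
  if (is.null(out_dir)) out_dir <- config$out_dir
  res <- list()
  if (isTRUE(config$mea$enabled)) res$mea <- mea_stage(config)
  if (isTRUE(config$morphometry$enabled)) {
    res$morphometry <- morphometry_stage(config)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg_path <- file.path(out_dir, "config.json")
    write_run_config(config, cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    wr <- function(df, name) utils::write.csv(
      df, file.path(out_dir, paste0(name, "_", substr(cfg_hash, 1, 8),
                                    ".csv")), row.names = FALSE)
    if (!is.null(res$mea)) {
      wr(res$mea$metrics, "well_metrics")
      wr(res$mea$relative, "normalized_metrics")
      wr(res$mea$effects$trajectories, "effect_trajectories")
      wr(res$mea$plate_map, "plate_map")
    }
    if (!is.null(res$morphometry)) {
      wr(res$morphometry$per_cell, "phenotypes_per_cell")
      wr(res$morphometry$wells, "phenotypes_per_well")
      wr(res$morphometry$qc, "morphometry_qc")
      jsonlite::write_json(
        lapply(unclass(res$morphometry$tests), function(x) {
          x$dunnett <- if (!is.null(x$dunnett)) unclass(x$dunnett) else NULL
          x
        }),
        file.path(out_dir, paste0("phenotype_tests_",
                                  substr(cfg_hash, 1, 8), ".json")),
        auto_unbox = TRUE, digits = NA, null = "null")
    }
    res$provenance <- list(config_hash = cfg_hash, seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("neuroscreen")))
    jsonlite::write_json(res$provenance,
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE)
  } else {
    res$provenance <- list(seed = config$seed)
  }
  res
}
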