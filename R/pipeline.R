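# Workflow layer: a single YAML configuration drives simulation, fitting
# and metrics; each step writes plain-text tables plus a JSON manifest or
# sidecar so runs are reproducible and self-describing.

#' Default pipeline configuration
#'
#' The curve sections carry the three aqueous conditions of the chitin SMFS
#' study as generating parameter sets (delta_g in k_BT/unit: DI water 1.50,
#' pH 5 3.412, pH 3 5.53); the frame sections span the conformational axis
#' (spread acid chain, collapsed alkaline chain); the viscosity section
#' carries the MD-derived radii of gyration and cell densities.
#'
#' @param seed Global seed; section seeds are derived from it.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    model = list(kuhn_length = 0.514, unit_length_free = 0.45,
                 unit_length_forced = 0.54, temperature = 298),
    fit = list(force_window = c(50, 1500), free = c("delta_g", "l_f")),
    hbond = list(max_da_distance = 3.5, min_dha_angle = 130),
    curves = list(
      DI = list(delta_g = 1.50, n_curves = 20, noise_sd = 10),
      pH5 = list(delta_g = 3.412, n_curves = 20, noise_sd = 10),
      pH3 = list(delta_g = 5.53, n_curves = 20, noise_sd = 10)),
    frames = list(
      pH3 = list(kappa = 0.1, n_bridge_waters = 8, n_intra_hbonds = 0,
                 n_bulk_waters = 15, n_frames = 10),
      water = list(kappa = 0.5, n_bridge_waters = 4, n_intra_hbonds = 1,
                   n_bulk_waters = 15, n_frames = 10),
      pH11 = list(kappa = 0.9, n_bridge_waters = 1, n_intra_hbonds = 2,
                  n_bulk_waters = 15, n_frames = 10)),
    viscosity = list(
      reference = "water",
      molar_mass = 1015,
      conditions = list(
        water = list(rg = 9.48, density = 0.991),
        pH3 = list(rg = 12.27, density = 0.983),
        pH11 = list(rg = 7, density = 0.989)))
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' YAML serialization; `read_pipeline_config(write_pipeline_config(x))` is
#' lossless for the fields the pipeline consumes.
#'
#' @param path YAML file path.
#' @return For the reader, a `pipeline_config`; the writer returns `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_params <- function(config, delta_g = 1.50) {
  m <- config$model
  two_state_parameters(kuhn_length = m$kuhn_length,
                       unit_length_free = m$unit_length_free,
                       unit_length_forced = m$unit_length_forced,
                       delta_g = delta_g,
                       temperature = m$temperature)
}

require_section <- function(config, section) {
  if (is.null(config[[section]])) {
    stop(sprintf("config is missing the '%s' section", section))
  }
  config[[section]]
}

#' Simulate the configured synthetic datasets to disk
#'
#' Writes one TSV curve file per configured curve environment and one
#' multi-frame extended-XYZ file per frame environment, plus a
#' `manifest.json` listing every written file with its MD5 content hash.
#' Re-running with the same configuration reproduces identical hashes.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @return The manifest as a data frame, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  curve_cfg <- require_section(config, "curves")
  for (i in seq_along(curve_cfg)) {
    env <- names(curve_cfg)[i]
    cc <- curve_cfg[[i]]
    spec <- synthetic_curve_spec(
      params = config_params(config, delta_g = cc$delta_g),
      n_curves = if (!is.null(cc$n_curves)) cc$n_curves else 20,
      noise_sd = if (!is.null(cc$noise_sd)) cc$noise_sd else 10,
      environment = env,
      seed = config$seed + 100L * i)
    path <- file.path(outdir, sprintf("curves_%s.tsv", env))
    write_curves(generate_fec(spec), path)
    files <- c(files, path)
  }
  frame_cfg <- require_section(config, "frames")
  for (i in seq_along(frame_cfg)) {
    env <- names(frame_cfg)[i]
    fc <- frame_cfg[[i]]
    spec <- synthetic_frame_spec(
      kappa = fc$kappa,
      n_bridge_waters = if (!is.null(fc$n_bridge_waters)) fc$n_bridge_waters else 4,
      n_bulk_waters = if (!is.null(fc$n_bulk_waters)) fc$n_bulk_waters else 15,
      n_intra_hbonds = if (!is.null(fc$n_intra_hbonds)) fc$n_intra_hbonds else 0,
      n_frames = if (!is.null(fc$n_frames)) fc$n_frames else 10,
      seed = config$seed + 1000L * i)
    frames <- generate_frame_series(spec)
    path <- file.path(outdir, sprintf("frames_%s.xyz", env))
    unlink(path)
    for (fr in frames) {
      tmp <- tempfile()
      write_frame_xyz(fr, tmp)
      file.append(path, tmp)
      unlink(tmp)
    }
    files <- c(files, path)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Normalize and fit curve files per environment
#'
#' Loads curves, groups them by environment label, normalizes each at
#' 1500 pN (curves that do not reach the reference force are excluded with a
#' warning), fits the TSQM-FJC model per environment and writes
#' `fit_report.tsv`, `comparison.tsv` and a JSON sidecar with the fit
#' configuration.
#'
#' @param curve_files Character vector of TSV curve files.
#' @param config A `pipeline_config`.
#' @param outdir Output directory.
#' @return List with `fits` (named by environment) and `comparison`.
#' @export
run_fit <- function(curve_files, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  curves <- unlist(lapply(curve_files, load_curves), recursive = FALSE)
  envs <- vapply(curves, `[[`, character(1), "environment")
  fit_cfg <- fit_configuration(
    force_window = unlist(require_section(config, "fit")$force_window),
    free = unlist(config$fit$free),
    params = config_params(config),
    seed = config$seed)
  fits <- list()
  for (env in unique(envs)) {
    ncurves <- list()
    for (cv in curves[envs == env]) {
      nc <- tryCatch(normalize_curve(cv), error = function(e) {
        warning(sprintf("curve '%s' excluded from normalization: %s",
                        cv$id, conditionMessage(e)))
        NULL
      })
      if (!is.null(nc)) ncurves[[length(ncurves) + 1]] <- nc
    }
    if (length(ncurves) == 0) {
      stop(sprintf("no normalizable curves in environment '%s'", env))
    }
    fits[[env]] <- fit_tsqm_fjc(ncurves, fit_cfg)
  }
  report <- data.frame(
    environment = names(fits),
    delta_g_kbt = vapply(fits, `[[`, numeric(1), "delta_g_kbt"),
    delta_g_kjmol = vapply(fits, `[[`, numeric(1), "delta_g_kjmol"),
    l_f_nm = vapply(fits, `[[`, numeric(1), "l_f"),
    residual_rms = vapply(fits, `[[`, numeric(1), "residual_rms"),
    n_points = vapply(fits, `[[`, numeric(1), "n_points"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  utils::write.table(report, file.path(outdir, "fit_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  comparison <- if (length(fits) >= 2) compare_environments(fits) else NULL
  if (!is.null(comparison)) {
    utils::write.table(comparison, file.path(outdir, "comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(force_window = fit_cfg$force_window, free = fit_cfg$free,
         model = config$model, seed = config$seed),
    file.path(outdir, "fit_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(fits = fits, comparison = comparison)
}

read_frames_any <- function(path) {
  if (grepl("\\.pdb$", path, ignore.case = TRUE)) {
    frames <- read_frame_pdb(path)
  } else {
    frames <- read_frame_xyz(path)
  }
  if (inherits(frames, "molecular_frame")) list(frames) else frames
}

#' Conformation and hydrogen-bond metrics over frame files
#'
#' For each named frame file (names are condition labels): per-frame solute
#' radius of gyration and end-to-end distance (`rg_series.tsv`), per-frame
#' hydrogen-bond counts (`hbonds.tsv`), and — when the configuration
#' supplies radii and densities — normalized characteristic viscosities
#' (`viscosity.tsv`); a JSON summary ties them together.  A missing
#' viscosity section is skipped with a warning.
#'
#' @param frame_files Named character vector: condition label -> XYZ/PDB
#'   file.
#' @param config A `pipeline_config`.
#' @param outdir Output directory.
#' @return List with `rg`, `hbonds`, `viscosity` tables.
#' @export
run_metrics <- function(frame_files, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(frame_files)) || any(!nzchar(names(frame_files)))) {
    names(frame_files) <- sub("\\.(xyz|pdb)$", "", basename(frame_files),
                              ignore.case = TRUE)
  }
  criteria <- hbond_criteria(
    max_da_distance = require_section(config, "hbond")$max_da_distance,
    min_dha_angle = config$hbond$min_dha_angle)

  rg_rows <- list(); hb_rows <- list()
  for (cond in names(frame_files)) {
    frames <- read_frames_any(frame_files[[cond]])
    rg <- rg_series(frames, "solute")
    ree <- vapply(frames, end_to_end_distance, numeric(1))
    rg_rows[[cond]] <- data.frame(
      condition = cond, frame = seq_along(frames),
      time_ns = vapply(frames, `[[`, numeric(1), "time"),
      rg_A = rg$rg, ree_A = ree)
    hb <- hbond_ratio_over_frames(frames, criteria)
    hb_rows[[cond]] <- cbind(condition = cond, hb$per_frame)
  }
  rg_tab <- do.call(rbind, rg_rows); row.names(rg_tab) <- NULL
  hb_tab <- do.call(rbind, hb_rows); row.names(hb_tab) <- NULL
  utils::write.table(rg_tab, file.path(outdir, "rg_series.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(hb_tab, file.path(outdir, "hbonds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  visc <- NULL
  vcfg <- config$viscosity
  if (is.null(vcfg) || is.null(vcfg$conditions)) {
    warning("no viscosity section in config; viscosity table omitted")
  } else {
    m <- if (!is.null(vcfg$molar_mass)) vcfg$molar_mass else 1015
    inputs <- lapply(vcfg$conditions, function(cc) {
      viscosity_input(cc$rg, cc$density, m)
    })
    ratios <- normalized_viscosity(inputs, vcfg$reference)
    visc <- data.frame(condition = names(ratios),
                       rg_A = vapply(inputs, `[[`, numeric(1), "rg"),
                       density_kg_L = vapply(inputs, `[[`, numeric(1), "density"),
                       normalized_eta = unname(ratios), row.names = NULL)
    utils::write.table(visc, file.path(outdir, "viscosity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  summary <- list(
    rg_mean_A = vapply(split(rg_tab$rg_A, rg_tab$condition), mean, numeric(1)),
    hbond_ratio = vapply(split(hb_tab, hb_tab$condition), function(d) {
      if (mean(d$intra) > 0) mean(d$inter) / mean(d$intra) else Inf
    }, numeric(1)))
  if (!is.null(visc)) {
    summary$normalized_eta <- stats::setNames(visc$normalized_eta,
                                              visc$condition)
  }
  jsonlite::write_json(summary, file.path(outdir, "metrics_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(rg = rg_tab, hbonds = hb_tab, viscosity = visc)
}

#' End-to-end reproduction workflow
#'
#' Chains [run_simulate()], [run_fit()] and [run_metrics()] under one
#' configuration: simulate the configured ensembles, fit the elasticity
#' model per environment, and compute conformational metrics.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory; subdirectories `data/`, `fit/`,
#'   `metrics/` are created.
#' @return List with `fit` and `metrics` results.
#' @export
run_reproduce <- function(config = default_pipeline_config(), outdir) {
  data_dir <- file.path(outdir, "data")
  run_simulate(config, data_dir)
  curve_files <- list.files(data_dir, pattern = "^curves_.*\\.tsv$",
                            full.names = TRUE)
  frame_files <- list.files(data_dir, pattern = "^frames_.*\\.xyz$",
                            full.names = TRUE)
  names(frame_files) <- sub("^frames_(.*)\\.xyz$", "\\1",
                            basename(frame_files))
  fit <- run_fit(curve_files, config, file.path(outdir, "fit"))
  metrics <- run_metrics(frame_files, config, file.path(outdir, "metrics"))
  list(fit = fit, metrics = metrics)
}
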