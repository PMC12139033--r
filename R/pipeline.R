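# Pipeline configuration and the end-to-end driver.

.schema <- list(
  seed = NA, output_dir = NA,
  scene = c("concentration_mol_per_l", "h_m", "w_m", "pixels",
    "multiplicity_fractions", "monomer_intensity_mean",
    "monomer_intensity_cv", "psf_sigma_px", "mode", "background_level",
    "background_variation_amplitude", "background_correlation_px",
    "readout_sigma", "n_micrographs", "n_preparations"),
  detection = c("method", "threshold_k", "prob_threshold", "model_path"),
  photometry = c("aperture_radius_px", "min_separation_px",
    "background_mode", "n_sites", "exclusion_radius_px",
    "inner_radius_px", "outer_radius_px"),
  mixture = c("K", "select_k", "constrained"),
  geometry = c("h_m", "w_m", "dilution"),
  titration = c("v_eq_sample_ul", "v_eq_blank_ul", "c_naoh_mol_per_l",
    "v_hcl_blank_ul", "v_hcl_sample_ul", "v_stock_taken_ul"),
  model = c("preset", "diameter_nm", "density_g_cm3",
    "unit_molar_mass_g_mol", "polymer_molar_mass_g_mol",
    "monomer_molar_mass_g_mol"),
  uncertainty = c("counting_rel_u", "titration_rel_components",
    "n_samples", "mc_seed"))

#' Read and validate a pipeline configuration
#'
#' Reads a YAML pipeline configuration and validates it against the
#' package's schema: unknown sections or keys are rejected with their
#' location.  Keys carry explicit unit suffixes (`h_m`, `c_naoh_mol_per_l`,
#' `v_eq_sample_ul`, ...) to keep unit errors out of configs.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return The validated configuration list.
#' @seealso [runPipeline()]
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.schema))
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .schema[[sec]]
    if (length(allowed) == 1L && is.na(allowed[1L])) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

sceneConfigFromList <- function(sc, seed) {
  SceneConfig(
    concentration = sc$concentration_mol_per_l %||% 1.0825e-12,
    h = sc$h_m %||% 38e-6, w = sc$w_m %||% 300e-6,
    pixels = as.integer(sc$pixels %||% 1024L),
    multiplicityFractions = unlist(sc$multiplicity_fractions %||%
      c(0.52, 0.30, 0.18)),
    monomerMean = sc$monomer_intensity_mean %||% 2000,
    monomerCV = sc$monomer_intensity_cv %||% 0.25,
    psfSigma = sc$psf_sigma_px %||% 1.3,
    mode = sc$mode %||% "upconversion",
    backgroundLevel = sc$background_level,
    backgroundAmplitude = sc$background_variation_amplitude,
    backgroundCorrelation = sc$background_correlation_px %||% 60,
    readoutSigma = sc$readout_sigma %||% 3,
    seed = seed)
}

logStage <- function(logPath, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = logPath, append = TRUE, sep = "")
  message("[npquant] ", stage)
}

#' Run the complete counting-and-quantification pipeline
#'
#' Executes simulate (when a `scene` section is present) -> detect ->
#' measure -> mixture -> count, then titrate and quantify with Monte Carlo
#' uncertainty when `titration` and `model` sections are present.  Every
#' stage's outputs are written under `outDir` (TIFF scenes with ground
#' truth, localization/spot CSVs, the fit and report JSONs, and a
#' JSON-lines run log).  All randomness flows from the single config seed,
#' so a re-run with the same configuration is reproducible; timestamps
#' appear only in the log, never in the report.
#'
#' @param config path to a YAML configuration or a list, validated by
#'   [readPipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return Invisibly, the report list (also written to
#'   `<outDir>/report.json`).
#' @export
runPipeline <- function(config, outDir = NULL) {
  cfg <- readPipelineConfig(config)
  outDir <- outDir %||% cfg$output_dir %||% stop("outDir is required")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.jsonl")
  if (file.exists(logPath)) unlink(logPath)
  seed <- as.integer(cfg$seed %||% 1L)
  report <- list(seed = seed, stages = character(0))

  if (is.null(cfg$scene))
    stop("this driver runs from simulated scenes; provide a 'scene' section",
         " (use endToEndCounting() directly for externally supplied images)")
  sc <- cfg$scene
  nPrep <- sc$n_preparations %||% 2L
  nMic <- sc$n_micrographs %||% 3L
  logStage(logPath, "simulate", n_preparations = nPrep, n_micrographs = nMic,
           seed = seed)
  preps <- vector("list", nPrep)
  totalSpots <- 0L
  idx <- 0L
  for (p in seq_len(nPrep)) {
    preps[[p]] <- vector("list", nMic)
    for (i in seq_len(nMic)) {
      idx <- idx + 1L
      scene <- simulateScene(sceneConfigFromList(sc, seed + 1000L * idx))
      writeScene(scene$micrograph, scene$groundTruth,
                 file.path(outDir, sprintf("scene_p%d_m%d.tif", p, i)))
      preps[[p]][[i]] <- scene$micrograph
      totalSpots <- totalSpots + spotCount(scene$groundTruth)
    }
  }
  report$stages <- c(report$stages, "simulate")

  det <- cfg$detection %||% list()
  phot <- cfg$photometry %||% list()
  mix <- cfg$mixture %||% list()
  geom <- cfg$geometry %||% list()
  psf <- sc$psf_sigma_px %||% 1.3

  if (totalSpots == 0L) {
    report$flags <- "no particles detected"
    logStage(logPath, "count", flag = "no particles detected")
  } else {
    logStage(logPath, "count", method = det$method %||% "classical")
    model <- if (!is.null(det$model_path)) loadSpotNet(det$model_path)
    counting <- endToEndCounting(preps,
      h = geom$h_m %||% sc$h_m %||% 38e-6,
      D = geom$dilution %||% 1,
      method = det$method %||% "classical", model = model,
      psfSigma = psf, thresholdK = det$threshold_k %||% 5,
      K = as.integer(mix$K %||% 3L), selectK = isTRUE(mix$select_k),
      apertureRadius = phot$aperture_radius_px %||% (3 * psf),
      backgroundMode = phot$background_mode %||% "auto",
      seed = seed)
    fit <- attr(counting, "fit")
    spotTabs <- attr(counting, "spots")
    for (i in seq_along(spotTabs))
      writeLocalizations(spotTabs[[i]],
                         file.path(outDir, sprintf("spots_%02d.csv", i)))
    report$counting <- list(
      N = counting@N, R = counting@R,
      particles_per_micrograph = counting@particlesPerMicrograph,
      spot_density_mm2 = counting@spotDensity,
      particle_density_mm2 = counting@particleDensity,
      c_per_preparation_mol_l = counting@cPerPreparation,
      c_stock_mol_l = counting@cStock, c_sd_mol_l = counting@cSD)
    report$mixture <- list(K = fit@K, area = fit@area, mean = fit@mean,
      sigma = fit@sigma, rss = fit@rss, converged = fit@converged)
    report$stages <- c(report$stages, "count")

    if (!is.null(cfg$titration)) {
      logStage(logPath, "titrate")
      tt <- cfg$titration
      rec <- TitrationRecord(
        VEqSample = unlist(tt$v_eq_sample_ul) * 1e-6,
        VEqBlank = unlist(tt$v_eq_blank_ul) * 1e-6,
        cNaOH = tt$c_naoh_mol_per_l %||% 2.5e-3,
        VHClBlank = (tt$v_hcl_blank_ul %||% 150) * 1e-6,
        VHClSample = (tt$v_hcl_sample_ul %||% 150) * 1e-6,
        VStockTaken = (tt$v_stock_taken_ul %||% 300) * 1e-6)
      titr <- carboxylConcentration(rec)
      report$titration <- titr
      report$stages <- c(report$stages, "titrate")

      if (!is.null(cfg$model)) {
        logStage(logPath, "quantify")
        mm <- cfg$model
        pm <- ParticleModel(mm$preset %||% "custom",
          diameter = mm$diameter_nm, density = mm$density_g_cm3,
          unitMolarMass = mm$unit_molar_mass_g_mol,
          polymerMolarMass = mm$polymer_molar_mass_g_mol,
          monomerMolarMass = mm$monomer_molar_mass_g_mol)
        un <- cfg$uncertainty %||% list()
        report$quantification <- runReport(counting, titr, pm,
          countingRelU = un$counting_rel_u %||% 0.08,
          titrationRelU = unlist(un$titration_rel_components %||%
            c(0.01, 0.01, 0.015)),
          nSamples = un$n_samples %||% 5e6,
          seed = as.integer(un$mc_seed %||% seed))
        report$stages <- c(report$stages, "quantify")
      }
    }
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logStage(logPath, "done", report = "report.json")
  invisible(report)
}
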