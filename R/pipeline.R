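#' Run configuration for the end-to-end analysis
#'
#' Collects the stage inputs; stages whose inputs are `NULL` are skipped
#' with a logged notice. All defaults of the underlying stages (65-px
#' crop, 229 px / 20 um scale, 30-px base diameter, alpha = 0.05) are
#' embedded here and overridable.
#'
#' @param images named list of [micrograph] objects or image file paths
#'   (one or more per formulation; names are formulation codes, optionally
#'   suffixed `_1`, `_2`)
#' @param assays tidy replicate data frame: `formulation`, `metric`,
#'   `replicate`, `value`
#' @param recipes data frame shaped like `study_table("recipes")`
#' @param calibration calibration-level data frame (`amount`, `area`)
#' @param peaks peak table: `formulation`, `retention_time`, `area`
#' @param imaging an [imaging_config]
#' @param prep a [sample_prep]
#' @param reference_rt,rt_window retention-time matching parameters (min)
#' @param noise_sd baseline area noise for detection limits (`NA` to skip)
#' @param alpha significance level for Tukey grouping
#' @param seed integer seed recorded in the manifest
#' @param out_dir output directory
#' @return a `run_config` list
#' @export
run_config <- function(images = NULL, assays = NULL, recipes = NULL,
                       calibration = NULL, peaks = NULL,
                       imaging = imaging_config(), prep = sample_prep(),
                       reference_rt = 3.85, rt_window = 0.1,
                       noise_sd = NA_real_, alpha = 0.05, seed = 1,
                       out_dir = tempfile("capmetrics_run_")) {
  structure(list(images = images, assays = assays, recipes = recipes,
                 calibration = calibration, peaks = peaks,
                 imaging = imaging, prep = prep,
                 reference_rt = reference_rt, rt_window = rt_window,
                 noise_sd = noise_sd, alpha = alpha, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_cap("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis: imaging, QC, HPLC, statistics, report
#'
#' Executes every stage whose inputs are present, writes report CSVs and
#' a machine-readable JSON run manifest (inputs, resolved configuration,
#' per-stage counts) into `cfg$out_dir`. A failing stage halts the run
#' with the stage name in the error; earlier stages' outputs remain on
#' disk.
#'
#' @param cfg a [run_config]
#' @return list with `manifest` (also written as `manifest.json`),
#'   `qc_tables`, `size_summaries`, `quantification`, `out_dir`
#' @export
run_end_to_end <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  skipped <- character(0)
  counts <- list()

  size_summaries <- list()
  if (!is.null(cfg$images)) {
    size_summaries <- stage("imaging", {
      out <- list()
      for (nm in names(cfg$images)) {
        im <- cfg$images[[nm]]
        if (is.character(im)) im <- read_micrograph(im,
          databar_height = cfg$imaging$crop_rows)
        res <- size_particles(im, cfg$imaging)
        out[[nm]] <- res$summary
        utils::write.csv(res$table,
                         file.path(cfg$out_dir, paste0("particles_", nm, ".csv")),
                         row.names = FALSE)
      }
      out
    })
    counts$images <- length(cfg$images)
    counts$valid_particles <- sum(vapply(size_summaries, function(s) {
      if (is.null(s)) 0L else s$valid_n
    }, integer(1)))
  } else skipped <- c(skipped, "imaging")

  qc_tables <- list()
  if (!is.null(cfg$assays)) {
    qc_tables <- stage("qc", {
      out <- list()
      for (m in unique(cfg$assays$metric)) {
        sub <- cfg$assays[cfg$assays$metric == m, ]
        smry <- replicate_summary(sub)
        hg <- homogeneous_groups(
          group_data(data.frame(label = smry$formulation, mean = smry$mean,
                                sd = smry$sd, n = smry$n)),
          alpha = cfg$alpha)
        smry$letters <- unname(hg$letters[smry$formulation])
        out[[m]] <- smry
      }
      out
    })
    counts$qc_metrics <- length(qc_tables)
  } else skipped <- c(skipped, "qc")

  quantification <- NULL
  if (!is.null(cfg$peaks) && !is.null(cfg$calibration)) {
    quantification <- stage("hplc", {
      curve <- fit_calibration(cfg$calibration)
      if (!is.na(cfg$noise_sd)) curve <- detection_limits(cfg$noise_sd, curve)
      pk <- cfg$peaks
      pk$matched <- match_peak(pk$retention_time, cfg$reference_rt,
                               cfg$rt_window)
      q <- quantify_injection(pk$area, curve)
      pk$amount_ng <- ifelse(pk$matched, q$amount, NA_real_)
      pk$flag <- ifelse(pk$matched, q$flag, "unmatched")
      pk$c_powder <- powder_concentration(pk$amount_ng, cfg$prep)
      if (!is.null(cfg$recipes)) {
        moil <- vapply(pk$formulation, function(fcode) {
          row <- cfg$recipes[cfg$recipes$formulation == fcode, ]
          if (nrow(row) != 1) return(NA_real_)
          formulation_mass_balance(formulation_recipe(
            row$oil_mass, row$emulsifier_mass,
            data.frame(mass = c(row$maltodextrin_solution, row$second_solution),
                       solid_fraction = rep(row$solid_fraction, 2))))$m_oil
        }, numeric(1))
        pk$c_core <- ifelse(is.na(moil), NA_real_,
                            core_concentration(pk$c_powder, moil))
      }
      utils::write.csv(pk, file.path(cfg$out_dir, "quantification.csv"),
                       row.names = FALSE)
      pk
    })
    counts$peaks <- nrow(cfg$peaks)
  } else skipped <- c(skipped, "hplc")

  stage("report", render_report(
    cfg$out_dir, qc_tables = qc_tables, size_summaries = size_summaries,
    metadata = list(seed = cfg$seed, alpha = cfg$alpha,
                    crop_rows = cfg$imaging$crop_rows,
                    base_diameter_px = cfg$imaging$base_diameter_px)))

  manifest <- list(
    seed = cfg$seed,
    alpha = cfg$alpha,
    config = list(crop_rows = cfg$imaging$crop_rows,
                  base_diameter_px = cfg$imaging$base_diameter_px,
                  min_area_px = cfg$imaging$min_area_px,
                  reference_rt = cfg$reference_rt,
                  rt_window = cfg$rt_window,
                  sample_mass_g = cfg$prep$sample_mass,
                  reconstitution_volume_ml = cfg$prep$reconstitution_volume,
                  injection_volume_ul = cfg$prep$injection_volume),
    formulations = sort(unique(c(
      if (!is.null(cfg$assays)) cfg$assays$formulation,
      if (!is.null(cfg$peaks)) cfg$peaks$formulation,
      names(cfg$images %||% list())))),
    stages_run = setdiff(c("imaging", "qc", "hplc", "report"), skipped),
    stages_skipped = skipped,
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(manifest = manifest, qc_tables = qc_tables,
       size_summaries = size_summaries, quantification = quantification,
       out_dir = cfg$out_dir)
}

#' Self-contained demonstration run on synthetic data
#'
#' Simulates the full study layout — nine formulations with triplicate
#' bench assays drawn at the published means and SDs, one synthetic
#' micrograph per formulation, a four-level calibration line and one peak
#' per formulation — then runs the end-to-end analysis. The demo exercises
#' every calculator on per-replicate raw measurements (e.g. dried masses
#' are back-derived from the target moisture so `moisture_content()` does
#' the work).
#'
#' @param seed integer seed
#' @param out_dir output directory
#' @param image_px demo micrograph content size (pixels; small by default
#'   so the demo runs in seconds)
#' @param n_particles particles per demo micrograph
#' @return the [run_end_to_end()] result
#' @export
run_demo <- function(seed = 7, out_dir = tempfile("capmetrics_demo_"),
                     image_px = 512, n_particles = 25) {
  t1 <- study_table("moisture_solubility")
  t2 <- study_table("oil_ee")
  t3 <- study_table("density_flow")
  t6 <- study_table("lutein")
  recipes <- study_table("recipes")
  forms <- t1$formulation

  sim <- function(mean_col, sd_col, tab, off) {
    simulate_assay_replicates(
      data.frame(formulation = tab$formulation,
                 true_mean = tab[[mean_col]],
                 replicate_sd = tab[[sd_col]]),
      seed = seed + off)
  }

  # moisture: derive dried mass from the target MC, recompute via Eq. path
  mc <- sim("moisture_mean", "moisture_sd", t1, 1)
  mc$value <- moisture_content(2.0, 2.0 * (1 - mc$value / 100))
  # solubility: derive aliquot residue, recompute
  sol <- sim("solubility_mean", "solubility_sd", t1, 2)
  sol$value <- solubility(sol$value / 100 * 0.100 / 2.5, m_powder = 0.100)
  # EE from simulated surface/total oil replicate pairs
  so <- sim("surface_oil_mean", "surface_oil_sd", t2, 3)
  to <- sim("total_oil_mean", "total_oil_sd", t2, 4)
  ee <- so
  ee$value <- encapsulation_efficiency(pmin(so$value, to$value), to$value)
  # flowability from simulated density replicate pairs (kg/m^3)
  rb <- sim("bulk_density_mean", "bulk_density_sd", t3, 5)
  rt_ <- sim("tapped_density_mean", "tapped_density_sd", t3, 6)
  fl <- flowability_indices(rb$value, pmax(rt_$value, rb$value))
  ci <- rb; ci$value <- fl$ci
  hr <- rb; hr$value <- fl$hr

  assays <- rbind(
    cbind(mc, metric = "moisture"),
    cbind(sol, metric = "solubility"),
    cbind(ee, metric = "encapsulation_efficiency"),
    cbind(ci, metric = "carr_index"),
    cbind(hr, metric = "hausner_ratio")
  )

  images <- list()
  for (i in seq_along(forms)) {
    ms <- simulate_micrograph(micrograph_sim_params(
      image_width = image_px, image_height = image_px,
      n_particles = n_particles, allow_border = TRUE,
      seed = seed + 100 + i))
    images[[forms[i]]] <- ms$image
  }

  curve_true <- calibration_curve(6379.25, 2232.78)
  cal <- data.frame(amount = c(2.45, 12.25, 61.25, 122.5))
  cal$area <- simulate_peak_areas(cal$amount, curve_true, noise_sd = 0,
                                  seed = seed)$area
  prep <- sample_prep()
  amounts <- t6$powder_conc_mean * prep$injection_volume *
    prep$sample_mass / prep$reconstitution_volume
  peaks <- simulate_peak_areas(amounts, curve_true, noise_sd = 50,
                               seed = seed + 200)
  peaks <- data.frame(formulation = forms,
                      retention_time = peaks$retention_time,
                      area = peaks$area)

  cfg <- run_config(images = images, assays = assays, recipes = recipes,
                    calibration = cal, peaks = peaks, noise_sd = 250,
                    seed = seed, out_dir = out_dir)
  run_end_to_end(cfg)
}
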