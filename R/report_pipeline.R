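#' Pipeline configuration
#'
#' Resolves every tunable of the end-to-end study analog into one object:
#' cohort generation, per-modality analysis constants, calibration-phantom
#' layout, the vBMD measurement settings, the pre-processing kernel and
#' the global seed. Any field left `NULL` takes the documented default.
#'
#' @param n_donors,bilateral,donor_sd,residual_sd,mean_density cohort
#'   parameters (see [generate_cohort()]).
#' @param noise_sd,texture_contrast phantom intensity noise and trabecular
#'   texture amplitude for the whole cohort.
#' @param seed global seed; every stochastic stage derives a sub-seed.
#' @param render_pair named list of render models.
#' @param spec_template base [phantom_spec()] (density, noise and texture
#'   fields are overridden per the arguments above).
#' @param median_kernel pre-processing median-filter kernel.
#' @param calibration_densities insert densities of the calibration
#'   phantom (mg/cm3).
#' @param calibration_noise_sd intensity noise on the calibration phantom.
#' @param krappinger a [krappinger_config()].
#' @param modality_configs named list of [modality_config()] objects.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_donors = 6, bilateral = TRUE,
                            donor_sd = 30, residual_sd = 5,
                            mean_density = 150,
                            noise_sd = 0, texture_contrast = 0.2,
                            seed = 1L,
                            render_pair = default_render_pair(),
                            spec_template = phantom_spec(),
                            median_kernel = 3L,
                            calibration_densities = c(0, 100, 200),
                            calibration_noise_sd = 0,
                            krappinger = krappinger_config(),
                            modality_configs = list(
                              clinical_ct = modality_config("clinical_ct"),
                              micro_ct = modality_config("micro_ct"))) {
  spec_template$noise_sd <- noise_sd
  spec_template$texture_contrast <- texture_contrast
  structure(
    list(n_donors = n_donors, bilateral = bilateral, donor_sd = donor_sd,
         residual_sd = residual_sd, mean_density = mean_density,
         noise_sd = noise_sd, texture_contrast = texture_contrast,
         seed = as.integer(seed), render_pair = render_pair,
         spec_template = spec_template, median_kernel = median_kernel,
         calibration_densities = calibration_densities,
         calibration_noise_sd = calibration_noise_sd,
         krappinger = krappinger, modality_configs = modality_configs),
    class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] may be overridden from a YAML
#' file; omitted fields keep their defaults.
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  allowed <- c("n_donors", "bilateral", "donor_sd", "residual_sd",
               "mean_density", "noise_sd", "texture_contrast", "seed",
               "median_kernel", "calibration_densities",
               "calibration_noise_sd")
  do.call(pipeline_config, y[intersect(names(y), allowed)])
}

unit_for <- function(method, modality) {
  if (method == "ctoam") return("a.u.")
  if (method == "bma" && modality == "micro_ct") return("mg HA/cm3")
  "mg/cm3"
}

#' Check that a statistics plan never mixes measurement units
#'
#' Comparisons that combine methods reported on different scales (e.g.
#' mg/cm3 vs a.u.) are refused unless the plan declares prior
#' z-standardization; absolute values are not comparable across scales or
#' across modalities.
#'
#' @param records specimen-level data.frame with columns `method`,
#'   `modality`, `unit`.
#' @param plan list of plan items; each item is a list with `methods`
#'   (character), `modality`, and logical `zscored`.
#' @return List with `pass` (logical) and `findings` (messages).
#' @export
validate_cohort_units <- function(records, plan) {
  if (nrow(records) == 0L) stop("no specimen records")
  findings <- character(0)
  for (item in plan) {
    u <- unique(records$unit[records$method %in% item$methods &
                             records$modality == item$modality])
    if (length(u) > 1L && !isTRUE(item$zscored))
      findings <- c(findings, sprintf(
        "plan mixes units (%s) for methods [%s] without z-standardization",
        paste(u, collapse = ", "), paste(item$methods, collapse = ", ")))
  }
  list(pass = length(findings) == 0L, findings = findings)
}

analyze_specimen <- function(phantom, modality, cfg, kcfg, cal,
                             median_kernel) {
  vol <- median_filter_3d(phantom$volume, median_kernel)
  vol <- resample_cubic(vol)
  extent <- detect_extent(vol, cfg$bone_threshold,
                          neck_landmark = phantom$neck_slice)
  vol <- crop_subregion(vol, extent)
  trab <- crop_subregion(phantom$trabecular_mask, extent)
  cext <- axial_extent(1L, n_slices(vol), extent$landmark_source)
  out <- list()
  if (modality == "clinical_ct") {
    rois <- krappinger_rois(vol, cext, trab, kcfg)
    out$krappinger <- krappinger_bmd(vol, rois, kcfg$water_hu,
                                     cal)$bmd_mgcm3
  }
  map <- refine_map(segment_compartments(vol, cfg))
  out$bma <- trabecular_density(
    vol, map, if (modality == "clinical_ct") cal else
      identity_calibration())
  out$ctoam <- specimen_ctoam(vol, cext, cfg, trab)$specimen_index
  out
}

#' Run the full study analog
#'
#' Generates (or accepts) a clustered bilateral cohort, renders each
#' specimen at both modalities, applies the pre-processing chain and the
#' three measurement workflows, and produces the comparison report:
#' specimen-level CSV, descriptive table, cross-modality regression table,
#' paired-comparison table, repeated-measures ANOVA table, a JSON summary
#' and a plain-text log of every resolved parameter. Outputs are staged
#' and moved into `out_dir` only on success, so a failed run leaves no
#' partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param manifest optional pre-built [generate_cohort()] manifest
#'   (overrides the cohort fields of `config`).
#' @return Invisibly, a list with `records` (specimen-level data.frame),
#'   `matrices` (per-modality cohort matrices), `report`
#'   (a [method_report()]), `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         manifest = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- file.path(tempfile("osteodens_run"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  log <- c(sprintf("osteodens pipeline, seed %d", config$seed),
           sprintf("cohort: %d donors, bilateral=%s, mean %g, donor_sd %g, residual_sd %g",
                   config$n_donors, config$bilateral, config$mean_density,
                   config$donor_sd, config$residual_sd),
           sprintf("phantom: noise_sd %g, texture_contrast %g, radial_gradient %g",
                   config$noise_sd, config$texture_contrast,
                   config$spec_template$radial_gradient),
           sprintf("median kernel %d; calibration inserts [%s] (noise %g)",
                   config$median_kernel,
                   paste(config$calibration_densities, collapse = ", "),
                   config$calibration_noise_sd))

  if (is.null(manifest))
    manifest <- generate_cohort(
      n_donors = config$n_donors, bilateral = config$bilateral,
      donor_sd = config$donor_sd, residual_sd = config$residual_sd,
      mean_density = config$mean_density,
      render_pair = config$render_pair, seed = config$seed,
      spec_template = config$spec_template)
  entries <- manifest$entries
  specimen_ids <- paste(entries$donor_id, entries$side, sep = "_")

  calph <- generate_calibration_phantom(
    config$calibration_densities, config$render_pair$clinical_ct,
    noise_sd = config$calibration_noise_sd,
    seed = hash_seed(config$seed, "calibration"))
  cal <- fit_calibration(measure_inserts(
    calph$volume, calph$insert_masks, calph$insert_densities))
  log <- c(log, sprintf(
    "clinical calibration: sigma %.6g, beta %.6g, r2 %.6g",
    cal$sigma, cal$beta, cal$r2))

  records <- list()
  for (i in seq_len(nrow(entries))) {
    for (modality in names(manifest$render_pair)) {
      phantom <- render_specimen(manifest, i, modality)
      vals <- tryCatch(
        analyze_specimen(phantom, modality,
                         config$modality_configs[[modality]],
                         config$krappinger, cal, config$median_kernel),
        error = function(e)
          stop("specimen ", specimen_ids[i], " (", modality, "): ",
               conditionMessage(e), call. = FALSE))
      for (method in names(vals))
        records[[length(records) + 1L]] <- data.frame(
          donor_id = entries$donor_id[i], side = entries$side[i],
          specimen = specimen_ids[i], modality = modality,
          method = method, value = vals[[method]],
          unit = unit_for(method, modality),
          true_density = entries$true_density[i],
          stringsAsFactors = FALSE)
      rm(phantom)
    }
  }
  records <- do.call(rbind, records)

  to_matrix <- function(modality) {
    sub <- records[records$modality == modality, ]
    methods <- unique(sub$method)
    m <- sapply(methods, function(me)
      sub$value[sub$method == me][match(specimen_ids,
                                        sub$specimen[sub$method == me])])
    cohort_matrix(m, methods = methods, specimens = specimen_ids,
                  units = vapply(methods, unit_for, "", modality))
  }
  mats <- lapply(names(manifest$render_pair), to_matrix)
  names(mats) <- names(manifest$render_pair)

  plan <- list(
    list(methods = c("krappinger", "bma"), modality = "clinical_ct",
         zscored = FALSE),
    list(methods = c("krappinger", "bma", "ctoam"),
         modality = "clinical_ct", zscored = TRUE))
  units_ok <- validate_cohort_units(records, plan)
  if (!units_ok$pass)
    stop("unit validation failed: ",
         paste(units_ok$findings, collapse = "; "))

  ct <- mats$clinical_ct
  micro <- mats$micro_ct
  colnames(micro) <- paste0(colnames(micro), "_micro")
  report <- method_report(
    ct,
    pairs_to_test = list(c("krappinger", "bma")),
    regressions_to_fit = list(c("ctoam", "ctoam_micro"),
                              c("bma", "bma_micro")),
    extra = micro,
    rmanova_columns = c("krappinger", "bma", "ctoam"))

  write.csv(records, file.path(stage, "specimens.csv"), row.names = FALSE)
  write.csv(report$descriptives, file.path(stage, "descriptives.csv"),
            row.names = FALSE)
  flat <- function(lst) do.call(rbind, lapply(lst, function(x)
    as.data.frame(x[!vapply(x, is.null, TRUE)])))
  if (length(report$paired))
    write.csv(flat(report$paired), file.path(stage, "paired.csv"),
              row.names = FALSE)
  if (length(report$regressions))
    write.csv(flat(report$regressions), file.path(stage, "regressions.csv"),
              row.names = FALSE)
  write.csv(as.data.frame(unclass(report$rmanova)),
            file.path(stage, "rmanova.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed,
         calibration = list(sigma = cal$sigma, beta = cal$beta,
                            r2 = cal$r2),
         n_records = nrow(records),
         rmanova = unclass(report$rmanova)),
    file.path(stage, "summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log, file.path(stage, "run_log.txt"))
  write_manifest(manifest, stage)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(stage, full.names = TRUE))
    file.copy(f, out_dir, overwrite = TRUE)

  invisible(list(records = records, matrices = mats, report = report,
                 calibration = cal, manifest = manifest,
                 out_dir = out_dir))
}
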