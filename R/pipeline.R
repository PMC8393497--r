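#' Assemble a pipeline run configuration
#'
#' Collects everything the two analysis stages need: where the cohort lives,
#' which scalar quantities to analyse, their histogram bin widths, the T/N
#' cutoff, the relaxation-time bands used for the biopsy comparison, VOI
#' settings and the optional field-strength conversion.
#'
#' @param cohort_dir cohort directory written by [simulate_cohort()] (or laid
#'   out the same way).
#' @param output_dir where stage outputs and the run manifest are written.
#' @param quantities subset of `c("T1", "T2", "ADC")`.
#' @param bin_widths named list of histogram bin widths per quantity;
#'   defaults 100 ms (T1), 5 ms (T2), 0.0005 mm^2/s (ADC).
#' @param tn_cutoff T/N threshold separating the uptake classes.
#' @param bands named list of closed bands per quantity for the stage-2 TCD
#'   comparison; default T1 band 1850–3200 ms.
#' @param voi_volume_cm3,voi_shape VOI settings for biopsy averaging.
#' @param convert_field apply [convert_field_strength()] to T1/T2 maps?
#' @param conversion a [field_conversion()] used when `convert_field` is
#'   `TRUE`.
#' @param coordinate_frame frame of the biopsy tables' world coordinates:
#'   `"RAS"` (NIfTI convention, default) or `"LPS"` (DICOM-derived
#'   navigation coordinates, converted by negating x and y).
#' @param seed integer seed recorded in the manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(cohort_dir, output_dir,
                       quantities = c("T1", "T2", "ADC"),
                       bin_widths = list(T1 = 100, T2 = 5, ADC = 0.0005),
                       tn_cutoff = 1.5,
                       bands = list(T1 = c(1850, 3200)),
                       voi_volume_cm3 = 1.0, voi_shape = "cube",
                       convert_field = FALSE,
                       conversion = field_conversion(),
                       coordinate_frame = c("RAS", "LPS"),
                       seed = 1L) {
  coordinate_frame <- match.arg(coordinate_frame)
  quantities <- match.arg(quantities, c("T1", "T2", "ADC"),
                          several.ok = TRUE)
  missing_bw <- setdiff(quantities, names(bin_widths))
  if (length(missing_bw))
    stop_relaxo("bad-parameter", "no bin width for: ",
                paste(missing_bw, collapse = ", "))
  structure(list(cohort_dir = cohort_dir, output_dir = output_dir,
                 quantities = quantities, bin_widths = bin_widths,
                 tn_cutoff = tn_cutoff, bands = bands,
                 voi_volume_cm3 = voi_volume_cm3, voi_shape = voi_shape,
                 convert_field = convert_field, conversion = conversion,
                 coordinate_frame = coordinate_frame,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_relaxo("missing-file", "no such file: ", path)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  if (!is.null(args$bands)) args$bands <- lapply(args$bands, unlist)
  if (!is.null(args$conversion))
    args$conversion <- do.call(field_conversion, args$conversion)
  do.call(run_config, args)
}

log_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
}

quantity_file <- c(T1 = "t1.nii.gz", T2 = "t2.nii.gz", ADC = "adc.nii.gz")

patient_dirs <- function(cohort_dir) {
  mf <- file.path(cohort_dir, "manifest.yaml")
  if (file.exists(mf)) {
    ids <- unlist(yaml::read_yaml(mf)$patient_ids)
  } else {
    ids <- basename(list.dirs(cohort_dir, recursive = FALSE))
  }
  setNames(file.path(cohort_dir, ids), ids)
}

read_patient_maps <- function(pd, quantities, convert_field, conversion) {
  maps <- list()
  for (q in quantities) {
    f <- file.path(pd, quantity_file[[q]])
    if (!file.exists(f)) next
    v <- read_volume(f)
    if (convert_field && q %in% c("T1", "T2"))
      v <- convert_field_strength(v, q, conversion)
    maps[[q]] <- v
  }
  maps
}

#' Stage 1: pooled voxelwise likeliness analysis against PET uptake
#'
#' For every patient with a PET volume, computes the T/N map against the
#' patient's reference mask, partitions the analysis-mask voxels at the
#' configured cutoff, and pools each requested quantity's voxel values
#' across patients into one pair of class histograms. Per quantity it then
#' computes the likeliness profile, applies the bin-exclusion rule and
#' extracts the positive range. Patients lacking a required volume are
#' skipped with a logged reason.
#'
#' @param config a [run_config()].
#' @return a `stage1_result`: list with `profiles` (per-quantity list of
#'   `pair`, `profile`, `positive_range`), `n_high`, `n_low`, `n_patients`
#'   and `patients` (ids used). Profile CSVs and a manifest are written to
#'   `output_dir` when it is non-`NULL`.
#' @export
run_stage1 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pds <- patient_dirs(config$cohort_dir)
  pooled <- lapply(config$quantities, function(q) list(high = list(),
                                                       low = list()))
  names(pooled) <- config$quantities
  n_high <- 0L; n_low <- 0L
  used <- character(0)
  for (id in names(pds)) {
    pd <- pds[[id]]
    pet_f <- file.path(pd, "pet.nii.gz")
    if (!file.exists(pet_f)) {
      log_stage("stage1", "skipping ", id, ": no PET volume")
      next
    }
    maps <- read_patient_maps(pd, config$quantities, config$convert_field,
                              config$conversion)
    if (length(maps) < length(config$quantities)) {
      log_stage("stage1", "skipping ", id, ": missing ",
                paste(setdiff(config$quantities, names(maps)),
                      collapse = ", "))
      next
    }
    pet <- read_volume(pet_f)
    amask <- read_mask(file.path(pd, "analysis_mask.nii.gz"))
    rmask <- read_mask(file.path(pd, "reference_mask.nii.gz"))
    tn <- compute_tn_map(pet, rmask)
    part <- partition_by_tn(tn, amask, config$tn_cutoff)
    n_high <- n_high + part$n_high
    n_low <- n_low + part$n_low
    for (q in config$quantities) {
      pooled[[q]]$high[[id]] <- maps[[q]]$data[part$high_mask$data]
      pooled[[q]]$low[[id]] <- maps[[q]]$data[part$low_mask$data]
    }
    used <- c(used, id)
    log_stage("stage1", id, ": ", part$n_high, " high / ", part$n_low,
              " low voxels")
  }
  if (length(used) == 0L)
    stop_relaxo("no-stage1-patients", "no stage-1 patients: no patient had ",
                "the required volumes")
  units_of <- c(T1 = "ms", T2 = "ms", ADC = "mm2_per_s")
  profiles <- list()
  for (q in config$quantities) {
    pair <- histogram_pair_from_values(
      unlist(pooled[[q]]$high, use.names = FALSE),
      unlist(pooled[[q]]$low, use.names = FALSE),
      config$bin_widths[[q]], 0, units_of[[q]])
    prof <- apply_exclusion_rule(pair, compute_likeliness(pair))
    profiles[[q]] <- list(pair = pair, profile = prof,
                          positive_range = extract_positive_range(prof))
  }
  res <- structure(list(profiles = profiles, n_high = n_high, n_low = n_low,
                        n_patients = length(used), patients = used),
                   class = "stage1_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (q in config$quantities)
      write_profile(profiles[[q]]$profile,
                    file.path(config$output_dir,
                              paste0("profile_", q, ".csv")))
    manifest <- list(
      stage = "stage1", seed = config$seed,
      tn_cutoff = config$tn_cutoff,
      bin_widths = config$bin_widths[config$quantities],
      n_high = n_high, n_low = n_low, n_total = n_high + n_low,
      patients = as.list(used),
      positive_ranges = lapply(profiles, function(p)
        as.list(p$positive_range))
    )
    yaml::write_yaml(manifest, file.path(config$output_dir,
                                         "stage1_manifest.yaml"))
  }
  res
}

#' @export
print.stage1_result <- function(x, ...) {
  cat("<stage1_result> ", x$n_patients, " patients, NH = ", x$n_high,
      ", NL = ", x$n_low, "\n", sep = "")
  for (q in names(x$profiles)) {
    r <- x$profiles[[q]]$positive_range
    cat("  ", q, " positive range: ",
        if (length(r)) paste(signif(r, 6), collapse = " - ") else "(none)",
        "\n", sep = "")
  }
  invisible(x)
}

#' Stage 2: biopsy validation against tumor cell density
#'
#' Reads every patient's biopsy table, measures each sample's TCD and
#' VOI-averaged map values, classifies samples against the configured bands,
#' and runs the pooled-variance t-test of in-band vs out-of-band TCD per
#' quantity. When PET is present, samples are additionally grouped by their
#' VOI-averaged T/N against the cutoff and the same comparison is run.
#'
#' @param config a [run_config()].
#' @return a `stage2_result`: list with `measurements` (one row per sample)
#'   and `comparisons` (named list of `group_comparison`, in-band group
#'   first). Written to `output_dir` as CSVs when non-`NULL`.
#' @export
run_stage2 <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pds <- patient_dirs(config$cohort_dir)
  rows <- list()
  for (id in names(pds)) {
    pd <- pds[[id]]
    bf <- file.path(pd, "biopsies.csv")
    if (!file.exists(bf)) {
      log_stage("stage2", "skipping ", id, ": no biopsy table")
      next
    }
    biopsies <- parse_biopsy_table(bf)
    if (nrow(biopsies) == 0L) next
    if (config$coordinate_frame == "LPS") {
      biopsies$x <- -biopsies$x
      biopsies$y <- -biopsies$y
    }
    maps <- read_patient_maps(pd, config$quantities, config$convert_field,
                              config$conversion)
    pet_f <- file.path(pd, "pet.nii.gz")
    if (file.exists(pet_f)) {
      pet <- read_volume(pet_f)
      rmask <- read_mask(file.path(pd, "reference_mask.nii.gz"))
      maps$TN <- compute_tn_map(pet, rmask)
    }
    if (length(maps) == 0L) {
      log_stage("stage2", "skipping ", id, ": no maps")
      next
    }
    meas <- measure_biopsies(biopsies, maps,
                             bands = config$bands[intersect(names(config$bands),
                                                            names(maps))],
                             voi_volume_cm3 = config$voi_volume_cm3,
                             shape = config$voi_shape)
    rows[[id]] <- meas
    log_stage("stage2", id, ": ", nrow(meas), " samples measured")
  }
  if (length(rows) == 0L) {
    warning("no biopsies found in cohort; stage 2 is empty")
    return(structure(list(measurements = data.frame(),
                          comparisons = list()),
                     class = "stage2_result"))
  }
  measurements <- do.call(rbind, c(rows, make.row.names = FALSE))
  usable <- measurements[measurements$voi_ok, , drop = FALSE]
  n_flagged <- sum(!measurements$voi_ok)
  if (n_flagged > 0)
    log_stage("stage2", n_flagged,
              " samples with VOI outside all maps excluded from tests")
  comparisons <- list()
  for (q in intersect(names(config$bands), config$quantities)) {
    if (!paste0("in_band_", q) %in% names(usable)) next
    cmp <- compare_tcd_by_band(usable, q)
    if (!is.null(cmp)) comparisons[[paste0("tcd_by_", q, "_band")]] <- cmp
  }
  if ("mean_TN" %in% names(usable)) {
    usable$in_band_TN <- usable$mean_TN > config$tn_cutoff
    cmp <- compare_tcd_by_band(usable, "TN")
    if (!is.null(cmp)) comparisons$tcd_by_tn <- cmp
  }
  res <- structure(list(measurements = measurements,
                        comparisons = comparisons),
                   class = "stage2_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- measurements
    write.csv(flat, file.path(config$output_dir, "measurements.csv"),
              row.names = FALSE)
    if (length(comparisons)) {
      cmpdf <- do.call(rbind, lapply(names(comparisons), function(nm) {
        cc <- comparisons[[nm]]
        data.frame(comparison = nm, n_in = cc$n1, n_out = cc$n2,
                   mean_in = cc$mean1, mean_out = cc$mean2,
                   pooled_sd = cc$pooled_sd, t = cc$t_statistic,
                   df = cc$degrees_of_freedom, p = cc$p_value)
      }))
      write.csv(cmpdf, file.path(config$output_dir, "comparisons.csv"),
                row.names = FALSE)
    }
  }
  res
}

#' @export
print.stage2_result <- function(x, ...) {
  cat("<stage2_result> ", nrow(x$measurements), " samples\n", sep = "")
  for (nm in names(x$comparisons)) {
    cat("  ", nm, ": ", sep = "")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

#' Run both analysis stages and synthesize tumor-load maps
#'
#' Executes stage 1 (pooled likeliness vs PET uptake) and stage 2 (biopsy
#' TCD validation), then synthesizes a tumor-load probability map from each
#' stage-1 patient's T1 map using the pooled T1 profile, writing
#' `tumorload_<id>.nii.gz` plus a validity mask to the output directory.
#'
#' @param config a [run_config()] whose quantities include `"T1"`.
#' @return list with elements `stage1`, `stage2`, `tumor_maps` (paths).
#' @export
run_pipeline <- function(config) {
  s1 <- run_stage1(config)
  s2 <- run_stage2(config)
  paths <- character(0)
  if ("T1" %in% names(s1$profiles) && !is.null(config$output_dir)) {
    prof <- s1$profiles$T1$profile
    for (id in s1$patients) {
      t1 <- read_volume(file.path(config$cohort_dir, id, "t1.nii.gz"))
      if (config$convert_field)
        t1 <- convert_field_strength(t1, "T1", config$conversion)
      tl <- synthesize_tumor_load_map(t1, prof)
      p <- file.path(config$output_dir, paste0("tumorload_", id, ".nii.gz"))
      write_volume(tl$probability, p)
      write_mask(tl$valid, file.path(config$output_dir,
                                     paste0("tumorload_valid_", id,
                                            ".nii.gz")))
      paths <- c(paths, p)
      log_stage("tumormap", id, ": written")
    }
  }
  list(stage1 = s1, stage2 = s2, tumor_maps = paths)
}
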