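#' Specification of a synthetic two-class voxel cohort
#'
#' Describes the statistical structure of a simulated co-registered patient
#' dataset: within the analysis mask every voxel belongs to a high- or
#' low-uptake class, and each class draws its T1, T2, ADC and
#' tumor-to-normal (T/N) values from truncated-normal distributions
#' (truncated at 0). The high class is right-shifted and narrower in T1 and
#' T2 than the low class, which is the qualitative structure the voxelwise
#' histogram contrast is designed to detect. Biopsy samples get a tumor cell
#' density drawn from the in-band distribution when the sampled voxel's T1
#' lies inside `tcd_band`, and from the out-band distribution otherwise.
#'
#' Class distribution parameters are synthetic choices (location, scale):
#' they reproduce the documented shape relations, not fitted clinical
#' values. The grid defaults to 256 x 256 x 48 voxels of
#' 0.9 x 0.9 x 3.3 mm, and the high-class fraction defaults to 0.367,
#' matching a pooled high:low split of roughly 100k:172k voxels.
#'
#' @param n_patients number of patients to simulate.
#' @param grid_dims integer length-3 grid dimensions.
#' @param grid_spacing numeric length-3 voxel spacing in mm.
#' @param class_fraction_high proportion of analysis-mask voxels in the
#'   high-uptake class, in (0, 1).
#' @param t1_high,t1_low,t2_high,t2_low `c(location, scale)` in ms.
#' @param adc_high,adc_low `c(location, scale)` in mm^2/s.
#' @param tn_high,tn_low `c(location, scale)` of the T/N ratio.
#' @param tcd_inband,tcd_outband `c(location, scale)` in cells/mm^2.
#' @param tcd_band closed T1 band (ms) inside which biopsies draw from
#'   `tcd_inband`.
#' @param n_biopsies biopsy samples per patient.
#' @param echo_times multi-echo acquisition times in ms, strictly increasing.
#' @param s0 proton-density signal scale of the echo decays.
#' @param noise_sd additive Gaussian noise SD on the echo signals (> 0 unless
#'   exactly 0 for noiseless synthesis).
#' @param count_noise_sd SD of the independent noise added to each biopsy
#'   field count before rounding.
#' @param ref_activity `c(location, scale)` of the normal-reference PET
#'   activity (arbitrary units).
#' @param mask_fraction approximate fraction of each grid axis spanned by the
#'   ellipsoidal analysis mask's semi-axes.
#' @param seed master integer seed; every random draw descends from it via
#'   per-patient substreams.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 10,
                        grid_dims = c(256L, 256L, 48L),
                        grid_spacing = c(0.9, 0.9, 3.3),
                        class_fraction_high = 0.367,
                        t1_high = c(2400, 300), t1_low = c(1500, 700),
                        t2_high = c(165, 25), t2_low = c(100, 45),
                        adc_high = c(0.0012, 0.00012),
                        adc_low = c(0.0008, 0.0003),
                        tn_high = c(2.0, 0.25), tn_low = c(1.0, 0.2),
                        tcd_inband = c(3000, 500), tcd_outband = c(1000, 400),
                        tcd_band = c(1850, 3200),
                        n_biopsies = 8L,
                        echo_times = seq(20, 140, by = 20),
                        s0 = 500, noise_sd = 5,
                        count_noise_sd = 3,
                        ref_activity = c(100, 5),
                        mask_fraction = 0.35,
                        seed = 1L) {
  if (!(class_fraction_high > 0 && class_fraction_high <= 1))
    stop_relaxo("bad-parameter", "class_fraction_high must be in (0, 1]")
  pairs <- list(t1_high = t1_high, t1_low = t1_low, t2_high = t2_high,
                t2_low = t2_low, adc_high = adc_high, adc_low = adc_low,
                tn_high = tn_high, tn_low = tn_low, tcd_inband = tcd_inband,
                tcd_outband = tcd_outband, ref_activity = ref_activity)
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    if (length(p) != 2L || p[1] <= 0 || p[2] <= 0)
      stop_relaxo("bad-parameter", nm,
                  " must be c(location, scale) with both > 0")
  }
  if (any(diff(echo_times) <= 0))
    stop_relaxo("bad-parameter", "echo_times must be strictly increasing")
  if (noise_sd < 0)
    stop_relaxo("bad-parameter", "noise_sd must be >= 0")
  structure(list(
    n_patients = as.integer(n_patients),
    grid_dims = as.integer(grid_dims), grid_spacing = grid_spacing,
    class_fraction_high = class_fraction_high,
    t1_high = t1_high, t1_low = t1_low, t2_high = t2_high, t2_low = t2_low,
    adc_high = adc_high, adc_low = adc_low,
    tn_high = tn_high, tn_low = tn_low,
    tcd_inband = tcd_inband, tcd_outband = tcd_outband,
    tcd_band = tcd_band, n_biopsies = as.integer(n_biopsies),
    echo_times = echo_times, s0 = s0, noise_sd = noise_sd,
    count_noise_sd = count_noise_sd, ref_activity = ref_activity,
    mask_fraction = mask_fraction, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Deterministic per-patient substream seed, invariant to n_patients.
patient_seed <- function(seed, patient_index) {
  as.integer((as.double(seed) + 104729 * patient_index) %% 2147483629)
}

# Truncated-normal (at 0) draws via inverse CDF, vectorised.
rtnorm0 <- function(n, location, scale) {
  lo <- pnorm(0, location, scale)
  qnorm(runif(n, lo, 1), location, scale)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Simulate one synthetic patient
#'
#' Generates co-registered T1, T2, ADC and PET volumes, an ellipsoidal
#' analysis mask with a disjoint normal-reference box, a biopsy table, and
#' (optionally) the multi-echo T2-weighted volumes
#' S(TE) = S0 exp(-TE / T2) + noise. The PET volume is scaled so that each
#' mask voxel's T/N ratio against the generated reference region equals its
#' drawn T/N value exactly. Biopsy field counts are
#' `round(TCD * field_area + noise)` over three fields, with the standard
#' 0.0497 mm^2 counting field.
#'
#' All randomness derives from the spec's master seed through a per-patient
#' substream, so patient `i` is reproducible independently of how many other
#' patients are simulated.
#'
#' @param spec a [cohort_spec()].
#' @param patient_index 1-based patient number.
#' @param include_echoes generate the multi-echo volumes (they dominate
#'   memory at full grid size)?
#' @return list with elements `t1`, `t2`, `adc`, `pet` (`voxel_volume`s),
#'   `analysis_mask`, `reference_mask` (`mask_volume`s), `biopsies`
#'   (a `biopsy_table`), `echoes` (named list of `voxel_volume`s or `NULL`),
#'   `truth` (list with the generator's per-voxel class mask and drawn T/N).
#' @export
simulate_patient <- function(spec, patient_index, include_echoes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  d <- spec$grid_dims
  sp <- spec$grid_spacing
  affine <- diag(c(sp, 1))
  # ellipsoidal analysis mask in the grid center
  ctr <- (d - 1) / 2
  semi <- spec$mask_fraction * d / 2
  ii <- (seq_len(d[1]) - 1 - ctr[1]) / semi[1]
  jj <- (seq_len(d[2]) - 1 - ctr[2]) / semi[2]
  kk <- (seq_len(d[3]) - 1 - ctr[3]) / semi[3]
  e2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  mask <- e2 <= 1
  if (!any(mask))
    stop_relaxo("empty-mask", "analysis mask fits nowhere in this grid")
  # reference box near a corner, disjoint from the ellipsoid by construction
  ref <- array(FALSE, dim = d)
  rx <- seq_len(max(1L, floor(0.11 * d[1])))
  ry <- seq_len(max(1L, floor(0.11 * d[2])))
  rz <- seq(max(1L, floor(d[3] / 3)), max(1L, floor(2 * d[3] / 3)))
  ref[rx, ry, rz] <- TRUE
  stopifnot(!any(ref & mask))

  nm <- sum(mask)
  nv <- prod(d)
  # High-uptake class occupies a central "core": the exact number of mask
  # voxels given by class_fraction_high, chosen nearest the mask center.
  # Spatial coherence matters downstream: a 1-cm^3 VOI average is only
  # informative when tissue classes form contiguous regions, as tumor core
  # and infiltrated margin do.
  e2m <- e2[mask]
  n_core <- round(nm * spec$class_fraction_high)
  cls_high <- rank(e2m, ties.method = "first") <= n_core
  with_local_seed(patient_seed(spec$seed, patient_index), {
    draw2 <- function(p_high, p_low) {
      v <- numeric(nm)
      v[cls_high] <- rtnorm0(sum(cls_high), p_high[1], p_high[2])
      v[!cls_high] <- rtnorm0(sum(!cls_high), p_low[1], p_low[2])
      v
    }
    t1m <- draw2(spec$t1_high, spec$t1_low)
    t2m <- draw2(spec$t2_high, spec$t2_low)
    adcm <- draw2(spec$adc_high, spec$adc_low)
    tnm <- draw2(spec$tn_high, spec$tn_low)
    # background (outside the analysis mask): low-class tissue
    t1 <- array(rtnorm0(nv, spec$t1_low[1], spec$t1_low[2]), dim = d)
    t2 <- array(rtnorm0(nv, spec$t2_low[1], spec$t2_low[2]), dim = d)
    adc <- array(rtnorm0(nv, spec$adc_low[1], spec$adc_low[2]), dim = d)
    t1[mask] <- t1m; t2[mask] <- t2m; adc[mask] <- adcm
    # PET: reference-level activity everywhere, then exact T/N inside mask
    pet <- array(rtnorm0(nv, spec$ref_activity[1], spec$ref_activity[2]),
                 dim = d)
    ref_mean <- mean(pet[ref])
    pet[mask] <- tnm * ref_mean
    tn_true <- array(NA_real_, dim = d)
    tn_true[mask] <- tnm

    # biopsies: voxels sampled inside the analysis mask, stratified over the
    # core and the margin so both tissue types are represented (sampling in
    # the emulated study deliberately targeted both enhancing and
    # non-enhancing tissue)
    mask_idx <- which(mask)
    core_pos <- which(cls_high)
    shell_pos <- which(!cls_high)
    n_core_bx <- round(spec$n_biopsies * spec$class_fraction_high)
    n_core_bx <- min(max(n_core_bx, if (length(shell_pos)) 0L else spec$n_biopsies),
                     spec$n_biopsies)
    pick <- function(pool, n) {
      if (n == 0L || length(pool) == 0L) return(integer(0))
      pool[sample.int(length(pool), n, replace = n > length(pool))]
    }
    take <- c(pick(core_pos, n_core_bx),
              pick(shell_pos, spec$n_biopsies - n_core_bx))
    if (length(take) < spec$n_biopsies)   # a stratum was empty
      take <- c(take, pick(seq_along(mask_idx),
                           spec$n_biopsies - length(take)))
    vox <- arrayInd(mask_idx[take], d) - 1L  # 0-based
    world <- t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
    t1_at <- t1[mask_idx[take]]
    inband <- t1_at >= spec$tcd_band[1] & t1_at <= spec$tcd_band[2]
    tcd <- numeric(spec$n_biopsies)
    tcd[inband] <- rtnorm0(sum(inband), spec$tcd_inband[1],
                           spec$tcd_inband[2])
    tcd[!inband] <- rtnorm0(sum(!inband), spec$tcd_outband[1],
                            spec$tcd_outband[2])
    field_area <- 0.0497
    counts <- lapply(seq_len(spec$n_biopsies), function(i) {
      raw <- round(tcd[i] * field_area + rnorm(3, 0, spec$count_noise_sd))
      as.integer(pmax(raw, 0L))
    })
    biopsies <- data.frame(
      patient_id = sprintf("p%02d", patient_index),
      x = world[, 1], y = world[, 2], z = world[, 3],
      enhancing = cls_high[take], stringsAsFactors = FALSE)
    biopsies$field_counts <- counts
    class(biopsies) <- c("biopsy_table", "data.frame")

    echoes <- NULL
    if (include_echoes) {
      echoes <- lapply(spec$echo_times, function(te) {
        s <- spec$s0 * exp(-te / t2)
        if (spec$noise_sd > 0) s <- s + array(rnorm(nv, 0, spec$noise_sd),
                                              dim = d)
        voxel_volume(s, affine, "activity")
      })
      names(echoes) <- sprintf("TE%03d", as.integer(spec$echo_times))
    }

    list(
      t1 = voxel_volume(t1, affine, "ms"),
      t2 = voxel_volume(t2, affine, "ms"),
      adc = voxel_volume(adc, affine, "mm2_per_s"),
      pet = voxel_volume(pet, affine, "activity"),
      analysis_mask = mask_volume(mask, affine),
      reference_mask = mask_volume(ref, affine),
      biopsies = biopsies,
      echoes = echoes,
      truth = list(class_high = cls_high, tn = tn_true,
                   tcd = tcd, tcd_inband = inband)
    )
  })
}

#' Simulate and write a cohort to disk
#'
#' Writes one directory per patient (`p01`, `p02`, ...) containing
#' `t1.nii.gz`, `t2.nii.gz`, `adc.nii.gz`, `pet.nii.gz`,
#' `analysis_mask.nii.gz`, `reference_mask.nii.gz` and `biopsies.csv`, plus a
#' top-level `manifest.yaml` recording the spec, the seed, the patient ids
#' and the MD5 hash of every written file. Re-running with the same spec
#' reproduces identical files.
#'
#' @param spec a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @param include_echoes also write the multi-echo volumes under
#'   `echoes/` per patient.
#' @return the manifest (invisibly), as a list.
#' @export
simulate_cohort <- function(spec, dir, include_echoes = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop_relaxo("unwritable", "cannot write to ", dir)
  ids <- sprintf("p%02d", seq_len(spec$n_patients))
  files <- character(0)
  for (i in seq_len(spec$n_patients)) {
    pd <- file.path(dir, ids[i])
    dir.create(pd, showWarnings = FALSE)
    pat <- simulate_patient(spec, i, include_echoes = include_echoes)
    write_volume(pat$t1, file.path(pd, "t1.nii.gz"))
    write_volume(pat$t2, file.path(pd, "t2.nii.gz"))
    write_volume(pat$adc, file.path(pd, "adc.nii.gz"))
    write_volume(pat$pet, file.path(pd, "pet.nii.gz"))
    write_mask(pat$analysis_mask, file.path(pd, "analysis_mask.nii.gz"))
    write_mask(pat$reference_mask, file.path(pd, "reference_mask.nii.gz"))
    bio <- pat$biopsies
    flat <- data.frame(patient_id = bio$patient_id, x = bio$x, y = bio$y,
                       z = bio$z,
                       counts = vapply(bio$field_counts, paste,
                                       character(1), collapse = ";"),
                       enhancing = as.integer(bio$enhancing))
    write.csv(flat, file.path(pd, "biopsies.csv"), row.names = FALSE)
    if (include_echoes) {
      ed <- file.path(pd, "echoes")
      dir.create(ed, showWarnings = FALSE)
      for (nm in names(pat$echoes))
        write_volume(pat$echoes[[nm]], file.path(ed, paste0(nm, ".nii.gz")))
    }
    files <- c(files, list.files(pd, recursive = TRUE, full.names = TRUE))
  }
  hashes <- tools::md5sum(files)
  manifest <- list(
    spec = unclass(spec),
    patient_ids = as.list(ids),
    files = as.list(setNames(unname(hashes),
                             substring(files, nchar(dir) + 2)))
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
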