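#' Mean map value within a volume-of-interest around a world coordinate
#'
#' Averages the map over the voxels whose centers lie inside an axis-aligned
#' cube (default) or sphere of the requested volume centered at the target
#' world coordinate. The default 1 cm^3 VOI corresponds to a 10 mm cube edge
#' (or an equal-volume sphere of radius ~6.2 mm). Non-finite voxels are
#' excluded from the mean.
#'
#' @param volume a `voxel_volume`.
#' @param center_world numeric length-3 world coordinate in mm.
#' @param voi_volume_cm3 VOI volume in cm^3 (default 1).
#' @param shape `"cube"` or `"sphere"`.
#' @return list with `mean` and `n_voxels` (count of contributing voxels).
#' @export
voi_mean <- function(volume, center_world, voi_volume_cm3 = 1.0,
                     shape = c("cube", "sphere")) {
  shape <- match.arg(shape)
  stopifnot(inherits(volume, "voxel_volume"))
  if (voi_volume_cm3 <= 0)
    stop_relaxo("bad-parameter", "voi_volume_cm3 must be > 0")
  d <- dim(volume$data)
  # world coordinates of every candidate voxel center near the target:
  # restrict to an index bounding box to avoid scanning the whole grid
  half_edge_mm <- if (shape == "cube") {
    (voi_volume_cm3^(1 / 3) * 10) / 2
  } else {
    (3 * voi_volume_cm3 * 1000 / (4 * pi))^(1 / 3)  # sphere radius in mm
  }
  ctr_idx <- world_to_voxel(center_world, volume)
  sp <- voxel_spacing(volume)
  pad <- ceiling(half_edge_mm / sp) + 1
  lo <- pmax(floor(ctr_idx - pad), 0)
  hi <- pmin(ceiling(ctr_idx + pad), d - 1)
  if (any(lo > hi))
    stop_relaxo("voi-outside", "VOI lies fully outside the image grid")
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  W <- voxel_to_world(g, volume)
  inside <- if (shape == "cube") {
    abs(W[, 1] - center_world[1]) <= half_edge_mm &
    abs(W[, 2] - center_world[2]) <= half_edge_mm &
    abs(W[, 3] - center_world[3]) <= half_edge_mm
  } else {
    rowSums(sweep(W, 2, center_world)^2) <= half_edge_mm^2
  }
  if (!any(inside))
    stop_relaxo("voi-outside", "no voxel centers fall inside the VOI")
  vals <- volume$data[g[inside, , drop = FALSE] + 1L]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop_relaxo("voi-outside", "no finite voxels inside the VOI")
  list(mean = mean(vals), n_voxels = length(vals))
}

#' Tumor cell density from per-field cell counts
#'
#' Mean of the per-field counts divided by the counting-field area. The
#' default field area is 0.0497 mm^2 (the x400 light-microscopy counting
#' field), with the mean taken over 3 fields per specimen in the standard
#' protocol.
#'
#' @param field_counts integer vector of cells counted per field (>= 1
#'   field, all counts >= 0).
#' @param field_area_mm2 counting-field area in mm^2.
#' @return tumor cell density in cells/mm^2.
#' @export
tcd_from_counts <- function(field_counts, field_area_mm2 = 0.0497) {
  if (length(field_counts) < 1L)
    stop_relaxo("bad-parameter", "need at least one field count")
  if (any(field_counts < 0))
    stop_relaxo("bad-parameter", "field counts must be >= 0")
  if (field_area_mm2 <= 0)
    stop_relaxo("bad-parameter", "field area must be > 0")
  mean(field_counts) / field_area_mm2
}

#' Classify a value against a closed band
#'
#' `TRUE` iff `low <= value <= high`: band membership is inclusive at both
#' edges, matching the convention "within the range low–high".
#'
#' @param value numeric value(s) in the quantity's units.
#' @param band numeric length-2 `c(low, high)` with `low < high`.
#' @return logical, same length as `value`; `NA` values classify as `NA`.
#' @export
classify_band <- function(value, band) {
  if (length(band) != 2L || !(band[1] < band[2]))
    stop_relaxo("bad-parameter", "band must be c(low, high) with low < high")
  value >= band[1] & value <= band[2]
}

#' Two-sample pooled-variance (equal-variance, unpaired) t-test
#'
#' Student's two-sample t-test under the equal-variance assumption:
#' t = (mean1 - mean2) / (sp * sqrt(1/n1 + 1/n2)) with the pooled standard
#' deviation sp on n1 + n2 - 2 degrees of freedom, two-sided p-value. When
#' the pooled variance is zero and the means are equal, t is defined as 0
#' (p = 1).
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @return a `group_comparison`: list with `n1`, `n2`, `mean1`, `mean2`,
#'   `pooled_sd`, `t_statistic`, `degrees_of_freedom`, `p_value`.
#' @export
pooled_t_test <- function(group1, group2) {
  group1 <- group1[is.finite(group1)]
  group2 <- group2[is.finite(group2)]
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L)
    stop_relaxo("bad-parameter", "each group needs >= 2 finite values (got ",
                n1, " and ", n2, ")")
  m1 <- mean(group1); m2 <- mean(group2)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / df
  sp <- sqrt(sp2)
  se <- sp * sqrt(1 / n1 + 1 / n2)
  if (se == 0) {
    tstat <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    tstat <- (m1 - m2) / se
  }
  p <- 2 * pt(-abs(tstat), df = df)
  structure(list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2, pooled_sd = sp,
                 t_statistic = tstat, degrees_of_freedom = df, p_value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> n = %d vs %d, means %.4g vs %.4g, t(%d) = %.3f, p = %.4g\n",
    x$n1, x$n2, x$mean1, x$mean2, x$degrees_of_freedom, x$t_statistic,
    x$p_value))
  invisible(x)
}

#' Measure biopsy samples against co-registered maps
#'
#' For every biopsy record, computes the tumor cell density from its field
#' counts and the VOI-averaged value of each supplied map at its world
#' coordinate, then flags band membership per quantity. Samples whose VOI
#' falls outside a map yield `NA` for that map and are flagged.
#'
#' @param biopsies a `biopsy_table` (see [parse_biopsy_table()]).
#' @param maps named list of `voxel_volume`s (e.g. `list(T1 = ..., T2 = ...)`).
#' @param bands named list of length-2 bands, names a subset of `names(maps)`.
#' @param voi_volume_cm3,shape passed to [voi_mean()].
#' @param field_area_mm2 passed to [tcd_from_counts()].
#' @return data.frame with one row per sample: `patient_id`, `tcd`,
#'   one `mean_<quantity>` column per map, one `in_band_<quantity>` per band,
#'   and `voi_ok` (FALSE when every map was unmeasurable there).
#' @export
measure_biopsies <- function(biopsies, maps, bands = list(),
                             voi_volume_cm3 = 1.0, shape = "cube",
                             field_area_mm2 = 0.0497) {
  stopifnot(is.list(maps), length(maps) >= 1L, !is.null(names(maps)))
  n <- nrow(biopsies)
  out <- data.frame(patient_id = biopsies$patient_id,
                    tcd = vapply(biopsies$field_counts, tcd_from_counts,
                                 numeric(1), field_area_mm2 = field_area_mm2),
                    enhancing = biopsies$enhancing,
                    stringsAsFactors = FALSE)
  for (q in names(maps)) {
    means <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      ctr <- c(biopsies$x[i], biopsies$y[i], biopsies$z[i])
      res <- tryCatch(
        voi_mean(maps[[q]], ctr, voi_volume_cm3 = voi_volume_cm3,
                 shape = shape),
        relaxo_voi_outside = function(e) NULL)
      if (!is.null(res)) means[i] <- res$mean
    }
    out[[paste0("mean_", q)]] <- means
  }
  for (q in names(bands)) {
    if (!q %in% names(maps))
      stop_relaxo("bad-parameter", "band given for unknown quantity ", q)
    out[[paste0("in_band_", q)]] <- classify_band(out[[paste0("mean_", q)]],
                                                  bands[[q]])
  }
  mean_cols <- paste0("mean_", names(maps))
  out$voi_ok <- rowSums(!is.na(as.matrix(out[, mean_cols, drop = FALSE]))) > 0
  out
}

#' Compare tumor cell density inside vs outside a band
#'
#' Splits measured biopsy samples by band membership for one quantity and
#' runs the pooled-variance t-test on their TCDs.
#'
#' @param measurements output of [measure_biopsies()] containing the
#'   `in_band_<quantity>` column.
#' @param quantity quantity name (e.g. `"T1"`).
#' @return a `group_comparison` (in-band group first), or `NULL` with a
#'   warning when either group has fewer than 2 usable samples.
#' @export
compare_tcd_by_band <- function(measurements, quantity) {
  col <- paste0("in_band_", quantity)
  if (!col %in% names(measurements))
    stop_relaxo("bad-parameter", "no band column for quantity ", quantity)
  flag <- measurements[[col]]
  ok <- !is.na(flag) & is.finite(measurements$tcd)
  g_in <- measurements$tcd[ok & flag]
  g_out <- measurements$tcd[ok & !flag]
  if (length(g_in) < 2L || length(g_out) < 2L) {
    warning("fewer than 2 samples in a band group for ", quantity,
            "; comparison skipped")
    return(NULL)
  }
  pooled_t_test(g_in, g_out)
}
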