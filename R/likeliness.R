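#' Paired class histograms of a scalar map over the analysis mask
#'
#' Bins the map values of the high- and low-uptake voxel classes into shared
#' half-open bins [k*w + origin, (k+1)*w + origin). The bin count B spans the
#' pooled observed range: from the bin containing the pooled minimum through
#' the bin containing the pooled maximum, inclusive of interior empty bins.
#' Non-finite voxels are dropped before binning, with a message reporting how
#' many.
#'
#' Default bin widths by quantity: 100 ms for T1, 5 ms for T2 and
#' 0.0005 mm^2/s for ADC.
#'
#' @param values `voxel_volume` of the scalar quantity being binned.
#' @param partition a [partition_by_tn()] result on the same grid.
#' @param bin_width bin width in the quantity's units (> 0).
#' @param bin_origin left edge of bin 0, same units (default 0).
#' @return a `histogram_pair`: data.frame-backed object with per-bin
#'   `bin_left`, `bin_right`, `n_high`, `n_low`, plus attributes `NH`, `NL`,
#'   `B`, `bin_width`, `bin_origin`, `units`.
#' @export
build_histogram_pair <- function(values, partition, bin_width,
                                 bin_origin = 0) {
  stopifnot(inherits(partition, "tn_partition"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_relaxo("bad-parameter", "bin_width must be > 0")
  check_same_grid(values, partition$high_mask, "values and partition")
  vh <- values$data[partition$high_mask$data]
  vl <- values$data[partition$low_mask$data]
  n_dropped <- sum(!is.finite(vh)) + sum(!is.finite(vl))
  if (n_dropped > 0)
    message("build_histogram_pair: dropped ", n_dropped, " non-finite voxels")
  histogram_pair_from_values(vh[is.finite(vh)], vl[is.finite(vl)],
                             bin_width, bin_origin, values$units)
}

#' Build a paired histogram directly from per-class value vectors
#'
#' Lower-level constructor behind [build_histogram_pair()], used when voxel
#' values from several patients are pooled into one pair of histograms.
#'
#' @param values_high,values_low finite numeric vectors of the quantity for
#'   the two classes; both must be non-empty.
#' @param bin_width,bin_origin as in [build_histogram_pair()].
#' @param units units tag carried into the result.
#' @return a `histogram_pair`.
#' @export
histogram_pair_from_values <- function(values_high, values_low, bin_width,
                                       bin_origin = 0, units = "ms") {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop_relaxo("bad-parameter", "bin_width must be > 0")
  vh <- values_high[is.finite(values_high)]
  vl <- values_low[is.finite(values_low)]
  if (length(vh) == 0L)
    stop_relaxo("empty-class", "no finite voxels in the high-uptake class")
  if (length(vl) == 0L)
    stop_relaxo("empty-class", "no finite voxels in the low-uptake class")
  kh <- floor((vh - bin_origin) / bin_width)
  kl <- floor((vl - bin_origin) / bin_width)
  kmin <- min(kh, kl)
  kmax <- max(kh, kl)
  ks <- kmin:kmax
  tab_h <- tabulate(kh - kmin + 1L, nbins = length(ks))
  tab_l <- tabulate(kl - kmin + 1L, nbins = length(ks))
  out <- data.frame(
    bin_left = ks * bin_width + bin_origin,
    bin_right = (ks + 1) * bin_width + bin_origin,
    n_high = tab_h,
    n_low = tab_l
  )
  structure(out,
            NH = length(vh), NL = length(vl), B = length(ks),
            bin_width = bin_width, bin_origin = bin_origin,
            units = units,
            class = c("histogram_pair", "data.frame"))
}

#' Per-bin likeliness of the high-uptake class
#'
#' For each bin k with per-class proportions pH = n_high/NH and
#' pL = n_low/NL, the likeliness is (pH - pL) / (pH + pL): a normalized
#' contrast in [-1, 1]. Positive values mean a voxel falling in that bin is
#' more characteristic of the high-uptake class; -1 and +1 mark bins occupied
#' by only one class. Bins empty in both classes have no defined likeliness
#' (`NA`) and are excluded outright.
#'
#' @param pair a [build_histogram_pair()] result; both class totals must be
#'   positive.
#' @return a `likeliness_profile`: data.frame with the pair's bin columns
#'   plus `likeliness` and `included`, and the pair's attributes.
#' @export
compute_likeliness <- function(pair) {
  stopifnot(inherits(pair, "histogram_pair"))
  NH <- attr(pair, "NH"); NL <- attr(pair, "NL")
  if (NH <= 0 || NL <= 0)
    stop_relaxo("empty-class", "both classes must have voxels (NH = ", NH,
                ", NL = ", NL, ")")
  ph <- pair$n_high / NH
  pl <- pair$n_low / NL
  tot <- ph + pl
  lik <- ifelse(tot > 0, (ph - pl) / tot, NA_real_)
  out <- data.frame(pair[c("bin_left", "bin_right", "n_high", "n_low")],
                    likeliness = lik, included = tot > 0)
  structure(out,
            NH = NH, NL = NL, B = attr(pair, "B"),
            bin_width = attr(pair, "bin_width"),
            bin_origin = attr(pair, "bin_origin"),
            units = attr(pair, "units"),
            class = c("likeliness_profile", "data.frame"))
}

#' Exclude low-mass bins from a likeliness profile
#'
#' Bins whose summed per-class probability mass pH + pL falls below 5% of the
#' mass expected under uniformity (the two histograms together carry total
#' mass 2, so the expectation per bin is 2/B and the threshold is 0.1/B, with
#' B the number of bins spanning the pooled range) are considered unreliable
#' and dropped: their inclusion flag is cleared and their likeliness removed.
#'
#' @param pair the [build_histogram_pair()] the profile was computed from.
#' @param profile a [compute_likeliness()] result.
#' @return the profile with `included` and `likeliness` updated.
#' @export
apply_exclusion_rule <- function(pair, profile) {
  stopifnot(inherits(pair, "histogram_pair"),
            inherits(profile, "likeliness_profile"))
  B <- attr(pair, "B")
  if (B < 1L) stop_relaxo("bad-parameter", "B must be >= 1")
  ph <- pair$n_high / attr(pair, "NH")
  pl <- pair$n_low / attr(pair, "NL")
  keep <- (ph + pl) >= 0.1 / B
  profile$included <- profile$included & keep
  profile$likeliness[!profile$included] <- NA_real_
  profile
}

#' Extract the positive-likeliness value range
#'
#' Finds the longest contiguous run of included bins with likeliness > 0 and
#' reports it as [left edge of the first bin, right edge of the last]. Ties
#' in run length are broken toward the run with the larger summed per-class
#' probability mass, then toward the lower edge. An empty result (no positive
#' bin) is a zero-length numeric vector.
#'
#' @param profile a `likeliness_profile` after [apply_exclusion_rule()].
#' @return numeric of length 2 (`c(low_edge, high_edge)`), or `numeric(0)`.
#' @export
extract_positive_range <- function(profile) {
  stopifnot(inherits(profile, "likeliness_profile"))
  pos <- profile$included & !is.na(profile$likeliness) & profile$likeliness > 0
  if (!any(pos)) return(numeric(0))
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])
  NH <- attr(profile, "NH"); NL <- attr(profile, "NL")
  runs$mass <- vapply(seq_len(nrow(runs)), function(i) {
    idx <- runs$start[i]:runs$end[i]
    sum(profile$n_high[idx] / NH + profile$n_low[idx] / NL)
  }, numeric(1))
  runs <- runs[order(-runs$len, -runs$mass, runs$start), ]
  best <- runs[1, ]
  c(profile$bin_left[best$start], profile$bin_right[best$end])
}

#' Synthesize a voxelwise tumor-load probability map
#'
#' Looks up each voxel of a scalar map (typically the T1-relaxation map) in
#' the likeliness profile's bins and assigns the two-class equal-prior
#' posterior probability p = (L + 1) / 2, equivalently
#' (pH) / (pH + pL) with the per-class bin proportions. Voxels falling in
#' excluded bins or outside the profile's bin range get probability 0 and are
#' flagged invalid in the accompanying validity mask.
#'
#' @param map `voxel_volume` of the same quantity (same units) the profile
#'   was built on.
#' @param profile a `likeliness_profile` after exclusion.
#' @return list with `probability` (a `voxel_volume`, units `"probability"`)
#'   and `valid` (a `mask_volume`: voxels whose bin was included).
#' @export
synthesize_tumor_load_map <- function(map, profile) {
  stopifnot(inherits(map, "voxel_volume"),
            inherits(profile, "likeliness_profile"))
  if (!identical(map$units, attr(profile, "units")))
    stop_relaxo("units-mismatch", "map units '", map$units,
                "' do not match profile units '", attr(profile, "units"), "'")
  w <- attr(profile, "bin_width")
  origin <- attr(profile, "bin_origin")
  k0 <- round((profile$bin_left[1] - origin) / w)  # first bin index
  k <- floor((map$data - origin) / w) - k0         # 0-based row offset
  idx <- k + 1L
  in_range <- is.finite(map$data) & idx >= 1L & idx <= nrow(profile)
  lik <- rep(NA_real_, length(idx))
  lik[in_range] <- profile$likeliness[idx[in_range]]
  valid <- in_range
  valid[in_range] <- profile$included[idx[in_range]] &
    !is.na(profile$likeliness[idx[in_range]])
  p <- ifelse(valid, (lik + 1) / 2, 0)
  list(
    probability = voxel_volume(array(p, dim = dim(map$data)), map$affine,
                               "probability"),
    valid = mask_volume(array(valid, dim = dim(map$data)), map$affine)
  )
}

#' Write a likeliness profile to CSV
#' @param profile a `likeliness_profile`.
#' @param path output CSV path; columns `bin_left, bin_right, n_high, n_low,
#'   likeliness, included`.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile)
  write.csv(df, path, row.names = FALSE)
  meta <- list(NH = attr(profile, "NH"), NL = attr(profile, "NL"),
               B = attr(profile, "B"), bin_width = attr(profile, "bin_width"),
               bin_origin = attr(profile, "bin_origin"),
               units = attr(profile, "units"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a likeliness profile written by [write_profile()]
#' @param path CSV path.
#' @return a `likeliness_profile`.
#' @export
read_profile <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(df, NH = as.numeric(meta$NH), NL = as.numeric(meta$NL),
            B = as.integer(meta$B),
            bin_width = as.numeric(meta$bin_width),
            bin_origin = as.numeric(meta$bin_origin),
            units = meta$units,
            class = c("likeliness_profile", "data.frame"))
}

#' Plot class histograms and the likeliness curve
#'
#' Frequency histograms of the two classes and the per-bin likeliness as a
#' function of the binned quantity, in the style of the study's correlation
#' figures. Requires ggplot2.
#'
#' @param profile a `likeliness_profile`.
#' @param quantity axis label for the binned quantity.
#' @return a ggplot object (two panels stacked via facets).
#' @export
plot_likeliness_profile <- function(profile, quantity = attr(profile, "units")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_relaxo("missing-dependency", "ggplot2 is required for plotting")
  NH <- attr(profile, "NH"); NL <- attr(profile, "NL")
  mid <- (profile$bin_left + profile$bin_right) / 2
  df <- rbind(
    data.frame(x = mid, y = profile$n_high / NH, panel = "frequency",
               series = "high uptake"),
    data.frame(x = mid, y = profile$n_low / NL, panel = "frequency",
               series = "low uptake"),
    data.frame(x = mid, y = profile$likeliness, panel = "likeliness",
               series = "likeliness")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$series)) +
    ggplot2::geom_step(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = quantity, y = NULL) +
    ggplot2::theme_minimal()
}
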