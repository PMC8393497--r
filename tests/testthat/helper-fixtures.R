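# Small in-code fixtures shared across test files.

# A volume with deterministic values and a simple scaled affine.
tiny_volume <- function(dims = c(6L, 5L, 4L), spacing = c(1, 1, 1),
                        units = "ms", values = NULL) {
  if (is.null(values)) values <- seq_len(prod(dims))
  voxel_volume(array(values, dim = dims), diag(c(spacing, 1)), units)
}

full_mask <- function(volume) {
  mask_volume(array(TRUE, dim = dim(volume$data)), volume$affine)
}

# A histogram pair built directly from counts, for statistic-level tests.
pair_from_counts <- function(n_high, n_low, bin_width = 100, bin_origin = 0,
                             units = "ms") {
  stopifnot(length(n_high) == length(n_low))
  ks <- seq_along(n_high) - 1
  out <- data.frame(bin_left = ks * bin_width + bin_origin,
                    bin_right = (ks + 1) * bin_width + bin_origin,
                    n_high = as.integer(n_high), n_low = as.integer(n_low))
  structure(out, NH = sum(n_high), NL = sum(n_low), B = length(ks),
            bin_width = bin_width, bin_origin = bin_origin, units = units,
            class = c("histogram_pair", "data.frame"))
}

# Exact cross-multiplied evaluation of the likeliness statistic: with
# integer counts, (nH/NH - nL/NL) / (nH/NH + nL/NL) equals
# (nH*NL - nL*NH) / (nH*NL + nL*NH), which doubles add exactly for counts of
# this size. Independent of the implementation's proportion arithmetic.
likeliness_oracle <- function(n_high, n_low, NH, NL) {
  num <- n_high * NL - n_low * NH
  den <- n_high * NL + n_low * NH
  ifelse(den > 0, num / den, NA_real_)
}

# Small synthetic patient for pipeline-level tests; any cohort_spec argument
# can be overridden.
test_spec <- function(...) {
  defaults <- list(n_patients = 2, grid_dims = c(24L, 24L, 10L),
                   grid_spacing = c(0.9, 0.9, 3.3), n_biopsies = 12L,
                   seed = 42)
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

# Mean of a normal(location, scale) truncated below at 0.
tnorm_mean <- function(location, scale) {
  a <- -location / scale
  location + scale * dnorm(a) / (1 - pnorm(a))
}
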