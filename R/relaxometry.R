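#' Field-strength conversion settings for relaxation times
#'
#' Relaxation times depend on field strength; maps acquired at 1.5 T are
#' rescaled to their 3-T equivalents by fixed multiplicative coefficients
#' (defaults 1.19 for T1 and 0.92 for T2, derived from normal-volunteer
#' calibration data). The coefficients are treated as fixed configurable
#' constants.
#'
#' @param t1_coeff multiplier applied to T1 maps (dimensionless, > 0).
#' @param t2_coeff multiplier applied to T2 maps (dimensionless, > 0).
#' @param source_field acquisition field strength in tesla.
#' @param target_field field strength the output is expressed at, in tesla.
#' @return a `field_conversion` object.
#' @export
field_conversion <- function(t1_coeff = 1.19, t2_coeff = 0.92,
                             source_field = 1.5, target_field = 3.0) {
  if (t1_coeff <= 0 || t2_coeff <= 0)
    stop_relaxo("bad-parameter", "conversion coefficients must be > 0")
  structure(list(t1_coeff = t1_coeff, t2_coeff = t2_coeff,
                 source_field = source_field, target_field = target_field),
            class = "field_conversion")
}

#' Convert a relaxation-time map between field strengths
#'
#' Multiplies every voxel by the quantity's coefficient. When the source and
#' target fields are equal the map passes through unchanged; either way the
#' result carries the provenance attribute `converted_to_3T` (more precisely,
#' "expressed at the target field") set to `TRUE`.
#'
#' @param volume a `voxel_volume` with units `"ms"`.
#' @param quantity `"T1"` or `"T2"`.
#' @param conversion a [field_conversion()].
#' @return the converted `voxel_volume` (same affine, units `"ms"`).
#' @export
convert_field_strength <- function(volume, quantity = c("T1", "T2"),
                                   conversion = field_conversion()) {
  quantity <- match.arg(quantity)
  check_units(volume, "ms")
  coeff <- switch(quantity, T1 = conversion$t1_coeff, T2 = conversion$t2_coeff)
  out <- volume
  if (!isTRUE(all.equal(conversion$source_field, conversion$target_field)))
    out$data <- volume$data * coeff
  attr(out, "converted_to_3T") <- TRUE
  out
}

#' Mono-exponential T2 estimate from multi-echo signals
#'
#' Log-linear least-squares fit of the decay S(TE) = S0 * exp(-TE / T2) for
#' one voxel's signal across echoes: a straight-line fit of ln S on TE whose
#' slope is -1/T2. Exact on noiseless data; under Rician (magnitude) noise
#' the log transform introduces a known downward bias at low SNR, which is
#' acceptable for the synthetic round-trip use this estimator serves.
#'
#' @param signals numeric vector of signal intensities, one per echo; all
#'   must be > 0 for the log-linear path.
#' @param echo_times echo times in ms, strictly increasing, length >= 2.
#' @return list with `t2` (ms), `s0`, and `physical` (`FALSE` when the fitted
#'   slope is >= 0, i.e. no decay; `t2` is then `Inf`).
#' @export
fit_t2_monoexponential <- function(signals, echo_times) {
  if (length(echo_times) < 2L)
    stop_relaxo("bad-parameter", "need at least 2 echoes")
  if (any(diff(echo_times) <= 0))
    stop_relaxo("bad-parameter", "echo times must be strictly increasing")
  if (length(signals) != length(echo_times))
    stop_relaxo("shape-mismatch", "signals and echo_times differ in length")
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop_relaxo("bad-parameter", "all signals must be finite and > 0")
  y <- log(signals)
  te <- echo_times
  # closed-form simple linear regression of y on te
  te_c <- te - mean(te)
  slope <- sum(te_c * y) / sum(te_c^2)
  intercept <- mean(y) - slope * mean(te)
  if (slope >= 0)
    return(list(t2 = Inf, s0 = exp(intercept), physical = FALSE))
  list(t2 = -1 / slope, s0 = exp(intercept), physical = TRUE)
}

#' Apparent diffusion coefficient from a b = 0 / b = 1000 signal pair
#'
#' ADC = ln(S_b0 / S_b1000) / b per voxel, with b = 1000 s/mm^2. Voxels where
#' either signal is non-positive cannot support the log and are set to `NA`
#' (masked out).
#'
#' @param b0_volume,b1000_volume `voxel_volume`s of diffusion signals on the
#'   same grid (units `"activity"`, i.e. arbitrary signal).
#' @param b_value diffusion weighting of the second acquisition in s/mm^2.
#' @return a `voxel_volume` with units `"mm2_per_s"`; masked voxels are `NA`.
#' @export
compute_adc <- function(b0_volume, b1000_volume, b_value = 1000) {
  check_same_grid(b0_volume, b1000_volume, "diffusion volumes")
  s0 <- b0_volume$data
  s1 <- b1000_volume$data
  adc <- array(NA_real_, dim = dim(s0))
  ok <- is.finite(s0) & is.finite(s1) & s0 > 0 & s1 > 0
  adc[ok] <- log(s0[ok] / s1[ok]) / b_value
  voxel_volume(adc, b0_volume$affine, "mm2_per_s")
}
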