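# Core complex-spectrum data model and phase algebra.
#
# Conventions used throughout the package:
#   * index 1 (k = 0 internally) is the LEFT end of the displayed spectrum,
#     i.e. the downfield / high-frequency end;
#   * phase factors multiply as e^{+i phi}: applying a PhasePair (PH0, PH1)
#     multiplies point k (0-based) by exp(i * pi/180 * (PH0 + PH1 * k/(N-1))),
#     so the left endpoint receives exactly PH0 and the right endpoint exactly
#     PH0 + PH1.  "Correcting" a phase error phi therefore means applying -phi.
#     A single constant, .phase_sign, controls the convention.

.phase_sign <- +1

#' Wrap an angle in degrees to (-180, 180]
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Construct a 1D complex NMR spectrum
#'
#' A `spectrum1d` holds the complex frequency-domain points of a 1D spectrum
#' together with optional axis metadata.  Index 1 is the left (downfield,
#' high-frequency) end of the displayed spectrum.
#'
#' @param points Complex (or numeric, taken as pure real) vector, length >= 2.
#' @param spectral_width Spectral width in Hz (optional, must be > 0 if set).
#' @param observe_freq Spectrometer observe frequency in MHz (optional).
#' @param ref_ppm Chemical shift (ppm) of the first (leftmost) point (optional).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(points, spectral_width = NULL, observe_freq = NULL,
                       ref_ppm = NULL) {
  points <- as.complex(points)
  if (length(points) < 2) stop("spectrum1d: need at least 2 points")
  if (any(!is.finite(Re(points))) || any(!is.finite(Im(points))))
    stop("spectrum1d: all points must be finite")
  if (!is.null(spectral_width)) {
    stopifnot(is.finite(spectral_width), spectral_width > 0)
  }
  structure(
    list(points = points, spectral_width = spectral_width,
         observe_freq = observe_freq, ref_ppm = ref_ppm),
    class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d: %d complex points%s>\n", length(x$points),
              if (!is.null(x$spectral_width))
                sprintf(", sw = %g Hz", x$spectral_width) else ""))
  invisible(x)
}

#' @export
length.spectrum1d <- function(x) length(x$points)

#' Construct a (PH0, PH1) phase pair
#'
#' PH0 is the zeroth-order (frequency-independent) phase; PH1 is the
#' first-order phase quoted as the *total* phase change across the full
#' spectral width, so the left end of the spectrum receives PH0 and the right
#' end PH0 + PH1.  PH0 is displayed wrapped to (-180, 180]; the stored value
#' is kept unwrapped so that phase arithmetic is exact.
#'
#' @param ph0 Zeroth-order phase in degrees.
#' @param ph1 First-order phase (total change across the spectrum) in degrees.
#' @return An object of class `phase_pair`.
#' @export
phase_pair <- function(ph0 = 0, ph1 = 0) {
  if (!is.finite(ph0) || !is.finite(ph1))
    stop("phase_pair: ph0 and ph1 must be finite")
  structure(list(ph0 = as.numeric(ph0), ph1 = as.numeric(ph1)),
            class = "phase_pair")
}

#' @export
print.phase_pair <- function(x, ...) {
  cat(sprintf("<phase_pair: PH0 = %.4g deg (wrapped %.4g), PH1 = %.4g deg>\n",
              x$ph0, wrap_deg(x$ph0), x$ph1))
  invisible(x)
}

#' Add two phase pairs componentwise
#' @param p1,p2 `phase_pair` objects.
#' @return Their componentwise sum as a `phase_pair`.
#' @export
phase_add <- function(p1, p2) phase_pair(p1$ph0 + p2$ph0, p1$ph1 + p2$ph1)

#' Negate a phase pair
#' @param p A `phase_pair`.
#' @return The componentwise negation.
#' @export
phase_neg <- function(p) phase_pair(-p$ph0, -p$ph1)

#' Construct a time-domain FID record
#'
#' @param samples Complex time-domain samples (length >= 2).
#' @param dwell_time Dwell time in seconds (> 0).
#' @param group_delay Digital-filter group delay in points (>= 0).  The
#'   spectrometer's digital filter delays the FID by this many dwell periods,
#'   which manifests as a large linear phase ramp in the spectrum; it is
#'   compensated by [group_delay_correct()] during processing, which removes
#'   any first-order error in excess of 360 degrees.
#' @return An object of class `fid_record`.
#' @export
fid_record <- function(samples, dwell_time, group_delay = 0) {
  samples <- as.complex(samples)
  if (length(samples) < 2) stop("fid_record: need at least 2 samples")
  if (!is.finite(dwell_time) || dwell_time <= 0)
    stop("fid_record: dwell_time must be > 0")
  if (!is.finite(group_delay) || group_delay < 0)
    stop("fid_record: group_delay must be >= 0")
  structure(list(samples = samples, dwell_time = dwell_time,
                 group_delay = group_delay),
            class = "fid_record")
}

#' FID processing parameters
#'
#' @param apod_line_broadening Exponential apodization line broadening in Hz
#'   (>= 0).  The FID is multiplied by exp(-pi * lb * t).
#' @param zero_fill_target Number of complex points after zero filling; must
#'   be a power of two at least as large as the FID (powers of two keep the
#'   FFT fast and match the spectrum lengths used for training data).  `NULL`
#'   selects the next power of two >= the FID length.
#' @return An object of class `processing_params`.
#' @export
processing_params <- function(apod_line_broadening = 0.3,
                              zero_fill_target = NULL) {
  stopifnot(is.finite(apod_line_broadening), apod_line_broadening >= 0)
  if (!is.null(zero_fill_target)) {
    zf <- as.integer(zero_fill_target)
    if (zf < 2 || bitwAnd(zf, zf - 1L) != 0L)
      stop("processing_params: zero_fill_target must be a power of two >= 2")
  }
  structure(list(apod_line_broadening = apod_line_broadening,
                 zero_fill_target = zero_fill_target),
            class = "processing_params")
}

next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

#' Apply a zeroth- and first-order phase correction to a spectrum
#'
#' Multiplies spectral point k (0-based, k = 0 is the left end) by
#' `exp(i * pi/180 * (PH0 + PH1 * k/(N-1)))`.  The left endpoint receives
#' exactly PH0 and the right endpoint exactly PH0 + PH1; the magnitude
#' spectrum is unchanged at every point.
#'
#' @param spec A [spectrum1d()].
#' @param phase A [phase_pair()] (degrees).
#' @return The phased `spectrum1d` (same length, same metadata).
#' @export
apply_phase <- function(spec, phase) {
  stopifnot(inherits(spec, "spectrum1d"))
  if (!inherits(phase, "phase_pair")) stop("apply_phase: phase must be a phase_pair")
  n <- length(spec$points)
  phi <- phase_ramp_deg(phase$ph0, phase$ph1, n) * (pi / 180) * .phase_sign
  out <- spec
  out$points <- spec$points * complex(real = cos(phi), imaginary = sin(phi))
  out
}

# Degrees of phase at each point k = 0..n-1 for a (ph0, ph1) pair.
phase_ramp_deg <- function(ph0, ph1, n) {
  ph0 + ph1 * (seq_len(n) - 1) / (n - 1)
}

#' Convert left/right endpoint phases to a (PH0, PH1) pair
#'
#' The endpoint parametrization describes a linear phase error by the phase at
#' the left and right ends of the spectrum; it maps to `PH0 = phase_left`,
#' `PH1 = phase_right - phase_left` and round-trips exactly with
#' [phasepair_to_endpoints()].
#'
#' @param phase_left Phase at the left (downfield) end, degrees.
#' @param phase_right Phase at the right end, degrees.
#' @return A [phase_pair()].
#' @export
endpoint_to_phasepair <- function(phase_left, phase_right) {
  if (!is.finite(phase_left) || !is.finite(phase_right))
    stop("endpoint_to_phasepair: inputs must be finite")
  phase_pair(ph0 = phase_left, ph1 = phase_right - phase_left)
}

#' Convert a (PH0, PH1) pair to left/right endpoint phases
#'
#' @param phase A [phase_pair()].
#' @return Numeric vector `c(left, right)` in degrees.
#' @export
phasepair_to_endpoints <- function(phase) {
  stopifnot(inherits(phase, "phase_pair"))
  c(left = phase$ph0, right = phase$ph0 + phase$ph1)
}

#' Compensate the digital-filter group delay of a spectrum
#'
#' The spectrometer's digital filter delays the FID by `group_delay` dwell
#' periods, which appears as a first-order phase ramp of about
#' 360 degrees per delay point across the spectrum.  This applies the standard
#' compensation, a first-order phase of `-360 * group_delay` degrees across
#' the full width; any small residual constant phase is absorbed by the
#' subsequent PH0 correction.
#'
#' @param spec A [spectrum1d()].
#' @param group_delay Group delay in points (>= 0; fractional values allowed).
#' @return The corrected `spectrum1d`.
#' @export
group_delay_correct <- function(spec, group_delay) {
  if (!is.finite(group_delay)) stop("group_delay_correct: group_delay must be finite")
  if (group_delay < 0) stop("group_delay_correct: group_delay must be >= 0")
  if (group_delay == 0) return(spec)
  apply_phase(spec, phase_pair(ph0 = 0, ph1 = -360 * group_delay))
}

#' Process a time-domain FID into a frequency-domain spectrum
#'
#' Standard 1D processing: exponential apodization, first-point halving (to
#' suppress the constant baseline offset of a truncated FID), zero filling to
#' a power of two, complex FFT with the output ordered so that index 1 is the
#' left (high-frequency) end, and digital-filter group-delay compensation.
#'
#' @param fid A [fid_record()].
#' @param params A [processing_params()].
#' @return A [spectrum1d()] with `spectral_width = 1/dwell_time`.
#' @export
process_fid <- function(fid, params = processing_params()) {
  stopifnot(inherits(fid, "fid_record"), inherits(params, "processing_params"))
  n_in <- length(fid$samples)
  zf <- if (is.null(params$zero_fill_target)) next_pow2(n_in)
        else as.integer(params$zero_fill_target)
  if (zf < n_in)
    stop(sprintf("process_fid: zero_fill_target (%d) < FID length (%d)", zf, n_in))
  t <- (seq_len(n_in) - 1) * fid$dwell_time
  s <- fid$samples * exp(-pi * params$apod_line_broadening * t)
  s[1] <- 0.5 * s[1]
  s <- c(s, complex(zf - n_in))
  x <- stats::fft(s)
  # fftshift then reverse: index 1 = highest (downfield) frequency
  pts <- rev(x[c((zf / 2 + 1):zf, 1:(zf / 2))])
  spec <- spectrum1d(pts, spectral_width = 1 / fid$dwell_time)
  group_delay_correct(spec, fid$group_delay)
}
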