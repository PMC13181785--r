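# Synthetic training-spectrum engine.
#
# Labeled spectra are generated from Voigt peak lists by time-domain
# synthesis (so absorption and dispersion parts are mutually consistent),
# augmented by segment shuffling / removal / displacement / axis inversion /
# shoulder peaks, decorated with a smooth Hermite baseline and Gaussian
# noise, and finally given a controlled PH0/PH1 phase error whose sign is
# the training label.
#
# All randomness flows from a single master seed through per-sample derived
# substreams, so dataset manifests are bit-reproducible.

# -- reproducible substreams -------------------------------------------------

#' Derive a reproducible sub-seed from a master seed
#'
#' Mixes a master seed with any number of integer indices into a new 31-bit
#' seed, so that every sample, augmentation and stage draws from its own
#' named substream of a single master seed.
#'
#' @param master Master seed (integer).
#' @param ... Integer indices identifying the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- master %% 2147483647
  for (v in idx) s <- (s * 16807 + (v %% 65536) * 2654435761 + v) %% 2147483647
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# -- peak lists --------------------------------------------------------------

#' Construct a Voigt peak list
#'
#' A peak list is a data frame with one row per resonance.  Positions are in
#' data points on a nominal axis of `axis_n` points; when a spectrum of a
#' different length is synthesized the positions are rescaled proportionally
#' while widths (FWHH, in data points) are kept as given.
#'
#' @param position Peak positions in points, in `[0, axis_n)` (fractional allowed).
#' @param fwhh Full widths at half height in points (> 0).
#' @param height Peak amplitudes (> 0).
#' @param gauss_fraction Gaussian fraction of the Voigt shape, in `[0, 1]`
#'   (0 = pure Lorentzian, 1 = pure Gaussian).
#' @param axis_n Nominal axis length in points the positions refer to.
#' @return A data frame of class `peak_list` with attribute `axis_n`.
#' @export
peak_list <- function(position, fwhh, height, gauss_fraction = 0,
                      axis_n = 131072) {
  n <- length(position)
  stopifnot(length(fwhh) %in% c(1, n), length(height) %in% c(1, n))
  if (n > 0) {
    stopifnot(all(fwhh > 0), all(height > 0),
              all(gauss_fraction >= 0 & gauss_fraction <= 1))
  }
  df <- data.frame(position = as.numeric(position),
                   fwhh = rep_len(as.numeric(fwhh), n),
                   height = rep_len(as.numeric(height), n),
                   gauss_fraction = rep_len(as.numeric(gauss_fraction), n))
  structure(df, axis_n = as.numeric(axis_n),
            class = c("peak_list", "data.frame"))
}

# Display position p on the nominal axis -> oscillation frequency in
# cycles/sample for an n-point spectrum (index 1 = highest frequency).
.pos_to_freq <- function(p, n) (n / 2 - 1 - p) / n

#' Synthesize a complex spectrum from a peak list
#'
#' Each peak contributes a damped complex oscillation to a simulated FID
#' (exponential damping for the Lorentzian component, Gaussian damping for the
#' Gaussian component, amplitudes normalized so the absorption-mode maximum of
#' an isolated on-grid peak equals its `height`); the FID is Fourier
#' transformed with first-point halving, giving a spectrum whose real part is
#' the sum of absorption-mode Voigt profiles and whose imaginary part is the
#' matching dispersion.
#'
#' @param peaks A [peak_list()].
#' @param n_points Number of complex points of the output spectrum.
#' @return A [spectrum1d()] of length `n_points` (all zero for an empty list).
#' @export
synthesize_spectrum <- function(peaks, n_points) {
  stopifnot(inherits(peaks, "peak_list"), n_points >= 4)
  n <- as.integer(n_points)
  fid <- complex(n)
  if (nrow(peaks) > 0) {
    axis_n <- attr(peaks, "axis_n")
    pos <- peaks$position * n / axis_n
    bad <- pos < 0 | pos >= n
    if (any(bad)) {
      warning(sprintf("synthesize_spectrum: %d peak position(s) outside axis; clipped",
                      sum(bad)))
      pos <- pmin(pmax(pos, 0), n - 1e-9)
    }
    g <- peaks$gauss_fraction
    aL <- (1 - g) * pi * peaks$fwhh / n
    aG <- g * pi * peaks$fwhh / (2 * sqrt(log(2)) * n)
    amp <- peaks$height / synth_damp_sum_cpp(aL, aG, n)
    fid <- synth_fid_cpp(.pos_to_freq(pos, n), aL, aG, amp, n)
  }
  fid[1] <- 0.5 * fid[1]
  x <- stats::fft(fid)
  spectrum1d(rev(x[c((n / 2 + 1):n, 1:(n / 2))]))
}

# -- generator configuration -------------------------------------------------

#' Synthetic-data generator configuration
#'
#' Defaults reproduce the training-data design used throughout the package:
#' three power-of-two spectrum lengths, fine-task PH0 errors of 0.5-5 degrees
#' and PH1 errors of 1-10 degrees (coarser 5-10 / 5-20 degree ranges for the
#' pretraining stage), peak widths of 3-30 points, local displacements up to
#' 2000 points, broad background peaks (FWHH up to `broad_fwhh_max`) in about
#' 30% of samples, a smooth baseline with five extrema and a maximum
#' amplitude of 0.6% of the tallest peak, and Gaussian noise.
#'
#' @param n_points_choices Spectrum lengths to synthesize at.
#' @param ph0_abs_range,ph1_abs_range Fine-task absolute phase-error ranges (degrees).
#' @param pretrain_ph0_range,pretrain_ph1_range Pretraining-stage ranges (degrees).
#' @param width_range Peak FWHH range in points for augmentation resampling.
#' @param max_displacement Maximum local peak displacement in points (nominal axis).
#' @param broad_peak_prob Probability a sample includes broad background peaks.
#' @param broad_fwhh_max Maximum FWHH of broad background peaks, points.
#' @param baseline_extrema Number of interior extrema of the synthetic baseline.
#' @param baseline_max_frac Maximum baseline amplitude as a fraction of the
#'   tallest spectral peak.
#' @param noise_sigma_range Per-sample noise standard deviation, drawn
#'   log-uniformly from this range, as a fraction of the tallest peak.
#' @param invert_prob Probability of mirroring the frequency axis.
#' @param shoulder_prob Per-peak probability of adding an overlapping shoulder.
#' @param n_augment_per_list Augmented lists generated per base list.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_points_choices = c(131072L, 65536L, 32768L),
                         ph0_abs_range = c(0.5, 5.0),
                         ph1_abs_range = c(1, 10),
                         pretrain_ph0_range = c(5, 10),
                         pretrain_ph1_range = c(5, 20),
                         width_range = c(3, 30),
                         max_displacement = 2000,
                         broad_peak_prob = 0.30,
                         broad_fwhh_max = 500,
                         baseline_extrema = 5,
                         baseline_max_frac = 0.006,
                         noise_sigma_range = c(1e-4, 5e-3),
                         invert_prob = 0.5,
                         shoulder_prob = 0.15,
                         n_augment_per_list = 1000) {
  cfg <- list(n_points_choices = as.integer(n_points_choices),
              ph0_abs_range = ph0_abs_range, ph1_abs_range = ph1_abs_range,
              pretrain_ph0_range = pretrain_ph0_range,
              pretrain_ph1_range = pretrain_ph1_range,
              width_range = width_range, max_displacement = max_displacement,
              broad_peak_prob = broad_peak_prob, broad_fwhh_max = broad_fwhh_max,
              baseline_extrema = baseline_extrema,
              baseline_max_frac = baseline_max_frac,
              noise_sigma_range = noise_sigma_range,
              invert_prob = invert_prob, shoulder_prob = shoulder_prob,
              n_augment_per_list = n_augment_per_list)
  for (nm in c("ph0_abs_range", "ph1_abs_range", "pretrain_ph0_range",
               "pretrain_ph1_range", "width_range", "noise_sigma_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("synth_config: ", nm, " must be ordered low <= high")
  }
  for (nm in c("broad_peak_prob", "invert_prob", "shoulder_prob")) {
    p <- cfg[[nm]]
    if (p < 0 || p > 1) stop("synth_config: ", nm, " must be in [0, 1]")
  }
  structure(cfg, class = "synth_config")
}

# -- augmentation ------------------------------------------------------------

#' Augment a peak list
#'
#' Builds a new list from a base list by (i) partitioning the nominal axis
#' into 8 equal segments and shuffling segment contents, (ii) removing a
#' random subset of peaks (fraction uniform in \\[0, 0.3\\]), (iii) displacing
#' survivors by up to `cfg$max_displacement` points, (iv) resampling widths
#' within `cfg$width_range` and heights log-uniformly over two orders of
#' magnitude, (v) mirroring all positions about the axis center with
#' probability `cfg$invert_prob`, and (vi) adding a partially overlapping
#' shoulder peak (offset < 1 FWHH, height 20-80% of the parent) per peak with
#' probability `cfg$shoulder_prob`.
#'
#' @param base A non-empty [peak_list()].
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this augmentation draw.
#' @param shuffle_segments,removal Logical switches for steps (i) and (ii)
#'   (disabling them gives a no-op configuration useful for testing).
#' @return A new [peak_list()] on the same nominal axis.
#' @export
augment_peaklist <- function(base, cfg = synth_config(), seed = 1,
                             shuffle_segments = TRUE, removal = TRUE) {
  stopifnot(inherits(base, "peak_list"), nrow(base) > 0)
  axis_n <- attr(base, "axis_n")
  with_seed(seed, {
    pos <- base$position
    fw <- base$fwhh
    ht <- base$height
    gf <- base$gauss_fraction

    if (shuffle_segments) {
      nseg <- 8L
      seg_len <- axis_n / nseg
      seg <- pmin(floor(pos / seg_len), nseg - 1)
      perm <- sample.int(nseg) - 1L
      pos <- pos + (perm[seg + 1] - seg) * seg_len
    }
    if (removal) {
      frac <- stats::runif(1, 0, 0.3)
      keep <- stats::runif(length(pos)) >= frac
      if (!any(keep)) keep[1] <- TRUE
      pos <- pos[keep]; fw <- fw[keep]; ht <- ht[keep]; gf <- gf[keep]
    }
    if (cfg$max_displacement > 0) {
      pos <- pos + stats::runif(length(pos), -cfg$max_displacement,
                                cfg$max_displacement)
    }
    fw <- stats::runif(length(pos), cfg$width_range[1], cfg$width_range[2])
    ht <- 10^stats::runif(length(pos), -2, 0)
    if (stats::runif(1) < cfg$invert_prob) pos <- (axis_n - 1) - pos
    pos <- pmin(pmax(pos, 0), axis_n - 1)

    if (cfg$shoulder_prob > 0) {
      sh <- stats::runif(length(pos)) < cfg$shoulder_prob
      if (any(sh)) {
        off <- stats::runif(sum(sh), 0.2, 0.8) * fw[sh] *
          sign(stats::runif(sum(sh)) - 0.5)
        pos <- c(pos, pmin(pmax(pos[sh] + off, 0), axis_n - 1))
        fw <- c(fw, fw[sh])
        ht <- c(ht, ht[sh] * stats::runif(sum(sh), 0.2, 0.8))
        gf <- c(gf, gf[sh])
      }
    }
    peak_list(pos, fw, ht, gf, axis_n = axis_n)
  })
}

# -- baseline and noise ------------------------------------------------------

#' Smooth synthetic baseline with a fixed number of extrema
#'
#' Places `n_extrema` interior control points with alternating-sign values at
#' jittered positions along the axis, frames them with small opposite-sign
#' endpoint values, and interpolates with a shape-preserving (monotone
#' Fritsch-Carlson) piecewise cubic Hermite scheme, so the interior control
#' points are exactly the local extrema.  The curve is rescaled so its
#' maximum absolute amplitude equals `max_amp` exactly.
#'
#' @param n_points Length of the baseline.
#' @param n_extrema Number of interior local extrema (>= 1).
#' @param max_amp Maximum absolute amplitude (>= 0; 0 gives a zero baseline).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_points`.
#' @export
hermite_baseline <- function(n_points, n_extrema = 5, max_amp = 1, seed = 1) {
  stopifnot(n_extrema >= 1, max_amp >= 0)
  if (n_points < 4 * (n_extrema + 2))
    stop("hermite_baseline: n_points too small for requested n_extrema")
  if (max_amp == 0) return(numeric(n_points))
  with_seed(seed, {
    # one control point per equal-width interior cell, jittered
    cell <- (n_points - 1) / (n_extrema + 1)
    xi <- cell * (seq_len(n_extrema) + stats::runif(n_extrema, -0.35, 0.35))
    x <- c(0, sort(xi), n_points - 1)
    s0 <- sample(c(-1, 1), 1)
    vi <- s0 * (-1)^(seq_len(n_extrema) - 1) * stats::runif(n_extrema, 0.3, 1)
    v <- c(-sign(vi[1]) * stats::runif(1, 0.05, 0.25),
           vi,
           -sign(vi[n_extrema]) * stats::runif(1, 0.05, 0.25))
    f <- stats::splinefun(x, v, method = "monoH.FC")
    b <- f(0:(n_points - 1))
    b * (max_amp / max(abs(b)))
  })
}

#' Add complex Gaussian noise to a spectrum
#'
#' Independent Gaussian noise of standard deviation `sigma` is added to the
#' real and imaginary channels.
#'
#' @param spec A [spectrum1d()].
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return The noisy `spectrum1d`.
#' @export
add_noise <- function(spec, sigma, seed = 1) {
  stopifnot(inherits(spec, "spectrum1d"), sigma >= 0)
  if (sigma == 0) return(spec)
  n <- length(spec$points)
  with_seed(seed, {
    spec$points <- spec$points +
      complex(real = stats::rnorm(n, 0, sigma),
              imaginary = stats::rnorm(n, 0, sigma))
  })
  spec
}

# -- labeled samples ---------------------------------------------------------

# Draw the per-sample stochastic plan (broad-peak inclusion, injected phases,
# noise level) from the sample's substream.  Used both when materializing a
# spectrum and when building a manifest without spectra, so the two agree.
draw_sample_params <- function(task, category, cfg, pretrain) {
  if (!task %in% c("ph0", "ph1")) stop("task must be 'ph0' or 'ph1'")
  if (!category %in% c("negative", "zero", "positive"))
    stop("category must be 'negative', 'zero' or 'positive'")
  has_broad <- stats::runif(1) < cfg$broad_peak_prob
  n_broad <- sample(1:3, 1)
  broad_fwhh <- stats::runif(n_broad, 100, cfg$broad_fwhh_max)
  broad_rel_pos <- stats::runif(n_broad, 0.1, 0.9)
  broad_rel_ht <- stats::runif(n_broad, 0.02, 0.15)
  sgn <- switch(category, negative = -1, zero = 0, positive = +1)
  r0 <- if (pretrain) cfg$pretrain_ph0_range else cfg$ph0_abs_range
  r1 <- if (pretrain) cfg$pretrain_ph1_range else cfg$ph1_abs_range
  if (task == "ph0") {
    ph0 <- sgn * stats::runif(1, r0[1], r0[2])
    ph1 <- 0
  } else {
    mag <- stats::runif(1, r1[1], r1[2])
    ph1 <- sgn * mag
    # accompanying PH0 of equal magnitude, independent random sign
    ph0 <- if (sgn == 0) 0 else sample(c(-1, 1), 1) * mag
  }
  noise_frac <- if (cfg$noise_sigma_range[2] <= 0) 0 else {
    lsr <- log(cfg$noise_sigma_range)
    exp(stats::runif(1, lsr[1], lsr[2]))
  }
  list(has_broad = has_broad, n_broad = n_broad, broad_fwhh = broad_fwhh,
       broad_rel_pos = broad_rel_pos, broad_rel_ht = broad_rel_ht,
       ph0 = ph0, ph1 = ph1, noise_frac = noise_frac)
}

#' Generate one labeled training sample
#'
#' Synthesizes a spectrum from the peak list (optionally adding broad
#' background peaks), adds the Hermite baseline and Gaussian noise, and
#' injects a phase error determined by `task` and `category`:
#' for `task = "ph0"` a PH0 of magnitude uniform in the configured range with
#' the category's sign (PH1 = 0); for `task = "ph1"` a PH1 of magnitude
#' uniform in its range with the category's sign, accompanied by a PH0 of
#' equal magnitude and independent random sign.  The `zero` category has no
#' phase error.  `pretrain = TRUE` switches to the coarser pretraining ranges.
#'
#' @param peaks A [peak_list()].
#' @param n_points Spectrum length.
#' @param task `"ph0"` or `"ph1"`.
#' @param category `"negative"`, `"zero"` or `"positive"`.
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this sample's substream.
#' @param pretrain Use the pretraining phase-error ranges.
#' @return A list of class `training_sample` with fields `spectrum`, `label`,
#'   `true_phase`, `task` and `provenance` (seed, broad-peak flag, tallest
#'   clean-peak height, maximum baseline amplitude, noise sigma).
#' @export
make_sample <- function(peaks, n_points, task, category,
                        cfg = synth_config(), seed = 1, pretrain = FALSE) {
  stopifnot(inherits(peaks, "peak_list"))
  par <- with_seed(seed, draw_sample_params(task, category, cfg, pretrain))
  axis_n <- attr(peaks, "axis_n")
  plist <- peaks
  tallest_ref <- if (nrow(peaks) > 0) max(peaks$height) else 1
  if (par$has_broad) {
    plist <- peak_list(
      c(peaks$position, par$broad_rel_pos * (axis_n - 1)),
      c(peaks$fwhh, par$broad_fwhh),
      c(peaks$height, par$broad_rel_ht * tallest_ref),
      c(peaks$gauss_fraction, rep(0.5, par$n_broad)),
      axis_n = axis_n)
  }
  spec <- synthesize_spectrum(plist, n_points)
  tallest <- max(Re(spec$points))
  if (tallest <= 0) tallest <- max(abs(spec$points), 1e-12)
  base <- hermite_baseline(n_points, cfg$baseline_extrema,
                           cfg$baseline_max_frac * tallest,
                           seed = derive_seed(seed, 101))
  phase <- phase_pair(par$ph0, par$ph1)
  spec <- apply_phase(spec, phase)
  spec$points <- spec$points + base
  sigma <- par$noise_frac * tallest
  spec <- add_noise(spec, sigma, seed = derive_seed(seed, 202))
  structure(
    list(spectrum = spec, label = category, true_phase = phase, task = task,
         provenance = list(seed = seed, n_points = n_points,
                           has_broad = par$has_broad,
                           tallest_peak = tallest,
                           baseline_max = max(abs(base)),
                           noise_sigma = sigma,
                           pretrain = pretrain)),
    class = "training_sample")
}

#' Build a labeled synthetic dataset
#'
#' For each base peak list, `cfg$n_augment_per_list` augmented lists are
#' generated; each augmented list is synthesized at every length in
#' `cfg$n_points_choices` and in all three phase categories, giving
#' `n_bases * n_augment * n_lengths * 3` samples with exactly balanced
#' classes.  The manifest records per-sample provenance and is byte-identical
#' across runs with the same configuration and master seed.
#'
#' @param bases List of base [peak_list()]s.
#' @param cfg A [synth_config()].
#' @param task `"ph0"` or `"ph1"`.
#' @param seed Master seed.
#' @param pretrain Use pretraining phase-error ranges.
#' @param materialize If `FALSE`, only the manifest is built (the per-sample
#'   substreams are drawn identically, so recorded labels, phases and
#'   broad-peak flags match a materialized run).
#' @return A list with `manifest` (data frame: id, base, augment, n_points,
#'   task, label, ph0, ph1, has_broad, seed) and `samples` (list of
#'   `training_sample`, or `NULL` if not materialized).
#' @export
build_dataset <- function(bases, cfg = synth_config(), task = "ph0", seed = 1,
                          pretrain = FALSE, materialize = TRUE) {
  stopifnot(is.list(bases), length(bases) >= 1)
  categories <- c("negative", "zero", "positive")
  rows <- list()
  samples <- if (materialize) list() else NULL
  id <- 0L
  for (b in seq_along(bases)) {
    for (a in seq_len(cfg$n_augment_per_list)) {
      aug <- augment_peaklist(bases[[b]], cfg, seed = derive_seed(seed, b, a))
      for (np in cfg$n_points_choices) {
        for (ci in seq_along(categories)) {
          id <- id + 1L
          s_seed <- derive_seed(seed, b, a, np, ci)
          if (materialize) {
            smp <- make_sample(aug, np, task, categories[ci], cfg,
                               seed = s_seed, pretrain = pretrain)
            samples[[id]] <- smp
            par <- list(ph0 = smp$true_phase$ph0, ph1 = smp$true_phase$ph1,
                        has_broad = smp$provenance$has_broad)
          } else {
            par <- with_seed(s_seed,
                             draw_sample_params(task, categories[ci], cfg, pretrain))
          }
          rows[[id]] <- data.frame(
            id = id, base = b, augment = a, n_points = np, task = task,
            label = categories[ci], ph0 = par$ph0, ph1 = par$ph1,
            has_broad = par$has_broad, seed = s_seed)
        }
      }
    }
  }
  list(manifest = do.call(rbind, rows), samples = samples)
}

#' Fixture peak lists emulating dense 1H metabolomics spectra
#'
#' Stand-in generator for experimental metabolomics peak lists (synthetic):
#' each list holds at least 100 peaks organized as multiplet clusters
#' (singlets, doublets and triplets with small splittings), with at least 40%
#' of peaks concentrated in a dense central region spanning 15% of the axis
#' (mimicking the crowded 3-4 ppm carbohydrate region of biofluid spectra)
#' and peak heights spanning more than two orders of magnitude.
#'
#' @param n_lists Number of lists to generate (>= 1).
#' @param seed Master seed.
#' @param n_peaks Approximate number of peaks per list (>= 100).
#' @param axis_n Nominal axis length in points.
#' @return A list of [peak_list()]s.
#' @export
fixture_peaklists <- function(n_lists = 2, seed = 1, n_peaks = 120,
                              axis_n = 131072) {
  stopifnot(n_lists >= 1, n_peaks >= 100)
  lapply(seq_len(n_lists), function(li) {
    with_seed(derive_seed(seed, li), {
      n_dense <- ceiling(0.45 * n_peaks)
      n_rest <- n_peaks - n_dense
      center <- 0.55 * axis_n
      half <- 0.075 * axis_n
      dense_centers <- stats::runif(n_dense, center - half, center + half)
      rest_centers <- stats::runif(n_rest, 0.05 * axis_n, 0.95 * axis_n)
      centers <- c(dense_centers, rest_centers)
      mult <- sample(1:3, length(centers), replace = TRUE,
                     prob = c(0.4, 0.35, 0.25))
      pos <- numeric(0); ht <- numeric(0)
      lh <- stats::runif(length(centers), -2, 0.5)
      for (i in seq_along(centers)) {
        split <- stats::runif(1, 4, 18)   # multiplet splitting, points
        m <- mult[i]
        offs <- (seq_len(m) - (m + 1) / 2) * split
        w <- if (m == 1) 1 else if (m == 2) c(1, 1) else c(0.5, 1, 0.5)
        pos <- c(pos, centers[i] + offs)
        ht <- c(ht, 10^lh[i] * w)
      }
      # guarantee a > 2 orders-of-magnitude height span
      ht[which.max(ht)] <- 10^0.5
      ht[which.min(ht)] <- 10^-2
      fw <- stats::runif(length(pos), 3, 30)
      gf <- stats::runif(length(pos), 0, 0.5)
      pos <- pmin(pmax(pos, 0), axis_n - 1)
      peak_list(pos, fw, ht / max(ht), gf, axis_n = axis_n)
    })
  })
}
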