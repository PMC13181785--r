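# Classical coarse phasing: first-derivative spectral entropy with a
# quadratic negativity penalty (ACME-style objective), minimized by an
# exhaustive 2D grid search over (PH0, PH1).

#' Spectral entropy of the real part of a spectrum
#'
#' Computes `H = -sum(h_k log h_k)` where `h_k = |dR_k| / sum |dR|` over the
#' first differences `dR` of the real part (zero terms contribute zero), plus
#' `negativity_weight` times the sum of `(R_k / R_max)^2` over negative real
#' points.  A well-phased absorption spectrum concentrates its derivative
#' near sharp peaks (low entropy) and has no negative intensity, so both
#' terms are minimized at the correct phase.  The objective is invariant
#' under uniform rescaling of the spectrum.
#'
#' @param spec A [spectrum1d()] (N >= 3).
#' @param negativity_weight Weight of the quadratic negativity penalty
#'   (default 1000).
#' @param decimate Integer stride for speed; the objective is evaluated on
#'   every `decimate`-th point (1 = use all points).
#' @return Non-negative scalar; 0 (with a warning) for an all-zero real part.
#' @export
spectral_entropy <- function(spec, negativity_weight = 1000, decimate = 1L) {
  stopifnot(inherits(spec, "spectrum1d"), length(spec$points) >= 3)
  r <- Re(spec$points)
  if (decimate > 1L) r <- r[seq(1L, length(r), by = as.integer(decimate))]
  entropy_of_real(r, negativity_weight)
}

# Internal worker on a plain real vector (used by the grid search to avoid
# re-wrapping spectra).
entropy_of_real <- function(r, negativity_weight) {
  d <- abs(diff(r))
  tot <- sum(d)
  if (tot == 0) {
    warning("spectral_entropy: all-zero (or constant) real part")
    return(0)
  }
  h <- d / tot
  ent <- -sum(h[h > 0] * log(h[h > 0]))
  if (negativity_weight != 0) {
    rmax <- max(abs(r))
    neg <- r[r < 0]
    if (length(neg) > 0) ent <- ent + negativity_weight * sum((neg / rmax)^2)
  }
  ent
}

#' Exhaustive 2D grid search for the entropy-minimal phase correction
#'
#' Evaluates [spectral_entropy()] of the spectrum phased by every `(p0, p1)`
#' combination on a regular grid (both endpoints included) and returns the
#' minimizer.  Ties are broken toward the smallest `|p0|`, then smallest
#' `|p1|`, then by grid order, so the result is deterministic.
#'
#' @param spec A [spectrum1d()].
#' @param lo,hi Grid limits in degrees (applied to both PH0 and PH1).
#' @param step Grid increment in degrees (> 0).
#' @param negativity_weight Passed to the entropy objective.
#' @param decimate Stride used when evaluating the objective; the default
#'   evaluates every 4th point for spectra longer than 16384 points.
#' @return A list of class `grid_search_result` with `best_phase`
#'   ([phase_pair()]), `objective_value`, `objective_grid` (matrix, rows =
#'   ph0 values, columns = ph1 values) and `grid_axes`.
#' @export
grid_search <- function(spec, lo = -180, hi = 180, step = 10,
                        negativity_weight = 1000, decimate = NULL) {
  stopifnot(inherits(spec, "spectrum1d"), step > 0, lo < hi)
  n <- length(spec$points)
  if (is.null(decimate)) decimate <- if (n > 16384) 4L else 1L
  idx <- seq(1L, n, by = as.integer(decimate))
  re <- Re(spec$points)[idx]
  im <- Im(spec$points)[idx]
  frac <- (idx - 1) / (n - 1)       # ramp fractions of the kept points
  vals <- seq(lo, hi, by = step)
  grid <- matrix(NA_real_, nrow = length(vals), ncol = length(vals),
                 dimnames = list(ph0 = vals, ph1 = vals))
  for (j in seq_along(vals)) {
    th1 <- .phase_sign * vals[j] * frac * (pi / 180)
    a <- re * cos(th1) - im * sin(th1)
    b <- re * sin(th1) + im * cos(th1)
    for (i in seq_along(vals)) {
      th0 <- .phase_sign * vals[i] * (pi / 180)
      grid[i, j] <- entropy_of_real(cos(th0) * a - sin(th0) * b,
                                    negativity_weight)
    }
  }
  mn <- min(grid)
  cand <- which(grid == mn, arr.ind = TRUE)
  ord <- order(abs(vals[cand[, 1]]), abs(vals[cand[, 2]]),
               vals[cand[, 1]], vals[cand[, 2]])
  best <- cand[ord[1], ]
  structure(
    list(best_phase = phase_pair(vals[best[1]], vals[best[2]]),
         objective_value = mn, objective_grid = grid, grid_axes = vals),
    class = "grid_search_result")
}
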