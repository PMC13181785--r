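# Full automated phasing workflow: entropy grid search for the coarse
# correction, then an iterative loop driven by the two sign-of-error
# classifiers, and finally a finite-difference ascent on the summed
# "no-phase-error" scores until the search step drops below the stop
# threshold.

#' Options for the automated phasing loop
#'
#' @param initial_step Step size (degrees) of the first ANN-guided correction.
#' @param stop_step Convergence threshold: refinement terminates once the
#'   search step falls below this (degrees).
#' @param max_iterations Maximum ANN-guided loop iterations.
#' @param fd_epsilon Finite-difference probe (degrees) for score-gradient
#'   estimation; the default refinement probes along the phase axes at the
#'   current step size, so this only affects alternative gradient-based
#'   refinement schemes.
#' @param min_peaks Minimum number of detected peaks for the classifiers to
#'   be considered applicable; below this a warning is logged.
#' @return A list of class `phaser_options`.
#' @export
phaser_options <- function(initial_step = 2, stop_step = 0.3,
                           max_iterations = 50, fd_epsilon = 0.5,
                           min_peaks = 15) {
  stopifnot(stop_step > 0, initial_step >= stop_step, max_iterations >= 0,
            fd_epsilon > 0, min_peaks >= 0)
  structure(list(initial_step = initial_step, stop_step = stop_step,
                 max_iterations = max_iterations, fd_epsilon = fd_epsilon,
                 min_peaks = min_peaks),
            class = "phaser_options")
}

#' Count peaks in the real part of a spectrum
#'
#' Counts local maxima of the real part exceeding five times a robust noise
#' estimate (the median absolute deviation of point-to-point differences,
#' scaled to a standard deviation).  Deterministic.
#'
#' @param spec A [spectrum1d()].
#' @return Integer peak count.
#' @export
count_peaks <- function(spec) {
  stopifnot(inherits(spec, "spectrum1d"))
  r <- Re(spec$points)
  n <- length(r)
  if (all(r == 0)) return(0L)
  noise <- stats::mad(diff(r)) / sqrt(2)
  thr <- 5 * noise
  if (noise == 0) thr <- 0
  inner <- r[2:(n - 1)]
  is_max <- inner > r[1:(n - 2)] & inner >= r[3:n] & inner > thr
  sum(is_max)
}

# Zero-class probabilities of both models for a given additional correction,
# applied on top of the base spectrum.
zero_scores <- function(spec, ph0_model, ph1_model, corr) {
  ph <- apply_phase(spec, corr)
  c(ph0 = unname(predict_phase_class(ph0_model, ph)$probs["zero"]),
    ph1 = unname(predict_phase_class(ph1_model, ph)$probs["zero"]))
}

#' Fully automated phase correction
#'
#' Three stages: (1) coarse correction by the entropy grid search; (2) an
#' iterative loop querying both classifiers on the corrected spectrum; for
#' each component whose predicted sign is not zero, a correction of the
#' current step size opposing the predicted sign is applied (PH0 and PH1
#' simultaneously), and a component's step is halved whenever its predicted
#' sign flips (or when the same sign/step pattern recurs three times); the
#' loop exits when both classifiers predict zero or `max_iterations` is
#' reached; (3) a finite-difference ascent on the sum of the two zero-class
#' probabilities over (PH0, PH1), with step halving, terminating when the
#' step falls below `stop_step`.
#'
#' @param spec A [spectrum1d()] (uncorrected).
#' @param ph0_model,ph1_model Trained classifiers for the PH0 and PH1 tasks.
#' @param opts A [phaser_options()].
#' @param grid_lo,grid_hi,grid_step Entropy grid-search parameters (degrees);
#'   set `grid_step = NULL` to skip the entropy stage.
#' @return A list of class `phaser_result`: `total_correction`
#'   ([phase_pair()]), `phased_spectrum`, `iterations` (data frame trace of
#'   every applied correction with classifier probabilities), `converged`,
#'   and `final_step` (degrees).
#' @export
deep_phase <- function(spec, ph0_model, ph1_model, opts = phaser_options(),
                       grid_lo = -180, grid_hi = 180, grid_step = 10) {
  stopifnot(inherits(spec, "spectrum1d"))
  if (!inherits(ph0_model, "tandem_model") || !inherits(ph1_model, "tandem_model"))
    stop("deep_phase: ph0_model and ph1_model must be tandem_model objects")
  if (!identical(ph0_model$cfg$input_channels, ph1_model$cfg$input_channels) ||
      !identical(ph0_model$cfg$max_field_of_view, ph1_model$cfg$max_field_of_view))
    stop("deep_phase: incompatible model configurations (input channels / field of view differ)")
  npk <- count_peaks(spec)
  if (npk < opts$min_peaks)
    warning(sprintf("deep_phase: only %d peaks detected (< %d); classifier guidance may be unreliable",
                    npk, opts$min_peaks))

  trace <- list()
  total <- phase_pair(0, 0)
  add_step <- function(label, corr, p0 = rep(NA_real_, 3), p1 = rep(NA_real_, 3)) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = label, ph0 = corr$ph0, ph1 = corr$ph1,
      p0_neg = p0[1], p0_zero = p0[2], p0_pos = p0[3],
      p1_neg = p1[1], p1_zero = p1[2], p1_pos = p1[3])
    total <<- phase_add(total, corr)
  }

  # (1) entropy coarse stage
  if (!is.null(grid_step)) {
    gs <- grid_search(spec, lo = grid_lo, hi = grid_hi, step = grid_step)
    add_step("entropy", gs$best_phase)
  }

  current <- function() apply_phase(spec, total)

  # (2) ANN-guided loop.  The zero-class score sum of every visited state is
  # recorded; if the loop ends in a worse state than the best one seen
  # (classifier misfires can walk the correction away from the optimum), the
  # best state is restored before refinement.
  steps <- c(ph0 = opts$initial_step, ph1 = opts$initial_step)
  last_sign <- c(ph0 = 0, ph1 = 0)
  recur <- 0L
  last_pattern <- ""
  both_zero <- FALSE
  best_total <- total
  best_zero_sum <- -Inf
  if (opts$max_iterations > 0) {
    for (it in seq_len(opts$max_iterations)) {
      cur <- current()
      p0 <- predict_phase_class(ph0_model, cur)$probs
      p1 <- predict_phase_class(ph1_model, cur)$probs
      zs <- p0["zero"] + p1["zero"]
      if (zs > best_zero_sum) { best_zero_sum <- zs; best_total <- total }
      s0 <- c(-1, 0, 1)[which.max(p0)]
      s1 <- c(-1, 0, 1)[which.max(p1)]
      if (s0 == 0 && s1 == 0) { both_zero <- TRUE; break }
      # halve a component's step when its predicted sign flips
      if (s0 != 0 && last_sign["ph0"] != 0 && s0 != last_sign["ph0"])
        steps["ph0"] <- steps["ph0"] / 2
      if (s1 != 0 && last_sign["ph1"] != 0 && s1 != last_sign["ph1"])
        steps["ph1"] <- steps["ph1"] / 2
      pattern <- paste(s0, s1, steps["ph0"], steps["ph1"])
      if (pattern == last_pattern) recur <- recur + 1L else recur <- 0L
      if (recur >= 2L) { steps <- steps / 2; recur <- 0L }  # oscillation guard
      last_pattern <- pattern
      corr <- phase_pair(-s0 * steps["ph0"], -s1 * steps["ph1"])
      add_step(sprintf("ann_%02d", it), corr, p0, p1)
      if (s0 != 0) last_sign["ph0"] <- s0
      if (s1 != 0) last_sign["ph1"] <- s1
    }
  }

  # revert to the best visited state if the loop drifted away from it
  if (opts$max_iterations > 0 && is.finite(best_zero_sum)) {
    end_scores <- zero_scores(spec, ph0_model, ph1_model, total)
    if (sum(end_scores) < best_zero_sum &&
        (abs(best_total$ph0 - total$ph0) > 1e-12 ||
         abs(best_total$ph1 - total$ph1) > 1e-12)) {
      add_step("revert_best", phase_pair(best_total$ph0 - total$ph0,
                                         best_total$ph1 - total$ph1))
    }
  }

  # (3) finite-difference ascent on the summed zero-class scores
  final_step <- opts$initial_step
  if (opts$max_iterations > 0) {
    score_at <- function(d0, d1)
      sum(zero_scores(spec, ph0_model, ph1_model,
                      phase_add(total, phase_pair(d0, d1))))
    step <- opts$initial_step
    best <- score_at(0, 0)
    refine_iter <- 0L
    while (step >= opts$stop_step && refine_iter < 200L) {
      refine_iter <- refine_iter + 1L
      # probe both phase axes at the current step size; take the best
      # improving move, halve the step when none improves
      cand <- rbind(c(step, 0), c(-step, 0), c(0, step), c(0, -step))
      vals <- apply(cand, 1, function(d) score_at(d[1], d[2]))
      k <- which.max(vals)
      if (vals[k] > best + 1e-9) {
        best <- vals[k]
        add_step("refine", phase_pair(cand[k, 1], cand[k, 2]))
      } else {
        step <- step / 2
      }
    }
    final_step <- step
  }

  converged <- both_zero || opts$max_iterations == 0
  if (opts$max_iterations > 0) {
    cur <- current()
    p0 <- predict_phase_class(ph0_model, cur)$probs
    p1 <- predict_phase_class(ph1_model, cur)$probs
    converged <- final_step < opts$stop_step &&
      which.max(p0) == 2 && which.max(p1) == 2
  }

  structure(
    list(total_correction = total, phased_spectrum = current(),
         iterations = if (length(trace)) do.call(rbind, trace) else
           data.frame(),
         converged = converged, final_step = final_step, n_peaks = npk),
    class = "phaser_result")
}

#' @export
print.phaser_result <- function(x, ...) {
  cat(sprintf("<phaser_result: PH0 = %.3f deg, PH1 = %.3f deg, %s after %d step(s), final step %.3g deg>\n",
              x$total_correction$ph0, x$total_correction$ph1,
              if (x$converged) "converged" else "not converged",
              nrow(x$iterations), x$final_step))
  invisible(x)
}

#' Classifier score surfaces over a grid of endpoint phase errors
#'
#' For every (left, right) endpoint-phase pair on the grid, the spectrum is
#' phased by the corresponding (PH0, PH1) and both models' zero-class
#' probabilities are recorded.  Both surfaces are computed from identical
#' phased inputs at each grid point.
#'
#' @param spec A [spectrum1d()].
#' @param ph0_model,ph1_model Trained classifiers.
#' @param grid_lo,grid_hi,step Grid of endpoint phases in degrees.
#' @return A list with `left`, `right` (grid axes), and matrices `ph0_score`,
#'   `ph1_score` (rows = left endpoint, columns = right endpoint).
#' @export
score_surface <- function(spec, ph0_model, ph1_model, grid_lo = -10,
                          grid_hi = 10, step = 2) {
  stopifnot(step > 0, grid_lo < grid_hi)
  vals <- seq(grid_lo, grid_hi, by = step)
  s0 <- matrix(NA_real_, length(vals), length(vals),
               dimnames = list(left = vals, right = vals))
  s1 <- s0
  for (i in seq_along(vals)) {
    for (j in seq_along(vals)) {
      ph <- apply_phase(spec, endpoint_to_phasepair(vals[i], vals[j]))
      s0[i, j] <- unname(predict_phase_class(ph0_model, ph)$probs["zero"])
      s1[i, j] <- unname(predict_phase_class(ph1_model, ph)$probs["zero"])
    }
  }
  list(left = vals, right = vals, ph0_score = s0, ph1_score = s1)
}
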