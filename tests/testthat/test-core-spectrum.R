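# Phase algebra and FID processing.

test_that("apply_phase matches a per-point complex-exponential oracle", {
  # direct oracle: multiply point k by exp(i * pi/180 * (ph0 + ph1*k/(N-1)))
  oracle <- function(pts, ph0, ph1) {
    n <- length(pts)
    k <- seq_len(n) - 1
    pts * exp(1i * pi / 180 * (ph0 + ph1 * k / (n - 1)))
  }

  # constant spectrum, PH0 = 90: every point becomes 0 + 1i
  s <- spectrum1d(rep(1 + 0i, 8))
  out <- apply_phase(s, phase_pair(90, 0))
  expect_equal(out$points, rep(0 + 1i, 8), tolerance = 1e-12)

  # N = 3 ramp: PH1 = 180 gives (1, i, -1)
  s3 <- spectrum1d(rep(1 + 0i, 3))
  out3 <- apply_phase(s3, phase_pair(0, 180))
  expect_equal(out3$points, c(1 + 0i, 0 + 1i, -1 + 0i), tolerance = 1e-12)

  # random spectra vs the oracle, 1e-10 relative
  set.seed(11)
  for (rep_i in 1:20) {
    n <- sample(c(16, 100, 333), 1)
    pts <- complex(real = rnorm(n), imaginary = rnorm(n))
    ph0 <- runif(1, -360, 360); ph1 <- runif(1, -360, 360)
    got <- apply_phase(spectrum1d(pts), phase_pair(ph0, ph1))$points
    want <- oracle(pts, ph0, ph1)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
})

test_that("apply_phase identity, inverse, additivity and magnitude preservation", {
  s <- dense_spec(1024, 12, seed = 2)
  expect_equal(apply_phase(s, phase_pair(0, 0))$points, s$points)

  p <- phase_pair(37.3, -101.2)
  back <- apply_phase(apply_phase(s, p), phase_neg(p))
  expect_lt(max(abs(back$points - s$points)) / max(abs(s$points)), 1e-10)

  # additive composition
  p1 <- phase_pair(12.5, 40); p2 <- phase_pair(-30, 13.7)
  seq_applied <- apply_phase(apply_phase(s, p1), p2)
  sum_applied <- apply_phase(s, phase_add(p1, p2))
  expect_lt(max(abs(seq_applied$points - sum_applied$points)) /
              max(abs(s$points)), 1e-10)

  # |S_k| preserved at every index
  ph <- apply_phase(s, phase_pair(77, -191))
  expect_equal(abs(ph$points), abs(s$points), tolerance = 1e-12)

  expect_error(apply_phase(s, phase_pair(NaN, 0)), "finite")
})

test_that("endpoint parametrization converts and round-trips", {
  expect_equal(unclass(endpoint_to_phasepair(0, 0))[c("ph0", "ph1")],
               list(ph0 = 0, ph1 = 0))
  p <- endpoint_to_phasepair(5, 5)
  expect_equal(c(p$ph0, p$ph1), c(5, 0))
  p <- endpoint_to_phasepair(-3, 7)
  expect_equal(c(p$ph0, p$ph1), c(-3, 10))

  set.seed(5)
  for (i in 1:1000) {
    lr <- runif(2, -720, 720)
    ep <- phasepair_to_endpoints(endpoint_to_phasepair(lr[1], lr[2]))
    expect_equal(unname(ep), lr, tolerance = 1e-12)
  }
})

test_that("wrap_deg maps into (-180, 180]", {
  expect_equal(wrap_deg(c(0, 180, -180, 360, 540, -190)),
               c(0, 180, 180, 0, 180, 170))
})

test_that("process_fid produces an absorptive Lorentzian at the right place", {
  # closed form: damped oscillation exp(i*2*pi*f*t - t/tau) transforms to a
  # Lorentzian at f with FWHH = 1/(pi*tau) Hz
  n <- 2048; dt <- 1e-3; f <- 120; tau <- 0.04
  tv <- (0:(n - 1)) * dt
  fid <- fid_record(exp(2i * pi * f * tv - tv / tau), dt)
  sp <- process_fid(fid, processing_params(apod_line_broadening = 0))
  r <- Re(sp$points)
  imax <- which.max(r)
  fs <- 1 / dt
  f_meas <- (n / 2 - 1 - (imax - 1)) / n * fs
  expect_lt(abs(f_meas - f), fs / n + 1e-9)  # within one grid spacing

  # FWHH via interpolated half-height crossings, vs 1/(pi*tau) Hz
  half <- max(r) / 2
  above <- which(r > half)
  lo <- min(above); hi <- max(above)
  frac_lo <- (r[lo] - half) / (r[lo] - r[lo - 1])
  frac_hi <- (r[hi] - half) / (r[hi] - r[hi + 1])
  width_pts <- (hi + frac_hi) - (lo - frac_lo)
  width_hz <- width_pts * fs / n
  expect_lt(abs(width_hz - 1 / (pi * tau)) / (1 / (pi * tau)), 0.05)

  # mostly absorptive: negligible negative excursion
  expect_gt(min(r) / max(r), -0.01)

  # all-zero FID gives an all-zero spectrum
  z <- process_fid(fid_record(complex(16), 1e-3))
  expect_true(all(z$points == 0))

  expect_error(process_fid(fid, processing_params(zero_fill_target = 1024)),
               "zero_fill_target")
})

test_that("group-delay correction compensates a digitally delayed FID", {
  s <- dense_spec(512, 6, seed = 3)
  # g = 0 is the identity
  expect_equal(group_delay_correct(s, 0)$points, s$points)
  # g = 1 on any spectrum equals apply_phase(0, -360)
  g1 <- group_delay_correct(s, 1)
  ref <- apply_phase(s, phase_pair(0, -360))
  expect_equal(g1$points, ref$points, tolerance = 1e-12)
  # correcting g then -g (via apply_phase) is the identity
  back <- apply_phase(group_delay_correct(s, 2.5), phase_pair(0, 360 * 2.5))
  expect_lt(max(abs(back$points - s$points)) / max(abs(s$points)), 1e-10)
  expect_error(group_delay_correct(s, -1), ">= 0")

  # self-consistency: an FID circularly delayed by an even number of points,
  # processed with the matching group_delay, matches the undelayed spectrum
  n <- 4096; dt <- 1e-3
  tv <- (0:(n - 1)) * dt
  sig <- exp(2i * pi * 150 * tv - tv / 0.05) + 0.5 * exp(-2i * pi * 80 * tv - tv / 0.03)
  g <- 2L
  delayed <- c(rep(0 + 0i, g), sig[1:(n - g)])
  sp_ref <- process_fid(fid_record(sig, dt, group_delay = 0))
  sp_del <- process_fid(fid_record(delayed, dt, group_delay = g))
  core <- 100:(n - 100)
  err <- max(abs(sp_del$points[core] - sp_ref$points[core]))
  expect_lt(err / max(abs(sp_ref$points)), 0.05)
})
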