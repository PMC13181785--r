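# Synthetic-spectrum generator.

test_that("voigt synthesis yields consistent absorption/dispersion lineshapes", {
  expect_true(all(synthesize_spectrum(peak_list(numeric(0), numeric(0),
                                                numeric(0), axis_n = 256),
                                      256)$points == 0))

  # single Lorentzian: height within 2%, FWHH within 5% (half-height crossings)
  s <- lorentzian_spec(n = 2048, pos = 1000, fwhh = 10, height = 1)
  r <- Re(s$points)
  expect_lt(abs(max(r) - 1), 0.02)
  expect_equal(which.max(r), 1001)
  half <- max(r) / 2
  above <- which(r > half)
  lo <- min(above); hi <- max(above)
  frac_lo <- (r[lo] - half) / (r[lo] - r[lo - 1])
  frac_hi <- (r[hi] - half) / (r[hi] - r[hi + 1])
  expect_lt(abs((hi + frac_hi) - (lo - frac_lo) - 10) / 10, 0.05)

  # dispersion part integrates to ~0 relative to the absorption integral
  expect_lt(abs(sum(Im(s$points))) / abs(sum(r)), 0.01)

  expect_warning(synthesize_spectrum(peak_list(5000, 10, 1, axis_n = 256), 256),
                 "clipped")
})

test_that("augmentation respects its switches, ranges, and mirror map", {
  base <- peak_list(c(100, 400, 900, 2000, 3000), fwhh = 10, height = 1,
                    axis_n = 4096)
  cfg0 <- synth_config(max_displacement = 0, invert_prob = 0,
                       shoulder_prob = 0, width_range = c(3, 30))
  noop <- augment_peaklist(base, cfg0, seed = 4, shuffle_segments = FALSE,
                           removal = FALSE)
  expect_equal(noop$position, base$position)

  # widths always inside [3, 30] when broad peaks are off
  for (sd in 1:5) {
    aug <- augment_peaklist(base, synth_config(), seed = sd)
    expect_true(all(aug$fwhh >= 3 & aug$fwhh <= 30))
  }

  # forced inversion mirrors every position about the axis center
  cfg_inv <- synth_config(max_displacement = 0, invert_prob = 1,
                          shoulder_prob = 0)
  inv <- augment_peaklist(base, cfg_inv, seed = 9, shuffle_segments = FALSE,
                          removal = FALSE)
  expect_equal(sort(inv$position), sort((4096 - 1) - base$position))
})

test_that("hermite baseline has the requested extrema and exact amplitude", {
  expect_true(all(hermite_baseline(1024, 5, 0, seed = 1) == 0))
  for (sd in 1:8) {
    b <- hermite_baseline(4096, 5, 0.006, seed = sd)
    d <- diff(b)
    sgn <- sign(d[d != 0])
    n_extrema <- sum(diff(sgn) != 0)
    expect_equal(n_extrema, 5)
    expect_equal(max(abs(b)), 0.006, tolerance = 1e-12)
  }
  expect_error(hermite_baseline(16, 5, 1), "too small")
})

test_that("added noise is Gaussian, calibrated, and channel-independent", {
  s <- lorentzian_spec(n = 512)
  expect_equal(add_noise(s, 0)$points, s$points)

  big <- spectrum1d(complex(100000))
  noisy <- add_noise(big, 1, seed = 7)
  expect_lt(abs(sd(Re(noisy$points)) - 1), 0.02)
  expect_lt(abs(sd(Im(noisy$points)) - 1), 0.02)
  expect_lt(abs(cor(Re(noisy$points), Im(noisy$points))), 0.02)
})

test_that("make_sample injects phases by task, category and range", {
  pl <- fixture_peaklists(1, seed = 2, axis_n = 4096)[[1]]

  z <- make_sample(pl, 1024, "ph0", "zero", seed = 1)
  expect_equal(c(z$true_phase$ph0, z$true_phase$ph1), c(0, 0))
  expect_equal(z$label, "zero")

  for (sd in 1:25) {
    sp <- make_sample(pl, 1024, "ph0", "positive", seed = sd)
    expect_true(sp$true_phase$ph0 >= 0.5 && sp$true_phase$ph0 <= 5.0)
    expect_identical(sp$true_phase$ph1, 0)

    sn <- make_sample(pl, 1024, "ph1", "negative", seed = sd)
    expect_lt(sn$true_phase$ph1, 0)
    expect_true(abs(sn$true_phase$ph1) >= 1 && abs(sn$true_phase$ph1) <= 10)
    expect_equal(abs(sn$true_phase$ph0), abs(sn$true_phase$ph1))

    pp <- make_sample(pl, 1024, "ph0", "negative", seed = sd, pretrain = TRUE)
    expect_true(abs(pp$true_phase$ph0) >= 5 && abs(pp$true_phase$ph0) <= 10)
    pq <- make_sample(pl, 1024, "ph1", "positive", seed = sd, pretrain = TRUE)
    expect_true(pq$true_phase$ph1 >= 5 && pq$true_phase$ph1 <= 20)
  }

  expect_error(make_sample(pl, 1024, "ph2", "zero"), "task")
  expect_error(make_sample(pl, 1024, "ph0", "none"), "category")
})

test_that("zero-error samples keep symmetric absorption peaks", {
  # noiseless, baseline-free: an isolated Lorentzian stays symmetric
  pl <- peak_list(512, fwhh = 12, height = 1, axis_n = 1024)
  smp <- make_sample(pl, 1024, "ph0", "zero", cfg = noiseless_config(),
                     seed = 3)
  r <- Re(smp$spectrum$points)
  ctr <- which.max(r)
  for (w in c(3, 6, 12, 24))
    expect_lt(abs(r[ctr + w] - r[ctr - w]) / max(r), 1e-6)
})

test_that("build_dataset counts, balances and reproduces deterministically", {
  base <- fixture_peaklists(1, seed = 6, axis_n = 4096)
  cfg <- synth_config(n_points_choices = 1024L, n_augment_per_list = 2L)
  ds <- build_dataset(base, cfg, task = "ph0", seed = 10)
  expect_equal(nrow(ds$manifest), 6)
  expect_equal(length(ds$samples), 6)
  expect_true(all(table(ds$manifest$label) == 2))

  # the class counts are exactly balanced per (base list, length)
  cfg2 <- synth_config(n_points_choices = c(512L, 1024L),
                       n_augment_per_list = 3L)
  ds2 <- build_dataset(base, cfg2, task = "ph1", seed = 11,
                       materialize = FALSE)
  tab <- table(ds2$manifest$n_points, ds2$manifest$label)
  expect_true(all(tab == 3))

  # full-scale bookkeeping: 2 bases x 1000 x 3 lengths x 3 categories = 18000
  big <- build_dataset(fixture_peaklists(2, seed = 1),
                       synth_config(n_augment_per_list = 1000L),
                       task = "ph0", seed = 1, materialize = FALSE)
  expect_equal(nrow(big$manifest), 18000)

  # byte-identical manifests across identical runs
  m1 <- build_dataset(base, cfg, task = "ph0", seed = 10)$manifest
  m2 <- build_dataset(base, cfg, task = "ph0", seed = 10)$manifest
  expect_identical(jsonlite::toJSON(m1, digits = NA),
                   jsonlite::toJSON(m2, digits = NA))

  # manifest-only runs record the same draws as materialized runs
  m3 <- build_dataset(base, cfg, task = "ph0", seed = 10,
                      materialize = FALSE)$manifest
  expect_identical(jsonlite::toJSON(m1, digits = NA),
                   jsonlite::toJSON(m3, digits = NA))
})

test_that("fixture peak lists are dense, multiplet-rich and wide in height", {
  lists <- fixture_peaklists(2, seed = 21)
  expect_length(lists, 2)
  for (pl in lists) {
    expect_gte(nrow(pl), 100)
    axis_n <- attr(pl, "axis_n")
    center <- 0.55 * axis_n; half <- 0.075 * axis_n
    dense_frac <- mean(pl$position >= center - half &
                         pl$position <= center + half)
    expect_gte(dense_frac, 0.40)
    expect_gte(max(pl$height) / min(pl$height), 100)
  }
})

test_that("broad-peak inclusion rate converges to its configured probability", {
  base <- fixture_peaklists(1, seed = 3)
  cfg <- synth_config(n_points_choices = 1024L, n_augment_per_list = 667L)
  man <- build_dataset(base, cfg, task = "ph0", seed = 31,
                       materialize = FALSE)$manifest
  n <- nrow(man)
  expect_gte(n, 2000)
  bt <- binom.test(sum(man$has_broad), n, p = 0.30)
  expect_gt(bt$p.value, 0.01)
})
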