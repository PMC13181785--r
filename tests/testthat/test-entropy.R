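# Entropy objective and the coarse 2D grid search.

test_that("spectral entropy has the expected analytic limits", {
  # strictly linear real part: |dR| is constant, entropy = ln(N-1)
  n <- 101
  lin <- spectrum1d(complex(real = seq(1, 2, length.out = n),
                            imaginary = numeric(n)))
  expect_equal(spectral_entropy(lin, negativity_weight = 0), log(n - 1),
               tolerance = 1e-12)
  # all-positive real part: the negativity penalty contributes nothing
  expect_equal(spectral_entropy(lin, negativity_weight = 1e6), log(n - 1),
               tolerance = 1e-12)

  expect_warning(h0 <- spectral_entropy(spectrum1d(complex(16)), 0),
                 "all-zero")
  expect_equal(h0, 0)

  # a phase error increases the objective of a clean Lorentzian
  s <- lorentzian_spec(2048, 1024, 10, 1)
  expect_lt(spectral_entropy(s, 0),
            spectral_entropy(apply_phase(s, phase_pair(10, 0)), 0))

  # scale invariance
  d <- dense_spec(2048, 20, seed = 8)
  d_err <- apply_phase(d, phase_pair(25, -40))
  big <- d_err; big$points <- big$points * 1e4
  expect_lt(abs(spectral_entropy(big) - spectral_entropy(d_err)), 1e-9)
})

test_that("grid search minimizes the objective and breaks ties at the origin", {
  s <- lorentzian_spec(1024, 512, 8, 1)
  gs0 <- grid_search(s)
  expect_equal(c(gs0$best_phase$ph0, gs0$best_phase$ph1), c(0, 0))

  err <- apply_phase(s, phase_pair(40, 0))
  gs <- grid_search(err)
  expect_equal(c(gs$best_phase$ph0, gs$best_phase$ph1), c(-40, 0))

  expect_equal(gs$objective_value, min(gs$objective_grid))
  expect_error(grid_search(s, step = 0), "step")
})

test_that("grid search equals a brute-force re-evaluation via apply_phase", {
  s <- apply_phase(dense_spec(512, 8, seed = 4), phase_pair(-50, 70))
  gs <- grid_search(s, lo = -90, hi = 90, step = 30, decimate = 1)
  vals <- seq(-90, 90, by = 30)
  brute <- matrix(NA_real_, length(vals), length(vals))
  for (i in seq_along(vals))
    for (j in seq_along(vals))
      brute[i, j] <- spectral_entropy(
        apply_phase(s, phase_pair(vals[i], vals[j])), 1000)
  expect_equal(gs$objective_grid, brute, tolerance = 1e-10,
               ignore_attr = TRUE)
  best <- which(brute == min(brute), arr.ind = TRUE)[1, ]
  expect_equal(c(gs$best_phase$ph0, gs$best_phase$ph1),
               c(vals[best[1]], vals[best[2]]))
})
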