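# Workflow mechanics that do not require trained classifiers; end-to-end
# recovery with trained models lives in test-acceptance.R.

test_that("count_peaks counts isolated resonances and ignores empty spectra", {
  expect_equal(count_peaks(spectrum1d(complex(256))), 0L)
  n <- 4096
  pos <- seq(200, 3900, length.out = 20)
  s <- synthesize_spectrum(peak_list(pos, fwhh = 8, height = 1, axis_n = n), n)
  expect_equal(count_peaks(s), 20L)
})

test_that("deep_phase with max_iterations = 0 reduces to the entropy search", {
  s <- apply_phase(dense_spec(1024, 20, seed = 7), phase_pair(60, -30))
  m <- build_model(tiny_net_config(), seed = 1, quiet = TRUE)
  res <- deep_phase(s, m, m, phaser_options(max_iterations = 0))
  gs <- grid_search(s)
  expect_equal(res$total_correction$ph0, gs$best_phase$ph0)
  expect_equal(res$total_correction$ph1, gs$best_phase$ph1)
  expect_equal(res$phased_spectrum$points,
               apply_phase(s, gs$best_phase)$points)
})

test_that("the iteration trace composes exactly to the total correction", {
  s <- apply_phase(dense_spec(1024, 20, seed = 9), phase_pair(25, 10))
  m <- build_model(tiny_net_config(), seed = 2, quiet = TRUE)
  res <- deep_phase(s, m, m, phaser_options(max_iterations = 5))
  tr <- res$iterations
  expect_gt(nrow(tr), 0)
  expect_equal(sum(tr$ph0), res$total_correction$ph0, tolerance = 1e-12)
  expect_equal(sum(tr$ph1), res$total_correction$ph1, tolerance = 1e-12)
  # applying the total correction to the raw input reproduces the output
  redo <- apply_phase(s, res$total_correction)
  expect_lt(max(abs(redo$points - res$phased_spectrum$points)) /
              max(abs(s$points)), 1e-8)
})

test_that("deep_phase validates inputs and warns on sparse spectra", {
  m <- build_model(tiny_net_config(), seed = 3, quiet = TRUE)
  sparse <- synthesize_spectrum(peak_list(512, 10, 1, axis_n = 1024), 1024)
  expect_warning(deep_phase(sparse, m, m, phaser_options(max_iterations = 0)),
                 "peaks")
  expect_error(deep_phase(dense_spec(512, 20, seed = 1), m, "nope"),
               "tandem_model")
  m_other <- build_model(net_config(downsample_factor = 8, embed_dim = 16,
                                    n_layers = 1, n_heads = 2,
                                    rel_bias_buckets = 8,
                                    max_field_of_view = 4096,
                                    conv_channels = c(4, 8),
                                    conv_strides = c(2, 2, 2),
                                    conv_kernels = c(5, 3, 3),
                                    head_hidden = 8, input_channels = 1),
                         seed = 1, quiet = TRUE)
  expect_error(deep_phase(dense_spec(512, 20, seed = 1), m, m_other),
               "incompatible")
})

test_that("score surfaces share the grid and stay within [0, 1]", {
  m <- build_model(tiny_net_config(), seed = 6, quiet = TRUE)
  s <- dense_spec(512, 20, seed = 4)
  su <- score_surface(s, m, m, grid_lo = -4, grid_hi = 4, step = 4)
  expect_equal(dim(su$ph0_score), c(3, 3))
  expect_equal(su$left, su$right)
  expect_true(all(su$ph0_score >= 0 & su$ph0_score <= 1))
  expect_true(all(su$ph1_score >= 0 & su$ph1_score <= 1))
  # identical models receive identical phased inputs: surfaces coincide
  expect_equal(su$ph0_score, su$ph1_score, tolerance = 1e-12)
})
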