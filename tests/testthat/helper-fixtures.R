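# Shared fixtures: everything is generated in code at test time.

# A single noiseless Lorentzian absorption spectrum.
lorentzian_spec <- function(n = 1024, pos = n / 2, fwhh = 10, height = 1) {
  synthesize_spectrum(peak_list(pos, fwhh, height, axis_n = n), n)
}

# A dense noiseless multi-peak spectrum (for entropy / peak-count tests).
dense_spec <- function(n = 4096, n_peaks = 30, seed = 1) {
  pl <- with_seed(seed, peak_list(
    position = sort(runif(n_peaks, 0.05 * n, 0.95 * n)),
    fwhh = runif(n_peaks, 4, 12),
    height = runif(n_peaks, 0.2, 1),
    axis_n = n))
  synthesize_spectrum(pl, n)
}

# Tiny network configuration for fast unit tests.
tiny_net_config <- function() {
  net_config(downsample_factor = 8, embed_dim = 16, n_layers = 2, n_heads = 2,
             rel_bias_buckets = 8, max_field_of_view = 8192, dropout = 0,
             conv_channels = c(4, 8), conv_strides = c(2, 2, 2),
             conv_kernels = c(5, 3, 3), mlp_mult = 2, head_hidden = 8,
             input_channels = 2)
}

# Noise-free generator configuration (for shape/symmetry assertions).
noiseless_config <- function(...) {
  synth_config(noise_sigma_range = c(0, 0), baseline_max_frac = 0,
               broad_peak_prob = 0, ...)
}

# Quick toy training set: small spectra, pretraining (coarse) error ranges.
toy_training_set <- function(n_per_class = 10, n_points = 512, task = "ph0",
                             seed = 1) {
  bases <- fixture_peaklists(1, seed = seed, axis_n = n_points)
  cfg <- synth_config(n_points_choices = as.integer(n_points),
                      n_augment_per_list = n_per_class)
  build_dataset(bases, cfg, task = task, seed = seed, pretrain = TRUE)$samples
}
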