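# Shared fixtures: all data is built in code at test time.

# Small random labelled dataset on an arbitrary axis.
tiny_dataset <- function(m = 20, n = 12, seed = 1, classes = c("a", "b")) {
  set.seed(seed)
  spectral_dataset(seq(400, by = 10, length.out = n),
                   matrix(rnorm(m * n), m, n),
                   rep_len(classes, m))
}

# Two-class separable dataset: class means shifted in a few columns.
separable_dataset <- function(m_per = 30, n = 8, shift = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(m_per * n), m_per, n),
             matrix(rnorm(m_per * n, mean = shift), m_per, n))
  spectral_dataset(seq(500, by = 25, length.out = n), X,
                   rep(c("neg", "pos"), each = m_per))
}

# Coarse-grid synthetic config (two classes, three differing bands) so the
# full pipeline runs fast in unit tests.
small_band_config <- function(n_per_class = 60, noise_sd = 0.02,
                              scale_jitter_sd = 0.05, amp_jitter_sd = 0.2,
                              seed = 1) {
  bands <- list(chromophore_band(700, 60, "bandA"),
                chromophore_band(1210, 40, "bandB"),
                chromophore_band(1500, 80, "bandC"))
  amp <- function(a, b, c) { v <- c(a, b, c); names(v) <- c("bandA", "bandB", "bandC"); v }
  synthetic_config(
    class_specs = list(
      tissue1 = list(amplitudes = amp(.50, .10, .40), baseline = 1.0),
      tissue2 = list(amplitudes = amp(.10, .55, .05), baseline = 0.95)),
    bands = bands, n_per_class = n_per_class, noise_sd = noise_sd,
    scale_jitter_sd = scale_jitter_sd, amp_jitter_sd = amp_jitter_sd,
    grid = list(start = 400, junction = 1100, end = 1700,
                fine_bin = 5, coarse_bin = 10), seed = seed)
}

expect_feature_subset <- function(fs) {
  expect_s3_class(fs, "feature_subset")
  expect_false(anyDuplicated(fs$indices) > 0)
  expect_equal(length(fs$nm), length(fs$indices))
}
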