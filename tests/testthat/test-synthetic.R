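# Synthetic generator: determinism, planted structure, ground-truth logic.

test_that("generation is deterministic and respects class counts", {
  cfg <- small_band_config(n_per_class = 15, seed = 42)
  g1 <- generate_dataset(cfg)
  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset$intensities, g2$dataset$intensities)
  expect_identical(g1$dataset$labels, g2$dataset$labels)
  expect_equal(unname(table(g1$dataset$labels)["tissue1"]), 15,
               ignore_attr = TRUE)
  expect_equal(nrow(g1$dataset$intensities), 30)
  cfg2 <- small_band_config(n_per_class = 15, seed = 43)
  expect_false(identical(generate_dataset(cfg2)$dataset$intensities,
                         g1$dataset$intensities))
})

test_that("zero noise gives identical rows within a class", {
  cfg <- small_band_config(n_per_class = 5, noise_sd = 0,
                           scale_jitter_sd = 0, amp_jitter_sd = 0)
  d <- generate_dataset(cfg)$dataset
  for (cl in unique(d$labels)) {
    rows <- d$intensities[d$labels == cl, ]
    expect_equal(max(apply(rows, 2, stats::sd)), 0)
  }
})

test_that("per-bin F statistic localises a single differing band", {
  # two classes differing only in the 1210 nm band amplitude; the band is
  # narrow relative to the bin width so the F landscape localises sharply
  bands <- list(chromophore_band(1210, 16, "lipid1210"))
  amp <- function(a) { v <- a; names(v) <- "lipid1210"; v }
  cfg <- synthetic_config(
    list(c1 = list(amplitudes = amp(0.1), baseline = 1),
         c2 = list(amplitudes = amp(0.6), baseline = 1)),
    bands, n_per_class = 100, noise_sd = 0.004,
    grid = list(start = 1100, junction = 1400, end = 1700,
                fine_bin = 2, coarse_bin = 4), seed = 9)
  d <- generate_dataset(cfg)$dataset
  y <- make_ovr_labels(d, "c2")
  # independent brute-force F over all bins via group means/variances
  f_oracle <- apply(d$intensities, 2, function(x) {
    m0 <- mean(x[y == 0]); m1 <- mean(x[y == 1]); n0 <- sum(y == 0); n1 <- sum(y == 1)
    gm <- mean(x)
    (n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2) /
      ((sum((x[y == 0] - m0)^2) + sum((x[y == 1] - m1)^2)) / (n0 + n1 - 2))
  })
  peak_nm <- d$wavelengths[which.max(f_oracle)]
  expect_lte(abs(peak_nm - 1210), 2 + 1e-9)  # within one fine bin
  expect_equal(unname(f_oracle), anova_f_relevance(d$intensities, y),
               tolerance = 1e-8)
})

test_that("default configuration matches the instrument grid and classes", {
  cfg <- default_ewdrs_config(n_per_class = 3, seed = 1)
  d <- generate_dataset(cfg)$dataset
  expected_bins <- (1100 - 355) / 0.76 + (1850 - 1100) / 1.6
  expect_lt(abs(length(d$wavelengths) - expected_bins), 3)
  expect_setequal(unique(d$labels),
                  c("boneCement", "boneMarrow", "cartilage", "cortBone",
                    "muscle", "traBone"))
  # fine bins below the junction, coarse above
  below <- diff(d$wavelengths[d$wavelengths < 1099])
  above <- diff(d$wavelengths[d$wavelengths >= 1100])
  expect_equal(unique(round(below, 6)), 0.76)
  expect_equal(unique(round(above, 6)), 1.6)
})

test_that("bone cement carries no chromophore dips", {
  cfg <- default_ewdrs_config(n_per_class = 2, noise_sd = 0,
                              scale_jitter_sd = 0, amp_jitter_sd = 0)
  d <- generate_dataset(cfg)$dataset
  cement <- d$intensities[d$labels == "boneCement", ][1, ]
  # cement rows are a pure scaled baseline: flat after dividing the shape out
  ratio <- cement / specsel:::baseline_shape(d$wavelengths)
  expect_lt(diff(range(ratio)), 1e-12)
  marrow <- d$intensities[d$labels == "boneMarrow", ][1, ]
  ratio_m <- marrow / specsel:::baseline_shape(d$wavelengths)
  expect_gt(diff(range(ratio_m)), 0.1)  # tissue classes do have dips
})

test_that("config validation rejects degenerate inputs", {
  bands <- list(chromophore_band(700, 50, "b"))
  amp <- function(a) { v <- a; names(v) <- "b"; v }
  expect_error(synthetic_config(list(), bands), class = "specsel_config_error")
  expect_error(
    synthetic_config(list(x = list(amplitudes = amp(1), baseline = 1)), bands),
    class = "specsel_config_error")
  expect_error(
    synthetic_config(list(x = list(amplitudes = amp(-1), baseline = 1),
                          y = list(amplitudes = amp(1), baseline = 1)), bands),
    class = "specsel_config_error")
  expect_error(
    synthetic_config(list(x = list(amplitudes = amp(1), baseline = 0),
                          y = list(amplitudes = amp(1), baseline = 1)), bands),
    class = "specsel_config_error")
  expect_error(chromophore_band(700, -5, "bad"), class = "specsel_config_error")
})

test_that("planted truth lists bands differing per class pair and per task", {
  cfg <- small_band_config()
  g <- generate_dataset(cfg)
  pair <- g$ground_truth[["tissue1|tissue2"]]
  expect_setequal(vapply(pair, function(b) b$name, character(1)),
                  c("bandA", "bandB", "bandC"))
  t1 <- ovr_truth(cfg, "tissue1")
  expect_setequal(vapply(t1, function(b) b$name, character(1)),
                  c("bandA", "bandB", "bandC"))
  expect_error(ovr_truth(cfg, "nope"), class = "specsel_unknown_class")
})

test_that("band distance measures against the band extent", {
  b <- chromophore_band(1440, 110, "water")
  expect_equal(band_distance(c(1440, 1385, 1495), b), c(0, 0, 0))
  expect_equal(band_distance(c(1360, 1520), b), c(25, 25))
  expect_equal(bands_recovered(c(1515), list(b), slack_nm = 20), TRUE)
  expect_equal(bands_recovered(c(1516), list(b), slack_nm = 20), FALSE)
})

test_that("top F bin lies within one FWHM of a planted band (low noise)", {
  cfg <- small_band_config(n_per_class = 30, noise_sd = 0.005,
                           scale_jitter_sd = 0, amp_jitter_sd = 0, seed = 5)
  d <- generate_dataset(cfg)$dataset
  y <- make_ovr_labels(d, "tissue2")
  f <- anova_f_relevance(d$intensities, y)
  top_nm <- d$wavelengths[which.max(f)]
  dists <- vapply(ovr_truth(cfg, "tissue2"),
                  function(b) abs(top_nm - b$center) <= b$fwhm, logical(1))
  expect_true(any(dists))
})
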