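# Preprocessing chain: averaging, calibration, splicing, smoothing, file IO.

ax <- seq(400, 499, by = 1)

test_that("average_repeats is the element-wise mean and checks axes", {
  s <- spectrum(ax, sin(ax / 10))
  expect_equal(average_repeats(rep(list(s), 5))$values, s$values)
  neg <- spectrum(ax, -s$values)
  expect_equal(average_repeats(list(s, neg))$values, rep(0, length(ax)))
  one_bin <- lapply(1:5, function(v) spectrum(500, v))
  expect_equal(average_repeats(one_bin)$values, 3.0)
  other <- spectrum(ax + 1, s$values)
  expect_error(average_repeats(list(s, other)), class = "specsel_axis_mismatch")
  expect_error(average_repeats(list()), class = "specsel_param_error")
})

test_that("calibrate computes (raw-bkgd)/(ref-bkgd) without clipping", {
  tr <- calibration_triple(spectrum(500, 5), spectrum(500, 9), spectrum(500, 1))
  expect_equal(calibrate(tr)$values, 0.5)
  raw <- spectrum(ax, runif(length(ax), 1, 2))
  bkgd <- spectrum(ax, rep(0.5, length(ax)))
  expect_equal(calibrate(calibration_triple(raw, raw, bkgd))$values,
               rep(1, length(ax)))
  expect_equal(calibrate(calibration_triple(bkgd, raw, bkgd))$values,
               rep(0, length(ax)))
  # values above 1 are preserved (no clipping)
  hot <- spectrum(500, 20)
  expect_equal(calibrate(calibration_triple(hot, spectrum(500, 10),
                                            spectrum(500, 0)))$values, 2)
  bad_ref <- spectrum(ax, c(rep(2, 50), 0.4, rep(2, 49)))
  err <- tryCatch(calibrate(calibration_triple(raw, bad_ref, bkgd)),
                  error = function(e) e)
  expect_s3_class(err, "specsel_degenerate_reference")
  expect_match(conditionMessage(err), "bin 51")
})

test_that("splice reproduces smooth functions across the junction", {
  lo_ax <- seq(355, 1100, by = 0.76)
  hi_ax <- seq(1100, 1850, by = 1.6)
  f_lin <- function(x) 0.3 + 0.0004 * x
  out <- splice(spectrum(lo_ax, f_lin(lo_ax)), spectrum(hi_ax, f_lin(hi_ax)))
  expect_lt(max(abs(out$values - f_lin(out$wavelengths))), 1e-9)
  # mixed bin widths preserved either side of the junction
  expect_true(all(diff(out$wavelengths) > 0))
  f_quad <- function(x) 1 + 2e-4 * x - 3e-7 * (x - 1000)^2
  out2 <- splice(spectrum(lo_ax, f_quad(lo_ax)), spectrum(hi_ax, f_quad(hi_ax)))
  expect_lt(max(abs(out2$values - f_quad(out2$wavelengths))), 1e-9)
  expect_error(splice(spectrum(seq(355, 1040, 1), rep(1, 686)),
                      spectrum(seq(1160, 1850, 2), rep(1, 346))),
               class = "specsel_gap_error")
})

test_that("Savitzky-Golay smoothing is exact for quadratics and linear", {
  n <- 60
  wl <- seq(400, by = 2, length.out = n)
  quad <- 2 + 0.05 * wl - 1e-4 * wl^2
  d <- spectral_dataset(wl, rbind(quad, rep(1.5, n)), c("q", "c"))
  sm <- smooth_sg(d, frame = 5, polyorder = 2)
  expect_lt(max(abs(sm$intensities[1, ] - quad)), 1e-9)
  expect_lt(max(abs(sm$intensities[2, ] - 1.5)), 1e-9)
  # linearity: sg(a x + b y) = a sg(x) + b sg(y)
  set.seed(7)
  x <- rnorm(n); y <- rnorm(n)
  sg <- function(v) smooth_sg(spectral_dataset(wl, matrix(v, 1), "r"))$intensities[1, ]
  expect_lt(max(abs(sg(2 * x - 3 * y) - (2 * sg(x) - 3 * sg(y)))), 1e-9)
  expect_error(smooth_sg(d, frame = 4), class = "specsel_param_error")
  expect_error(smooth_sg(d, frame = 61), class = "specsel_param_error")
  expect_error(smooth_sg(d, frame = 5, polyorder = 5), class = "specsel_param_error")
})

test_that("SG impulse response matches hand-computed least-squares weights", {
  # derive the frame-5 order-2 central weight from the local polynomial fit
  A <- outer(-2:2, 0:2, "^")
  H <- A %*% solve(crossprod(A), t(A))
  w_centre <- H[3, 3]
  n <- 41
  wl <- seq(500, by = 1, length.out = n)
  quad <- 1 + 0.01 * wl - 2e-5 * wl^2
  imp <- quad; j <- 21
  imp[j] <- imp[j] + 1
  sm <- smooth_sg(spectral_dataset(wl, matrix(imp, 1), "r"))$intensities[1, ]
  expect_equal(sm[j] - quad[j], w_centre, tolerance = 1e-9)
  expect_lt(abs(sm[j] - quad[j]), 1)  # impulse shrinks toward the quadratic
})

test_that("dataset IO round-trips values and labels", {
  d <- tiny_dataset(m = 7, n = 5, classes = c("x", "y", "z"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- read_dataset(path)
  expect_equal(d2$wavelengths, d$wavelengths)
  expect_equal(d2$intensities, d$intensities)
  expect_equal(d2$labels, d$labels)
  # header-driven shape bookkeeping
  writeLines(c("label,400.0,401.6", "a,1,2", "b,3,4"), path)
  d3 <- read_dataset(path)
  expect_equal(dim(d3$intensities), c(2L, 2L))
  expect_equal(d3$wavelengths, c(400, 401.6))
  writeLines(c("label,400.0,401.6", "a,1,2", "b,3"), path)
  expect_error(read_dataset(path), class = "specsel_format_error")
  writeLines(c("label,abc,401.6", "a,1,2"), path)
  expect_error(read_dataset(path), class = "specsel_format_error")
})

test_that("dataset invariants are enforced", {
  expect_error(spectral_dataset(c(2, 1), matrix(0, 1, 2), "a"),
               class = "specsel_format_error")
  expect_error(spectral_dataset(c(1, 2), matrix(0, 1, 3), "a"),
               class = "specsel_format_error")
  expect_error(spectral_dataset(c(1, 2), matrix(0, 2, 2), "a"),
               class = "specsel_format_error")
  expect_error(spectral_dataset(c(1, 2), matrix(c(NA, 0, 0, 0), 2, 2), c("a", "b")),
               class = "specsel_format_error")
})

test_that("full preprocessing chain runs end to end", {
  lo_ax <- seq(355, 1100, by = 4)
  hi_ax <- seq(1100, 1850, by = 8)
  shape <- function(x) 0.6 + 0.3 * exp(-((x - 1000) / 500)^2)
  mk <- function(ax, scale) spectrum(ax, scale * shape(ax))
  out <- preprocess_measurement(
    low_repeats = lapply(c(.98, 1, 1.02), function(s) mk(lo_ax, 60 * s)),
    high_repeats = lapply(c(.99, 1, 1.01), function(s) mk(hi_ax, 40 * s)),
    low_ref = mk(lo_ax, 100), low_bkgd = spectrum(lo_ax, rep(2, length(lo_ax))),
    high_ref = mk(hi_ax, 80), high_bkgd = spectrum(hi_ax, rep(1, length(hi_ax))))
  expect_s3_class(out, "spectrum")
  expect_true(all(is.finite(out$values)))
  expect_equal(length(out$values), length(out$wavelengths))
})
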