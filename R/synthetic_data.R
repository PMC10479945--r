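# Synthetic extended-wavelength DRS generator. Spectra follow a
# Beer-Lambert-style multiplicative model: a smooth broadband baseline,
# scaled per class, attenuated by Gaussian chromophore absorption bands with
# class-specific amplitudes, plus additive Gaussian noise. The band
# amplitudes that differ between classes are the planted ground truth that
# the selection frameworks are expected to recover.

#' Chromophore absorption band
#'
#' @param center band centre in nm.
#' @param fwhm full width at half maximum in nm (> 0).
#' @param name chromophore label, e.g. "lipid1210".
#' @return object of class `chromophore_band`.
#' @export
chromophore_band <- function(center, fwhm, name) {
  if (fwhm <= 0) stop_specsel("fwhm must be positive", "specsel_config_error")
  structure(list(center = center, fwhm = fwhm, name = name),
            class = "chromophore_band")
}

# Unit-height Gaussian profile of a band evaluated on an axis.
band_profile <- function(band, wavelengths) {
  sigma <- band$fwhm / (2 * sqrt(2 * log(2)))
  exp(-((wavelengths - band$center)^2) / (2 * sigma^2))
}

#' Synthetic dataset configuration
#'
#' @param class_specs named list, one entry per class, each a list with
#'   `amplitudes` (named numeric vector over the band library, absorbance
#'   units) and `baseline` (positive scalar intensity scale).
#' @param bands list of [chromophore_band()] objects (the band library).
#' @param n_per_class measurements per class.
#' @param noise_sd additive noise standard deviation (reflectance units).
#' @param scale_jitter_sd sd of the per-measurement log-normal intensity
#'   scale factor (probe-coupling variability); 0 disables it.
#' @param amp_jitter_sd sd of the per-measurement log-normal multiplier on
#'   every band amplitude (between-specimen chromophore variability); 0
#'   disables it.
#' @param grid list with `start`, `junction`, `end` (nm) and `fine_bin`,
#'   `coarse_bin` (nm) describing the dual-spectrometer axis.
#' @param seed integer seed governing all draws.
#' @param truth_tol amplitude difference below which two classes are treated
#'   as sharing a band (used when listing planted differing bands).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(class_specs, bands, n_per_class = 100,
                             noise_sd = 0.02, scale_jitter_sd = 0,
                             amp_jitter_sd = 0,
                             grid = list(start = 355, junction = 1100, end = 1850,
                                         fine_bin = 0.76, coarse_bin = 1.6),
                             seed = 1, truth_tol = 0.05) {
  if (length(class_specs) < 2)
    stop_specsel("need at least two classes", "specsel_config_error")
  if (is.null(names(class_specs)) || any(names(class_specs) == ""))
    stop_specsel("class_specs must be a named list", "specsel_config_error")
  bn <- vapply(bands, function(b) b$name, character(1))
  for (cs in class_specs) {
    a <- cs$amplitudes
    if (!all(is.finite(a)) || any(a < 0))
      stop_specsel("band amplitudes must be finite and non-negative", "specsel_config_error")
    if (!all(names(a) %in% bn))
      stop_specsel("amplitude names must match the band library", "specsel_config_error")
    if (is.null(cs$baseline) || cs$baseline <= 0)
      stop_specsel("baseline scale must be positive", "specsel_config_error")
  }
  ax <- synthetic_axis(grid)
  if (any(diff(ax) <= 0))
    stop_specsel("grid must produce a strictly increasing axis", "specsel_config_error")
  structure(list(class_specs = class_specs, bands = bands,
                 n_per_class = n_per_class, noise_sd = noise_sd,
                 scale_jitter_sd = scale_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd, grid = grid,
                 seed = seed, truth_tol = truth_tol),
            class = "synthetic_config")
}

# Dual-resolution axis: fine bins below the junction, coarse bins above.
synthetic_axis <- function(grid) {
  fine <- seq(grid$start, grid$junction - 1e-9, by = grid$fine_bin)
  coarse <- seq(grid$junction, grid$end, by = grid$coarse_bin)
  c(fine, coarse)
}

#' Default six-class extended-wavelength DRS configuration
#'
#' Emulates an orthopedic DRS study design: six classes (bone cement, bone
#' marrow, cartilage, cortical bone, muscle, trabecular bone) on a
#' 355-1850 nm axis with ~0.76 nm bins below 1100 nm and 1.6 nm above.
#' Chromophore bands: hemoglobin at 550/576 nm, collagen at 1200/1500/1725
#' nm, lipid at 1210 nm, water at 1440 nm. Bone cement carries no
#' chromophore absorption (a non-biological acrylic) and is separated from
#' tissue mainly by overall signal intensity; tissue classes differ in both
#' band depth and baseline scale. Amplitudes are absorbance-like units
#' chosen to caricature the relative chromophore content of each tissue
#' (marrow lipid-rich, cartilage water/collagen-rich, muscle blood-rich,
#' cortical bone collagen-rich). Per-measurement intensity jitter emulates
#' probe-coupling variability; together with the additive noise floor it
#' leaves the hardest one-versus-rest task (cortical bone) around 95%
#' separable with all features, while bone cement stays fully separable.
#'
#' @param n_per_class measurements per class (default 100).
#' @param noise_sd additive noise sd (default 0.02).
#' @param scale_jitter_sd per-measurement log-scale intensity sd (default 0.08).
#' @param amp_jitter_sd per-measurement log-scale band-amplitude sd
#'   (default 0.30, calibrated so the cortical-bone task sits near 95%
#'   separability with all features).
#' @param seed integer seed.
#' @return a `synthetic_config`.
#' @export
default_ewdrs_config <- function(n_per_class = 100, noise_sd = 0.02,
                                 scale_jitter_sd = 0.08, amp_jitter_sd = 0.30,
                                 seed = 1) {
  bands <- list(
    chromophore_band(550, 40, "Hb550"),
    chromophore_band(576, 30, "Hb576"),
    chromophore_band(1200, 60, "collagen1200"),
    chromophore_band(1210, 40, "lipid1210"),
    chromophore_band(1440, 110, "water1440"),
    chromophore_band(1500, 90, "collagen1500"),
    chromophore_band(1725, 60, "collagen1725"))
  amp <- function(...) {
    a <- c(...)
    names(a) <- c("Hb550", "Hb576", "collagen1200", "lipid1210",
                  "water1440", "collagen1500", "collagen1725")
    a
  }
  class_specs <- list(
    boneCement = list(amplitudes = amp(0, 0, 0, 0, 0, 0, 0), baseline = 1.10),
    boneMarrow = list(amplitudes = amp(.10, .10, .05, .80, .35, .05, .15), baseline = 1.00),
    cartilage  = list(amplitudes = amp(.05, .05, .10, .10, .65, .30, .10), baseline = 0.90),
    cortBone   = list(amplitudes = amp(.15, .30, .15, .65, .35, .55, .45), baseline = 1.05),
    muscle     = list(amplitudes = amp(.55, .60, .10, .15, .60, .10, .05), baseline = 0.80),
    traBone    = list(amplitudes = amp(.25, .30, .15, .65, .30, .35, .20), baseline = 0.95))
  synthetic_config(class_specs, bands, n_per_class = n_per_class,
                   noise_sd = noise_sd, scale_jitter_sd = scale_jitter_sd,
                   amp_jitter_sd = amp_jitter_sd, seed = seed)
}

# Smooth broadband baseline shape shared by all classes (lamp spectrum x
# tissue scattering): slowly varying, peaking in the NIR.
baseline_shape <- function(wavelengths) {
  0.55 + 0.45 * exp(-((wavelengths - 1000) / 700)^2)
}

#' Generate a synthetic spectral dataset with planted ground truth
#'
#' Each row of class c is
#' `s_i * baseline_c(lambda) * exp(-sum_b a_cb * G(lambda; center_b, fwhm_b)) + eps`
#' with unit-height Gaussian band profiles G, iid Gaussian noise eps, and a
#' per-measurement intensity factor `s_i = exp(N(0, scale_jitter_sd^2))`
#' emulating probe-coupling variability (identically 1 when
#' `scale_jitter_sd = 0`). Deterministic given `cfg$seed`.
#'
#' @param cfg a `synthetic_config`.
#' @return list with `dataset` (a `spectral_dataset`) and `ground_truth`:
#'   for every unordered class pair, the bands whose amplitudes differ by
#'   more than `cfg$truth_tol`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!length(cfg$class_specs)) stop_specsel("empty class_specs", "specsel_config_error")
  ax <- synthetic_axis(cfg$grid)
  base <- baseline_shape(ax)
  profiles <- vapply(cfg$bands, band_profile, numeric(length(ax)), wavelengths = ax)
  colnames(profiles) <- vapply(cfg$bands, function(b) b$name, character(1))
  classes <- names(cfg$class_specs)
  m <- cfg$n_per_class * length(classes)
  X <- matrix(0, m, length(ax))
  labels <- character(m)
  with_seed(cfg$seed, {
    row <- 1L
    for (cl in classes) {
      cs <- cfg$class_specs[[cl]]
      a <- rep(0, length(cfg$bands)); names(a) <- colnames(profiles)
      a[names(cs$amplitudes)] <- cs$amplitudes
      for (i in seq_len(cfg$n_per_class)) {
        s_i <- if (cfg$scale_jitter_sd > 0)
          exp(stats::rnorm(1, 0, cfg$scale_jitter_sd)) else 1
        a_i <- if (cfg$amp_jitter_sd > 0)
          a * exp(stats::rnorm(length(a), 0, cfg$amp_jitter_sd)) else a
        clean <- cs$baseline * base * exp(-as.numeric(profiles %*% a_i))
        X[row, ] <- s_i * clean + stats::rnorm(length(ax), 0, cfg$noise_sd)
        labels[row] <- cl
        row <- row + 1L
      }
    }
  })
  truth <- planted_truth(cfg)
  list(dataset = spectral_dataset(ax, X, labels,
                                  meta = list(generator = "specsel_synthetic",
                                              seed = cfg$seed)),
       ground_truth = truth)
}

# Bands whose amplitudes differ (beyond tol) for each unordered class pair.
planted_truth <- function(cfg) {
  classes <- names(cfg$class_specs)
  bn <- vapply(cfg$bands, function(b) b$name, character(1))
  ampmat <- matrix(unlist(lapply(classes, function(cl) {
    a <- rep(0, length(bn)); names(a) <- bn
    a[names(cfg$class_specs[[cl]]$amplitudes)] <- cfg$class_specs[[cl]]$amplitudes
    a
  })), nrow = length(bn))
  out <- list()
  for (i in seq_along(classes)) for (j in seq_along(classes)) if (i < j) {
    diff_b <- bn[abs(ampmat[, i] - ampmat[, j]) > cfg$truth_tol]
    out[[paste(classes[i], classes[j], sep = "|")]] <-
      cfg$bands[match(diff_b, bn)]
  }
  out
}

#' Distance from wavelengths to a band's spectral extent
#'
#' Minimum nm distance from each wavelength to the band's extent
#' (center +/- fwhm/2); 0 inside the band. A band is an extended absorption
#' feature, so localization is measured against its span, not its center.
#'
#' @param nm numeric vector of wavelengths.
#' @param band a `chromophore_band`.
#' @return numeric vector of distances (nm).
#' @export
band_distance <- function(nm, band) {
  lo <- band$center - band$fwhm / 2
  hi <- band$center + band$fwhm / 2
  pmax(0, pmax(lo - nm, nm - hi))
}

#' Check recovery of planted bands by a selection
#'
#' @param nm selected wavelengths.
#' @param bands list of `chromophore_band` (e.g. from [ovr_truth()]).
#' @param slack_nm allowed distance beyond the band extent (default 20).
#' @return logical vector, one per band: TRUE when some selected wavelength
#'   lies within `slack_nm` of the band.
#' @export
bands_recovered <- function(nm, bands, slack_nm = 20) {
  vapply(bands, function(b) any(band_distance(nm, b) <= slack_nm), logical(1))
}

#' Bands a one-versus-rest task must recover
#'
#' The planted bands whose amplitude in the positive class differs (beyond
#' `truth_tol`) from its amplitude in *every* other class: any classifier
#' separating the positive class from the pooled rest has signal at these
#' bands regardless of which rest class is nearby.
#'
#' @param cfg a `synthetic_config`.
#' @param positive_class class name.
#' @return list of `chromophore_band` objects.
#' @export
ovr_truth <- function(cfg, positive_class) {
  classes <- names(cfg$class_specs)
  if (!positive_class %in% classes)
    stop_specsel("unknown positive class", "specsel_unknown_class")
  bn <- vapply(cfg$bands, function(b) b$name, character(1))
  getamp <- function(cl) {
    a <- rep(0, length(bn)); names(a) <- bn
    a[names(cfg$class_specs[[cl]]$amplitudes)] <- cfg$class_specs[[cl]]$amplitudes
    a
  }
  pos <- getamp(positive_class)
  others <- matrix(unlist(lapply(setdiff(classes, positive_class), getamp)),
                   nrow = length(bn))
  keep <- apply(abs(others - pos) > cfg$truth_tol, 1, all)
  cfg$bands[keep]
}
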