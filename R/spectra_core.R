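# Data model and preprocessing chain for diffuse reflectance spectra:
# repeat averaging, reflectance calibration against a standard, splicing of
# the two spectrometer channels, and Savitzky-Golay smoothing.

#' Construct a single spectrum
#'
#' A spectrum is a wavelength axis (nm, strictly increasing) paired with one
#' intensity value per bin.
#'
#' @param wavelengths strictly increasing numeric vector of nm values.
#' @param values numeric vector, same length as `wavelengths`.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelengths, values) {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop_specsel("wavelengths and values must have equal length", "specsel_format_error")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop_specsel("wavelength axis must be strictly increasing", "specsel_format_error")
  structure(list(wavelengths = wavelengths, values = values), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d bins, %.1f-%.1f nm>\n", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Construct a labelled spectral dataset
#'
#' The central container: an m x n intensity matrix (rows = measurements,
#' columns = wavelength bins), a strictly increasing wavelength axis in nm,
#' and one class label per row.
#'
#' @param wavelengths strictly increasing numeric axis (nm), length n.
#' @param intensities numeric m x n matrix of (relative) reflectance.
#' @param labels character/factor vector of length m.
#' @param meta optional named list of free-form annotations.
#' @return object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(wavelengths, intensities, labels, meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.matrix(intensities)
  labels <- as.character(labels)
  if (any(diff(wavelengths) <= 0))
    stop_specsel("wavelength axis must be strictly increasing", "specsel_format_error")
  if (ncol(intensities) != length(wavelengths))
    stop_specsel("column count must equal wavelength count", "specsel_format_error")
  if (nrow(intensities) != length(labels))
    stop_specsel("label count must equal row count", "specsel_format_error")
  if (anyNA(intensities) || anyNA(labels))
    stop_specsel("dataset must not contain missing values", "specsel_format_error")
  dimnames(intensities) <- NULL
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 labels = labels, meta = meta),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset: %d samples x %d bins, %.1f-%.1f nm>\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$wavelengths), max(x$wavelengths)))
  tab <- table(x$labels)
  cat("  classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a spectral dataset
#'
#' @param d a `spectral_dataset`.
#' @param rows optional row index vector.
#' @param cols optional column (wavelength bin) index vector.
#' @return a `spectral_dataset`.
#' @export
subset_dataset <- function(d, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(nrow(d$intensities))
  cols <- cols %||% seq_along(d$wavelengths)
  spectral_dataset(d$wavelengths[cols], d$intensities[rows, cols, drop = FALSE],
                   d$labels[rows], d$meta)
}

#' Average repeated acquisitions
#'
#' Element-wise arithmetic mean over repeats taken at one location; all
#' repeats must share the same wavelength axis.
#'
#' @param repeats list of `spectrum` objects over one axis.
#' @return a `spectrum` of the same axis.
#' @export
average_repeats <- function(repeats) {
  if (length(repeats) < 1) stop_specsel("need at least one repeat", "specsel_param_error")
  ax <- repeats[[1]]$wavelengths
  for (r in repeats)
    if (length(r$wavelengths) != length(ax) || any(r$wavelengths != ax))
      stop_specsel("repeats must share one wavelength axis", "specsel_axis_mismatch")
  M <- matrix(unlist(lapply(repeats, `[[`, "values")), nrow = length(ax))
  spectrum(ax, rowMeans(M))
}

#' Calibration triple
#'
#' Bundles the raw measurement, the reflectance-standard reference, and the
#' dark/background spectrum over one common axis.
#'
#' @param raw,ref,bkgd `spectrum` objects on the same axis.
#' @return object of class `calibration_triple`.
#' @export
calibration_triple <- function(raw, ref, bkgd) {
  ax <- raw$wavelengths
  for (s in list(ref, bkgd))
    if (length(s$wavelengths) != length(ax) || any(s$wavelengths != ax))
      stop_specsel("raw/ref/bkgd must share one wavelength axis", "specsel_axis_mismatch")
  structure(list(raw = raw, ref = ref, bkgd = bkgd), class = "calibration_triple")
}

#' Reflectance calibration
#'
#' Standard dark-corrected reflectance: (raw - bkgd) / (ref - bkgd),
#' element-wise. Values are deliberately not clipped to \[0, 1\]: downstream
#' selection methods are scale-tolerant and clipping would bias peak picking.
#'
#' @param t a `calibration_triple`.
#' @return a calibrated `spectrum`.
#' @export
calibrate <- function(t) {
  stopifnot(inherits(t, "calibration_triple"))
  denom <- t$ref$values - t$bkgd$values
  bad <- which(denom <= 0)
  if (length(bad))
    stop_specsel(sprintf("reference minus background is not positive at bin %d (%.2f nm)",
                         bad[1], t$raw$wavelengths[bad[1]]), "specsel_degenerate_reference")
  spectrum(t$raw$wavelengths, (t$raw$values - t$bkgd$values) / denom)
}

#' Splice specification
#'
#' Defines how the two spectrometer channels are merged: the junction
#' wavelength, the unified target axis, and the spline used to resample.
#' When `target_axis` is NULL it is built at splice time from the two native
#' grids (duplicates within half the coarse bin width of the junction are
#' dropped; the low band wins at the junction bin).
#'
#' @param junction_nm junction wavelength in nm (default 1100).
#' @param target_axis optional strictly increasing unified axis.
#' @param order spline interpolation order; 3 = cubic (the only order
#'   implemented, matching standard practice).
#' @return object of class `splice_spec`.
#' @export
splice_spec <- function(junction_nm = 1100, target_axis = NULL, order = 3) {
  if (!is.null(target_axis) && any(diff(target_axis) <= 0))
    stop_specsel("target_axis must be strictly increasing", "specsel_param_error")
  structure(list(junction_nm = junction_nm, target_axis = target_axis, order = order),
            class = "splice_spec")
}

#' Splice two spectrometer channels into one spectrum
#'
#' Bins below the junction are interpolated from the low band's cubic
#' spline, bins at/above from the high band's. Both bands must reach within
#' `gap_tol_nm` of the junction, otherwise a gap error is raised.
#'
#' @param low_band,high_band `spectrum` objects covering the ranges below and
#'   above the junction.
#' @param spec a `splice_spec`.
#' @param gap_tol_nm maximum allowed distance (nm) between a band's end and
#'   the junction before it is considered non-adjacent.
#' @return a `spectrum` on the target axis.
#' @export
splice <- function(low_band, high_band, spec = splice_spec(), gap_tol_nm = 10) {
  j <- spec$junction_nm
  if (max(low_band$wavelengths) < j - gap_tol_nm ||
      min(high_band$wavelengths) > j + gap_tol_nm)
    stop_specsel(sprintf("bands do not cover the junction at %.1f nm", j),
                 "specsel_gap_error")
  axis <- spec$target_axis
  if (is.null(axis)) {
    lw <- low_band$wavelengths; hw <- high_band$wavelengths
    coarse <- stats::median(diff(hw))
    lo_keep <- lw[lw <= j]                 # low band wins at the junction bin
    hi_keep <- hw[hw > j]
    # drop high-band bins duplicating the end of the low band within half a
    # coarse bin width
    hi_keep <- hi_keep[hi_keep - max(lo_keep) > coarse / 2]
    axis <- c(lo_keep, hi_keep)
  }
  f_lo <- stats::splinefun(low_band$wavelengths, low_band$values, method = "natural")
  f_hi <- stats::splinefun(high_band$wavelengths, high_band$values, method = "natural")
  vals <- ifelse(axis <= j, f_lo(axis), f_hi(axis))
  spectrum(axis, vals)
}

#' Savitzky-Golay smoothing
#'
#' Applies an SG filter of odd frame length and given polynomial order to
#' each row independently along the wavelength axis. Shape is preserved;
#' boundary bins use the filter's least-squares polynomial edge fits, so any
#' polynomial of degree <= `polyorder` passes through unchanged.
#'
#' @param d a `spectral_dataset`.
#' @param frame odd integer window length (default 5).
#' @param polyorder polynomial order (default 2), must be < frame.
#' @return a smoothed `spectral_dataset`.
#' @export
smooth_sg <- function(d, frame = 5, polyorder = 2) {
  n <- length(d$wavelengths)
  if (frame %% 2 == 0 || frame >= n || polyorder >= frame)
    stop_specsel("frame must be odd, < number of bins, and > polyorder",
                 "specsel_param_error")
  sm <- t(apply(d$intensities, 1, function(row)
    signal::sgolayfilt(row, p = polyorder, n = frame)))
  spectral_dataset(d$wavelengths, sm, d$labels, d$meta)
}

#' Read a spectral dataset from a delimited table
#'
#' Expected layout: a header row whose first field is the label column name
#' and whose remaining fields are numeric wavelengths in nm; one row per
#' measurement with the class label first.
#'
#' @param path file path.
#' @param sep field delimiter ("," default; "\t" for TSV).
#' @return a `spectral_dataset`. A JSON sidecar `<path>.meta.json`, when
#'   present, is loaded into `meta`.
#' @export
read_dataset <- function(path, sep = ",") {
  lines <- readLines(path)
  if (!length(lines)) stop_specsel("empty file", "specsel_format_error")
  parts <- strsplit(lines, sep, fixed = TRUE)
  header <- parts[[1]]
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wl))
    stop_specsel("non-numeric wavelength header", "specsel_format_error")
  body <- parts[-1]
  nfield <- length(header)
  if (any(lengths(body) != nfield))
    stop_specsel("ragged rows in spectral table", "specsel_format_error")
  labels <- vapply(body, `[`, character(1), 1L)
  vals <- suppressWarnings(vapply(body, function(p) as.numeric(p[-1]), numeric(nfield - 1)))
  if (anyNA(vals)) stop_specsel("non-numeric intensity value", "specsel_format_error")
  meta <- list()
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  spectral_dataset(wl, if (nfield - 1 == 1) matrix(vals, ncol = 1) else t(vals),
                   labels, meta)
}

#' Write a spectral dataset to a delimited table
#'
#' Inverse of [read_dataset()]: labels in the first column, wavelengths in
#' the header, full double precision so write/read round-trips are lossless.
#'
#' @param d a `spectral_dataset`.
#' @param path output file path.
#' @param sep field delimiter.
#' @param meta_sidecar write `meta` to `<path>.meta.json` when non-empty.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path, sep = ",", meta_sidecar = TRUE) {
  header <- paste(c("label", sprintf("%.10g", d$wavelengths)), collapse = sep)
  rows <- vapply(seq_len(nrow(d$intensities)), function(i)
    paste(c(d$labels[i], sprintf("%.17g", d$intensities[i, ])), collapse = sep),
    character(1))
  writeLines(c(header, rows), path)
  if (meta_sidecar && length(d$meta))
    jsonlite::write_json(d$meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Full preprocessing chain for one measurement
#'
#' Mirrors the acquisition pipeline: average the repeats per channel,
#' calibrate each channel against its reference/background, splice the two
#' channels at the junction, then smooth.
#'
#' @param low_repeats,high_repeats lists of raw `spectrum` repeats for the
#'   low (fine) and high (coarse) channel.
#' @param low_ref,low_bkgd,high_ref,high_bkgd reference and background
#'   spectra per channel.
#' @param spec a `splice_spec`.
#' @param sg_frame,sg_poly Savitzky-Golay settings.
#' @return a preprocessed `spectrum`.
#' @export
preprocess_measurement <- function(low_repeats, high_repeats,
                                   low_ref, low_bkgd, high_ref, high_bkgd,
                                   spec = splice_spec(), sg_frame = 5, sg_poly = 2) {
  lo <- calibrate(calibration_triple(average_repeats(low_repeats), low_ref, low_bkgd))
  hi <- calibrate(calibration_triple(average_repeats(high_repeats), high_ref, high_bkgd))
  sp <- splice(lo, hi, spec)
  d <- spectral_dataset(sp$wavelengths, matrix(sp$values, nrow = 1), "unlabelled")
  sm <- smooth_sg(d, frame = sg_frame, polyorder = sg_poly)
  spectrum(sm$wavelengths, sm$intensities[1, ])
}
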