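# Internal helpers shared across modules.

#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library functions never perturb user randomness.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a parent seed and a stream label; keeps all
# derived seeds positive and below 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483563) + 1L
}

#' Nearest wavelength bin
#'
#' Index of the axis bin closest to `nm`; ties break toward the lower
#' wavelength so bookkeeping by nm value is deterministic on mixed grids.
#' @param wavelengths strictly increasing numeric axis (nm).
#' @param nm query wavelength(s) in nm.
#' @return integer index (vectorised over `nm`).
#' @export
nearest_bin <- function(wavelengths, nm) {
  vapply(nm, function(x) {
    d <- abs(wavelengths - x)
    which(d <= min(d) + 1e-12)[1L]  # lower wavelength wins ties
  }, integer(1))
}

stop_specsel <- function(msg, class) {
  stop(structure(class = c(class, "specsel_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
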