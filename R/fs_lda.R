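# Moving-window LDA framework: tile the axis with windows of several nm
# lengths, keep the largest-|coefficient| feature per window from a
# window-local LDA fit, deduplicate with a 30 nm separation rule, retain
# the top 75% by collinearity-aware ranking, and search the final subset
# by simulated annealing with an LDA CV cost.

#' Moving-window LDA candidates
#'
#' For each interval size the axis is tiled into consecutive windows; a
#' binary LDA is fitted on each window's features and the feature with the
#' largest absolute discriminant coefficient is kept. Picks are pooled over
#' all sizes and windows (relevance = |coefficient| from the window fit),
#' then duplicates and features within `min_sep_nm` of a higher-ranked one
#' are discarded.
#'
#' @param d_train training `spectral_dataset`.
#' @param y 0/1 labels for the training rows.
#' @param interval_sizes_nm window lengths in nm
#'   (default c(25, 50, 75, 100, 150, 200, 300)).
#' @param min_sep_nm separation rule applied to the pooled picks (default 30).
#' @return a `feature_subset` of candidates.
#' @export
lda_window_candidates <- function(d_train, y,
                                  interval_sizes_nm = c(25, 50, 75, 100, 150, 200, 300),
                                  min_sep_nm = 30) {
  wl <- d_train$wavelengths
  if (diff(range(wl)) < max(interval_sizes_nm))
    stop_specsel("dataset must span the largest interval", "specsel_param_error")
  X <- d_train$intensities
  idx <- integer(0); coefs <- numeric(0)
  for (size in interval_sizes_nm) {
    grid <- interval_grid(wl, size)
    for (cols in grid$intervals) {
      keep <- cols[apply(X[, cols, drop = FALSE], 2, stats::sd) > 1e-12]
      if (!length(keep)) { warning("window with only zero-variance features skipped"); next }
      fit <- tryCatch(suppressWarnings(MASS::lda(X[, keep, drop = FALSE],
                                                 grouping = factor(y, levels = c(0, 1)))),
                      error = function(e) NULL)
      if (is.null(fit)) next
      co <- abs(fit$scaling[, 1])
      best <- which.max(co)
      idx <- c(idx, keep[best]); coefs <- c(coefs, co[best])
    }
  }
  if (!length(idx))
    stop_specsel("no usable windows", "specsel_param_error")
  # pool: per bin keep the largest coefficient seen
  ord <- order(-coefs, wl[idx])
  idx <- idx[ord]; coefs <- coefs[ord]
  first <- !duplicated(idx)
  cand <- feature_subset(idx[first], wl[idx[first]], coefs[first],
                         source = "lda>windows")
  min_separation_filter(cand, min_sep_nm)
}

#' Retain the top fraction of candidates by collinearity-aware ranking
#'
#' A binary LDA is refitted on the candidate set; its absolute coefficients
#' are the relevance for greedy collinearity removal keeping
#' `ceiling(fraction * n_candidates)` features.
#'
#' @param candidates a `feature_subset`.
#' @param X data matrix over the full axis.
#' @param y 0/1 labels.
#' @param fraction fraction to retain (default 0.75).
#' @return a `feature_subset`.
#' @export
retain_top_fraction <- function(candidates, X, y, fraction = 0.75) {
  if (!length(candidates$indices))
    stop_specsel("empty candidate set", "specsel_param_error")
  keep_n <- ceiling(fraction * length(candidates$indices))
  fit <- suppressWarnings(MASS::lda(X[, candidates$indices, drop = FALSE],
                                    grouping = factor(y, levels = c(0, 1))))
  rel <- abs(fit$scaling[, 1])
  out <- sequential_collinearity_removal(candidates, X, relevance = rel,
                                         k = keep_n)
  out$source <- "lda>top_fraction"
  out
}

#' Run the moving-window LDA selection framework
#'
#' Pipeline: stratified split; window candidates over the seven interval
#' sizes with the 30 nm rule; top-75% retention by collinearity-aware
#' ranking; simulated annealing (2000 iterations, always activated) over
#' the retained pool maximising LDA CV balanced accuracy; final subset of
#' size k.
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class of the OVR task.
#' @param k final subset size (default 10).
#' @param protocol an `eval_protocol`.
#' @param sa an `sa_config` (default 2000 iterations, always activated).
#' @param interval_sizes_nm window sizes in nm.
#' @param fraction retained fraction (default 0.75).
#' @return a `selection_report`.
#' @export
run_lda_framework <- function(d, positive_class, k = 10, protocol = eval_protocol(),
                              sa = NULL,
                              interval_sizes_nm = c(25, 50, 75, 100, 150, 200, 300),
                              fraction = 0.75) {
  t0 <- proc.time()[3]
  sp <- stratified_split(d, protocol$holdout_frac, protocol$seed)
  y <- make_ovr_labels(sp$train, positive_class)
  cand <- lda_window_candidates(sp$train, y, interval_sizes_nm = interval_sizes_nm)
  retained <- retain_top_fraction(cand, sp$train$intensities, y, fraction = fraction)
  warn <- character(0)
  sa <- sa %||% sa_config(iterations = 2000, seed = derive_seed(protocol$seed, "lda_sa"),
                          early_stop_on_perfect = FALSE)
  if (length(retained$indices) <= k) {
    warn <- sprintf("retained pool has only %d candidates (<= k = %d); returning pool",
                    length(retained$indices), k)
    final <- retained
    sel <- NULL
  } else {
    cost <- make_cv_cost(sp$train$intensities, y, folds = 3, repeats = 1,
                         seed = derive_seed(protocol$seed, "lda_cost"))
    sel <- sa_select(retained, k, function(pos) cost(retained$indices[pos]), sa)
    final <- sel$subset
  }
  final$source <- "lda"
  build_report("lda", d, sp, final, positive_class, protocol, k,
               runtime = proc.time()[3] - t0, warnings = warn,
               extra = list(candidates = cand, retained = retained,
                            sa_trace = if (!is.null(sel)) sel$trace else numeric(0)))
}
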