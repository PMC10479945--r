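# Backward interval PLS framework: tile the axis into nm-sized intervals,
# recursively eliminate the interval whose removal lowers RMSECV most,
# repeat over interval sizes and fixed CV shuffles, vote for the surviving
# bins, and finish with a VIP-ranked least-collinear subset.

#' Tile the wavelength axis into intervals of a given nm size
#'
#' Intervals are consecutive half-open nm ranges from the axis start; each
#' is stored as a (start, end) pair of bin indices. Intervals are disjoint
#' and cover the axis; on a mixed-resolution axis the bin count per interval
#' varies.
#'
#' @param wavelengths strictly increasing axis (nm).
#' @param size_nm interval length in nm.
#' @return object of class `interval_grid`: list with `size_nm` and
#'   `intervals`, a list of integer index vectors.
#' @export
interval_grid <- function(wavelengths, size_nm) {
  if (size_nm <= 0) stop_specsel("size_nm must be positive", "specsel_param_error")
  edges <- seq(min(wavelengths), max(wavelengths) + size_nm, by = size_nm)
  cut_id <- findInterval(wavelengths, edges, rightmost.closed = FALSE)
  ids <- sort(unique(cut_id))
  intervals <- lapply(ids, function(i) which(cut_id == i))
  structure(list(size_nm = size_nm, intervals = intervals), class = "interval_grid")
}

#' Backward interval elimination by RMSECV
#'
#' Starting from the all-interval baseline, repeatedly deletes the interval
#' whose removal yields the lowest RMSECV, while that best deletion still
#' improves on the current baseline. Stops when no deletion improves, or
#' when a single interval remains (or `min_intervals` is reached).
#'
#' @param X predictor matrix over the full axis slice.
#' @param y01 0/1-coded response.
#' @param grid an `interval_grid` over the columns of X.
#' @param cv_shuffle fixed fold assignment for all RMSECV evaluations.
#' @param max_components PLS component budget per regression.
#' @param min_intervals elimination floor (default 1).
#' @return list with `retained` (indices into `grid$intervals`), `trace`
#'   (data.frame of step, eliminated interval, RMSECV), and `baseline_rmse`.
#' @export
bipls_eliminate <- function(X, y01, grid, cv_shuffle, max_components = 30,
                            min_intervals = 1) {
  n_int <- length(grid$intervals)
  if (n_int < 2) stop_specsel("need >= 2 intervals", "specsel_param_error")
  if (all(apply(X, 2, stats::sd) < 1e-12))
    stop_specsel("X has zero variance everywhere", "specsel_param_error")
  remaining <- seq_len(n_int)
  cols_of <- function(ints) sort(unlist(grid$intervals[ints]))
  evaluator <- make_rmsecv_evaluator(X, y01, cv_shuffle, max_components)
  base <- evaluator(cols_of(remaining))$best_rmse
  baseline_rmse <- base
  trace <- data.frame(step = integer(0), eliminated = integer(0), rmsecv = numeric(0))
  step <- 0L
  while (length(remaining) > min_intervals) {
    cand_rmse <- vapply(remaining, function(i) {
      evaluator(cols_of(setdiff(remaining, i)))$best_rmse
    }, numeric(1))
    best_pos <- which.min(cand_rmse)
    if (cand_rmse[best_pos] >= base) break  # no deletion improves the baseline
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     eliminated = remaining[best_pos],
                                     rmsecv = cand_rmse[best_pos]))
    base <- cand_rmse[best_pos]
    remaining <- remaining[-best_pos]
  }
  list(retained = remaining, trace = trace, baseline_rmse = baseline_rmse)
}

#' Vote table from repeated interval eliminations
#'
#' Runs one elimination per (interval size, CV shuffle) pair; every feature
#' inside a retained interval gains one vote. The CV shuffles are generated
#' once from the seed and kept consistent across sizes.
#'
#' @param d_train training `spectral_dataset`.
#' @param y 0/1 labels for the training rows.
#' @param sizes_nm interval sizes in nm (default c(20, 40, 60, 70, 80, 95)).
#' @param n_shuffles number of fixed CV shuffles (default 5).
#' @param seed integer seed.
#' @param folds folds per shuffle (default 5).
#' @param max_components PLS component budget.
#' @return object of class `vote_table`: list with `votes` (integer per
#'   feature), `runs`, and the per-run `retained` interval records.
#' @export
bipls_vote <- function(d_train, y, sizes_nm = c(20, 40, 60, 70, 80, 95),
                       n_shuffles = 5, seed = 1, folds = 5, max_components = 30) {
  X <- d_train$intensities
  shuffles <- lapply(seq_len(n_shuffles), function(s)
    make_cv_shuffle(nrow(X), folds = folds, seed = derive_seed(seed, paste0("shuffle", s))))
  votes <- integer(ncol(X))
  runs <- 0L
  records <- list()
  for (size in sizes_nm) {
    grid <- interval_grid(d_train$wavelengths, size)
    for (s in seq_len(n_shuffles)) {
      el <- bipls_eliminate(X, y, grid, shuffles[[s]], max_components = max_components)
      keep_cols <- sort(unlist(grid$intervals[el$retained]))
      votes[keep_cols] <- votes[keep_cols] + 1L
      runs <- runs + 1L
      records[[length(records) + 1L]] <- list(size_nm = size, shuffle = s,
                                              retained = el$retained)
    }
  }
  structure(list(votes = votes, runs = runs, records = records),
            class = "vote_table")
}

#' Run the backward interval PLS selection framework
#'
#' Pipeline: stratified split; interval eliminations over all (size,
#' shuffle) pairs on the training split; features at the highest vote
#' levels (expanded level by level until the pool holds at least `3 * k`
#' candidates) form the pool; the final subset is the top-k least collinear
#' pool features with VIP relevance from a PLS fit on the pool.
#'
#' Runtime controls: `bin_step` keeps every bin_step-th wavelength bin and
#' `row_frac` subsamples training rows (stratified), so the framework runs
#' at desk scale; `folds`/`max_components` bound each RMSECV.
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class of the OVR task.
#' @param k final subset size (default 10).
#' @param protocol an `eval_protocol`.
#' @param sizes_nm interval sizes (nm).
#' @param n_shuffles CV shuffles per size.
#' @param bin_step wavelength-bin subsampling stride (1 = all bins).
#' @param row_frac fraction of training rows used for elimination (1 = all).
#' @param folds RMSECV folds.
#' @param max_components PLS component budget.
#' @return a `selection_report`.
#' @export
run_bipls_framework <- function(d, positive_class, k = 10, protocol = eval_protocol(),
                                sizes_nm = c(20, 40, 60, 70, 80, 95),
                                n_shuffles = 5, bin_step = 1, row_frac = 1,
                                folds = 5, max_components = 30) {
  t0 <- proc.time()[3]
  sp <- stratified_split(d, protocol$holdout_frac, protocol$seed)
  train <- sp$train
  cols <- seq(1, length(d$wavelengths), by = bin_step)
  sub <- subset_dataset(train, cols = cols)
  if (row_frac < 1) {
    # stratified row subsample: the "holdout" side of a split at frac = row_frac
    rs <- stratified_split(sub, frac = row_frac,
                           seed = derive_seed(protocol$seed, "rowsub"))
    sub <- rs$holdout
  }
  y <- make_ovr_labels(sub, positive_class)
  vt <- bipls_vote(sub, y, sizes_nm = sizes_nm, n_shuffles = n_shuffles,
                   seed = derive_seed(protocol$seed, "bipls"),
                   folds = folds, max_components = max_components)
  # pool: highest vote levels, expanded level by level until it holds at
  # least 3k candidates that survive the 20 nm separation rule (so the
  # least-collinear stage never runs short)
  lev <- sort(unique(vt$votes[vt$votes > 0]), decreasing = TRUE)
  pool_local <- integer(0)
  for (v in lev) {
    pool_local <- c(pool_local, which(vt$votes == v))
    sep_n <- length(min_separation_filter(
      feature_subset(pool_local, sub$wavelengths[pool_local],
                     vt$votes[pool_local]), 20)$indices)
    if (sep_n >= 3 * k) break
  }
  if (!length(pool_local)) pool_local <- seq_along(sub$wavelengths)
  pool_local <- sort(pool_local)
  fit <- pls1_fit(sub$intensities[, pool_local, drop = FALSE], y,
                  ncomp = min(max_components, 10))
  vip <- pls_vip(fit)
  pool_global <- cols[pool_local]
  pool <- feature_subset(pool_global, d$wavelengths[pool_global], vip,
                         source = "bipls>votes")
  warn <- character(0)
  if (length(pool$indices) < k)
    warn <- sprintf("pool has only %d candidates (< k = %d)", length(pool$indices), k)
  # unique features first (20 nm LED-bandwidth rule), then correlation removal
  sep_pool <- min_separation_filter(pool, 20)
  final <- sequential_collinearity_removal(sep_pool, train$intensities, k = k)
  final$source <- "bipls"
  build_report("bipls", d, sp, final, positive_class, protocol, k,
               runtime = proc.time()[3] - t0, warnings = warn,
               extra = list(vote_table = vt, pool = pool))
}
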