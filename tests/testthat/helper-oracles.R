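# Independent oracles used by both unit and acceptance tests.

# Recursive backward interval elimination coded directly from the
# definition, using rmsecv() on explicit column subsets; independent of the
# package's elimination loop.
oracle_eliminate <- function(X, y, grid, shuffle, max_components) {
  remaining <- seq_along(grid$intervals)
  cols <- function(ints) sort(unlist(grid$intervals[ints]))
  best <- rmsecv(X[, cols(remaining), drop = FALSE], y,
                 max_components, shuffle)$best_rmse
  repeat {
    if (length(remaining) == 1) break
    scores <- sapply(remaining, function(i)
      rmsecv(X[, cols(setdiff(remaining, i)), drop = FALSE], y,
             max_components, shuffle)$best_rmse)
    if (min(scores) >= best) break
    best <- min(scores)
    remaining <- remaining[-which.min(scores)]
  }
  remaining
}

# Interval toy: iid noise everywhere except one signal-bearing interval.
make_interval_toy <- function(n = 60, n_int = 5, bins_per = 6, seed = 1,
                              noise = 0) {
  set.seed(seed)
  wl <- seq(1000, by = 10, length.out = n_int * bins_per)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * length(wl), 0, 1), n, length(wl))
  si <- min(3L, n_int)
  sig <- ((si - 1) * bins_per + 1):(si * bins_per)
  X[, sig] <- X[, sig] * 0.1 + outer(y, rep(1, bins_per)) +
    noise * rnorm(n * bins_per)
  list(X = X, y = y, wl = wl, signal_interval = si)
}
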