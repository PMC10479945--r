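# Shared selection machinery: ANOVA-F relevance, Pearson collinearity
# matrix, greedy collinearity removal, minimum-separation filtering, and the
# simulated-annealing subset optimizer used by several frameworks.

#' Ordered feature subset
#'
#' @param indices wavelength-bin indices (unique, in acceptance order).
#' @param nm corresponding wavelengths in nm.
#' @param relevance parallel relevance scores.
#' @param source provenance tag (which framework/stage produced it).
#' @return object of class `feature_subset`.
#' @export
feature_subset <- function(indices, nm, relevance = rep(NA_real_, length(indices)),
                           source = "unspecified") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices))
    stop_specsel("feature indices must be unique", "specsel_param_error")
  if (length(nm) != length(indices) || length(relevance) != length(indices))
    stop_specsel("indices, nm and relevance must be parallel", "specsel_param_error")
  structure(list(indices = indices, nm = as.numeric(nm),
                 relevance = as.numeric(relevance), source = source),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset [%s]: %d features>\n", x$source, length(x$indices)))
  if (length(x$indices))
    print(data.frame(index = x$indices, nm = round(x$nm, 2),
                     relevance = signif(x$relevance, 4)))
  invisible(x)
}

#' One-way ANOVA F relevance per feature
#'
#' Between/within-group F statistic of each column against a binary label;
#' larger means more class-relevant. Zero-variance columns score 0 so the
#' pipeline stays total on degenerate inputs.
#'
#' @param X numeric matrix (rows = samples).
#' @param y binary 0/1 labels.
#' @return numeric vector of F values, one per column.
#' @export
anova_f_relevance <- function(X, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop_specsel("both classes must be present", "specsel_param_error")
  n0 <- sum(y == 0); n1 <- sum(y == 1); n <- n0 + n1
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  gm <- (n0 * m0 + n1 * m1) / n
  ssb <- n0 * (m0 - gm)^2 + n1 * (m1 - gm)^2
  ssw <- colSums((X[y == 0, , drop = FALSE] - rep(m0, each = n0))^2) +
         colSums((X[y == 1, , drop = FALSE] - rep(m1, each = n1))^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)
  f <- ifelse(msw <= 1e-300, ifelse(msb > 0, Inf, 0), msb / msw)
  tot <- colSums((X - rep(gm, each = n))^2)
  f[tot <= 1e-24 * n] <- 0  # constant columns carry no signal
  unname(f)
}

#' Pearson correlation matrix with degenerate columns handled
#'
#' Symmetric, unit diagonal, entries in \[-1, 1\]. Off-diagonal entries
#' involving a zero-variance column are defined as 0.
#'
#' @param X numeric matrix with >= 2 rows.
#' @return correlation matrix.
#' @export
pearson_matrix <- function(X) {
  if (nrow(X) < 2) stop_specsel("need >= 2 rows", "specsel_param_error")
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- NULL
  r
}

#' Greedy collinearity removal
#'
#' Accept the highest-relevance remaining candidate; discard the single
#' remaining candidate most |Pearson|-correlated with it; repeat until `k`
#' features are accepted or the pool is exhausted. Relevance ties break
#' toward the lower wavelength. With `discard_all_above` set, all remaining
#' candidates with |r| above that threshold are discarded per acceptance
#' instead of just the single most correlated one.
#'
#' @param candidates a `feature_subset` (the candidate pool).
#' @param X data matrix over the full axis (columns indexed by
#'   `candidates$indices`).
#' @param relevance relevance score per candidate (defaults to
#'   `candidates$relevance`).
#' @param k maximum number of accepted features.
#' @param discard_all_above optional |r| threshold switching to
#'   discard-all-above-threshold behaviour.
#' @return a `feature_subset` of size <= k, ordered by acceptance.
#' @export
sequential_collinearity_removal <- function(candidates, X, relevance = NULL,
                                            k = 10, discard_all_above = NULL) {
  if (k < 1) stop_specsel("k must be >= 1", "specsel_param_error")
  if (!length(candidates$indices))
    stop_specsel("candidate pool is empty", "specsel_param_error")
  relevance <- relevance %||% candidates$relevance
  pool <- seq_along(candidates$indices)
  R <- abs(pearson_matrix(X[, candidates$indices, drop = FALSE]))
  acc <- integer(0)
  while (length(acc) < k && length(pool) > 0) {
    best <- pool[order(-relevance[pool], candidates$nm[pool])][1]
    acc <- c(acc, best)
    pool <- setdiff(pool, best)
    if (length(pool)) {
      if (!is.null(discard_all_above)) {
        pool <- pool[R[best, pool] <= discard_all_above]
      } else if (length(pool) > k - length(acc)) {
        # discard the single most correlated candidate, but never shrink the
        # pool below what is still needed to reach k
        rs <- R[best, pool]
        drop <- pool[order(-rs, candidates$nm[pool])][1]
        pool <- setdiff(pool, drop)
      }
    }
  }
  feature_subset(candidates$indices[acc], candidates$nm[acc], relevance[acc],
                 source = paste0(candidates$source, ">collinearity_removal"))
}

#' Minimum wavelength-separation filter
#'
#' Scans candidates in relevance order and keeps one only if its nm distance
#' to every already-kept candidate is >= `min_nm`. Exact duplicates are
#' always dropped.
#'
#' @param candidates a `feature_subset`.
#' @param min_nm minimum pairwise separation in nm (>= 0).
#' @return filtered `feature_subset`.
#' @export
min_separation_filter <- function(candidates, min_nm) {
  if (min_nm < 0) stop_specsel("min_nm must be non-negative", "specsel_param_error")
  ord <- order(-candidates$relevance, candidates$nm)
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) && any(abs(candidates$nm[kept] - candidates$nm[i]) < min_nm))
      next
    if (any(candidates$nm[kept] == candidates$nm[i])) next  # exact duplicate
    kept <- c(kept, i)
  }
  feature_subset(candidates$indices[kept], candidates$nm[kept],
                 candidates$relevance[kept],
                 source = paste0(candidates$source, ">min_separation"))
}

#' Simulated-annealing configuration
#'
#' @param iterations number of SA iterations.
#' @param t0 initial temperature.
#' @param cooling geometric cooling factor in (0, 1); temperature at
#'   iteration i is `t0 * cooling^i`.
#' @param seed integer seed for the move proposals.
#' @param early_stop_on_perfect if TRUE and the initial state already scores
#'   `max_cost`, the search is inactivated and the initial state returned.
#' @param max_cost known upper bound of the cost (1 for accuracies); the
#'   search also halts once the best-ever cost reaches it, since no move can
#'   improve further. Set to NA for unbounded costs.
#' @return object of class `sa_config`.
#' @export
sa_config <- function(iterations = 600, t0 = 0.05, cooling = 0.995, seed = 1,
                      early_stop_on_perfect = TRUE, max_cost = 1) {
  if (iterations < 1) stop_specsel("iterations must be >= 1", "specsel_param_error")
  if (cooling <= 0 || cooling >= 1)
    stop_specsel("cooling must be in (0,1)", "specsel_param_error")
  structure(list(iterations = iterations, t0 = t0, cooling = cooling,
                 seed = seed, early_stop_on_perfect = early_stop_on_perfect,
                 max_cost = max_cost),
            class = "sa_config")
}

#' Simulated-annealing subset search
#'
#' Maximises `cost` over size-`k` subsets of the pool. The initial state is
#' the top-k by relevance (deterministic); each move swaps one selected with
#' one unselected element uniformly at random and is accepted when the cost
#' does not decrease, otherwise with probability `exp(delta / T)`. Returns
#' the best-ever subset. When `cfg$early_stop_on_perfect` is set and the
#' initial state already attains `cfg$max_cost`, the search is inactivated.
#'
#' @param pool a `feature_subset` (candidate pool, relevance used for the
#'   initial state).
#' @param k subset size.
#' @param cost function taking a vector of pool positions
#'   (`1..length(pool$indices)`) and returning a scalar to maximise.
#' @param cfg an `sa_config`.
#' @return list with `subset` (a `feature_subset`), `best_cost`, `trace`
#'   (best-ever cost after each iteration) and `activated`.
#' @export
sa_select <- function(pool, k, cost, cfg = sa_config()) {
  n <- length(pool$indices)
  if (n < k) stop_specsel("pool smaller than k", "specsel_param_error")
  as_subset <- function(sel, src) {
    sel <- sel[order(-pool$relevance[sel], pool$nm[sel])]
    feature_subset(pool$indices[sel], pool$nm[sel], pool$relevance[sel], source = src)
  }
  init <- order(-pool$relevance, pool$nm)[seq_len(k)]
  c0 <- cost(init)
  if (n == k)
    return(list(subset = as_subset(init, paste0(pool$source, ">sa")),
                best_cost = c0, trace = c0, activated = FALSE))
  if (cfg$early_stop_on_perfect && !is.na(cfg$max_cost) && c0 >= cfg$max_cost)
    return(list(subset = as_subset(init, paste0(pool$source, ">sa")),
                best_cost = c0, trace = c0, activated = FALSE))
  cur <- init; cur_cost <- c0
  best <- init; best_cost <- c0
  trace <- numeric(cfg$iterations)
  with_seed(cfg$seed, {
    for (i in seq_len(cfg$iterations)) {
      temp <- cfg$t0 * cfg$cooling^i
      out_pos <- sample(length(cur), 1)
      cand_in <- setdiff(seq_len(n), cur)
      new <- cur; new[out_pos] <- cand_in[sample(length(cand_in), 1)]
      new_cost <- cost(new)
      delta <- new_cost - cur_cost
      if (delta >= 0 || stats::runif(1) < exp(delta / max(temp, 1e-12))) {
        cur <- new; cur_cost <- new_cost
      }
      if (cur_cost > best_cost) { best <- cur; best_cost <- cur_cost }
      trace[i] <- best_cost
      if (!is.na(cfg$max_cost) && best_cost >= cfg$max_cost) {
        trace <- trace[seq_len(i)]
        break
      }
    }
  })
  list(subset = as_subset(best, paste0(pool$source, ">sa")),
       best_cost = best_cost, trace = trace, activated = TRUE)
}
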