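# Ensemble selection framework: three univariate filters (mRMR, mutual
# information, ReliefF) feed their union into a shadow-feature random
# forest wrapper (Boruta-style); the confirmed rank is finalized either as
# a narrow spectral band (SB: top-k by ANOVA F) or as the top-k least
# collinear features (LC). Tree-SHAP contributions explain the final model,
# and the framework can be run per spectral range and aggregated.

#' Spectral range specification
#'
#' Canonical ranges: VIS 355-700 nm, VIS/NIR 355-1000 nm, VIS/NIR/SWIR
#' 355-1850 nm (NIR = 700-1000, SWIR = 1000-1850).
#'
#' @param name one of "VIS", "VIS/NIR", "VIS/NIR/SWIR".
#' @return object of class `range_spec` with nm `bounds`.
#' @export
range_spec <- function(name = c("VIS/NIR/SWIR", "VIS", "VIS/NIR")) {
  name <- match.arg(name)
  bounds <- switch(name,
    "VIS" = c(355, 700),
    "VIS/NIR" = c(355, 1000),
    "VIS/NIR/SWIR" = c(355, 1850))
  structure(list(name = name, bounds = bounds), class = "range_spec")
}

#' Ensemble framework configuration
#'
#' @param top_k per-filter output size before the union (default 100).
#' @param boruta list with `max_iter`, `alpha`, `trees` for the
#'   shadow-feature wrapper (defaults 100 / 0.05 / 200).
#' @param finalization "LC" (least collinear) or "SB" (spectral band).
#' @param range a [range_spec()].
#' @param mi_neighbors k for the nearest-neighbour MI estimator.
#' @param relieff_neighbors neighbours per class for ReliefF.
#' @param seed integer seed (overridden by the protocol seed inside
#'   [run_ensemble_framework()]).
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(top_k = 100,
                            boruta = list(max_iter = 100, alpha = 0.05, trees = 200),
                            finalization = c("LC", "SB"),
                            range = range_spec("VIS/NIR/SWIR"),
                            mi_neighbors = 3, relieff_neighbors = 10, seed = 1) {
  if (top_k < 10) stop_specsel("top_k must be >= 10", "specsel_param_error")
  structure(list(top_k = top_k, boruta = boruta,
                 finalization = match.arg(finalization), range = range,
                 mi_neighbors = mi_neighbors,
                 relieff_neighbors = relieff_neighbors, seed = seed),
            class = "ensemble_config")
}

#' Greedy minimum-redundancy maximum-relevance ranking
#'
#' Relevance is the ANOVA F statistic against the binary label, expressed
#' on its equivalent correlation scale `sqrt(F / (F + n - 2))` (the point-
#' biserial correlation) so it is commensurable with the redundancy term;
#' redundancy = mean absolute Pearson correlation with the already-selected
#' features; the difference criterion picks the next feature. The first
#' pick is the maximum-F feature.
#'
#' @param X data matrix.
#' @param y 0/1 labels.
#' @param top_k number of features to rank.
#' @param wavelengths optional axis (defaults to column index).
#' @return a `feature_subset` in selection order (relevance = correlation-
#'   scaled F).
#' @export
mrmr_rank <- function(X, y, top_k = 100, wavelengths = seq_len(ncol(X))) {
  f_raw <- anova_f_relevance(X, y)
  n <- nrow(X)
  f <- sqrt(f_raw / (f_raw + n - 2))  # point-biserial scale, in [0, 1]
  f[!is.finite(f_raw)] <- 1
  top_k <- min(top_k, ncol(X))
  sel <- integer(0)
  red_sum <- numeric(ncol(X))
  for (step in seq_len(top_k)) {
    if (!length(sel)) {
      pick <- order(-f, wavelengths)[1]
    } else {
      crit <- f - red_sum / length(sel)
      crit[sel] <- -Inf
      pick <- order(-crit, wavelengths)[1]
    }
    sel <- c(sel, pick)
    if (step < top_k) {
      r <- abs(suppressWarnings(stats::cor(X, X[, pick])))
      r[is.na(r)] <- 0
      red_sum <- red_sum + r
    }
  }
  feature_subset(sel, wavelengths[sel], f[sel], source = "ensemble>mrmr")
}

#' Mutual information ranking
#'
#' Mutual information between each feature and the binary class label, in
#' nats. Continuous features use a nearest-neighbour estimator for the
#' continuous/discrete pair (k-th neighbour within class, neighbour counts
#' in the pooled sample) with a tiny seeded jitter to break ties; features
#' with few distinct values fall back to the plug-in estimate on the
#' empirical contingency table. Negative estimates clamp to 0.
#'
#' @param X data matrix.
#' @param y 0/1 labels.
#' @param top_k number of features to rank.
#' @param n_neighbors k of the NN estimator (default 3).
#' @param seed seed for the jitter.
#' @param wavelengths optional axis.
#' @return a `feature_subset` ranked by descending MI.
#' @export
mi_rank <- function(X, y, top_k = 100, n_neighbors = 3, seed = 1,
                    wavelengths = seq_len(ncol(X))) {
  y <- as.integer(y)
  n <- length(y)
  mi <- numeric(ncol(X))
  with_seed(seed, {
    for (j in seq_len(ncol(X))) {
      x <- X[, j]
      if (length(unique(x)) <= max(10, floor(sqrt(n) / 4))) {
        mi[j] <- discrete_mi(x, y)
      } else {
        x <- x + stats::rnorm(n, 0, 1e-10 * max(stats::sd(x), 1e-30))
        mi[j] <- knn_mi_cd(x, y, k = n_neighbors)
      }
    }
  })
  mi[mi < 0] <- 0
  top_k <- min(top_k, ncol(X))
  ord <- order(-mi, wavelengths)[seq_len(top_k)]
  feature_subset(ord, wavelengths[ord], mi[ord], source = "ensemble>mi")
}

# Plug-in MI for a discrete feature vs a discrete label (nats).
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  s
}

# Nearest-neighbour MI estimator for one continuous feature vs a discrete
# label: psi(N) - <psi(N_c)> + psi(k) - <psi(m_i)> with the k-th same-class
# neighbour distance as the search radius. In 1-D the k nearest same-class
# neighbours lie among the k sorted predecessors/successors, so the k-th
# distance is found by vectorised shifted differences.
knn_mi_cd <- function(x, y, k = 3) {
  n <- length(x)
  ord <- order(x); xs <- x[ord]; ys <- y[ord]
  d_k <- numeric(n)
  for (cl in unique(ys)) {
    pos <- which(ys == cl)
    xc <- xs[pos]
    nc_ <- length(xc)
    kk <- min(k, nc_ - 1)
    if (kk < 1) { d_k[pos] <- Inf; next }
    # candidate distances: kk left and kk right sorted-order neighbours
    M <- matrix(Inf, nc_, 2 * kk)
    for (o in seq_len(kk)) {
      dif <- xc[(1 + o):nc_] - xc[1:(nc_ - o)]
      M[(1 + o):nc_, o] <- dif          # left neighbour at offset o
      M[1:(nc_ - o), kk + o] <- dif     # right neighbour at offset o
    }
    # k-th smallest per row by repeated min removal (ties broken by jitter)
    for (pass in seq_len(kk)) {
      mn <- do.call(pmin, as.data.frame(M))
      if (pass == kk) { d_k[pos] <- mn; break }
      M[M == mn] <- Inf
    }
  }
  # m_i: pooled-sample neighbours strictly within the radius (self excluded)
  fin <- is.finite(d_k)
  m <- rep(n - 1L, n)
  eps <- 1e-12 * max(abs(xs), 1)
  m[fin] <- findInterval(xs[fin] + d_k[fin] - eps, xs) -
            findInterval(xs[fin] - d_k[fin] + eps, xs, left.open = TRUE) - 1L
  m[m < 0L] <- 0L
  nc <- table(ys)[as.character(ys)]
  digamma(n) - mean(digamma(as.numeric(nc))) + digamma(k) - mean(digamma(m + 1))
}

#' ReliefF feature weighting
#'
#' Binary ReliefF over all instances: features are min-max scaled, each
#' instance contributes the averaged per-feature value differences to its
#' `n_neighbors` nearest misses minus those to its nearest hits (Euclidean
#' neighbour search, range-normalised diff). Weights lie in \[-1, 1\];
#' constant features get weight 0.
#'
#' @param X data matrix.
#' @param y 0/1 labels.
#' @param top_k number of features to rank.
#' @param n_neighbors neighbours per class (default 10).
#' @param wavelengths optional axis.
#' @return a `feature_subset` ranked by descending weight.
#' @export
relieff_rank <- function(X, y, top_k = 100, n_neighbors = 10,
                         wavelengths = seq_len(ncol(X))) {
  y <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) diff(range(v)))
  ok <- rng > 1e-300
  Z <- X
  Z[, ok] <- sweep(sweep(X[, ok, drop = FALSE], 2,
                         apply(X[, ok, drop = FALSE], 2, min)), 2, rng[ok], "/")
  Z[, !ok] <- 0
  # squared Euclidean distances via the Gram matrix
  sq <- rowSums(Z^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Z)
  diag(D2) <- Inf
  w <- numeric(p)
  kk <- n_neighbors
  for (i in seq_len(n)) {
    hits <- which(y == y[i]); hits <- hits[hits != i]
    miss <- which(y != y[i])
    nh <- hits[order(D2[i, hits])][seq_len(min(kk, length(hits)))]
    nm <- miss[order(D2[i, miss])][seq_len(min(kk, length(miss)))]
    if (!length(nh) || !length(nm)) next
    dh <- colMeans(abs(Z[nh, , drop = FALSE] -
                         matrix(Z[i, ], length(nh), p, byrow = TRUE)))
    dm <- colMeans(abs(Z[nm, , drop = FALSE] -
                         matrix(Z[i, ], length(nm), p, byrow = TRUE)))
    w <- w + (dm - dh)
  }
  w <- w / n
  w[!ok] <- 0
  top_k <- min(top_k, p)
  ord <- order(-w, wavelengths)[seq_len(top_k)]
  feature_subset(ord, wavelengths[ord], w[ord], source = "ensemble>relieff")
}

#' Shadow-feature random forest wrapper (Boruta-style)
#'
#' Iteratively compares each candidate's random-forest importance against
#' the maximum importance among shadow features (column-permuted copies of
#' all candidates). A two-sided binomial test on the hit count at `alpha`
#' confirms or rejects features; rejected features leave the candidate set.
#' Runs until every feature is decided or `max_iter` is reached; undecided
#' (tentative) features are not returned.
#'
#' @param X_union data matrix restricted to the union pool columns.
#' @param y 0/1 labels.
#' @param cfg list with `max_iter`, `alpha`, `trees`.
#' @param seed integer seed.
#' @param wavelengths optional axis for the pool columns.
#' @return a `feature_subset` of confirmed features (positions refer to the
#'   columns of `X_union`), ranked by mean importance over the iterations.
#' @export
boruta_rf <- function(X_union, y, cfg = list(max_iter = 100, alpha = 0.05, trees = 200),
                      seed = 1, wavelengths = seq_len(ncol(X_union))) {
  p <- ncol(X_union)
  if (!p) stop_specsel("empty union pool", "specsel_param_error")
  if (is.null(cfg$trees) || cfg$trees < 1)
    stop_specsel("need at least one tree", "specsel_param_error")
  y_f <- factor(y, levels = c(0, 1))
  active <- rep(TRUE, p)      # not yet rejected
  decided <- rep(FALSE, p)
  hits <- integer(p); trials <- integer(p)
  imp_sum <- numeric(p); imp_n <- integer(p)
  min_iter <- 5L
  with_seed(seed, {
    for (it in seq_len(cfg$max_iter)) {
      cand <- which(active & !decided)
      if (!length(cand)) break
      Xa <- X_union[, cand, drop = FALSE]
      Xs <- apply(Xa, 2, sample)  # shadows: per-column row permutations
      XX <- cbind(Xa, Xs)
      colnames(XX) <- c(paste0("f", cand), paste0("s", seq_along(cand)))
      fit <- ranger::ranger(y = y_f, x = as.data.frame(XX),
                            num.trees = cfg$trees, importance = "impurity",
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      real <- imp[seq_along(cand)]
      sh_max <- max(imp[-seq_along(cand)])
      hits[cand] <- hits[cand] + as.integer(real > sh_max)
      trials[cand] <- trials[cand] + 1L
      imp_sum[cand] <- imp_sum[cand] + real
      imp_n[cand] <- imp_n[cand] + 1L
      if (it >= min_iter) {
        for (j in cand) {
          pval <- stats::binom.test(hits[j], trials[j], p = 0.5)$p.value
          if (pval < cfg$alpha) {
            decided[j] <- TRUE
            if (hits[j] <= trials[j] / 2) active[j] <- FALSE  # rejected
          }
        }
      }
    }
  })
  confirmed <- which(decided & active)
  mean_imp <- ifelse(imp_n > 0, imp_sum / pmax(imp_n, 1L), 0)
  ord <- confirmed[order(-mean_imp[confirmed], wavelengths[confirmed])]
  feature_subset(ord, wavelengths[ord], mean_imp[ord], source = "ensemble>boruta")
}

#' Spectral-band finalization (SB)
#'
#' Top-k of the confirmed rank, re-ordered by ANOVA F. No separation
#' constraint is applied, so the output typically forms a narrow
#' contiguous band around the strongest absorption difference.
#'
#' @param ranked confirmed `feature_subset` (indices on the full axis).
#' @param X data matrix over the full axis.
#' @param y 0/1 labels.
#' @param k subset size (default 10).
#' @return a `feature_subset`.
#' @export
finalize_sb <- function(ranked, X, y, k = 10) {
  n <- length(ranked$indices)
  if (n < k) warning(sprintf("rank has only %d features (< k = %d)", n, k))
  take <- seq_len(min(k, n))
  idx <- ranked$indices[take]
  f <- anova_f_relevance(X[, idx, drop = FALSE], y)
  ord <- order(-f, ranked$nm[take])
  feature_subset(idx[ord], ranked$nm[take][ord], f[ord], source = "ensemble_sb")
}

#' Least-collinear finalization (LC)
#'
#' The confirmed rank is reduced to unique features by the 20 nm
#' minimum-separation rule (ANOVA-F relevance), then refined by greedy
#' collinearity removal keeping k features; the output is guaranteed
#' pairwise >= `min_sep_nm` apart.
#'
#' @inheritParams finalize_sb
#' @param min_sep_nm separation enforced among the final features
#'   (default 20, the bandwidth of a typical LED).
#' @return a `feature_subset`.
#' @export
finalize_lc <- function(ranked, X, y, k = 10, min_sep_nm = 20) {
  f <- anova_f_relevance(X[, ranked$indices, drop = FALSE], y)
  pool <- feature_subset(ranked$indices, ranked$nm, f, source = ranked$source)
  pool <- min_separation_filter(pool, min_sep_nm)
  out <- sequential_collinearity_removal(pool, X, k = k)
  out$source <- "ensemble_lc"
  out
}

#' Tree-SHAP contribution summary
#'
#' Trains a gradient-boosted tree ensemble on the selected features of the
#' training split and computes exact per-sample tree-SHAP contributions on
#' the evaluation rows. Additivity holds: for every row, base value +
#' contributions equals the model margin (log-odds) output.
#'
#' @param X_train,y_train training data restricted to the final subset.
#' @param X_eval evaluation rows (same columns), typically the holdout.
#' @param feature_names column names for reporting.
#' @param nrounds,max_depth,eta boosting configuration (kept moderate so
#'   margins stay well-conditioned and the single-precision contribution
#'   sums match the margin tightly).
#' @param seed integer seed.
#' @return list with `contributions` (rows x features), `base_value`,
#'   `margin` (model output per row), `mean_abs` (per-feature mean absolute
#'   contribution), `model`, and `X_eval`.
#' @export
shap_summary <- function(X_train, y_train, X_eval,
                         feature_names = colnames(X_train),
                         nrounds = 30, max_depth = 3, eta = 0.05, seed = 1) {
  feature_names <- feature_names %||% paste0("f", seq_len(ncol(X_train)))
  Xtr <- as.matrix(X_train); Xev <- as.matrix(X_eval)
  colnames(Xtr) <- colnames(Xev) <- feature_names
  dtr <- xgboost::xgb.DMatrix(Xtr, label = as.numeric(y_train), nthread = 1)
  dev <- xgboost::xgb.DMatrix(Xev, nthread = 1)
  model <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtr, nrounds = nrounds))
  contrib <- stats::predict(model, dev, predcontrib = TRUE)
  margin <- stats::predict(model, dev, outputmargin = TRUE)
  base <- contrib[, ncol(contrib)]
  C <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(C) <- feature_names
  list(contributions = C, base_value = base, margin = margin,
       mean_abs = colMeans(abs(C)), model = model, X_eval = Xev)
}

# Shared stages of the ensemble framework on a prepared split.
ensemble_core <- function(sp, positive_class, k, protocol, cfg) {
  train <- sp$train
  y <- make_ovr_labels(train, positive_class)
  X <- train$intensities
  wl <- train$wavelengths
  seed <- derive_seed(protocol$seed, "ensemble")
  f_mrmr <- mrmr_rank(X, y, top_k = cfg$top_k, wavelengths = wl)
  f_mi <- mi_rank(X, y, top_k = cfg$top_k, n_neighbors = cfg$mi_neighbors,
                  seed = derive_seed(seed, "mi"), wavelengths = wl)
  f_rel <- relieff_rank(X, y, top_k = cfg$top_k,
                        n_neighbors = cfg$relieff_neighbors, wavelengths = wl)
  union_idx <- sort(unique(c(f_mrmr$indices, f_mi$indices, f_rel$indices)))
  confirmed_local <- boruta_rf(X[, union_idx, drop = FALSE], y, cfg = cfg$boruta,
                               seed = derive_seed(seed, "boruta"),
                               wavelengths = wl[union_idx])
  confirmed <- feature_subset(union_idx[confirmed_local$indices],
                              confirmed_local$nm, confirmed_local$relevance,
                              source = "ensemble>boruta")
  list(filters = list(mrmr = f_mrmr, mi = f_mi, relieff = f_rel),
       union_idx = union_idx, confirmed = confirmed, y = y)
}

#' Run the ensemble selection framework
#'
#' Pipeline: stratified split; mRMR, MI and ReliefF each rank `top_k`
#' features on the training split; the union feeds the shadow-feature RF
#' wrapper; the confirmed rank is finalized as SB and/or LC; tree-SHAP
#' contributions are computed on the holdout split.
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class of the OVR task.
#' @param k final subset size (default 10).
#' @param protocol an `eval_protocol`.
#' @param cfg an [ensemble_config()].
#' @param finalization "SB", "LC", or both.
#' @return a single `selection_report`, or a named list (`sb`, `lc`) when
#'   both finalizations are requested.
#' @export
run_ensemble_framework <- function(d, positive_class, k = 10,
                                   protocol = eval_protocol(),
                                   cfg = ensemble_config(),
                                   finalization = cfg$finalization) {
  t0 <- proc.time()[3]
  bounds <- cfg$range$bounds
  in_range <- which(d$wavelengths >= bounds[1] & d$wavelengths <= bounds[2])
  if (!length(in_range))
    stop_specsel(sprintf("no wavelengths inside range %s", cfg$range$name),
                 "specsel_param_error")
  d_r <- subset_dataset(d, cols = in_range)
  sp <- stratified_split(d_r, protocol$holdout_frac, protocol$seed)
  core <- ensemble_core(sp, positive_class, k, protocol, cfg)
  confirmed <- core$confirmed
  warn <- if (length(confirmed$indices) < k)
    sprintf("only %d confirmed features (< k = %d)", length(confirmed$indices), k)
  else character(0)
  one <- function(mode) {
    final <- if (mode == "SB")
      suppressWarnings(finalize_sb(confirmed, sp$train$intensities, core$y, k = k))
    else finalize_lc(confirmed, sp$train$intensities, core$y, k = k)
    shap <- shap_summary(sp$train$intensities[, final$indices, drop = FALSE],
                         core$y,
                         sp$holdout$intensities[, final$indices, drop = FALSE],
                         feature_names = sprintf("%.1fnm", final$nm),
                         seed = derive_seed(protocol$seed, "shap"))
    rep <- build_report(if (mode == "SB") "ensemble_sb" else "ensemble_lc",
                        d_r, sp, final, positive_class, protocol, k,
                        runtime = proc.time()[3] - t0, warnings = warn,
                        range = cfg$range$name,
                        extra = list(filters = core$filters,
                                     union_size = length(core$union_idx),
                                     confirmed = confirmed,
                                     shap_mean_abs = shap$mean_abs,
                                     shap = shap))
    rep
  }
  if (length(finalization) == 1) return(one(finalization))
  list(sb = one("SB"), lc = one("LC"))
}

#' Run the ensemble framework per spectral range and aggregate
#'
#' Runs the framework independently on the VIS, VIS/NIR and VIS/NIR/SWIR
#' column slices (incremental aggregation of ranges).
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class of the OVR task.
#' @param cfg an [ensemble_config()] (its `range` field is overridden).
#' @param k final subset size.
#' @param protocol an `eval_protocol`.
#' @param ranges character vector of range names (default all three).
#' @return named list of `selection_report`, one per range.
#' @export
partition_and_aggregate <- function(d, positive_class, cfg = ensemble_config(),
                                    k = 10, protocol = eval_protocol(),
                                    ranges = c("VIS", "VIS/NIR", "VIS/NIR/SWIR")) {
  out <- list()
  for (rn in ranges) {
    cfg_r <- cfg; cfg_r$range <- range_spec(rn)
    out[[rn]] <- run_ensemble_framework(d, positive_class, k = k,
                                        protocol = protocol, cfg = cfg_r,
                                        finalization = cfg$finalization)
  }
  out
}

#' Sequential-inclusion accuracy curve
#'
#' CV balanced accuracy using the first j ranked features of the final
#' subset, for j = 1..k. Mirrors the tradeoff between feature count and
#' model accuracy; on well-separated data the curve typically plateaus
#' after 3-4 features.
#'
#' @param final a ranked `feature_subset`.
#' @param d the `spectral_dataset` to evaluate on (typically the training
#'   split).
#' @param positive_class positive class of the OVR task.
#' @param protocol an `eval_protocol`.
#' @return data.frame with columns `j`, `mean`, `sd`.
#' @export
sequential_inclusion_curve <- function(final, d, positive_class,
                                       protocol = eval_protocol()) {
  if (!length(final$indices)) stop_specsel("empty subset", "specsel_param_error")
  rows <- lapply(seq_along(final$indices), function(j) {
    s <- cv_balanced_accuracy(d, final$indices[seq_len(j)], protocol, positive_class)
    data.frame(j = j, mean = s$mean, sd = s$sd)
  })
  do.call(rbind, rows)
}
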