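# PCA selection framework: project the training spectra onto leading
# principal components, search PC subsets by simulated annealing with an
# LDA cross-validation cost, read candidate wavelengths off the selected
# eigenvectors as peaks, and finish with ANOVA-F-ranked collinearity
# removal back in the original wavelength space.

#' Peak inclusion criteria for eigenvector candidates
#'
#' @param min_sep_nm minimum horizontal separation between kept peaks (nm).
#' @param min_norm_intensity minimum peak height after normalising each
#'   |eigenvector| to max 1 (vertical threshold in \[0, 1\]).
#' @return object of class `peak_criteria`.
#' @export
peak_criteria <- function(min_sep_nm = 20, min_norm_intensity = 0.20) {
  if (min_norm_intensity < 0 || min_norm_intensity > 1)
    stop_specsel("min_norm_intensity must be in [0,1]", "specsel_param_error")
  structure(list(min_sep_nm = min_sep_nm, min_norm_intensity = min_norm_intensity),
            class = "peak_criteria")
}

#' Principal component pool of a training matrix
#'
#' Centred (unscaled) PCA via singular value decomposition; returns the
#' leading `n_pcs` scores and loadings. Loadings are orthonormal and
#' explained variance is non-increasing.
#'
#' @param X_train numeric training matrix.
#' @param n_pcs number of components to keep (default 30).
#' @return list with `scores` (m x n_pcs), `loadings` (n x n_pcs),
#'   `variance` (per-PC score variance), and `center`.
#' @export
pca_pc_pool <- function(X_train, n_pcs = 30) {
  m <- nrow(X_train); n <- ncol(X_train)
  if (n_pcs < 1 || n_pcs > min(m, n))
    stop_specsel("n_pcs must be in 1..min(m, n)", "specsel_param_error")
  ctr <- colMeans(X_train)
  Xc <- sweep(X_train, 2, ctr)
  sv <- svd(Xc, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  list(scores = scores, loadings = sv$v,
       variance = sv$d[seq_len(n_pcs)]^2 / (m - 1), center = ctr)
}

#' Simulated-annealing search over principal components
#'
#' Selects the `k` PCs whose score columns jointly maximise LDA
#' cross-validated balanced accuracy. Honors the inactivation rule: if the
#' deterministic initial state (leading k PCs) already scores 100%, the
#' search is skipped and that state returned.
#'
#' @param scores PC score matrix from [pca_pc_pool()].
#' @param y 0/1 labels.
#' @param k number of PCs to select (default 10).
#' @param cfg an `sa_config` (default 600 iterations).
#' @param cost_folds,cost_repeats CV shape of the internal LDA cost.
#' @return list from [sa_select()]; `subset$indices` are PC numbers.
#' @export
sa_pc_subset <- function(scores, y, k = 10, cfg = sa_config(iterations = 600),
                         cost_folds = 3, cost_repeats = 1) {
  n_pcs <- ncol(scores)
  if (n_pcs < k) stop_specsel("fewer PCs than k", "specsel_param_error")
  # pool ordered by variance rank: PC1 first (relevance = reverse rank)
  pool <- feature_subset(seq_len(n_pcs), nm = seq_len(n_pcs),
                         relevance = rev(seq_len(n_pcs)), source = "pca>pcs")
  cost <- make_cv_cost(scores, y, folds = cost_folds, repeats = cost_repeats,
                       seed = derive_seed(cfg$seed, "sacost"))
  res <- sa_select(pool, k, function(sel) cost(pool$indices[sel]), cfg)
  res
}

# Deterministic LDA CV cost over column subsets of a fixed matrix; the fold
# assignment is frozen up-front so the cost is a pure function of the subset.
make_cv_cost <- function(X, y, folds = 3, repeats = 1, seed = 1) {
  ids <- lapply(seq_len(repeats), function(r)
    stratified_fold_ids(y, folds, seed + (r - 1L)))
  function(cols) {
    s <- numeric(0)
    for (r in seq_len(repeats)) for (f in seq_len(folds)) {
      te <- which(ids[[r]] == f)
      pred <- fit_predict("LDA", X[-te, cols, drop = FALSE], y[-te],
                          X[te, cols, drop = FALSE])
      s <- c(s, bacc_from_pred(y[te], pred))
    }
    mean(s)
  }
}

#' Candidate wavelengths from eigenvector peaks
#'
#' Per selected PC the |loading| vector is normalised to max 1; local
#' maxima at or above the vertical threshold become candidates (relevance =
#' normalised height). Candidates are pooled across PCs, deduplicated, and
#' peaks within `min_sep_nm` of a stronger peak are removed.
#'
#' @param loadings_subset n x q matrix of the selected PCs' loadings.
#' @param wavelengths axis (nm), length n.
#' @param crit a [peak_criteria()].
#' @return a `feature_subset` of candidate wavelengths.
#' @export
eigenvector_peaks <- function(loadings_subset, wavelengths,
                              crit = peak_criteria()) {
  loadings_subset <- as.matrix(loadings_subset)
  if (!ncol(loadings_subset)) stop_specsel("empty PC subset", "specsel_param_error")
  idx <- integer(0); height <- numeric(0)
  for (j in seq_len(ncol(loadings_subset))) {
    v <- abs(loadings_subset[, j])
    if (max(v) <= 0) { warning("all-zero loading vector skipped"); next }
    v <- v / max(v)
    n <- length(v)
    left <- c(-Inf, v[-n]); right <- c(v[-1], -Inf)
    is_peak <- v >= left & v > right  # plateau tie breaks toward lower nm
    keep <- which(is_peak & v >= crit$min_norm_intensity)
    idx <- c(idx, keep); height <- c(height, v[keep])
  }
  if (!length(idx))
    return(feature_subset(integer(0), numeric(0), numeric(0), source = "pca>peaks"))
  # deduplicate bins, keeping the greatest height per bin
  ord <- order(-height, wavelengths[idx])
  idx <- idx[ord]; height <- height[ord]
  first <- !duplicated(idx)
  cand <- feature_subset(idx[first], wavelengths[idx[first]], height[first],
                         source = "pca>peaks")
  min_separation_filter(cand, crit$min_sep_nm)
}

#' Run the PCA selection framework
#'
#' Pipeline: stratified split; centred PCA on the training split
#' (`n_pcs` leading components); SA search for the `k` PCs maximising LDA
#' CV accuracy (600 iterations, inactivated at an initial 100%); peak
#' picking on the selected eigenvectors (20 nm / 20% criteria); final
#' subset by ANOVA-F-ranked collinearity removal over the peak candidates.
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class of the OVR task.
#' @param k final subset size (default 10).
#' @param protocol an `eval_protocol`.
#' @param n_pcs PC pool size (default 30).
#' @param sa an `sa_config` (default 600 iterations, seeded from protocol).
#' @param crit a [peak_criteria()].
#' @return a `selection_report`.
#' @export
run_pca_framework <- function(d, positive_class, k = 10, protocol = eval_protocol(),
                              n_pcs = 30, sa = NULL, crit = peak_criteria()) {
  t0 <- proc.time()[3]
  sp <- stratified_split(d, protocol$holdout_frac, protocol$seed)
  y <- make_ovr_labels(sp$train, positive_class)
  pool <- pca_pc_pool(sp$train$intensities, n_pcs = n_pcs)
  sa <- sa %||% sa_config(iterations = 600, seed = derive_seed(protocol$seed, "pca_sa"))
  sel <- sa_pc_subset(pool$scores, y, k = k, cfg = sa)
  pcs <- sel$subset$indices
  cand <- eigenvector_peaks(pool$loadings[, pcs, drop = FALSE],
                            d$wavelengths, crit)
  warn <- character(0)
  if (length(cand$indices) < k)
    warn <- sprintf("only %d peak candidates (< k = %d); returning all",
                    length(cand$indices), k)
  f_rel <- anova_f_relevance(sp$train$intensities[, cand$indices, drop = FALSE], y)
  final <- sequential_collinearity_removal(cand, sp$train$intensities,
                                           relevance = f_rel, k = k)
  final$source <- "pca"
  build_report("pca", d, sp, final, positive_class, protocol, k,
               runtime = proc.time()[3] - t0, warnings = warn,
               extra = list(pcs = pcs, sa_trace = sel$trace,
                            sa_activated = sel$activated, candidates = cand))
}
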