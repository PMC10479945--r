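# Selection reports: the common result container produced by every
# framework, JSON serialization, the run-everything driver, and figures.

# Shared report constructor used by all frameworks: scores the final subset
# (top-1 and top-k) by CV on the training split and on the holdout split.
build_report <- function(framework, d, sp, final, positive_class, protocol, k,
                         runtime = NA_real_, warnings = character(0),
                         extra = list(), range = "full") {
  top1_idx <- final$indices[1]
  cv1 <- cv_balanced_accuracy(sp$train, top1_idx, protocol, positive_class)
  cvk <- cv_balanced_accuracy(sp$train, final$indices, protocol, positive_class)
  h1 <- holdout_balanced_accuracy(sp$train, sp$holdout, top1_idx, protocol,
                                  positive_class)
  hk <- holdout_balanced_accuracy(sp$train, sp$holdout, final$indices, protocol,
                                  positive_class)
  structure(list(
    framework = framework, positive_class = positive_class, range = range,
    subset = final, k = k, top_feature_nm = final$nm[1],
    scores = list(
      top1 = list(cv_mean = cv1$mean, cv_sd = cv1$sd, holdout = h1),
      topk = list(cv_mean = cvk$mean, cv_sd = cvk$sd, holdout = hk)),
    protocol = protocol, seed = protocol$seed, runtime = runtime,
    warnings = warnings, extra = extra),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report: %s | %s vs rest | range %s>\n",
              x$framework, x$positive_class, x$range))
  cat(sprintf("  final %d features (nm): %s\n", length(x$subset$nm),
              paste(round(x$subset$nm, 1), collapse = ", ")))
  cat(sprintf("  top feature: %.1f nm\n", x$top_feature_nm))
  s <- x$scores
  cat(sprintf("  top-1 : CV %.3f +/- %.3f | holdout %.3f\n",
              s$top1$cv_mean, s$top1$cv_sd, s$top1$holdout))
  cat(sprintf("  top-%d: CV %.3f +/- %.3f | holdout %.3f\n", length(x$subset$nm),
              s$topk$cv_mean, s$topk$cv_sd, s$topk$holdout))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a selection report to stable JSON
#'
#' The JSON payload is a pure function of the inputs and the seed: the
#' runtime field (wall-clock) and bulky internals in `extra` are excluded so
#' that re-running with the same seed produces byte-identical files.
#'
#' @param report a `selection_report`.
#' @param path output path; NULL returns the JSON string.
#' @return the path (invisibly) or a JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(
    framework = report$framework,
    positive_class = report$positive_class,
    range = report$range,
    k = report$k,
    final_nm = round(report$subset$nm, 4),
    final_indices = report$subset$indices,
    relevance = signif(report$subset$relevance, 8),
    top_feature_nm = round(report$top_feature_nm, 4),
    scores = rapply(report$scores, function(v) signif(v, 8), how = "replace"),
    seed = report$seed,
    protocol = list(holdout_frac = report$protocol$holdout_frac,
                    folds = report$protocol$folds,
                    repeats = report$protocol$repeats,
                    classifier = report$protocol$classifier),
    warnings = report$warnings)
  if (!is.null(report$extra$shap_mean_abs))
    payload$shap_mean_abs <- signif(report$extra$shap_mean_abs, 8)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Run every selection framework on one OVR task
#'
#' Executes the PCA, LDA, biPLS and ensemble (SB and LC finalizations)
#' frameworks under one protocol and seed and returns the five reports. A
#' framework failure is recorded in its slot without stopping the others.
#'
#' @param d a `spectral_dataset`.
#' @param positive_class positive class of the OVR task.
#' @param protocol an `eval_protocol`.
#' @param k final subset size.
#' @param bipls_args list of extra arguments for [run_bipls_framework()]
#'   (e.g. `bin_step` for desk-scale runs).
#' @param ensemble_cfg an [ensemble_config()].
#' @return named list of `selection_report` (pca, lda, bipls, ensemble_sb,
#'   ensemble_lc); failed entries carry class `selection_failure`.
#' @export
run_all <- function(d, positive_class, protocol = eval_protocol(), k = 10,
                    bipls_args = list(), ensemble_cfg = ensemble_config()) {
  safely <- function(expr) tryCatch(expr, error = function(e)
    structure(list(message = conditionMessage(e)), class = "selection_failure"))
  out <- list()
  out$pca <- safely(run_pca_framework(d, positive_class, k = k, protocol = protocol))
  out$lda <- safely(run_lda_framework(d, positive_class, k = k, protocol = protocol))
  out$bipls <- safely(do.call(run_bipls_framework,
                              c(list(d, positive_class, k = k, protocol = protocol),
                                bipls_args)))
  ens <- safely(run_ensemble_framework(d, positive_class, k = k,
                                       protocol = protocol, cfg = ensemble_cfg,
                                       finalization = c("SB", "LC")))
  if (inherits(ens, "selection_failure")) {
    out$ensemble_sb <- ens; out$ensemble_lc <- ens
  } else {
    out$ensemble_sb <- ens$sb; out$ensemble_lc <- ens$lc
  }
  out
}

#' Side-by-side comparison table of reports
#'
#' @param reports list of `selection_report` (e.g. from [run_all()]).
#' @return data.frame with one row per report: framework, top feature, and
#'   the top-1 / top-k CV and holdout balanced accuracies.
#' @export
comparison_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    if (inherits(r, "selection_failure"))
      return(data.frame(framework = NA, positive_class = NA, top_feature_nm = NA,
                        top1_cv = NA, top1_holdout = NA, topk_cv = NA,
                        topk_holdout = NA))
    data.frame(framework = r$framework, positive_class = r$positive_class,
               top_feature_nm = r$top_feature_nm,
               top1_cv = r$scores$top1$cv_mean, top1_holdout = r$scores$top1$holdout,
               topk_cv = r$scores$topk$cv_mean, topk_holdout = r$scores$topk$holdout)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(reports)
  out
}

#' Plot selected wavelengths over class-mean spectra
#'
#' Class-mean spectra with +/- 1 sd ribbons and vertical marks at the
#' report's selected wavelengths.
#'
#' @param d the `spectral_dataset` the selection was run on.
#' @param report a `selection_report`.
#' @param path optional output file (png/pdf by extension).
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_selection <- function(d, report, path = NULL) {
  if (!length(report$subset$indices))
    stop_specsel("report has an empty feature subset", "specsel_param_error")
  classes <- sort(unique(d$labels))
  df <- do.call(rbind, lapply(classes, function(cl) {
    Xc <- d$intensities[d$labels == cl, , drop = FALSE]
    data.frame(nm = d$wavelengths, mean = colMeans(Xc),
               sd = apply(Xc, 2, stats::sd), class = cl)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$nm, y = .data$mean,
                                        colour = .data$class, fill = .data$class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = report$subset$nm, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance (a.u.)",
                  title = sprintf("%s: %s vs rest", report$framework,
                                  report$positive_class)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) { ggplot2::ggsave(path, p, width = 9, height = 5); return(invisible(p)) }
  p
}

#' Plot a sequential-inclusion accuracy curve
#'
#' @param curve data.frame from [sequential_inclusion_curve()].
#' @param path optional output file.
#' @return the ggplot object.
#' @export
plot_curve <- function(curve, path = NULL) {
  if (!nrow(curve)) stop_specsel("empty curve", "specsel_param_error")
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$j, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd), alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = curve$j) +
    ggplot2::labs(x = "number of ranked features included",
                  y = "CV balanced accuracy") +
    ggplot2::theme_minimal()
  if (!is.null(path)) { ggplot2::ggsave(path, p, width = 7, height = 4); return(invisible(p)) }
  p
}

#' Plot a SHAP contribution summary
#'
#' Beeswarm-style summary: one row per feature (ordered by mean absolute
#' contribution), points jittered vertically, coloured by the feature value.
#'
#' @param shap result of [shap_summary()].
#' @param path optional output file.
#' @return the ggplot object.
#' @export
plot_shap <- function(shap, path = NULL) {
  C <- shap$contributions
  X <- shap$X_eval
  ord <- order(colMeans(abs(C)))
  df <- do.call(rbind, lapply(seq_len(ncol(C)), function(j) {
    v <- X[, j]
    data.frame(feature = colnames(C)[j], shap = C[, j],
               value = (v - min(v)) / max(max(v) - min(v), 1e-12),
               rank = match(j, ord))
  }))
  df$feature <- stats::reorder(factor(df$feature), df$rank)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$shap, y = .data$feature,
                                        colour = .data$value)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   name = "feature value") +
    ggplot2::labs(x = "SHAP value (log-odds contribution)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(path)) { ggplot2::ggsave(path, p, width = 7, height = 5); return(invisible(p)) }
  p
}
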