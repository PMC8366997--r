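# The package's modelling surface: fit a patient-similarity-network
# stratification model and assign new patients to its subgroups.

#' Fit a patient-similarity-network stratification model
#'
#' End-to-end fit of the unsupervised risk-stratification model: derive
#' trajectory features from the longitudinal measurements, flag gross
#' outliers, mean-impute and z-score, build the patient-patient similarity
#' matrix, and cluster patients on their similarity profiles with seeded
#' k-means. The returned object carries the full preprocessing transform so
#' held-out patients can be assigned via [predict.psn_fit()] without leaking
#' test information into the fit.
#'
#' @param x A `synthetic_cohort` (or any list with `measurements` and
#'   `static` data frames), a raw `feature_matrix`, or an already scaled
#'   `feature_matrix` / numeric matrix.
#' @param K Number of subgroups (default 4).
#' @param metric Patient similarity metric, `"cosine"` (default) or `"pcc"`.
#' @param window_days Three-month window for trajectory features (default 92).
#' @param z_limit Robust-z outlier threshold (default 4; `Inf` disables).
#' @param sd_type Scaling denominator, `"population"` (default) or `"sample"`.
#' @param seed Integer seed for the k-means initialization.
#' @param n_start k-means restarts, best SSE kept (default 5).
#' @return Object of class `psn_fit`: the scaled training `features`, the
#'   training `sim`ilarity matrix, the `km` (`psn_kmeans`) model, `labels`,
#'   and the fit parameters.
#' @seealso [predict.psn_fit()], [stability_analysis()], [select_k()]
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 80, seed = 3))
#' fit <- psn_fit(coh, K = 4, seed = 1)
#' print(fit)
#' table(fitted(fit), coh$truth$subgroup)
psn_fit <- function(x, K = 4, metric = c("cosine", "pcc"), window_days = 92,
                    z_limit = 4, sd_type = c("population", "sample"), seed = 1L,
                    n_start = 5L) {
  metric <- match.arg(metric)
  sd_type <- match.arg(sd_type)
  fm <- .as_feature_matrix(x, window_days)
  if (!isTRUE(fm$scaled)) {
    fm <- suppressMessages(remove_outliers(fm, z_limit))
    fm <- impute_and_scale(fm, sd_type)
  }
  sim <- similarity_matrix(fm, metric)
  km <- psn_kmeans(sim, K, seed = seed, n_start = n_start)
  out <- list(features = fm, sim = sim, km = km, labels = km$labels, K = K,
              metric = metric, window_days = window_days, z_limit = z_limit,
              seed = as.integer(seed), call = match.call())
  class(out) <- "psn_fit"
  out
}

.as_feature_matrix <- function(x, window_days) {
  if (inherits(x, "feature_matrix")) return(x)
  if (is.list(x) && !is.null(x$measurements))
    return(build_feature_matrix(x$measurements, x$static, window_days))
  if (is.matrix(x)) {
    fm <- list(x = x, ids = rownames(x),
               feature_info = data.frame(feature = colnames(x),
                                         base_variable = colnames(x),
                                         kind = "static", stringsAsFactors = FALSE),
               scaled = !anyNA(x))
    class(fm) <- "feature_matrix"
    return(fm)
  }
  stop("cannot interpret 'x' as patient data")
}

#' @export
print.psn_fit <- function(x, ...) {
  cat("Patient similarity network stratification\n")
  cat(sprintf("  %d patients x %d features; %s similarity; K = %d (seed %d)\n",
              nrow(x$features$x), ncol(x$features$x), x$metric, x$K, x$seed))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$K), collapse = "/"),
      sprintf("; SSE = %.4g\n", x$km$sse))
  invisible(x)
}

#' @export
summary.psn_fit <- function(object, outcomes = NULL, ...) {
  sizes <- tabulate(object$labels, object$K)
  out <- list(K = object$K, sizes = sizes, sse = object$km$sse,
              metric = object$metric, n = length(object$labels))
  if (!is.null(outcomes)) {
    stopifnot(inherits(outcomes, "outcome_table"))
    ot <- outcomes[match(names(object$labels), outcomes$patient_id), ]
    g <- factor(object$labels)
    out$enrichment <- chi2_enrichment(g, ot$de_novo_ctrcd)
    out$km_os <- km_by_group(ot$os_years, ot$death, g)
    out$km_denovo <- km_by_group(ot$denovo_years, ot$de_novo_ctrcd, g)
  }
  class(out) <- "summary.psn_fit"
  out
}

#' @export
print.summary.psn_fit <- function(x, ...) {
  cat(sprintf("psn_fit: K = %d on %d patients (%s similarity), SSE = %.4g\n",
              x$K, x$n, x$metric, x$sse))
  cat("  cluster sizes:", paste(x$sizes, collapse = "/"), "\n")
  if (!is.null(x$enrichment)) {
    cat("\nDe novo cardiac event enrichment by cluster:\n")
    print(x$enrichment, row.names = FALSE, digits = 3)
    cat(sprintf("\nOmnibus log-rank p: overall survival %.3g; de novo events %.3g\n",
                x$km_os$omnibus_p, x$km_denovo$omnibus_p))
  }
  invisible(x)
}

#' @export
fitted.psn_fit <- function(object, ...) object$labels

#' Assign held-out patients to fitted subgroups
#'
#' Applies the training preprocessing transform (training outlier bounds,
#' imputation means and scaling) to the new patients, computes their
#' similarity profiles against the training patients, and assigns each to the
#' nearest k-means centroid. Deterministic.
#'
#' @param object A `psn_fit`.
#' @param newdata A cohort-like list (`measurements` + `static`), a raw
#'   `feature_matrix`, or `NULL` to return the training labels.
#' @param similarity Optional precomputed test-versus-training similarity
#'   matrix (test patients x training patients); overrides `newdata`.
#' @param ... Unused.
#' @return Named integer vector of cluster labels.
#' @export
predict.psn_fit <- function(object, newdata = NULL, similarity = NULL, ...) {
  if (is.null(newdata) && is.null(similarity)) return(object$labels)
  if (is.null(similarity)) {
    fm_new <- .as_feature_matrix(newdata, object$window_days)
    if (isTRUE(fm_new$scaled) && is.null(fm_new$center))
      warning("newdata appears already scaled; applying training transform anyway")
    fm_new$scaled <- FALSE
    fm_new <- apply_preprocess(fm_new, object$features)
    similarity <- cross_similarity(object$features, fm_new, object$metric)
  }
  assign_clusters(object$km, similarity)
}

#' @export
plot.psn_fit <- function(x, outcomes = NULL, ...) {
  if (is.null(outcomes)) {
    graphics::barplot(tabulate(x$labels, x$K), names.arg = seq_len(x$K),
                      xlab = "Cluster", ylab = "Patients",
                      main = "Subgroup sizes", ...)
  } else {
    stopifnot(inherits(outcomes, "outcome_table"))
    ot <- outcomes[match(names(x$labels), outcomes$patient_id), ]
    plot(km_by_group(ot$os_years, ot$death, factor(x$labels)),
         main = "Overall survival by subgroup", ...)
  }
  invisible(x)
}
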