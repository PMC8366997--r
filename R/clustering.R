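# K-means on patient similarity profiles, K selection, stability, assignment.

# Squared Euclidean distances from rows of X to rows of C.
.sqdist_to_centers <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
  pmax(d2, 0)
}

# Greedy k-means++ seeding: each new centre is the best of a few candidates
# drawn proportionally to squared distance (4 + log(K) trials).
.kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  n_trials <- 4L + as.integer(log(K))
  centers <- integer(K)
  centers[1] <- sample.int(n, 1)
  d2 <- .sqdist_to_centers(X, X[centers[1], , drop = FALSE])[, 1]
  for (k in seq_len(K - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    cand <- sample.int(n, n_trials, replace = TRUE, prob = prob)
    pots <- vapply(cand, function(cc)
      sum(pmin(d2, .sqdist_to_centers(X, X[cc, , drop = FALSE])[, 1])),
      numeric(1))
    centers[k + 1] <- cand[which.min(pots)]
    d2 <- pmin(d2, .sqdist_to_centers(X, X[centers[k + 1], , drop = FALSE])[, 1])
  }
  X[centers, , drop = FALSE]
}

# One Lloyd run; returns NULL if a cluster empties.
.lloyd_run <- function(X, K, max_iter) {
  C <- .kmeanspp_init(X, K)
  labels <- max.col(-.sqdist_to_centers(X, C), ties.method = "first")
  sse_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (length(unique(labels)) < K) return(NULL)
    for (k in seq_len(K)) C[k, ] <- colMeans(X[labels == k, , drop = FALSE])
    d2 <- .sqdist_to_centers(X, C)
    new_labels <- max.col(-d2, ties.method = "first")
    sse <- sum(d2[cbind(seq_len(nrow(X)), new_labels)])
    sse_trace <- c(sse_trace, sse)
    if (all(new_labels == labels)) break
    labels <- new_labels
  }
  if (length(unique(labels)) < K) return(NULL)
  list(labels = labels, centers = C, sse = sse, sse_trace = sse_trace, iter = it)
}

#' K-means clustering of patients on their similarity profiles
#'
#' Each patient's feature vector is its row of the full (unthresholded)
#' similarity matrix; clustering is standard Lloyd iteration from a k-means++
#' initialization with the sum of squared errors
#' \eqn{SSE = \sum_i (X_i - \bar X)^2} as the objective. If a cluster empties,
#' the fit is retried once with a perturbed seed before erroring. Cluster
#' labels are canonicalized by descending cluster size.
#'
#' @param sim A `similarity_matrix` (or any numeric matrix whose rows are the
#'   clustering features).
#' @param K Number of clusters, `2 <= K <= n - 1` (K = n is allowed and gives
#'   SSE 0).
#' @param seed Integer seed; identical seeds reproduce labels exactly.
#' @param max_iter Lloyd iteration cap (default 100).
#' @param n_start Number of random restarts; the lowest-SSE run is kept
#'   (default 1, so single runs expose initialization sensitivity for
#'   [stability_analysis()]).
#' @return Object of class `psn_kmeans`: `K`, `centroids` (K x n_train),
#'   `labels` (named integer vector), `training_ids`, `sse`, `sse_trace`
#'   (non-increasing across iterations), `seed`, `iter`.
#' @export
psn_kmeans <- function(sim, K, seed = 1L, max_iter = 100L, n_start = 1L) {
  X <- unclass(as.matrix(sim))
  n <- nrow(X)
  if (K < 2 || K > n) stop("K must be in [2, n]")
  one_start <- function(s) {
    set.seed(s)
    fit <- .lloyd_run(X, K, max_iter)
    if (is.null(fit)) {      # empty cluster: re-seed once, then give up
      set.seed(s + 1000003L)
      fit <- .lloyd_run(X, K, max_iter)
    }
    fit
  }
  fits <- lapply(seed + 7919L * (seq_len(n_start) - 1L), one_start)
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("empty cluster after convergence (all restarts), K = ", K)
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "sse"))]]
  stopifnot(all(diff(fit$sse_trace) <= 1e-8 * max(fit$sse_trace[1], 1)))
  ord <- order(tabulate(fit$labels, K), decreasing = TRUE)
  relab <- match(seq_len(K), ord)
  labels <- relab[fit$labels]
  centroids <- fit$centers[ord, , drop = FALSE]
  ids <- rownames(X) %||% as.character(seq_len(n))
  names(labels) <- ids
  out <- list(K = K, centroids = centroids, labels = labels,
              training_ids = ids, sse = fit$sse, sse_trace = fit$sse_trace,
              seed = as.integer(seed), iter = fit$iter)
  class(out) <- "psn_kmeans"
  out
}

#' @export
print.psn_kmeans <- function(x, ...) {
  cat(sprintf("k-means on similarity profiles: K = %d, n = %d, SSE = %.4g (%d iterations)\n",
              x$K, length(x$labels), x$sse, x$iter))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$K), collapse = "/"), "\n")
  invisible(x)
}

#' Assign new patients to fitted clusters
#'
#' Each new patient is represented by its similarities to the training
#' patients (same axis order as training) and assigned to the nearest centroid
#' in Euclidean distance. Deterministic.
#'
#' @param model A `psn_kmeans` (or `psn_fit`) object.
#' @param sim_test_vs_train Numeric matrix, test patients x training patients.
#' @return Named integer vector of cluster labels.
#' @export
assign_clusters <- function(model, sim_test_vs_train) {
  if (inherits(model, "psn_fit")) model <- model$km
  stopifnot(inherits(model, "psn_kmeans"))
  P <- as.matrix(sim_test_vs_train)
  if (ncol(P) != ncol(model$centroids))
    stop(sprintf("profile dimension (%d) does not match training-set size (%d)",
                 ncol(P), ncol(model$centroids)))
  labels <- max.col(-.sqdist_to_centers(unclass(P), model$centroids), ties.method = "first")
  names(labels) <- rownames(P)
  labels
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions (up to
#' label permutation), about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-300) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Mutual information and entropies from a contingency table (nats).
.mi_entropies <- function(tab) {
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / (pi_[row(pij)[nz]] * pj_[col(pij)[nz]])))
  hu <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hv <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  list(mi = mi, hu = hu, hv = hv)
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance under the permutation
#' (hypergeometric) model, normalized by the arithmetic mean of the two
#' entropies: `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`.
#'
#' @param a,b Label vectors of equal length.
#' @return AMI, at most 1; about 0 for independent partitions.
#' @export
adjusted_mutual_info <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ai <- rowSums(tab); bj <- colSums(tab)
  me <- .mi_entropies(tab)
  if (me$hu == 0 && me$hv == 0) return(1)
  # E[MI] under random permutations with fixed margins
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - n)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      nij <- lo:hi
      lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) + lgamma(n - ai[i] + 1) +
        lgamma(n - bj[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai[i] - nij + 1) - lgamma(bj[j] - nij + 1) -
        lgamma(n - ai[i] - bj[j] + nij + 1)
      emi <- emi + sum(exp(lp) * (nij / n) * log(n * nij / (ai[i] * bj[j])))
    }
  }
  denom <- (me$hu + me$hv) / 2 - emi
  if (abs(denom) < 1e-300) return(0)
  (me$mi - emi) / denom
}

#' Clustering stability across random restarts
#'
#' Refits k-means `n_runs` times from different random initial states and
#' compares every run to the lowest-SSE run (the reference) by ARI and AMI.
#'
#' @param sim A `similarity_matrix`.
#' @param K Number of clusters.
#' @param n_runs Number of restarts (default 100).
#' @param base_seed Seed for run 1; run r uses `base_seed + r - 1`.
#' @param ari_threshold Threshold for the "stable run" count (default 0.8).
#' @return Object of class `stability_report`: data frame `runs` (run, seed,
#'   sse, ari, ami), `reference_run`, `n_stable`, `ari_threshold`.
#' @export
stability_analysis <- function(sim, K, n_runs = 100, base_seed = 1L,
                               ari_threshold = 0.8) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  fits <- lapply(seq_len(n_runs), function(r) psn_kmeans(sim, K, seed = base_seed + r - 1L))
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  ref <- which.min(sse)
  ari <- vapply(fits, function(f) adjusted_rand_index(f$labels, fits[[ref]]$labels),
                numeric(1))
  ami <- vapply(fits, function(f) adjusted_mutual_info(f$labels, fits[[ref]]$labels),
                numeric(1))
  out <- list(
    runs = data.frame(run = seq_len(n_runs), seed = base_seed + seq_len(n_runs) - 1L,
                      sse = sse, ari = ari, ami = ami),
    reference_run = ref,
    n_stable = sum(ari >= ari_threshold),
    ari_threshold = ari_threshold
  )
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability: %d/%d runs with ARI >= %.2f vs lowest-SSE reference (run %d)\n",
              x$n_stable, nrow(x$runs), x$ari_threshold, x$reference_run))
  cat(sprintf("  mean ARI %.3f, mean AMI %.3f\n", mean(x$runs$ari), mean(x$runs$ami)))
  invisible(x)
}

#' Outcome-guided selection of the number of clusters
#'
#' For each candidate K, fits k-means on the similarity profiles and tests
#' whether the clusters separate both overall survival and de novo cardiac
#' events: the omnibus log-rank p must be below `alpha` for both endpoints and
#' every pairwise log-rank comparison (Benjamini-Hochberg adjusted within each
#' endpoint and K) must be significant. Among qualifying K the largest is
#' selected, favouring the finest stratification. The SSE elbow curve is
#' reported alongside.
#'
#' @param sim A `similarity_matrix`.
#' @param outcomes An `outcome_table` (see [classify_events()]) aligned to the
#'   patients in `sim`.
#' @param k_range Candidate K values (default 3:10).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed used for every fit.
#' @return Object of class `k_selection`: `K` (selected, or `NA` if none
#'   qualifies) and `report`, one row per candidate K with SSE, omnibus and
#'   worst pairwise BH-adjusted p per endpoint, and a `qualifies` flag.
#' @export
select_k <- function(sim, outcomes, k_range = 3:10, alpha = 0.05, seed = 1L) {
  stopifnot(inherits(outcomes, "outcome_table"))
  ids <- rownames(sim)
  ot <- outcomes[match(ids, outcomes$patient_id), ]
  if (anyNA(ot$patient_id)) stop("outcomes missing for some patients in sim")
  rows <- lapply(k_range, function(K) {
    fit <- psn_kmeans(sim, K, seed = seed)
    g <- factor(fit$labels)
    os <- km_by_group(ot$os_years, ot$death, g)
    dn <- km_by_group(ot$denovo_years, ot$de_novo_ctrcd, g)
    data.frame(
      K = K, sse = fit$sse,
      p_os = os$omnibus_p, p_denovo = dn$omnibus_p,
      max_pairwise_bh_os = max(os$pairwise$p_bh),
      max_pairwise_bh_denovo = max(dn$pairwise$p_bh),
      qualifies = os$omnibus_p < alpha && dn$omnibus_p < alpha &&
        all(os$pairwise$p_bh < alpha) && all(dn$pairwise$p_bh < alpha)
    )
  })
  report <- do.call(rbind, rows)
  K_sel <- if (any(report$qualifies)) max(report$K[report$qualifies]) else NA_integer_
  out <- list(K = K_sel, report = report, alpha = alpha)
  class(out) <- "k_selection"
  out
}

#' @export
print.k_selection <- function(x, ...) {
  if (is.na(x$K)) cat("No K qualifies at alpha =", x$alpha, "\n")
  else cat("Selected K =", x$K,
           "(largest K with omnibus and all pairwise BH log-rank p <", x$alpha, ")\n")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}
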