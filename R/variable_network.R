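# Per-subgroup clinical-variable correlation networks, top-K% edge selection,
# centrality ranking and cross-subgroup variable clustering.

#' Pairwise Pearson correlations with p-values within one cluster
#'
#' Pearson r for every pair of noncategorical variables over the patients of
#' one subgroup, with two-sided p-values from the t distribution. Constant
#' columns are excluded.
#'
#' @param x Numeric matrix (patients of one cluster x variables).
#' @param min_n Minimum cluster size (default 3).
#' @return List with matrices `r` and `p` (diagonal `NA`), and `n`.
#' @export
cluster_pcc <- function(x, min_n = 3) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < min_n) stop("cluster too small (n = ", n, ", need >= ", min_n, ")")
  sds <- apply(x, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!all(keep)) x <- x[, keep, drop = FALSE]
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(r) <- NA; diag(p) <- NA
  list(r = r, p = p, n = n)
}

#' Collapse derived-feature families to variable-level correlations
#'
#' Longitudinal variables enter the feature matrix as five derived features
#' each. For network construction these families are collapsed back to one
#' node per base variable: the correlation between a family and another
#' variable is the member correlation with the maximum absolute value, its
#' sign retained. Pairs of two families are aggregated the same way over all
#' member pairs when `within_families = "aggregate"`, or dropped (`NA`) when
#' `"exclude"` (the default, which restricts aggregation to family-versus-
#' other pairs).
#'
#' @param pcc Result of [cluster_pcc()] (list with `r`, `p`).
#' @param families Named list: base variable name -> character vector of its
#'   derived feature names (empty families are skipped).
#' @param within_families `"exclude"` (default) or `"aggregate"`.
#' @return List with aggregated `r` and `p` matrices over base variables plus
#'   all non-family variables.
#' @export
aggregate_derived_family <- function(pcc, families,
                                     within_families = c("exclude", "aggregate")) {
  within_families <- match.arg(within_families)
  r <- pcc$r; p <- pcc$p
  families <- families[vapply(families, length, integer(1)) > 0]
  families <- lapply(families, intersect, colnames(r))
  families <- families[vapply(families, length, integer(1)) > 0]
  fam_members <- unlist(families, use.names = FALSE)
  singles <- setdiff(colnames(r), fam_members)
  vars <- c(names(families), singles)
  groups <- c(families, stats::setNames(as.list(singles), singles))
  m <- length(vars)
  ra <- matrix(NA_real_, m, m, dimnames = list(vars, vars))
  pa <- ra
  is_fam <- vars %in% names(families)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      if (is_fam[i] && is_fam[j] && within_families == "exclude") next
      sub_r <- r[groups[[i]], groups[[j]], drop = FALSE]
      sub_p <- p[groups[[i]], groups[[j]], drop = FALSE]
      if (all(is.na(sub_r))) next
      k <- which.max(abs(sub_r))
      ra[i, j] <- sub_r[k]
      pa[i, j] <- sub_p[k]
    }
  }
  list(r = ra, p = pa, n = pcc$n)
}

#' Build a variable network from the top K% strongest correlations
#'
#' Keeps the `fraction` of candidate variable pairs with the largest absolute
#' correlation: the threshold is the `ceiling(fraction * n_pairs)`-th largest
#' `|r|`, and every pair at or above it is included (ties at the threshold are
#' all kept, so the edge count can exceed the nominal quota). Degree and
#' normalized shortest-path betweenness are computed on the unweighted
#' thresholded graph.
#'
#' @param pcc List with `r` (and optionally `p`) matrices, from
#'   [cluster_pcc()] or [aggregate_derived_family()].
#' @param fraction Fraction of candidate pairs to keep, in (0, 1] (default
#'   0.15).
#' @param categories Optional named character vector tagging each variable
#'   (cardiac / echocardiogram / lab / demographics).
#' @return Object of class `variable_network`: `edges` (var1, var2, r, p),
#'   `nodes` (variable, category, degree, betweenness), `threshold`,
#'   `fraction`, `max_p` (largest edge p-value).
#' @export
topk_edges <- function(pcc, fraction = 0.15, categories = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  r <- pcc$r
  p <- pcc$p %||% matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  ut <- upper.tri(r)
  cand <- which(ut & !is.na(r), arr.ind = TRUE)
  if (!nrow(cand)) stop("no candidate variable pairs")
  absr <- abs(r[cand])
  k <- ceiling(fraction * length(absr))
  threshold <- sort(absr, decreasing = TRUE)[k]
  keep <- absr >= threshold
  edges <- data.frame(
    var1 = rownames(r)[cand[keep, 1]], var2 = colnames(r)[cand[keep, 2]],
    r = r[cand[keep, , drop = FALSE]], p = p[cand[keep, , drop = FALSE]],
    stringsAsFactors = FALSE
  )
  net <- .varnet_from_edges(edges, all_vars = rownames(r), categories = categories)
  net$threshold <- threshold
  net$fraction <- fraction
  net$max_p <- if (all(is.na(edges$p))) NA_real_ else max(edges$p, na.rm = TRUE)
  net
}

.varnet_from_edges <- function(edges, all_vars, categories = NULL) {
  cent <- centrality(edges, all_vars)
  nodes <- data.frame(variable = all_vars,
                      category = if (is.null(categories)) NA_character_
                                 else unname(categories[all_vars]),
                      degree = cent$degree, betweenness = cent$betweenness,
                      stringsAsFactors = FALSE)
  out <- list(edges = edges, nodes = nodes)
  class(out) <- "variable_network"
  out
}

#' @export
print.variable_network <- function(x, ...) {
  cat(sprintf("Variable network: %d nodes, %d edges", nrow(x$nodes), nrow(x$edges)))
  if (!is.null(x$threshold))
    cat(sprintf(" (top %.0f%%, |r| >= %.3f)", 100 * x$fraction, x$threshold))
  cat("\n")
  top <- x$nodes[order(-x$nodes$degree), ][seq_len(min(5, nrow(x$nodes))), ]
  cat("  highest degree:", paste(sprintf("%s (%d)", top$variable, top$degree),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Degree and betweenness centrality of a variable network
#'
#' Unweighted degree and normalized shortest-path betweenness on the
#' thresholded graph (edge weights are ignored).
#'
#' @param edges Data frame with columns `var1`, `var2` (or a
#'   `variable_network`).
#' @param all_vars Node universe; isolated variables get degree and
#'   betweenness 0.
#' @return List with named numeric vectors `degree` and `betweenness`.
#' @export
centrality <- function(edges, all_vars = NULL) {
  if (inherits(edges, "variable_network")) {
    all_vars <- all_vars %||% edges$nodes$variable
    edges <- edges$edges
  }
  if (is.null(all_vars)) all_vars <- unique(c(edges$var1, edges$var2))
  g <- igraph::graph_from_data_frame(edges[, c("var1", "var2")], directed = FALSE,
                                     vertices = data.frame(name = all_vars))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = TRUE)
  list(degree = deg[all_vars], betweenness = btw[all_vars])
}

#' Cluster variables by their degree profiles across subgroups
#'
#' Complete-linkage hierarchical clustering on the Euclidean distances between
#' the variables' degree profiles across the subgroup networks.
#'
#' @param degree_matrix Numeric matrix, variables x subgroups, of degrees.
#' @param k Optional number of flat clusters to cut.
#' @return List with the `hclust` object, `leaf_order` (variable names in
#'   dendrogram order) and, if `k` given, `clusters`.
#' @export
cluster_variables <- function(degree_matrix, k = NULL) {
  degree_matrix <- as.matrix(degree_matrix)
  if (nrow(degree_matrix) == 1) {   # singleton tree
    out <- list(hclust = NULL, leaf_order = rownames(degree_matrix))
    if (!is.null(k)) out$clusters <- stats::setNames(1L, rownames(degree_matrix))
    return(out)
  }
  hc <- stats::hclust(stats::dist(degree_matrix), method = "complete")
  out <- list(hclust = hc, leaf_order = rownames(degree_matrix)[hc$order])
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Fraction of weakly correlated variable pairs in the full cohort
#'
#' Summarizes collinearity across all features: the fraction of variable pairs
#' whose absolute Pearson correlation is below `threshold`.
#'
#' @param x Numeric matrix (patients x features), constant columns excluded
#'   automatically.
#' @param threshold Absolute-correlation threshold (default 0.25).
#' @return List with `fraction`, `threshold`, `n_pairs` and the correlation
#'   matrix `r`.
#' @export
collinearity_summary <- function(x, threshold = 0.25) {
  x <- as.matrix(x)
  sds <- apply(x, 2, stats::sd)
  x <- x[, is.finite(sds) & sds > 0, drop = FALSE]
  r <- stats::cor(x)
  off <- abs(r[upper.tri(r)])
  list(fraction = mean(off < threshold), threshold = threshold,
       n_pairs = length(off), r = r)
}

#' Per-variable cluster summaries versus a reference cluster
#'
#' Mean per cluster and two-sample Kolmogorov-Smirnov p-value of each cluster
#' against the reference cluster, per variable.
#'
#' @param x Numeric matrix (patients x variables).
#' @param cluster_labels Cluster labels aligned to rows of `x`.
#' @param reference Reference cluster label (default: the first level).
#' @return Data frame: variable, cluster, mean, ks_p (`NA` for the reference).
#' @export
variable_group_summary <- function(x, cluster_labels, reference = NULL) {
  x <- as.matrix(x)
  cl <- factor(cluster_labels)
  reference <- as.character(reference %||% levels(cl)[1])
  rows <- lapply(colnames(x), function(v) {
    ref_vals <- x[cl == reference, v]
    do.call(rbind, lapply(levels(cl), function(g) {
      vals <- x[cl == g, v]
      ks_p <- if (g == reference) NA_real_ else
        suppressWarnings(stats::ks.test(vals, ref_vals)$p.value)
      data.frame(variable = v, cluster = g, mean = mean(vals), ks_p = ks_p,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derived-feature family map for a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param base_variables Base variables to treat as families (default: all
#'   longitudinal ones found in the feature info).
#' @return Named list base variable -> its derived feature column names.
#' @export
feature_families <- function(fm, base_variables = NULL) {
  info <- fm$feature_info
  long <- info[info$kind != "static", ]
  base_variables <- base_variables %||% unique(long$base_variable)
  stats::setNames(lapply(base_variables, function(b) long$feature[long$base_variable == b]),
                  base_variables)
}

#' Export a variable network
#' @param net A `variable_network`.
#' @param path_edges Tab-separated edge list path.
#' @param path_graphml Optional GraphML path.
#' @return Invisibly, `path_edges`.
#' @export
write_variable_network <- function(net, path_edges, path_graphml = NULL) {
  stopifnot(inherits(net, "variable_network"))
  utils::write.table(net$edges, path_edges, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(net$edges[, c("var1", "var2")],
                                       directed = FALSE,
                                       vertices = data.frame(name = net$nodes$variable))
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(path_edges)
}
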