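# Patient-patient similarity matrix and density-selected network.

#' Pairwise patient similarity matrix
#'
#' Cosine similarity of the patients' feature vectors,
#' \eqn{\sum_i A_i B_i / \sqrt{\sum_i A_i^2}\sqrt{\sum_i B_i^2}}, or Pearson
#' correlation (cosine of the row-centred vectors).
#'
#' @param x A scaled `feature_matrix` or a plain numeric matrix
#'   (patients x features).
#' @param metric `"cosine"` (default) or `"pcc"`.
#' @return Object of class `similarity_matrix`: a dense symmetric matrix with
#'   patient ids as dimnames, unit diagonal, and a `metric` attribute.
#'   Zero-norm patient vectors yield similarity 0 to every other patient, with
#'   a warning.
#' @export
similarity_matrix <- function(x, metric = c("cosine", "pcc")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "feature_matrix")) x$x else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 patients")
  if (anyNA(m)) stop("similarity_matrix expects imputed (NA-free) features")
  if (metric == "pcc") m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm < 1e-300
  if (any(zero)) {
    warning(sum(zero), " zero-norm patient vector(s); their similarities set to 0")
    nrm[zero] <- 1
  }
  s <- tcrossprod(m / nrm)
  if (any(zero)) { s[zero, ] <- 0; s[, zero] <- 0 }
  s <- (s + t(s)) / 2            # exact symmetry despite float round-off
  s[s > 1] <- 1; s[s < -1] <- -1
  diag(s) <- 1
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  dimnames(s) <- list(ids, ids)
  class(s) <- c("similarity_matrix", "matrix")
  attr(s, "metric") <- metric
  s
}

#' @export
print.similarity_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("%s similarity matrix: %d patients; off-diagonal range [%.3f, %.3f]\n",
              attr(x, "metric"), nrow(x), min(off), max(off)))
  invisible(x)
}

#' Network density
#'
#' Ratio of actual edges to all possible edges, `n_edges / (n (n - 1) / 2)`.
#'
#' @param n_edges Number of undirected edges.
#' @param n_nodes Number of nodes (>= 2).
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(n_edges, n_nodes) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  possible <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > possible) stop("n_edges exceeds possible links (", possible, ")")
  if (n_edges < 0) stop("n_edges must be >= 0")
  n_edges / possible
}

# Edge/node counts at a strict similarity cutoff.
.edge_counts <- function(sim, cutoff) {
  adj <- sim > cutoff
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  list(n_edges = sum(adj) / 2, n_nodes = sum(deg > 0), degree = deg)
}

#' Select the visualization cutoff by density minimization
#'
#' Scans a grid of similarity cutoffs; at each cutoff the network keeps edges
#' with similarity strictly above the cutoff and only nodes retaining at least
#' one edge, and its density is computed over those nodes. Returns the cutoff
#' with the lowest density (ties broken toward the smaller cutoff, which
#' retains more patients). Cutoffs at which the network is empty are excluded
#' from the argmin but kept in the profile.
#'
#' @param sim A `similarity_matrix`.
#' @param grid_step Cutoff increment (default 0.05).
#' @param grid_range Length-2 numeric; defaults to the off-diagonal similarity
#'   range rounded to the grid.
#' @return List with `cutoff` (argmin) and `profile`, a data frame of cutoff,
#'   n_nodes, n_edges and density.
#' @export
select_density_cutoff <- function(sim, grid_step = 0.05, grid_range = NULL) {
  stopifnot(inherits(sim, "similarity_matrix"))
  off <- sim[upper.tri(sim)]
  if (is.null(grid_range)) {
    grid_range <- c(floor(min(off) / grid_step) * grid_step,
                    ceiling(max(off) / grid_step) * grid_step)
  }
  grid <- seq(grid_range[1], grid_range[2], by = grid_step)
  prof <- do.call(rbind, lapply(grid, function(cut) {
    ec <- .edge_counts(sim, cut)
    dens <- if (ec$n_nodes >= 2) network_density(ec$n_edges, ec$n_nodes) else NA_real_
    data.frame(cutoff = cut, n_nodes = ec$n_nodes, n_edges = ec$n_edges,
               density = dens)
  }))
  ok <- which(!is.na(prof$density) & prof$n_edges > 0)
  if (!length(ok)) {
    err <- simpleError("all candidate networks are empty")
    err$profile <- prof
    stop(err)
  }
  best <- ok[which.min(prof$density[ok])]  # which.min takes the first = smallest cutoff
  list(cutoff = prof$cutoff[best], profile = prof)
}

#' Threshold the similarity matrix into a patient network
#'
#' Patients are connected when their similarity is strictly greater than the
#' cutoff. Isolated patients are excluded from the node list but reported.
#'
#' @param sim A `similarity_matrix`.
#' @param cutoff Similarity cutoff in `[-1, 1]` (`1` yields an empty edge
#'   set since the inequality is strict).
#' @return Object of class `patient_network`: list with `edges` (data frame
#'   `from`, `to`, `weight`), `nodes`, `isolated`, `cutoff`, `density`.
#' @export
build_network <- function(sim, cutoff) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (cutoff < -1 || cutoff > 1) stop("cutoff must be in [-1, 1]")
  ids <- rownames(sim)
  adj <- sim > cutoff
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      weight = sim[idx], stringsAsFactors = FALSE)
  deg <- rowSums(adj)
  nodes <- ids[deg > 0]
  dens <- if (length(nodes) >= 2) network_density(nrow(edges), length(nodes)) else NA_real_
  out <- list(edges = edges, nodes = nodes, isolated = ids[deg == 0],
              cutoff = cutoff, density = dens)
  class(out) <- "patient_network"
  out
}

#' @export
print.patient_network <- function(x, ...) {
  cat(sprintf("Patient network: %d nodes, %d edges (cutoff > %.3g; %d isolated)\n",
              length(x$nodes), nrow(x$edges), x$cutoff, length(x$isolated)))
  if (!is.na(x$density)) cat(sprintf("  density %.4g%%\n", 100 * x$density))
  invisible(x)
}

#' Export a patient network for external viewers
#'
#' Writes a tab-separated edge list and, optionally, GraphML via igraph.
#'
#' @param net A `patient_network`.
#' @param path_edges Path for the `from  to  weight` tsv.
#' @param path_graphml Optional GraphML path.
#' @return Invisibly, `path_edges`.
#' @export
write_network <- function(net, path_edges, path_graphml = NULL) {
  stopifnot(inherits(net, "patient_network"))
  utils::write.table(net$edges, path_edges, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(path_edges)
}

#' Similarity of new patients against a training set
#'
#' Rectangular similarity matrix between held-out patients and the training
#' patients, in the training patients' axis order, as needed to place new
#' patients into a fitted similarity-profile space.
#'
#' @param train,test Scaled `feature_matrix` objects or numeric matrices with
#'   identical feature columns.
#' @param metric `"cosine"` or `"pcc"`.
#' @return Numeric matrix, test patients x training patients.
#' @export
cross_similarity <- function(train, test, metric = c("cosine", "pcc")) {
  metric <- match.arg(metric)
  a <- if (inherits(train, "feature_matrix")) train$x else as.matrix(train)
  b <- if (inherits(test, "feature_matrix")) test$x else as.matrix(test)
  if (ncol(a) != ncol(b)) stop("train and test must share the feature space")
  if (metric == "pcc") { a <- a - rowMeans(a); b <- b - rowMeans(b) }
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  za <- na < 1e-300; zb <- nb < 1e-300
  if (any(za) || any(zb))
    warning("zero-norm patient vector(s); their similarities set to 0")
  na[za] <- 1; nb[zb] <- 1
  s <- tcrossprod(b / nb, a / na)
  if (any(zb)) s[zb, ] <- 0
  if (any(za)) s[, za] <- 0
  s[s > 1] <- 1; s[s < -1] <- -1
  dimnames(s) <- list(rownames(b), rownames(a))
  s
}
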