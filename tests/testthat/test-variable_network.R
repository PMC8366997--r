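test_that("pairwise Pearson correlations match first-principles computation", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = 2 * c(1, 2, 3, 4, 5) + 1,
             c = c(2, 1, 4, 3, 5))
  p <- cluster_pcc(x)
  expect_equal(p$r["a", "b"], 1)
  # hand oracle: covariance over sd product
  byhand <- function(u, v) {
    num <- sum((u - mean(u)) * (v - mean(v)))
    num / sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_equal(p$r["a", "c"], byhand(x[, "a"], x[, "c"]), tolerance = 1e-12)
  expect_equal(p$p["a", "c"],
               cor.test(x[, "a"], x[, "c"])$p.value, tolerance = 1e-10)
  expect_error(cluster_pcc(x[1:2, ]), "too small")

  set.seed(30)
  big <- matrix(rnorm(20000), 10000, 2)
  expect_lt(abs(cluster_pcc(big)$r[1, 2]), 0.05)  # null property

  # constant columns excluded
  xc <- cbind(x, d = rep(7, 5))
  expect_false("d" %in% colnames(cluster_pcc(xc)$r))
})

test_that("derived-feature families aggregate by max absolute correlation, sign kept", {
  r <- matrix(0, 4, 4, dimnames = rep(list(c("e_max", "e_min", "e_slope", "y")), 2))
  r["e_max", "y"] <- 0.2;  r["y", "e_max"] <- 0.2
  r["e_min", "y"] <- -0.9; r["y", "e_min"] <- -0.9
  r["e_slope", "y"] <- 0.5; r["y", "e_slope"] <- 0.5
  diag(r) <- NA
  pcc <- list(r = r, p = abs(r) / 10, n = 10)
  agg <- aggregate_derived_family(pcc, list(e = c("e_max", "e_min", "e_slope")))
  expect_equal(agg$r["e", "y"], -0.9)
  expect_equal(agg$p["e", "y"], 0.09)

  # single-member family is the identity
  agg1 <- aggregate_derived_family(pcc, list(e = "e_max"))
  expect_equal(agg1$r["e", "y"], 0.2)

  # random families equal a brute-force scan
  set.seed(31)
  m <- 8
  rr <- matrix(runif(m * m, -1, 1), m, m)
  rr <- (rr + t(rr)) / 2; diag(rr) <- NA
  dimnames(rr) <- rep(list(paste0("v", 1:m)), 2)
  fams <- list(A = c("v1", "v2", "v3"), B = c("v4", "v5"))
  agg2 <- aggregate_derived_family(list(r = rr, p = rr, n = 5), fams,
                                   within_families = "aggregate")
  sub <- rr[fams$A, fams$B]
  expect_equal(agg2$r["A", "B"], sub[which.max(abs(sub))])
  sub2 <- rr[fams$A, "v6", drop = FALSE]
  expect_equal(agg2$r["A", "v6"], sub2[which.max(abs(sub2))])
  # default excludes family-family pairs
  agg3 <- aggregate_derived_family(list(r = rr, p = rr, n = 5), fams)
  expect_true(is.na(agg3$r["A", "B"]))
  expect_false(is.na(agg3$r["A", "v6"]))
})

test_that("top-percent edge selection keeps ceil(fraction * pairs) with ties", {
  set.seed(32)
  m <- 10
  r <- matrix(runif(m * m, -1, 1), m, m); r <- (r + t(r)) / 2; diag(r) <- NA
  dimnames(r) <- rep(list(paste0("v", 1:m)), 2)
  net <- topk_edges(list(r = r, n = 20), fraction = 0.15)
  absr <- abs(r[upper.tri(r)])
  expect_equal(net$threshold, oracle_topk_threshold(absr, 0.15))
  expect_equal(nrow(net$edges), sum(absr >= net$threshold))
  expect_gte(nrow(net$edges), ceiling(0.15 * length(absr)))

  # 10 candidate pairs at fraction 0.15 -> 2 edges (no ties in generic draws)
  r5 <- matrix(runif(25, -1, 1), 5, 5); r5 <- (r5 + t(r5)) / 2; diag(r5) <- NA
  dimnames(r5) <- rep(list(paste0("w", 1:5)), 2)
  expect_equal(nrow(topk_edges(list(r = r5, n = 9), fraction = 0.15)$edges), 2)

  full <- topk_edges(list(r = r, n = 20), fraction = 1)
  expect_equal(nrow(full$edges), choose(m, 2))
  expect_error(topk_edges(list(r = r, n = 20), fraction = 0), "fraction")
})

test_that("degree and betweenness match exhaustive path enumeration", {
  path3 <- data.frame(var1 = c("a", "b"), var2 = c("b", "c"))
  cent <- centrality(path3, c("a", "b", "c"))
  expect_equal(unname(cent$betweenness), c(0, 1, 0))
  expect_equal(unname(cent$degree), c(1, 2, 1))

  cg <- expand.grid(var1 = letters[1:4], var2 = letters[1:4],
                    stringsAsFactors = FALSE)
  cg <- cg[cg$var1 < cg$var2, ]
  expect_true(all(centrality(cg, letters[1:4])$betweenness == 0))

  set.seed(33)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- runif(1) < 0.4
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(idx)) next
    ed <- data.frame(var1 = paste0("n", idx[, 1]), var2 = paste0("n", idx[, 2]))
    cent2 <- centrality(ed, paste0("n", 1:n))
    expect_equal(unname(cent2$betweenness), oracle_betweenness(adj),
                 tolerance = 1e-12)
    expect_equal(unname(cent2$degree), rowSums(adj))
  }
})

test_that("variable clustering follows complete linkage; singletons survive", {
  d <- rbind(a = c(0, 0), b = c(0.1, 0), c = c(5, 5), d = c(5.1, 5))
  cl <- cluster_variables(d, k = 2)
  expect_equal(unname(cl$clusters[c("a", "b")]), c(1, 1))
  expect_equal(unname(cl$clusters[c("c", "d")]), c(2, 2))
  # merge heights equal the manual complete-linkage trace
  ref <- hclust(dist(d), method = "complete")
  expect_equal(cl$hclust$height, ref$height)

  single <- cluster_variables(d[1, , drop = FALSE])
  expect_equal(single$leaf_order, "a")
  expect_null(single$hclust)
})

test_that("collinearity summary counts weakly correlated pairs", {
  set.seed(34)
  dup <- matrix(rnorm(50), 50, 1)[, rep(1, 4)]
  expect_equal(collinearity_summary(dup, 0.25)$fraction, 0)

  ind <- matrix(rnorm(4000 * 112), 4000, 112)
  cs <- collinearity_summary(ind, 0.25)
  expect_gt(cs$fraction, 0.999)
  expect_equal(cs$n_pairs, choose(112, 2))
  cs1 <- collinearity_summary(dup, 1.0)
  expect_equal(cs1$fraction, 0)  # all pairs are exactly |r| = 1
})

test_that("per-cluster networks are invariant to permuting patients within the cluster", {
  coh <- planted_cohort(n = 300, seed = 41)
  fit <- psn_fit(coh, K = 4, seed = 1)
  tr <- truth_of(coh, rownames(fit$features$x))
  x1 <- fit$features$x[tr == 1, ]
  p1 <- cluster_pcc(x1)
  p2 <- cluster_pcc(x1[sample(nrow(x1)), ])
  expect_equal(p1$r, p2$r, tolerance = 1e-12)
})

test_that("cardiac biomarkers are better connected in the cardiac-dominant subgroup", {
  coh <- planted_cohort(n = 2000, seed = 11)
  fit <- psn_fit(coh, K = 4, seed = 1)
  tr <- truth_of(coh, rownames(fit$features$x))
  fams <- feature_families(fit$features)
  noncat <- setdiff(colnames(fit$features$x), c("sex_male", "tumor_hematologic"))
  deg <- list(); btw <- list()
  for (g in c(1, 2)) {
    pcc <- cluster_pcc(fit$features$x[tr == g, noncat])
    vn <- topk_edges(aggregate_derived_family(pcc, fams,
                                              within_families = "aggregate"),
                     fraction = 0.15)
    deg[[g]] <- stats::setNames(vn$nodes$degree, vn$nodes$variable)
    btw[[g]] <- stats::setNames(vn$nodes$betweenness, vn$nodes$variable)
  }
  cardiac <- c("NTproBNP", "TroponinT")
  expect_gt(sum(deg[[1]][cardiac]), sum(deg[[2]][cardiac]))
  # rank of the cardiac biomarkers' centrality is higher in the high-risk net
  rank_of <- function(v, nm) mean(rank(v)[nm])
  expect_gt(rank_of(deg[[1]], cardiac), rank_of(deg[[2]], cardiac))
  expect_gte(rank_of(btw[[1]], cardiac), rank_of(btw[[2]], cardiac))
})

test_that("group summaries report means and KS p-values against the reference", {
  set.seed(35)
  x <- cbind(v1 = c(rnorm(50, 5), rnorm(50, 0)), v2 = rnorm(100))
  cl <- rep(c("hi", "lo"), each = 50)
  gs <- variable_group_summary(x, cl, reference = "lo")
  expect_lt(gs$ks_p[gs$variable == "v1" & gs$cluster == "hi"], 1e-6)
  expect_gt(gs$ks_p[gs$variable == "v2" & gs$cluster == "hi"], 0.01)
  expect_true(is.na(gs$ks_p[gs$cluster == "lo"][1]))
})
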