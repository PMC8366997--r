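# Independent brute-force oracles. These deliberately use naive loops and
# first-principles formulas so they share no code path with the package.

oracle_cosine <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(x[i, ] * x[j, ])
    den <- sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2))
    s[i, j] <- if (den > 0) num / den else 0
  }
  s
}

oracle_pcc <- function(x) {
  xc <- t(apply(x, 1, function(r) r - mean(r)))
  oracle_cosine(xc)
}

oracle_density <- function(adj) {
  # adj: logical adjacency (no diagonal); density over nodes with degree >= 1
  deg <- rowSums(adj)
  keep <- deg > 0
  m <- sum(keep)
  if (m < 2) return(NA_real_)
  e <- sum(adj[keep, keep]) / 2
  e / (m * (m - 1) / 2)
}

# threshold for keeping the top `fraction` of |r| values (ties included)
oracle_topk_threshold <- function(absr, fraction) {
  k <- ceiling(fraction * length(absr))
  sort(absr, decreasing = TRUE)[k]
}

# ARI by direct pair counting (no contingency-table shortcut)
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

oracle_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    nij <- sum(a == u & b == v)
    if (nij == 0) next
    mi <- mi + (nij / n) * log(n * nij / (sum(a == u) * sum(b == v)))
  }
  mi
}

oracle_entropy <- function(a) {
  p <- table(a) / length(a)
  -sum(p * log(p))
}

# AMI with E[MI] computed by exhaustive permutation of one labelling (n <= 7)
oracle_ami <- function(a, b) {
  n <- length(a)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  emi <- mean(vapply(perms(seq_len(n)), function(p) oracle_mi(a, b[p]), numeric(1)))
  mi <- oracle_mi(a, b)
  h <- (oracle_entropy(a) + oracle_entropy(b)) / 2
  if (h == emi) return(if (mi == emi) 0 else 1)
  (mi - emi) / (h - emi)
}

# Kaplan-Meier product-limit at each event time, with Greenwood variance
oracle_km <- function(time, status) {
  ts <- sort(unique(time[status == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & status == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Nelson-Aalen cumulative hazard step sum
oracle_na <- function(time, status) {
  ts <- sort(unique(time[status == 1]))
  ch <- numeric(length(ts))
  h <- 0
  for (k in seq_along(ts)) {
    h <- h + sum(time == ts[k] & status == 1) / sum(time >= ts[k])
    ch[k] <- h
  }
  data.frame(time = ts, cumhaz = ch)
}

# Benjamini-Hochberg from the definition (step-up)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Normalized betweenness by exhaustive enumeration of all simple paths (n <= 9)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(from, to, visited) {
    if (from == to) return(list(from))
    out <- list()
    for (nxt in which(adj[from, ] & !visited)) {
      v2 <- visited; v2[nxt] <- TRUE
      for (p in all_paths(nxt, to, v2)) out[[length(out) + 1]] <- c(from, p)
    }
    out
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    vis <- rep(FALSE, n); vis[s] <- TRUE
    paths <- all_paths(s, t, vis)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    shortest <- paths[lens == min(lens)]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      frac <- mean(vapply(shortest, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + frac
    }
  }
  btw / ((n - 1) * (n - 2) / 2)
}

# O(n^2) scan over ordered pairs for the windowed excursion features
oracle_window_features <- function(t, v, window) {
  inc <- dec <- NULL
  o <- order(t); t <- t[o]; v <- v[o]
  for (i in seq_along(t)) for (j in seq_along(t)) {
    if (i < j && t[j] - t[i] <= window && t[j] > t[i]) {
      inc <- c(inc, v[j] - v[i])
      dec <- c(dec, v[i] - v[j])
    }
  }
  list(max_increase = if (is.null(inc)) NA_real_ else max(0, max(inc)),
       max_decrease = if (is.null(dec)) NA_real_ else max(0, max(dec)))
}
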