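# Independent brute-force oracles used to check the package's fast paths.

# Step-up FDR adjustment written directly from the definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# Exhaustive centrality recomputation: Floyd-Warshall distances plus
# shortest-path counting. Suitable for graphs up to ~8 nodes.
brute_centralities <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(sigma) <- 1
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (a == b) next
    d[a, b] <- d[b, a] <- 1
    sigma[a, b] <- sigma[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j]) {
      d[i, j] <- alt
      sigma[i, j] <- sigma[i, k] * sigma[k, j]
    } else if (alt == d[i, j] && is.finite(alt)) {
      sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
    }
  }
  deg <- vapply(nodes, function(v)
    sum((edges$from == v | edges$to == v) & edges$from != edges$to), 0L)
  clo <- vapply(seq_len(n), function(i) {
    s <- sum(d[i, is.finite(d[i, ])])
    if (s > 0) 1 / s else 0
  }, 0)
  btw <- vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t]) || sigma[s, t] == 0) next
      if (d[s, v] + d[v, t] == d[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    tot
  }, 0)
  data.frame(node = nodes, degree = as.integer(deg), closeness = clo,
             betweenness = btw, stringsAsFactors = FALSE)
}

# Random simple undirected graph on <= max_nodes nodes (at least one edge).
random_small_graph <- function(max_nodes = 8) {
  repeat {
    n <- sample(3:max_nodes, 1)
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (any(keep)) break
  }
  data.frame(from = paste0("V", pairs[keep, 1]),
             to = paste0("V", pairs[keep, 2]),
             stringsAsFactors = FALSE)
}

# DEG-table builder for meta-analysis tests: CIs normal-consistent with
# the stated standard errors.
make_deg_table <- function(gene, fc, se, p = NULL) {
  if (is.null(p)) p <- 2 * pnorm(-abs(fc / se))
  data.frame(gene = gene, log2FC = fc,
             CI.L = fc - 1.96 * se, CI.R = fc + 1.96 * se,
             P.Value = p, stringsAsFactors = FALSE)
}
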