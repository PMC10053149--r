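# Independent brute-force oracles used to validate the package's own
# implementations. These deliberately take different computational routes
# than the code under test.

# Betweenness and stress by explicit enumeration of every shortest path
# (igraph::all_shortest_paths), counting interior occurrences per node.
enum_betweenness_stress <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  btw <- stats::setNames(numeric(n), nm)
  str <- stats::setNames(numeric(n), nm)
  if (n < 3) return(list(betweenness = btw, stress = str))
  for (s in 1:(n - 1)) {
    sp <- suppressWarnings(igraph::all_shortest_paths(g, from = s, to = (s + 1):n))
    paths <- sp$res
    if (!length(paths)) next
    ends <- vapply(paths, function(p) as.integer(p[length(p)]), 1L)
    for (t in unique(ends)) {
      pt <- paths[ends == t]
      sigma <- length(pt)
      interior <- unlist(lapply(pt, function(p) nm[as.integer(p[-c(1, length(p))])]))
      if (length(interior)) {
        cnt <- table(interior)
        str[names(cnt)] <- str[names(cnt)] + as.numeric(cnt)
        btw[names(cnt)] <- btw[names(cnt)] + as.numeric(cnt) / sigma
      }
    }
  }
  list(betweenness = btw, stress = str)
}

# Bottleneck oracle: same canonical tree rule (lexicographically smallest
# predecessor) but descendant counts obtained by walking each node's
# parent chain to the root, instead of subtree accumulation.
enum_bottleneck <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  D <- igraph::distances(g)
  bn <- stats::setNames(integer(n), nm)
  for (s in seq_len(n)) {
    dist <- D[s, ]
    parent <- rep(NA_integer_, n)
    for (v in seq_len(n)) {
      if (v == s || is.infinite(dist[v])) next
      preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      parent[v] <- preds[order(nm[preds])][1]
    }
    reach <- which(is.finite(dist))
    tree_n <- length(reach)
    desc <- stats::setNames(integer(n), nm)
    for (u in reach) {
      if (u == s) next
      v <- parent[u]
      while (!is.na(v)) {           # every strict ancestor gains u
        desc[v] <- desc[v] + 1L
        v <- parent[v]
      }
    }
    hit <- setdiff(reach, s)
    hit <- hit[desc[hit] > tree_n / 4]
    bn[hit] <- bn[hit] + 1L
  }
  bn
}

# Benjamini-Hochberg step-up from its textbook definition.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) query
# draws from a universe of size N with an annotated set of size M.
enum_hyper_p <- function(N, M, n, k) {
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= M)        # set = elements 1..M
  mean(overlaps >= k)
}

# Random named simple graph for oracle comparisons.
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# Tiny expression dataset built in code.
toy_dataset <- function(expr, groups, dataset = "DS1") {
  colnames(expr) <- paste0("S", seq_len(ncol(expr)))
  sheet <- data.frame(sample = colnames(expr), group = groups,
                      dataset = dataset, stringsAsFactors = FALSE)
  expression_dataset(expr, sheet)
}

# Minimal gene stats table for consensus tests.
toy_calls <- function(up = character(0), down = character(0),
                      ns = character(0)) {
  data.frame(gene = c(up, down, ns),
             call = c(rep("up", length(up)), rep("down", length(down)),
                      rep("ns", length(ns))),
             stringsAsFactors = FALSE)
}
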