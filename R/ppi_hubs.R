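#' Dice neighborhood similarity between two nodes
#'
#' \code{2 |N_u intersect N_v| / (|N_u| + |N_v|)} over open neighborhoods
#' (each neighborhood may contain the other endpoint). Equals 1 iff the two
#' neighborhoods are identical and non-empty, 0 when disjoint.
#'
#' @param u,v Node names.
#' @param g An \code{igraph} undirected graph.
#' @return A number in [0, 1].
#' @export
dice_similarity <- function(u, v, g) {
  vn <- igraph::V(g)$name
  if (!(u %in% vn) || !(v %in% vn)) stop("node not in graph")
  nu <- igraph::neighbors(g, u)$name
  nv <- igraph::neighbors(g, v)$name
  if (length(nu) + length(nv) == 0L) {
    stop("Dice similarity undefined: both nodes are isolated")
  }
  2 * length(intersect(nu, nv)) / (length(nu) + length(nv))
}

# BFS from one source over an adjacency list: distances and counts of
# shortest paths (sigma) to every node. Unweighted graph.
bfs_sigma <- function(adj, s, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# All-pairs BFS: distance matrix D and shortest-path-count matrix S.
all_pairs_sigma <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    bs <- bfs_sigma(adj, s, n)
    D[s, ] <- bs$dist
    S[s, ] <- bs$sigma
  }
  list(D = D, S = S)
}

#' Degree centrality
#'
#' @param g An \code{igraph} undirected graph.
#' @return Named integer vector of neighbor counts.
#' @export
degree_centrality <- function(g) {
  d <- igraph::degree(g, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

# Shared engine for betweenness and stress: for node v and every unordered
# pair (s,t), sigma_st(v) = sigma_sv * sigma_vt when d_sv + d_vt = d_st.
pair_path_counts <- function(g) {
  n <- igraph::vcount(g)
  ap <- all_pairs_sigma(g)
  D <- ap$D; S <- ap$S
  btw <- numeric(n); str <- numeric(n)
  if (n < 3L) {
    names(btw) <- names(str) <- igraph::V(g)$name
    return(list(betweenness = btw, stress = str))
  }
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], `+`) == D        # d_sv + d_vt == d_st
    through <- outer(S[, v], S[v, ]) * on_path        # sigma_st(v)
    through[v, ] <- 0; through[, v] <- 0
    diag(through) <- 0
    str[v] <- sum(through) / 2                         # unordered pairs
    frac <- through / S
    frac[S == 0] <- 0
    btw[v] <- sum(frac) / 2
  }
  names(btw) <- names(str) <- igraph::V(g)$name
  list(betweenness = btw, stress = str)
}

#' Betweenness centrality (unnormalized, unordered pairs)
#'
#' Shortest-path betweenness \code{sum over pairs s != v != t of
#' sigma_st(v) / sigma_st}, each unordered pair counted once. Disconnected
#' pairs contribute nothing.
#'
#' @param g An \code{igraph} undirected graph.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(g) pair_path_counts(g)$betweenness

#' Stress centrality
#'
#' Total count (not fraction) of shortest paths passing through each node,
#' summed over unordered source-target pairs.
#'
#' @param g An \code{igraph} undirected graph.
#' @return Named numeric vector of non-negative integers.
#' @export
stress_centrality <- function(g) pair_path_counts(g)$stress

# Canonical BFS shortest-path tree rooted at s: each non-root reachable node
# takes as parent its lexicographically smallest predecessor (neighbor at
# distance d - 1). Returns parent indices (NA for root/unreachable).
canonical_sp_tree <- function(adj, dist, nodes, s) {
  n <- length(nodes)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    if (v == s || is.infinite(dist[v])) next
    preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
    parent[v] <- preds[order(nodes[preds])][1L]
  }
  parent
}

#' Bottleneck centrality
#'
#' For each root s, a canonical BFS shortest-path tree is built (ties broken
#' by taking each node's lexicographically smallest predecessor, so the
#' result is deterministic). A node v != s is a bottleneck of that tree when
#' the subtree strictly below v (its descendants, v excluded) holds more than
#' a quarter of the tree's nodes. The centrality of v is the number of roots
#' for which v is a bottleneck; a root is never its own bottleneck.
#'
#' @param g An \code{igraph} undirected graph.
#' @return Named integer vector.
#' @export
bottleneck_centrality <- function(g) {
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  bn <- integer(n)
  names(bn) <- nodes
  if (n < 2L) return(bn)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  for (s in seq_len(n)) {
    dist <- bfs_sigma(adj, s, n)$dist
    parent <- canonical_sp_tree(adj, dist, nodes, s)
    reach <- which(is.finite(dist))
    tree_n <- length(reach)
    # subtree sizes by accumulating from deepest nodes upward
    size <- integer(n)
    size[reach] <- 1L
    ord <- reach[order(dist[reach], decreasing = TRUE)]
    for (v in ord) {
      if (!is.na(parent[v])) size[parent[v]] <- size[parent[v]] + size[v]
    }
    desc <- size - 1L            # strict descendants
    hit <- reach[desc[reach] > tree_n / 4 & reach != s]
    bn[hit] <- bn[hit] + 1L
  }
  bn
}

#' Centrality table for a network
#'
#' Computes all four topological measures (degree, betweenness, stress,
#' bottleneck) per node. Disconnected graphs are handled naturally:
#' cross-component pairs contribute nothing and isolated nodes score 0
#' everywhere.
#'
#' @param g An \code{igraph} undirected simple graph with named nodes.
#' @return Data frame: \code{node}, \code{degree}, \code{betweenness},
#'   \code{stress}, \code{bottleneck}.
#' @export
centrality_table <- function(g) {
  pp <- pair_path_counts(g)
  data.frame(node = igraph::V(g)$name,
             degree = as.integer(degree_centrality(g)),
             betweenness = pp$betweenness,
             stress = pp$stress,
             bottleneck = bottleneck_centrality(g),
             stringsAsFactors = FALSE)
}

#' Union of per-measure top lists
#'
#' The key-gene set is the union of the ranked lists, one per topological
#' measure. Exposed separately so externally supplied (e.g. published)
#' per-measure lists can be combined without recomputing centralities.
#'
#' @param lists Named list of character vectors (one per measure).
#' @return Sorted character vector (symbols normalized).
#' @export
key_gene_union <- function(lists) {
  sort(unique(norm_symbols(unlist(lists, use.names = FALSE))))
}

#' Select key genes by union of per-centrality top-k lists
#'
#' For each of the four measures, the k highest-valued nodes are taken (ties
#' broken lexicographically by symbol); the key-gene set is the union of the
#' four lists.
#'
#' @param table A centrality table from \code{\link{centrality_table}}.
#' @param k Ranked-list length per measure.
#' @return A \code{key_gene_selection}: list with \code{lists} (named list of
#'   the four top-k vectors), \code{union} (sorted character vector) and
#'   \code{k}.
#' @export
select_key_genes <- function(table, k = 6L) {
  if (!nrow(table)) stop("empty centrality table")
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(table)) {
    warning("k exceeds node count; returning all nodes per list")
    k <- nrow(table)
  }
  measures <- c("degree", "betweenness", "stress", "bottleneck")
  lists <- lapply(measures, function(m) {
    ord <- order(-table[[m]], table$node)
    table$node[ord][seq_len(k)]
  })
  names(lists) <- measures
  structure(list(lists = lists, union = key_gene_union(lists),
                 k = as.integer(k)),
            class = "key_gene_selection")
}

#' @export
print.key_gene_selection <- function(x, ...) {
  cat(sprintf("key_gene_selection: k = %d, |union| = %d\n", x$k,
              length(x$union)))
  cat("  ", paste(x$union, collapse = ", "), "\n")
  invisible(x)
}

#' Write a centrality table with per-measure ranks to TSV
#'
#' @param table Centrality table.
#' @param path Output path.
#' @export
write_centralities <- function(table, path) {
  for (m in c("degree", "betweenness", "stress", "bottleneck")) {
    table[[paste0("rank_", m)]] <-
      rank(-table[[m]], ties.method = "min")
  }
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
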