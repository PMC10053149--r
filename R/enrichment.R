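#' Over-representation analysis against a gene-set collection
#'
#' For a query of n genes drawn from a universe of N genes, the p-value for a
#' set of size M with overlap k is the one-sided upper hypergeometric tail
#' \deqn{p = \sum_{x=k}^{\min(n,M)} \binom{M}{x}\binom{N-M}{n-x} / \binom{N}{n},}
#' i.e. the Fisher exact test for over-representation in the 2x2 contingency
#' table (overlap vs the rest of the universe). Depletion is not tested.
#' Query genes outside the universe are dropped with a warning and do not
#' count toward n. P-values are BH-adjusted across the collection.
#'
#' @param query Character vector of query genes.
#' @param collection A \code{\link{gene_set_collection}}.
#' @return Data frame sorted by p ascending: \code{term}, \code{k}, \code{M},
#'   \code{n}, \code{N}, \code{overlap} (\code{"k/M"}), \code{p},
#'   \code{adj_p}, \code{genes} (overlap genes, ';'-separated).
#' @export
enrich <- function(query, collection) {
  query <- unique(norm_symbols(query))
  inside <- intersect(query, collection$universe)
  if (length(inside) < length(query)) {
    warning(length(query) - length(inside),
            " query gene(s) outside the universe dropped")
  }
  if (!length(inside)) stop("no query genes inside the universe")
  n <- length(inside)
  N <- length(collection$universe)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    M <- length(s)
    hit <- intersect(inside, s)
    k <- length(hit)
    # upper tail P(X >= k); phyper works in log space internally
    p <- stats::phyper(k - 1L, M, N - M, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, M = M, n = n, N = N,
               overlap = paste0(k, "/", M), p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("term", "k", "M", "n", "N", "overlap", "p", "adj_p", "genes")]
}

#' Write enrichment results to TSV
#'
#' @param result Data frame from \code{\link{enrich}}.
#' @param path Output path.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result[, c("term", "overlap", "p", "adj_p", "genes")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
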