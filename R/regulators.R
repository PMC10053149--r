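#' Rank regulators by degree onto a target gene set
#'
#' The degree of a regulator is the number of its edges landing inside the
#' supplied target set (not its global degree). Key regulators are those with
#' degree at least \code{min_degree}, ranked by degree descending with
#' lexicographic tie-break. Transcription factors and miRNAs share the same
#' logic and are partitioned by the \code{type} column.
#'
#' @param net A \code{\link{regulatory_network}}.
#' @param targets Character vector of target genes (e.g. the key-gene set).
#' @param min_degree Selection threshold on degree (default 4).
#' @param type Optional filter: \code{"TF"} or \code{"miRNA"}; default keeps
#'   both.
#' @return Data frame ranked by degree: \code{regulator}, \code{type},
#'   \code{degree}, \code{selected}.
#' @export
rank_regulators <- function(net, targets, min_degree = 4L, type = NULL) {
  if (!length(targets)) stop("targets must be non-empty")
  targets <- unique(norm_symbols(targets))
  edges <- net
  if (!is.null(type)) {
    type <- match.arg(type, c("TF", "miRNA"))
    edges <- edges[edges$type == type, , drop = FALSE]
  }
  onto <- edges[edges$target %in% targets, , drop = FALSE]
  regs <- unique(edges[, c("regulator", "type")])
  key <- function(d) paste(d$regulator, d$type, sep = "\r")
  deg <- table(factor(key(onto), levels = key(regs)))
  out <- data.frame(regulator = regs$regulator, type = regs$type,
                    degree = as.integer(deg[key(regs)]),
                    stringsAsFactors = FALSE)
  out$selected <- out$degree >= min_degree
  out <- out[order(-out$degree, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Key regulators of a target set
#'
#' Convenience wrapper returning only the selected regulators of
#' \code{\link{rank_regulators}}.
#'
#' @inheritParams rank_regulators
#' @return Character vector of key regulator names, ranked.
#' @export
key_regulators <- function(net, targets, min_degree = 4L, type = NULL) {
  r <- rank_regulators(net, targets, min_degree = min_degree, type = type)
  r$regulator[r$selected]
}

#' Write a regulator ranking to TSV
#'
#' @param ranking Data frame from \code{\link{rank_regulators}}.
#' @param path Output path.
#' @export
write_regulators <- function(ranking, path) {
  utils::write.table(ranking, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
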