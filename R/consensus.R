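#' Intersect per-dataset DEG calls into consensus DEGs
#'
#' Common up-regulated genes are the intersection of the per-dataset up sets,
#' and likewise for down; the consensus DEG (cDEG) set is their union. A gene
#' absent from some dataset's matrix is simply not called there and therefore
#' cannot be a cDEG; a gene called up in one dataset and down in another is
#' excluded from both common sets by construction.
#'
#' @param calls Named list of gene statistics tables (one per dataset, each
#'   with columns \code{gene} and \code{call}).
#' @return A \code{consensus_sets}: list with \code{up_common},
#'   \code{down_common} (character vectors, sorted) and \code{per_dataset}
#'   (named list of \code{list(up, down)}).
#' @export
intersect_degs <- function(calls) {
  if (!length(calls)) stop("empty dataset map")
  if (is.null(names(calls)) || any(!nzchar(names(calls)))) {
    stop("calls must be a named list (one entry per dataset)")
  }
  per <- lapply(calls, function(st) {
    list(up = sort(st$gene[st$call == "up"]),
         down = sort(st$gene[st$call == "down"]))
  })
  up_common <- sort(Reduce(intersect, lapply(per, `[[`, "up")))
  down_common <- sort(Reduce(intersect, lapply(per, `[[`, "down")))
  structure(list(up_common = up_common, down_common = down_common,
                 per_dataset = per),
            class = "consensus_sets")
}

#' @export
print.consensus_sets <- function(x, ...) {
  cat(sprintf("consensus_sets: %d common up, %d common down (%d datasets)\n",
              length(x$up_common), length(x$down_common),
              length(x$per_dataset)))
  invisible(x)
}

#' All consensus DEGs (union of common up and down sets)
#'
#' @param sets A \code{consensus_sets}.
#' @return Sorted character vector of cDEGs.
#' @export
cdegs <- function(sets) sort(union(sets$up_common, sets$down_common))

#' Gene-by-dataset membership matrix
#'
#' Binary indicator of whether each gene was called (up or down) in each
#' dataset, for genes called in at least one dataset, with a per-gene dataset
#' count. Backs Venn-style reporting of call overlap.
#'
#' @param sets A \code{consensus_sets}.
#' @return Data frame: \code{gene}, one 0/1 column per dataset,
#'   \code{n_datasets}.
#' @export
membership_matrix <- function(sets) {
  ds <- names(sets$per_dataset)
  called <- lapply(sets$per_dataset, function(p) union(p$up, p$down))
  genes <- sort(unique(unlist(called, use.names = FALSE)))
  ind <- vapply(called, function(s) as.integer(genes %in% s),
                integer(length(genes)))
  ind <- matrix(ind, nrow = length(genes), dimnames = list(NULL, ds))
  out <- data.frame(gene = genes, ind, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$n_datasets <- if (length(genes)) rowSums(ind) else integer(0)
  out
}

#' Write consensus DEGs to TSV
#'
#' Columns: gene, direction, n_datasets (number of datasets in which the
#' gene was called in its consensus direction — by construction all of them).
#'
#' @param sets A \code{consensus_sets}.
#' @param path Output path.
#' @export
write_cdegs <- function(sets, path) {
  n <- length(sets$per_dataset)
  df <- rbind(
    data.frame(gene = sets$up_common, direction = "up",
               n_datasets = n, stringsAsFactors = FALSE),
    data.frame(gene = sets$down_common, direction = "down",
               n_datasets = n, stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
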