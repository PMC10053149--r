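#' Read a gene-by-sample expression matrix with its sample sheet
#'
#' The matrix is a TSV whose first column holds gene identifiers and whose
#' header holds sample identifiers; the sample sheet is a CSV with columns
#' \code{sample}, \code{group} (\code{tumor} or \code{normal}) and
#' \code{dataset}. The returned dataset covers exactly the intersection of
#' matrix columns and sheet rows, in sheet order; matrix columns absent from
#' the sheet are dropped with a warning. Gene symbols are upper-cased;
#' duplicate gene rows (e.g. multiple probes per gene) are retained and
#' collapsed only after testing (see \code{\link{run_de}}).
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample-sheet CSV.
#' @param log2_transform If \code{TRUE}, apply \code{log2(x + 1)} to the
#'   values (use when the matrix holds raw intensities/counts).
#' @return An \code{expression_dataset}: list with \code{expr} (numeric
#'   matrix, genes x samples, log2 scale) and \code{samples} (data.frame with
#'   \code{sample}, \code{group}, \code{dataset}).
#' @export
read_expression <- function(matrix_path, sample_sheet_path,
                            log2_transform = FALSE) {
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 2L) stop("expression matrix needs a gene column and >=1 sample")
  genes <- norm_symbols(mat[[1L]])
  expr <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- genes
  sheet <- utils::read.csv(sample_sheet_path, stringsAsFactors = FALSE)
  expression_dataset(expr, sheet, log2_transform = log2_transform)
}

#' Construct and validate an expression dataset
#'
#' @param expr Numeric gene-by-sample matrix (rownames = genes, colnames =
#'   samples).
#' @param samples Data frame with columns \code{sample}, \code{group},
#'   \code{dataset}.
#' @inheritParams read_expression
#' @return An \code{expression_dataset}.
#' @export
expression_dataset <- function(expr, samples, log2_transform = FALSE) {
  need <- c("sample", "group", "dataset")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  samples$sample <- as.character(samples$sample)
  samples$group <- as.character(samples$group)
  samples$dataset <- as.character(samples$dataset)
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(samples$group), c("tumor", "normal"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'tumor' or 'normal')")
  }
  if (is.null(colnames(expr))) stop("expression matrix must have sample names")
  dropped <- setdiff(colnames(expr), samples$sample)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " matrix column(s) absent from the sample sheet: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  }
  keep <- samples$sample[samples$sample %in% colnames(expr)]
  samples <- samples[match(keep, samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  expr <- expr[, keep, drop = FALSE]
  if (anyNA(expr)) stop("expression matrix contains missing values")
  if (log2_transform) expr <- log2(expr + 1)
  n1 <- sum(samples$group == "tumor")
  n2 <- sum(samples$group == "normal")
  if (n1 < 2L || n2 < 2L) {
    stop("need >=2 samples per group (got ", n1, " tumor, ", n2, " normal)")
  }
  structure(list(expr = expr, samples = samples), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$samples$group == "tumor"),
              sum(x$samples$group == "normal")))
  invisible(x)
}

#' Write an expression dataset back to TSV + CSV
#'
#' Inverse of \code{\link{read_expression}} (round-trip identity up to
#' numeric formatting).
#'
#' @param dataset An \code{expression_dataset}.
#' @param matrix_path Output TSV path.
#' @param sample_sheet_path Output CSV path.
#' @export
write_expression <- function(dataset, matrix_path, sample_sheet_path) {
  df <- data.frame(gene = rownames(dataset$expr), dataset$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(dataset$samples, sample_sheet_path, row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}

#' Read an undirected PPI edge list (TSV or SIF)
#'
#' Two-column TSV (an optional third score column is ignored), or SIF
#' (\code{node relation node}) when the file extension is \code{.sif}.
#' Node symbols are upper-cased; self-loops are dropped and duplicate edges in
#' either orientation collapsed, yielding a simple undirected graph.
#'
#' @param path Path to the edge-list file.
#' @return An \code{igraph} undirected simple graph.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(lines, "[\t ]+")
  nf <- lengths(parts)
  sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  min_fields <- if (sif) 3L else 2L
  if (any(nf < min_fields)) {
    stop("edge-list line(s) with too few fields: line ",
         which(nf < min_fields)[1L])
  }
  a <- norm_symbols(vapply(parts, `[`, "", 1L))
  b <- norm_symbols(vapply(parts, `[`, "", if (sif) 3L else 2L))
  edges_to_graph(a, b)
}

edges_to_graph <- function(a, b) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]
  nodes <- sort(unique(c(a, b, lo, hi)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(lo)) g <- igraph::add_edges(g, rbind(lo, hi))
  g
}

#' Write a network as a two-column TSV edge list
#'
#' @param g An \code{igraph} graph.
#' @param path Output path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' Gene symbols are upper-cased. The universe defaults to the union of all
#' set members unless \code{universe} overrides it.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector overriding the gene universe.
#' @return A \code{gene_set_collection}: list with \code{sets} (named list of
#'   character vectors) and \code{universe}.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("GMT set with no genes at line ", which(lengths(parts) < 3L)[1L])
  }
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(norm_symbols(p[-(1:2)])))
  names(sets) <- nm
  gene_set_collection(sets, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors (each non-empty).
#' @param universe Optional character universe; defaults to the union of all
#'   set members. Sets are harmonized to (intersected with) the universe.
#' @return A \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a non-empty named list")
  }
  sets <- lapply(sets, function(s) unique(norm_symbols(s)))
  if (any(lengths(sets) == 0L)) stop("empty gene set")
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets, use.names = FALSE)))
  } else {
    universe <- sort(unique(norm_symbols(universe)))
    sets <- lapply(sets, intersect, y = universe)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param collection A \code{gene_set_collection}.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, nm, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a receptor-by-drug binding-affinity matrix (CSV)
#'
#' Receptors are rows, drugs are columns, entries are docking scores in
#' kcal/mol (more negative = stronger predicted binding). The matrix must be
#' complete: any empty or non-numeric cell is an error — no imputation.
#'
#' @param path Path to the CSV.
#' @return A numeric matrix (receptors x drugs) with unique dimnames.
#' @export
read_affinity <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!ncol(df)) stop("affinity matrix has no drug columns")
  suppressWarnings(am <- vapply(df, as.numeric, numeric(nrow(df))))
  am <- matrix(am, nrow = nrow(df),
               dimnames = list(rownames(df), colnames(df)))
  affinity_matrix(am)
}

#' Validate a binding-affinity matrix
#'
#' @param am Numeric matrix, receptors x drugs, complete, unique dimnames.
#' @return The validated matrix.
#' @export
affinity_matrix <- function(am) {
  if (!is.matrix(am) || !is.numeric(am)) stop("affinity matrix must be numeric")
  if (anyNA(am)) stop("affinity matrix contains missing/non-numeric cells")
  if (is.null(rownames(am)) || is.null(colnames(am))) {
    stop("affinity matrix needs receptor and drug names")
  }
  if (anyDuplicated(rownames(am))) stop("duplicate receptor names")
  if (anyDuplicated(colnames(am))) stop("duplicate drug names")
  am
}

#' Write an affinity matrix to CSV
#'
#' @param am Affinity matrix.
#' @param path Output path.
#' @export
write_affinity <- function(am, path) {
  utils::write.csv(data.frame(receptor = rownames(am), am,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Read a bipartite regulator-target edge list
#'
#' TSV with columns \code{regulator}, \code{target}, \code{type}
#' (\code{TF} or \code{miRNA}). Target symbols are upper-cased (they are
#' genes); regulator names are kept verbatim (miRNA names are case
#' sensitive). Duplicate triples are collapsed.
#'
#' @param path Path to the TSV.
#' @return A \code{regulatory_network}: data.frame with \code{regulator},
#'   \code{target}, \code{type}.
#' @export
read_regulatory <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  regulatory_network(df)
}

#' Construct a bipartite regulatory network
#'
#' @param edges Data frame with columns \code{regulator}, \code{target},
#'   \code{type} in \code{c("TF", "miRNA")}.
#' @return A validated \code{regulatory_network} data.frame.
#' @export
regulatory_network <- function(edges) {
  need <- c("regulator", "target", "type")
  if (!all(need %in% names(edges))) {
    stop("regulatory network needs columns: ", paste(need, collapse = ", "))
  }
  edges <- edges[, need]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- norm_symbols(edges$target)
  edges$type <- as.character(edges$type)
  bad <- setdiff(unique(edges$type), c("TF", "miRNA"))
  if (length(bad)) stop("unknown regulator type(s): ", paste(bad, collapse = ", "))
  edges <- unique(edges)
  rownames(edges) <- NULL
  class(edges) <- c("regulatory_network", "data.frame")
  edges
}
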