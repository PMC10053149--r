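#' Rank receptors by aggregate binding strength
#'
#' Receptors are ordered by the row sum of the affinity matrix. Affinities
#' are negative (kcal/mol), so the arithmetically smallest (most negative)
#' total — the strongest aggregate binder — comes first. Ties break
#' lexicographically.
#'
#' @param am Affinity matrix (receptors x drugs).
#' @return Character vector: receptor names, strongest first.
#' @export
rank_receptors <- function(am) {
  rs <- rowSums(am)
  rownames(am)[order(rs, rownames(am))]
}

#' Rank drugs by aggregate binding strength
#'
#' Drugs are ordered by column sum (most negative first). Each drug carries
#' its mean affinity across receptors and its hit count: the number of
#' receptors bound at or below \code{tau_hit} kcal/mol.
#'
#' @param am Affinity matrix (receptors x drugs).
#' @param tau_hit Per-cell significance cutoff in kcal/mol (default -7.0).
#' @return A \code{drug_ranking}: data.frame ordered strongest-first with
#'   \code{drug}, \code{column_sum}, \code{mean_affinity}, \code{hits}; the
#'   receptor count m and \code{tau_hit} are attached as attributes.
#' @export
rank_drugs <- function(am, tau_hit = -7.0) {
  cs <- colSums(am)
  out <- data.frame(drug = colnames(am), column_sum = cs,
                    mean_affinity = colMeans(am),
                    hits = as.integer(colSums(am <= tau_hit)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$column_sum, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- nrow(am)
  attr(out, "tau_hit") <- tau_hit
  class(out) <- c("drug_ranking", "data.frame")
  out
}

#' Select candidate drugs
#'
#' A drug is a candidate when it hits at least
#' \code{ceiling(min_hit_fraction * m)} of the m receptors at \code{tau_hit}
#' and its mean affinity is at or below \code{tau_mean}. The default hit
#' fraction \code{(m - 1) / m} demands all but one receptor.
#'
#' @param ranking A \code{\link{drug_ranking}}.
#' @param config A \code{\link{pipeline_config}} supplying \code{tau_mean}
#'   and \code{min_hit_fraction}.
#' @return The candidate rows of the ranking (strongest first), with a
#'   \code{thresholds} attribute recording the cutoffs used.
#' @export
select_candidates <- function(ranking, config = pipeline_config()) {
  m <- attr(ranking, "m")
  if (is.null(m)) stop("ranking lacks receptor count; use rank_drugs()")
  frac <- config$min_hit_fraction
  if (is.na(frac)) frac <- (m - 1) / m
  min_hits <- ceiling(frac * m)
  sel <- ranking$hits >= min_hits & ranking$mean_affinity <= config$tau_mean
  out <- ranking[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(tau_hit = attr(ranking, "tau_hit"),
                                  tau_mean = config$tau_mean,
                                  min_hits = min_hits, m = m)
  out
}

#' Cross-validate a drug ranking against an independent receptor panel
#'
#' The two matrices are inner-joined on drug names; each is ranked by column
#' sum over the shared drugs. Reports the fraction of the main panel's
#' top-\code{top_n} drugs recovered in the independent panel's top-n, and
#' the Kendall rank correlation of the shared column sums.
#'
#' @param am_main,am_indep Affinity matrices sharing drug columns.
#' @param top_n Size of the top lists compared.
#' @return List: \code{overlap} (fraction in [0, 1]), \code{tau} (Kendall),
#'   \code{shared} (number of shared drugs), \code{top_main},
#'   \code{top_indep} (character vectors).
#' @export
crossvalidate <- function(am_main, am_indep, top_n) {
  shared <- intersect(colnames(am_main), colnames(am_indep))
  if (!length(shared)) stop("no shared drugs between the two panels")
  if (top_n < 1L || top_n > length(shared)) {
    stop("top_n must be between 1 and the number of shared drugs")
  }
  cs1 <- colSums(am_main[, shared, drop = FALSE])
  cs2 <- colSums(am_indep[, shared, drop = FALSE])
  top1 <- shared[order(cs1, shared)][seq_len(top_n)]
  top2 <- shared[order(cs2, shared)][seq_len(top_n)]
  tau <- if (length(shared) > 1L) {
    stats::cor(cs1, cs2, method = "kendall")
  } else 1
  list(overlap = length(intersect(top1, top2)) / top_n, tau = tau,
       shared = length(shared), top_main = top1, top_indep = top2)
}

#' Assemble an affinity matrix from per-pair docking score files
#'
#' Each file holds the scored poses of one (receptor, drug) pair, named
#' \code{<receptor>__<drug>.<ext>}; the cell value is the best (most
#' negative) pose score. Files are parsed as AutoDock-Vina-style result
#' tables: lines whose first field is a pose index followed by the affinity
#' in kcal/mol. Every receptor-drug combination seen must be covered.
#'
#' @param paths Character vector of score-file paths.
#' @return Affinity matrix (receptors x drugs).
#' @export
parse_vina_results <- function(paths) {
  if (!length(paths)) stop("no score files supplied")
  base <- sub("\\.[^.]*$", "", basename(paths))
  parts <- strsplit(base, "__", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("file name(s) not of the form <receptor>__<drug>.<ext>: ",
         basename(paths)[lengths(parts) != 2L][1L])
  }
  rec <- vapply(parts, `[`, "", 1L)
  drg <- vapply(parts, `[`, "", 2L)
  score <- vapply(seq_along(paths), function(i) {
    lines <- readLines(paths[i])
    m <- regmatches(lines,
                    regexec("^\\s*\\d+\\s+(-?[0-9]+\\.?[0-9]*)", lines))
    vals <- suppressWarnings(as.numeric(vapply(m, function(x)
      if (length(x) == 2L) x[2L] else NA_character_, "")))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) stop("unparseable score file: ", basename(paths[i]))
    min(vals)
  }, numeric(1))
  receptors <- sort(unique(rec)); drugs <- sort(unique(drg))
  am <- matrix(NA_real_, length(receptors), length(drugs),
               dimnames = list(receptors, drugs))
  am[cbind(rec, drg)] <- score
  if (anyNA(am)) {
    miss <- which(is.na(am), arr.ind = TRUE)
    stop("missing receptor-drug pair(s): ",
         paste(receptors[miss[, 1L]], drugs[miss[, 2L]],
               sep = "/", collapse = ", "))
  }
  affinity_matrix(am)
}

#' Write a drug ranking to TSV
#'
#' @param ranking A \code{\link{drug_ranking}}; if \code{candidates} is
#'   given, a logical \code{selected} column is added.
#' @param path Output path.
#' @param candidates Optional candidate set from
#'   \code{\link{select_candidates}}.
#' @export
write_drug_ranking <- function(ranking, path, candidates = NULL) {
  out <- as.data.frame(ranking)
  if (!is.null(candidates)) out$selected <- out$drug %in% candidates$drug
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Reorder an affinity matrix by receptor and drug strength
#'
#' Rows and columns sorted strongest-first (heatmap-ready layout).
#'
#' @param am Affinity matrix.
#' @return The reordered matrix.
#' @export
order_affinity <- function(am) {
  am[rank_receptors(am), rank_drugs(am)$drug, drop = FALSE]
}
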