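#' Pipeline configuration
#'
#' Bundles every tunable threshold of the signature-discovery pipeline in one
#' validated object. Defaults reproduce the decision rules used throughout the
#' package: DEGs are genes with BH-adjusted p below \code{alpha} and
#' \code{|aLog2FC|} above \code{lfc_threshold}; key genes are the union of the
#' per-centrality top-\code{top_k} lists; key regulators need degree at least
#' \code{regulator_min_degree} onto the key-gene set; a candidate drug must
#' bind at least \code{ceiling(min_hit_fraction * m)} of the \code{m} receptors
#' at or below \code{tau_hit} kcal/mol and have mean affinity at or below
#' \code{tau_mean} kcal/mol.
#'
#' @param alpha Adjusted-p cutoff for DEG calls, in (0, 1].
#' @param lfc_threshold Absolute average log2 fold-change cutoff, >= 0.
#' @param top_k Per-centrality ranked-list length for key-gene selection.
#' @param regulator_min_degree Minimum degree onto the target set for a key
#'   regulator.
#' @param tau_hit Per-cell affinity significance cutoff (kcal/mol, <= 0).
#' @param tau_mean Mean-affinity candidate cutoff (kcal/mol, <= 0).
#' @param min_hit_fraction Fraction of receptors a candidate drug must hit, in
#'   (0, 1]. \code{NA} (default) resolves to \code{(m - 1) / m} at selection
#'   time, i.e. all but one receptor.
#' @param log2_transform If \code{TRUE}, readers apply \code{log2(x + 1)} to
#'   raw (non-log) expression values.
#' @param seed Integer seed recorded for reproducibility of any downstream
#'   simulation.
#' @return An object of class \code{pipeline_config} (a validated list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$alpha
#' @export
pipeline_config <- function(alpha = 0.01, lfc_threshold = 1.0, top_k = 6L,
                            regulator_min_degree = 4L, tau_hit = -7.0,
                            tau_mean = -7.5, min_hit_fraction = NA_real_,
                            log2_transform = FALSE, seed = 1L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (top_k < 1) stop("top_k must be >= 1")
  if (regulator_min_degree < 0) stop("regulator_min_degree must be >= 0")
  if (tau_hit > 0) stop("tau_hit must be <= 0 (kcal/mol)")
  if (tau_mean > 0) stop("tau_mean must be <= 0 (kcal/mol)")
  if (!is.na(min_hit_fraction) &&
      (min_hit_fraction <= 0 || min_hit_fraction > 1)) {
    stop("min_hit_fraction must be in (0, 1]")
  }
  structure(
    list(alpha = alpha, lfc_threshold = lfc_threshold,
         top_k = as.integer(top_k),
         regulator_min_degree = as.integer(regulator_min_degree),
         tau_hit = tau_hit, tau_mean = tau_mean,
         min_hit_fraction = min_hit_fraction,
         log2_transform = isTRUE(log2_transform),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  cat(sprintf("  alpha = %g, lfc_threshold = %g, top_k = %d\n",
              x$alpha, x$lfc_threshold, x$top_k))
  cat(sprintf("  regulator_min_degree = %d\n", x$regulator_min_degree))
  cat(sprintf("  tau_hit = %g, tau_mean = %g, min_hit_fraction = %s\n",
              x$tau_hit, x$tau_mean,
              if (is.na(x$min_hit_fraction)) "(m-1)/m" else
                format(x$min_hit_fraction)))
  invisible(x)
}

#' Normalize gene/protein symbols
#'
#' Upper-cases and trims whitespace so symbols join reliably across pipeline
#' stages (expression tables, PPI networks, gene sets, receptor panels).
#' Idempotent.
#'
#' @param x Character vector of symbols.
#' @return Normalized character vector.
#' @export
norm_symbols <- function(x) toupper(trimws(as.character(x)))
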