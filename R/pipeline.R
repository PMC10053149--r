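#' Run the full signature-discovery pipeline
#'
#' Chains the stages end to end: per-dataset moderated-t differential
#' expression, direction-wise consensus into cDEGs, centrality-based key-gene
#' selection on the PPI network (restricted to cDEG nodes when
#' \code{induce_cdegs}), optional gene-set enrichment of the cDEGs, optional
#' regulator ranking onto the key genes, and optional drug prioritization
#' with cross-validation against an independent receptor panel.
#'
#' @param datasets Named list of \code{expression_dataset} objects.
#' @param ppi \code{igraph} PPI network (optional).
#' @param collection \code{gene_set_collection} for enrichment (optional).
#' @param regnet \code{regulatory_network} (optional).
#' @param am Affinity matrix, receptors x drugs (optional).
#' @param am_indep Independent-panel affinity matrix (optional; needs
#'   \code{am}).
#' @param config A \code{\link{pipeline_config}}.
#' @param induce_cdegs Restrict the PPI network to cDEG nodes before
#'   computing centralities (default TRUE).
#' @param top_n_crossval Top-list size for cross-validation; defaults to the
#'   number of selected candidate drugs.
#' @return List of stage results: \code{de} (per-dataset stats tables),
#'   \code{consensus}, \code{cdegs}, \code{centralities}, \code{key_genes},
#'   \code{enrichment}, \code{regulators}, \code{drug_ranking},
#'   \code{candidates}, \code{crossval}.
#' @export
run_pipeline <- function(datasets, ppi = NULL, collection = NULL,
                         regnet = NULL, am = NULL, am_indep = NULL,
                         config = pipeline_config(), induce_cdegs = TRUE,
                         top_n_crossval = NULL) {
  de <- lapply(datasets, run_de, config = config)
  cons <- intersect_degs(de)
  cd <- cdegs(cons)
  out <- list(de = de, consensus = cons, cdegs = cd)
  if (!is.null(ppi)) {
    g <- ppi
    if (induce_cdegs) {
      keep <- intersect(igraph::V(g)$name, cd)
      g <- igraph::induced_subgraph(g, keep)
    }
    ct <- centrality_table(g)
    out$centralities <- ct
    if (nrow(ct)) {
      out$key_genes <- select_key_genes(ct, k = min(config$top_k, nrow(ct)))
    }
  }
  if (!is.null(collection) && length(cd)) {
    out$enrichment <- enrich(cd, collection)
  }
  if (!is.null(regnet) && !is.null(out$key_genes)) {
    out$regulators <- rank_regulators(regnet, out$key_genes$union,
                                      min_degree = config$regulator_min_degree)
  }
  if (!is.null(am)) {
    rk <- rank_drugs(am, tau_hit = config$tau_hit)
    cand <- select_candidates(rk, config)
    out$drug_ranking <- rk
    out$candidates <- cand
    if (!is.null(am_indep)) {
      tn <- if (is.null(top_n_crossval)) max(nrow(cand), 1L) else top_n_crossval
      out$crossval <- crossvalidate(am, am_indep, top_n = tn)
    }
  }
  out
}
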