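#' Published colorectal-cancer example: centrality top lists and regulators
#'
#' A worked example drawn from a published colorectal-cancer signature
#' study: the per-measure top-ranked gene lists from the cDEG PPI network
#' (degree, bottleneck, betweenness, stress) whose union forms the reported
#' 11-gene key-gene set, and the four key transcription factors regulating
#' it. Uniting key genes and key TFs yields the 15-protein receptor panel
#' used for drug docking. Two key-gene entries (CEMIP, ADH1C) appear in the
#' reported union but their column assignment is not recoverable from the
#' published table layout; they are placed synthetically in the degree and
#' betweenness columns, which leaves the union — the quantity the lists are
#' used for — unchanged.
#'
#' @return List: \code{centrality_lists} (named list of four character
#'   vectors), \code{key_tfs}, \code{key_mirnas} (character vectors).
#' @export
crc_example_lists <- function() {
  list(
    centrality_lists = list(
      degree      = c("GUCA2A", "GUCA2B", "CLDN1", "CLCA4", "MS4A12", "CEMIP"),
      bottleneck  = c("CLDN1", "CXCL8", "CLCA4", "MMP7", "ZG16"),
      betweenness = c("CXCL8", "CLDN1", "GUCA2A", "MMP7", "CA4", "ADH1C"),
      stress      = c("CLDN1", "GUCA2A", "GUCA2B", "CXCL8", "CA4")
    ),
    key_tfs = c("FOXC1", "YY1", "GATA2", "NFKB1"),
    key_mirnas = c("hsa-mir-16-5p", "hsa-mir-195-5p", "hsa-mir-203a-3p",
                   "hsa-mir-34a-5p", "hsa-mir-107", "hsa-mir-27a-3p",
                   "hsa-mir-429", "hsa-mir-335-5p")
  )
}

#' Receptor panel from key genes and key transcription factors
#'
#' The docking receptor panel is the union of the key-gene proteins and
#' their key transcriptional regulators.
#'
#' @param key_genes Character vector of key genes.
#' @param key_tfs Character vector of key TFs.
#' @return Sorted character vector of receptor names.
#' @export
receptor_panel <- function(key_genes, key_tfs) {
  sort(unique(norm_symbols(c(key_genes, key_tfs))))
}
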