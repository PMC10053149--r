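#' ROC AUC via the Mann-Whitney identity
#'
#' The area under the ROC curve equals the fraction of (positive, negative)
#' score pairs in which the positive scores higher, with ties counted one
#' half. Computed from midranks, so ties are handled exactly.
#'
#' @param scores Numeric score vector (higher = more tumor-like).
#' @param labels Binary vector (1/TRUE = tumor/positive), same length.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)                       # midranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False- and true-positive rates at every score threshold (descending),
#' suitable for plotting or export.
#'
#' @inheritParams roc_auc
#' @return Data frame: \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & labels == 0L) / n0,
      tpr = sum(pred & labels == 1L) / n1)
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, pts)
}

#' Two-group separation of unsupervised hierarchical clustering
#'
#' Samples are clustered by average-linkage hierarchical clustering on
#' pairwise distances (1 - Pearson correlation of expression profiles by
#' default, Euclidean optionally), the tree is cut at two clusters, and
#' purity is the accuracy of the best assignment of cluster identities to
#' the two class labels. Chance level is the majority class proportion.
#'
#' @param expr Numeric gene-by-sample matrix (e.g. restricted to key genes).
#' @param labels Binary vector, one per sample (1/TRUE = tumor).
#' @param metric \code{"correlation"} (default) or \code{"euclidean"}.
#' @return Purity in [0.5, 1] for balanced classes (max class proportion, 1
#'   in general).
#' @export
cluster_purity <- function(expr, labels, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  labels <- as.integer(as.logical(labels))
  if (ncol(expr) != length(labels)) stop("labels must match sample count")
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  if (nrow(expr) < 2L) stop("need >= 2 genes")
  if (metric == "correlation") {
    sds <- apply(expr, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant sample profile(s), correlation undefined: ",
           paste(colnames(expr)[sds == 0], collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(expr))
  } else {
    d <- stats::dist(t(expr))
  }
  cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2L)
  tab <- table(factor(cl, levels = 1:2), factor(labels, levels = 0:1))
  max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1]) / length(labels)
}
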