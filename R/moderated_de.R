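#' Fit per-gene two-group linear models
#'
#' For each gene, the two-group linear model on log2 expression is fit by
#' group means: the contrast estimate \code{gamma_hat} is mean(tumor) -
#' mean(normal), \code{s2} the pooled within-group residual variance on
#' \code{df_residual = n1 + n2 - 2} degrees of freedom, and \code{delta =
#' 1/n1 + 1/n2} the design scale factor so that \code{Var(gamma_hat) =
#' delta * sigma_g^2}. Per-sample weights are accepted as a hook but only the
#' default unit weights are supported in the decision rules downstream.
#'
#' @param dataset An \code{expression_dataset}.
#' @param weights Optional per-sample positive weights (length = number of
#'   samples). The default \code{NULL} means unit weights.
#' @return A data.frame (one row per gene row of the matrix): \code{gene},
#'   \code{gamma_hat}, \code{s2}, \code{df_residual}, \code{delta}.
#' @export
fit_gene_models <- function(dataset, weights = NULL) {
  expr <- dataset$expr
  grp <- dataset$samples$group
  n1 <- sum(grp == "tumor"); n2 <- sum(grp == "normal")
  df <- n1 + n2 - 2L
  if (df < 1L) stop("zero residual degrees of freedom")
  if (is.null(weights)) weights <- rep(1, ncol(expr))
  if (length(weights) != ncol(expr) || any(weights <= 0)) {
    stop("weights must be positive, one per sample")
  }
  w <- weights
  idx1 <- which(grp == "tumor"); idx2 <- which(grp == "normal")
  w1 <- w[idx1]; w2 <- w[idx2]
  m1 <- as.vector(expr[, idx1, drop = FALSE] %*% w1) / sum(w1)
  m2 <- as.vector(expr[, idx2, drop = FALSE] %*% w2) / sum(w2)
  r1 <- sweep(expr[, idx1, drop = FALSE], 1L, m1)
  r2 <- sweep(expr[, idx2, drop = FALSE], 1L, m2)
  ss <- as.vector(r1^2 %*% w1) + as.vector(r2^2 %*% w2)
  s2 <- pmax(ss / df, 0)
  data.frame(gene = rownames(expr), gamma_hat = m1 - m2, s2 = s2,
             df_residual = df, delta = 1 / sum(w1) + 1 / sum(w2),
             stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Solves \code{trigamma(y) = x} for \code{y > 0} by monotone bisection
#' (trigamma is strictly decreasing on the positive axis). Used to
#' moment-match the prior degrees of freedom from the spread of log sample
#' variances.
#'
#' @param x Positive target value.
#' @param tol Absolute tolerance on \code{y}.
#' @return The solution \code{y}.
#' @export
trigamma_inverse <- function(x, tol = 1e-8) {
  stopifnot(is.finite(x), x > 0)
  lo <- 1e-6; hi <- 1
  while (trigamma(lo) < x) lo <- lo / 2       # trigamma(lo) must exceed x
  while (trigamma(hi) > x) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > x) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Estimate the variance prior by moment matching
#'
#' Treats the gene-wise sample variances as draws from a scaled inverse
#' chi-square prior with degrees of freedom \code{d0} and scale \code{s0_sq},
#' and recovers both hyperparameters from the first two moments of
#' \code{e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)}: the excess variance
#' of \code{e_g} over \code{trigamma(d_g/2)} identifies \code{d0} through
#' trigamma inversion, and its mean then gives \code{s0_sq} in closed form.
#' When the excess variance is non-positive (no detectable gene-to-gene
#' variance heterogeneity) the prior is degenerate: \code{d0 = Inf} with
#' \code{s0_sq} at the corresponding limit.
#'
#' @param fits Data frame from \code{\link{fit_gene_models}} (uses columns
#'   \code{s2} and \code{df_residual}).
#' @return A \code{variance_prior}: list with \code{d0} and \code{s0_sq}.
#' @export
estimate_prior <- function(fits) {
  s2 <- fits$s2
  d <- fits$df_residual
  ok <- s2 > 0
  if (sum(ok) < 10L) stop("need >= 10 genes with positive sample variance")
  s2 <- s2[ok]; d <- if (length(d) == 1L) rep(d, sum(ok)) else d[ok]
  if (max(s2) - min(s2) == 0) {
    return(structure(list(d0 = Inf, s0_sq = s2[1L]), class = "variance_prior"))
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat(sprintf("variance_prior: d0 = %g, s0_sq = %g\n", x$d0, x$s0_sq))
  invisible(x)
}

#' Moderated t-statistics
#'
#' Shrinks each gene's sample variance toward the prior via the posterior
#' variance \code{s2_post = (d0 * s0_sq + d_g * s2_g) / (d0 + d_g)} and forms
#' \code{t_mod = gamma_hat / sqrt(s2_post * delta)}, referred to a
#' t-distribution with \code{d_g + d0} degrees of freedom (two-sided).
#' With \code{d0 = 0} this is exactly the classical pooled two-sample t;
#' as \code{d0 -> Inf} it tends to \code{gamma_hat / sqrt(s0_sq * delta)}
#' with a normal reference.
#'
#' @param fits Data frame from \code{\link{fit_gene_models}}.
#' @param prior A \code{variance_prior}.
#' @return Data frame: \code{gene}, \code{t_mod}, \code{p}, \code{df_total}.
#' @export
moderated_t <- function(fits, prior) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  d <- fits$df_residual
  s2_post <- if (is.infinite(d0)) rep(s0, nrow(fits)) else
    (d0 * s0 + d * fits$s2) / (d0 + d)
  df_total <- d + d0
  se <- sqrt(s2_post * fits$delta)
  t_mod <- fits$gamma_hat / se
  zero_se <- se == 0
  if (any(zero_se)) {
    warning(sum(zero_se), " gene(s) with zero posterior variance; ",
            "infinite statistic mapped to p = 0")
    t_mod[zero_se] <- sign(fits$gamma_hat[zero_se]) * Inf
    t_mod[zero_se & fits$gamma_hat == 0] <- 0
  }
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[is.infinite(t_mod)] <- 0
  data.frame(gene = fits$gene, t_mod = t_mod, p = p, df_total = df_total,
             stringsAsFactors = FALSE)
}

#' Average log2 fold-change, tumor vs normal
#'
#' Unpaired: difference of group means on the log2 scale. Paired: mean of
#' per-pair log2 ratios, with the i-th tumor sample (in sample-sheet order)
#' paired with the i-th normal sample. On already-log2 data the two coincide
#' when pairs align; the paired formula is applied only when pairing is
#' declared, never inferred from equal group sizes.
#'
#' @param dataset An \code{expression_dataset} (values on log2 scale).
#' @param paired Logical; use the paired formula.
#' @return Named numeric vector of aLog2FC per gene row.
#' @export
average_log2_fc <- function(dataset, paired = FALSE) {
  expr <- dataset$expr
  grp <- dataset$samples$group
  t_idx <- which(grp == "tumor"); c_idx <- which(grp == "normal")
  if (paired) {
    if (length(t_idx) != length(c_idx)) {
      stop("paired aLog2FC requires equal group sizes")
    }
    out <- rowMeans(expr[, t_idx, drop = FALSE] - expr[, c_idx, drop = FALSE])
  } else {
    out <- rowMeans(expr[, t_idx, drop = FALSE]) -
      rowMeans(expr[, c_idx, drop = FALSE])
  }
  names(out) <- rownames(expr)
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up by default (monotone, order-preserving), or
#' Bonferroni.
#'
#' @param p Vector of p-values in [0, 1].
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return Adjusted p-values, same order as input.
#' @export
adjust_bh <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Call differentially expressed genes
#'
#' A gene is called \code{up} when \code{adj_p < alpha} and \code{alog2fc >
#' lfc_threshold}, \code{down} when \code{adj_p < alpha} and \code{alog2fc <
#' -lfc_threshold}, otherwise \code{ns}.
#'
#' @param stats Data frame with columns \code{adj_p} and \code{alog2fc}.
#' @param config A \code{\link{pipeline_config}}.
#' @return The input with a \code{call} column added.
#' @export
call_degs <- function(stats, config = pipeline_config()) {
  sig <- stats$adj_p < config$alpha
  call <- rep("ns", nrow(stats))
  call[sig & stats$alog2fc > config$lfc_threshold] <- "up"
  call[sig & stats$alog2fc < -config$lfc_threshold] <- "down"
  stats$call <- call
  stats
}

#' Volcano-plot categorization
#'
#' Four-way categorization by raw p-value and log2 fold-change, the
#' convention used for volcano plots (distinct from the DEG call, which uses
#' adjusted p): \code{NS} (neither), \code{FC-only} (|lfc| > lfc_color only),
#' \code{P-only} (p <= p_color only), \code{both}.
#'
#' @param stats Data frame with columns \code{p} and \code{alog2fc}.
#' @param p_color Raw-p threshold (default 0.05).
#' @param lfc_color |log2FC| threshold (default 1.0).
#' @return Character vector of categories.
#' @export
volcano_table <- function(stats, p_color = 0.05, lfc_color = 1.0) {
  fc <- abs(stats$alog2fc) > lfc_color
  sp <- stats$p <= p_color
  out <- rep("NS", nrow(stats))
  out[fc & !sp] <- "FC-only"
  out[!fc & sp] <- "P-only"
  out[fc & sp] <- "both"
  out
}

#' Run the full differential-expression stage on one dataset
#'
#' Fits the per-gene models, estimates the variance prior, computes moderated
#' t-statistics, average log2 fold-changes, BH-adjusted p-values and DEG
#' calls. Duplicate gene rows (multiple probes) are collapsed by keeping, per
#' gene, the row with the smallest adjusted p-value.
#'
#' @param dataset An \code{expression_dataset}.
#' @param config A \code{\link{pipeline_config}}.
#' @param paired Logical; passed to \code{\link{average_log2_fc}}.
#' @return A gene statistics table: data.frame with \code{gene},
#'   \code{gamma_hat}, \code{alog2fc}, \code{t_mod}, \code{p}, \code{adj_p},
#'   \code{call}, one row per gene.
#' @export
run_de <- function(dataset, config = pipeline_config(), paired = FALSE) {
  fits <- fit_gene_models(dataset)
  prior <- estimate_prior(fits)
  tt <- moderated_t(fits, prior)
  stats <- data.frame(gene = fits$gene, gamma_hat = fits$gamma_hat,
                      alog2fc = average_log2_fc(dataset, paired = paired),
                      t_mod = tt$t_mod, p = tt$p,
                      stringsAsFactors = FALSE)
  stats$adj_p <- adjust_bh(stats$p)
  stats <- call_degs(stats, config)
  if (anyDuplicated(stats$gene)) {
    ord <- order(stats$adj_p, stats$p)   # keep best probe per gene
    stats <- stats[ord, , drop = FALSE]
    stats <- stats[!duplicated(stats$gene), , drop = FALSE]
    stats <- stats[order(stats$gene), , drop = FALSE]
  }
  rownames(stats) <- NULL
  stats
}

#' Write a gene statistics table to TSV
#'
#' Column layout fixed for downstream stages: gene, gamma_hat, alog2fc,
#' t_mod, p, adj_p, call.
#'
#' @param stats Gene statistics table from \code{\link{run_de}}.
#' @param path Output path.
#' @export
write_gene_stats <- function(stats, path) {
  cols <- c("gene", "gamma_hat", "alog2fc", "t_mod", "p", "adj_p", "call")
  utils::write.table(stats[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
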