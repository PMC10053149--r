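#' Simulate multi-dataset two-group expression with planted DE genes
#'
#' Emulates the generative model the moderated-t machinery assumes: each
#' gene's variance is drawn scaled-inverse-chi-square,
#' \code{sigma_g^2 = s0_sq * d0 / chi2(d0)}, expression values are
#' \code{Normal(theta_group, sigma_g^2)} on the log2 scale around a gene
#' baseline of \code{Normal(8, 1)}, and a fraction \code{pi_de} of genes is
#' shifted by \code{+/-lfc} in the tumor group. Across the \code{n_datasets}
#' cohorts a core of \code{round(shared_fraction * pi_de * G)} DE genes is
#' shared (same genes, same directions); the remaining DE slots of each
#' dataset are dataset-specific. Variances are redrawn per dataset.
#'
#' @param G Number of genes.
#' @param n1,n2 Tumor and normal sample counts per dataset (>= 2).
#' @param pi_de Fraction of DE genes per dataset, in [0, 1).
#' @param lfc Planted effect magnitude (log2 units).
#' @param d0 Prior degrees of freedom of the variance distribution.
#' @param s0_sq Prior variance (scale of the inverse-chi-square).
#' @param n_datasets Number of cohorts.
#' @param shared_fraction Fraction of each dataset's DE genes drawn from the
#'   shared core, in [0, 1].
#' @param seed Integer seed; same seed and parameters give byte-identical
#'   output.
#' @return List: \code{datasets} (named list of \code{expression_dataset}),
#'   \code{truth} (list with \code{planted_de} data.frame of gene/true_lfc
#'   for the shared core, \code{per_dataset_de}, \code{params},
#'   \code{seed}).
#' @export
simulate_expression <- function(G = 2000L, n1 = 10L, n2 = 10L, pi_de = 0.1,
                                lfc = 2, d0 = 4, s0_sq = 0.5,
                                n_datasets = 3L, shared_fraction = 1,
                                seed = 1L) {
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  if (pi_de < 0 || pi_de >= 1) stop("pi_de must be in [0, 1)")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(G))
  n_de <- round(pi_de * G)
  n_core <- round(shared_fraction * n_de)
  core <- sort(sample(genes, n_core))
  core_dir <- sample(c(1, -1), n_core, replace = TRUE)
  names(core_dir) <- core
  baseline <- stats::rnorm(G, mean = 8, sd = 1)
  names(baseline) <- genes
  datasets <- list()
  per_ds_de <- list()
  for (ds in seq_len(n_datasets)) {
    ds_name <- paste0("DS", ds)
    extra_pool <- setdiff(genes, core)
    extra <- if (n_de > n_core) sample(extra_pool, n_de - n_core) else character(0)
    de_genes <- c(core, extra)
    dir <- c(core_dir, stats::setNames(
      sample(c(1, -1), length(extra), replace = TRUE), extra))
    sigma2 <- s0_sq * d0 / stats::rchisq(G, df = d0)
    mu_n <- baseline
    mu_t <- baseline
    mu_t[de_genes] <- mu_t[de_genes] + lfc * dir[de_genes]
    n <- n1 + n2
    expr <- matrix(stats::rnorm(G * n,
                                mean = c(rep(mu_t, n1), rep(mu_n, n2)),
                                sd = rep(sqrt(sigma2), n)),
                   nrow = G, ncol = n)
    rownames(expr) <- genes
    colnames(expr) <- c(sprintf("%s_T%02d", ds_name, seq_len(n1)),
                        sprintf("%s_N%02d", ds_name, seq_len(n2)))
    sheet <- data.frame(sample = colnames(expr),
                        group = c(rep("tumor", n1), rep("normal", n2)),
                        dataset = ds_name, stringsAsFactors = FALSE)
    datasets[[ds_name]] <- expression_dataset(expr, sheet)
    per_ds_de[[ds_name]] <- data.frame(gene = de_genes,
                                       true_lfc = lfc * dir[de_genes],
                                       stringsAsFactors = FALSE)
  }
  truth <- list(
    planted_de = data.frame(gene = core, true_lfc = lfc * core_dir,
                            stringsAsFactors = FALSE),
    per_dataset_de = per_ds_de,
    params = list(G = G, n1 = n1, n2 = n2, pi_de = pi_de, lfc = lfc,
                  d0 = d0, s0_sq = s0_sq, n_datasets = n_datasets,
                  shared_fraction = shared_fraction),
    seed = seed
  )
  list(datasets = datasets, truth = truth)
}

#' Simulate a PPI network with a planted hub set
#'
#' Every pair touching at least one hub is an edge with probability
#' \code{p_in}; all other pairs with probability \code{p_out}. With
#' \code{p_out < p_in} the hubs dominate every topological centrality.
#'
#' @param genes Character vector of node names (default 50 synthetic genes).
#' @param hub_count Number of planted hubs.
#' @param p_in Edge probability for hub-touching pairs.
#' @param p_out Edge probability for background pairs.
#' @param seed Integer seed.
#' @return List: \code{graph} (igraph), \code{truth} (list with
#'   \code{planted_hubs}, \code{params}, \code{seed}).
#' @export
simulate_ppi <- function(genes = sprintf("G%03d", 1:50), hub_count = 6L,
                         p_in = 0.6, p_out = 0.05, seed = 1L) {
  n <- length(genes)
  if (hub_count >= n) stop("hub_count must be < number of genes")
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    stop("need 0 <= p_out <= p_in <= 1")
  }
  set.seed(seed)
  genes <- norm_symbols(genes)
  hubs <- sort(sample(genes, hub_count))
  pairs <- utils::combn(genes, 2L)
  touch_hub <- pairs[1L, ] %in% hubs | pairs[2L, ] %in% hubs
  p <- ifelse(touch_hub, p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < p
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = sort(genes))
  if (any(keep)) g <- igraph::add_edges(g, pairs[, keep, drop = FALSE])
  list(graph = g,
       truth = list(planted_hubs = hubs,
                    params = list(n = n, hub_count = hub_count,
                                  p_in = p_in, p_out = p_out),
                    seed = seed))
}

#' Simulate a bipartite regulatory network with planted key regulators
#'
#' \code{key_count} regulators are wired to at least \code{key_min_degree}
#' targets (degree drawn uniformly between \code{key_min_degree} and the
#' target count); the remaining regulators receive
#' \code{Poisson(background_degree_mean)} edges (capped at the target
#' count).
#'
#' @param regulator_count Total number of regulators.
#' @param targets Character vector of target genes.
#' @param key_count Number of planted key regulators.
#' @param key_min_degree Minimum degree of a planted regulator.
#' @param background_degree_mean Poisson mean of background degrees.
#' @param type Regulator type label, \code{"TF"} or \code{"miRNA"}.
#' @param seed Integer seed.
#' @return List: \code{network} (\code{regulatory_network}), \code{truth}.
#' @export
simulate_regulatory <- function(regulator_count = 30L, targets,
                                key_count = 6L, key_min_degree = 4L,
                                background_degree_mean = 1,
                                type = c("TF", "miRNA"), seed = 1L) {
  type <- match.arg(type)
  targets <- unique(norm_symbols(targets))
  nt <- length(targets)
  if (key_count > regulator_count) stop("key_count must be <= regulator_count")
  if (key_min_degree > nt) stop("key_min_degree exceeds number of targets")
  set.seed(seed)
  regs <- sprintf("%s%03d", if (type == "TF") "TF" else "mir", seq_len(regulator_count))
  key <- sort(sample(regs, key_count))
  deg <- stats::setNames(integer(regulator_count), regs)
  deg[key] <- key_min_degree +
    sample.int(nt - key_min_degree + 1L, key_count, replace = TRUE) - 1L
  bg <- setdiff(regs, key)
  deg[bg] <- pmin(stats::rpois(length(bg), background_degree_mean), nt)
  edges <- do.call(rbind, lapply(regs, function(r) {
    if (deg[r] == 0L) return(NULL)
    data.frame(regulator = r, target = sample(targets, deg[r]),
               type = type, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(regulator = character(0), target = character(0),
                        type = character(0), stringsAsFactors = FALSE)
  }
  list(network = regulatory_network(edges),
       truth = list(planted_regulators = key,
                    params = list(regulator_count = regulator_count,
                                  key_count = key_count,
                                  key_min_degree = key_min_degree,
                                  background_degree_mean = background_degree_mean,
                                  type = type),
                    seed = seed))
}

#' Simulate a binding-affinity matrix with planted pan-binder drugs
#'
#' Background cells are \code{Normal(mu_bg, sd_bg)}; the columns of
#' \code{binder_count} planted drugs are \code{Normal(mu_binder, sd_binder)}
#' with \code{mu_binder < mu_bg} (stronger binding). Defaults put roughly
#' 6 background standard deviations between the two regimes, so planted
#' pan-binders dominate both the hit-count and mean-affinity criteria.
#'
#' @param m Number of receptors.
#' @param n Number of drugs.
#' @param binder_count Number of planted pan-binders.
#' @param mu_bg,sd_bg Background mean and sd (kcal/mol).
#' @param mu_binder,sd_binder Planted-binder mean and sd (kcal/mol).
#' @param seed Integer seed.
#' @return List: \code{am} (affinity matrix), \code{truth}.
#' @export
simulate_affinity <- function(m = 15L, n = 100L, binder_count = 9L,
                              mu_bg = -5.5, sd_bg = 0.6,
                              mu_binder = -9.0, sd_binder = 0.4,
                              seed = 1L) {
  if (binder_count > n) stop("binder_count must be <= n")
  if (mu_binder >= mu_bg) stop("mu_binder must be < mu_bg (binders stronger)")
  set.seed(seed)
  receptors <- sprintf("R%02d", seq_len(m))
  drugs <- sprintf("D%03d", seq_len(n))
  binders <- sort(sample(drugs, binder_count))
  am <- matrix(stats::rnorm(m * n, mu_bg, sd_bg), m, n,
               dimnames = list(receptors, drugs))
  am[, binders] <- stats::rnorm(m * binder_count, mu_binder, sd_binder)
  list(am = affinity_matrix(am),
       truth = list(planted_binders = binders,
                    params = list(m = m, n = n, binder_count = binder_count,
                                  mu_bg = mu_bg, sd_bg = sd_bg,
                                  mu_binder = mu_binder,
                                  sd_binder = sd_binder),
                    seed = seed))
}
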