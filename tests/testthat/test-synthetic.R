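test_that("expression generator: determinism, null case, and planted structure", {
  a <- simulate_expression(G = 100, n1 = 3, n2 = 3, n_datasets = 2, seed = 99)
  b <- simulate_expression(G = 100, n1 = 3, n2 = 3, n_datasets = 2, seed = 99)
  expect_identical(a$datasets[[1]]$expr, b$datasets[[1]]$expr)
  expect_identical(a$truth, b$truth)

  null_sim <- simulate_expression(G = 100, n1 = 3, n2 = 3, pi_de = 0,
                                  n_datasets = 1, seed = 1)
  expect_equal(nrow(null_sim$truth$planted_de), 0L)

  sim <- simulate_expression(G = 200, n1 = 4, n2 = 4, pi_de = 0.2, lfc = 2,
                             n_datasets = 3, shared_fraction = 0.5, seed = 2)
  expect_equal(nrow(sim$truth$planted_de), round(0.5 * 0.2 * 200))
  for (ds in names(sim$datasets)) {
    per <- sim$truth$per_dataset_de[[ds]]
    expect_equal(nrow(per), round(0.2 * 200))
    expect_true(all(sim$truth$planted_de$gene %in% per$gene))
    # core directions agree across datasets
    m <- merge(sim$truth$planted_de, per, by = "gene")
    expect_equal(m$true_lfc.x, m$true_lfc.y)
    expect_true(all(abs(per$true_lfc) >= 2))
  }
  expect_error(simulate_expression(pi_de = 1.2), "pi_de")
  expect_error(simulate_expression(n1 = 1), ">= 2 samples")
})

test_that("PPI generator: determinism and extreme regimes", {
  a <- simulate_ppi(seed = 7)
  b <- simulate_ppi(seed = 7)
  expect_identical(igraph::as_edgelist(a$graph), igraph::as_edgelist(b$graph))
  expect_length(a$truth$planted_hubs, 6)

  # p_in = 1, p_out = 0: hubs connect to everything, others only to hubs
  g <- simulate_ppi(genes = sprintf("G%02d", 1:12), hub_count = 3,
                    p_in = 1, p_out = 0, seed = 3)
  deg <- degree_centrality(g$graph)
  expect_true(all(deg[g$truth$planted_hubs] == 11))
  expect_true(all(deg[setdiff(names(deg), g$truth$planted_hubs)] == 3))
  # every centrality is (weakly) maximal at the hubs; degree, betweenness
  # and stress strictly separate them, while bottleneck concentrates on the
  # one hub the canonical-tree tie-break routes through
  ct <- centrality_table(g$graph)
  is_hub <- ct$node %in% g$truth$planted_hubs
  for (m in c("degree", "betweenness", "stress")) {
    expect_gt(min(ct[[m]][is_hub]), max(ct[[m]][!is_hub]))
  }
  expect_true(ct$node[which.max(ct$bottleneck)] %in% g$truth$planted_hubs)
  sel <- select_key_genes(ct, k = 3)
  expect_true(all(g$truth$planted_hubs %in% sel$union))

  expect_error(simulate_ppi(genes = letters[1:5], hub_count = 5), "hub_count")
  expect_error(simulate_ppi(p_in = 0.1, p_out = 0.5), "p_out")
})

test_that("regulatory generator wires planted keys above threshold", {
  targets <- sprintf("KG%02d", 1:11)
  a <- simulate_regulatory(targets = targets, seed = 5)
  b <- simulate_regulatory(targets = targets, seed = 5)
  expect_identical(a$network, b$network)

  # background_degree_mean = 0: only key regulators carry edges
  quiet <- simulate_regulatory(regulator_count = 20, targets = targets,
                               key_count = 4, background_degree_mean = 0,
                               seed = 6)
  expect_setequal(unique(quiet$network$regulator),
                  quiet$truth$planted_regulators)
  rk <- rank_regulators(quiet$network, targets, min_degree = 4)
  expect_setequal(rk$regulator[rk$selected], quiet$truth$planted_regulators)

  expect_error(simulate_regulatory(targets = letters[1:3],
                                   key_min_degree = 4), "exceeds")
})

test_that("affinity generator plants recoverable pan-binders", {
  a <- simulate_affinity(seed = 8)
  b <- simulate_affinity(seed = 8)
  expect_identical(a$am, b$am)
  expect_length(a$truth$planted_binders, 9)

  # zero spread: binder column sums exactly m * mu_binder
  det <- simulate_affinity(m = 5, n = 10, binder_count = 2, sd_bg = 0,
                           sd_binder = 0, seed = 9)
  cs <- colSums(det$am[, det$truth$planted_binders])
  expect_true(all(cs == 5 * -9.0))

  expect_error(simulate_affinity(binder_count = 101, n = 100), "binder_count")
  expect_error(simulate_affinity(mu_binder = -5, mu_bg = -6), "mu_binder")
})

test_that("null generators produce chance-level downstream behavior", {
  # no planted hubs: flat edge probability
  g <- simulate_ppi(genes = sprintf("G%02d", 1:30), hub_count = 5,
                    p_in = 0.2, p_out = 0.2, seed = 10)
  deg <- degree_centrality(g$graph)
  hub_mean <- mean(deg[g$truth$planted_hubs])
  bg_mean <- mean(deg[setdiff(names(deg), g$truth$planted_hubs)])
  expect_lt(abs(hub_mean - bg_mean), 4)  # same distribution, MC slack

  # pi_de = 0: no gene carries a true effect
  sim <- simulate_expression(G = 50, n1 = 3, n2 = 3, pi_de = 0,
                             n_datasets = 1, seed = 11)
  expect_equal(nrow(sim$truth$per_dataset_de[[1]]), 0L)
})

test_that("generated outputs survive the package's own writers and readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_expression(G = 30, n1 = 3, n2 = 3, n_datasets = 1, seed = 12)
  ds <- sim$datasets[[1]]
  write_expression(ds, file.path(dir, "m.tsv"), file.path(dir, "s.csv"))
  rt <- read_expression(file.path(dir, "m.tsv"), file.path(dir, "s.csv"))
  expect_equal(rt$expr, ds$expr, tolerance = 1e-12)

  g <- simulate_ppi(seed = 13)$graph
  write_edge_list(g, file.path(dir, "e.tsv"))
  g2 <- read_edge_list(file.path(dir, "e.tsv"))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))

  am <- simulate_affinity(m = 4, n = 6, binder_count = 2, seed = 14)$am
  write_affinity(am, file.path(dir, "a.csv"))
  expect_equal(read_affinity(file.path(dir, "a.csv")), am, tolerance = 1e-12)
})
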