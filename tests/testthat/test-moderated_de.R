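test_that("per-gene model fits match hand-computed pooled statistics", {
  expr <- rbind(c(2, 2, 1, 1),
                c(3, 1, 2, 0),
                c(5, 6, 5, 6))
  rownames(expr) <- c("A", "B", "C")
  ds <- toy_dataset(expr, c("tumor", "tumor", "normal", "normal"))
  f <- fit_gene_models(ds)
  expect_equal(f$gamma_hat, c(1, 1, 0))       # constant, hand-pooled, identical
  expect_equal(f$s2, c(0, 2, 0.5))            # hand pooled variances
  expect_equal(f$df_residual, rep(2L, 3))
  expect_equal(f$delta, rep(1, 3))
})

test_that("prior estimation recovers simulated hyperparameters and degenerates cleanly", {
  set.seed(11)
  d0 <- 4; s0 <- 1; dg <- 4
  s2 <- s0 * d0 / rchisq(5000, d0) * rchisq(5000, dg) / dg
  fits <- data.frame(gene = as.character(1:5000), s2 = s2,
                     df_residual = dg, delta = 0.5)
  pr <- estimate_prior(fits)
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.10)

  # all variances identical: sentinel Inf prior with the common value
  fits2 <- data.frame(gene = as.character(1:20), s2 = 2,
                      df_residual = 4, delta = 0.5)
  pr2 <- estimate_prior(fits2)
  expect_equal(pr2$d0, Inf)
  expect_equal(pr2$s0_sq, 2)

  # near-equal variances: shrinkage regime detected (large d0). At d0 = 1000
  # the excess log-variance spread is tiny, so many genes are needed to
  # resolve it from sampling noise.
  set.seed(12)
  s2b <- s0 * 1000 / rchisq(20000, 1000) * rchisq(20000, dg) / dg
  fits3 <- data.frame(gene = as.character(1:20000), s2 = s2b,
                      df_residual = dg, delta = 0.5)
  expect_gte(estimate_prior(fits3)$d0, 100)

  expect_error(estimate_prior(fits2[1:5, ]), ">= 10 genes")
})

test_that("trigamma inversion solves trigamma(y) = x to tolerance", {
  for (y in c(0.01, 0.5, 2, 50, 1000)) {
    expect_equal(trigamma_inverse(trigamma(y)), y, tolerance = 1e-6)
  }
})

test_that("moderated t: hand case, null case, and zero-variance mapping", {
  fit <- data.frame(gene = "g", gamma_hat = 1, s2 = 2, df_residual = 2,
                    delta = 1)
  pr <- structure(list(d0 = 2, s0_sq = 2), class = "variance_prior")
  mt <- moderated_t(fit, pr)
  expect_equal(mt$t_mod, 1 / sqrt(2))          # s2_post = 2
  expect_equal(mt$df_total, 4)
  expect_equal(mt$p, 2 * pt(-1 / sqrt(2), 4))

  fit0 <- data.frame(gene = "g", gamma_hat = 0, s2 = 2, df_residual = 2,
                     delta = 1)
  mt0 <- moderated_t(fit0, pr)
  expect_equal(mt0$t_mod, 0)
  expect_equal(mt0$p, 1)

  fitz <- data.frame(gene = "g", gamma_hat = 1, s2 = 0, df_residual = 2,
                     delta = 1)
  prz <- structure(list(d0 = 0, s0_sq = 1), class = "variance_prior")
  expect_warning(mtz <- moderated_t(fitz, prz), "zero posterior variance")
  expect_equal(mtz$t_mod, Inf)
  expect_equal(mtz$p, 0)
})

test_that("d0 = 0 reproduces the classical pooled t; d0 = Inf its closed-form limit", {
  set.seed(21)
  sim <- simulate_expression(G = 300, n1 = 4, n2 = 5, pi_de = 0.2, lfc = 1.5,
                             n_datasets = 1, seed = 21)
  ds <- sim$datasets[[1]]
  fits <- fit_gene_models(ds)
  pr0 <- structure(list(d0 = 0, s0_sq = 1), class = "variance_prior")
  t0 <- moderated_t(fits, pr0)
  grp <- ds$samples$group
  classical <- apply(ds$expr, 1, function(z) {
    unname(t.test(z[grp == "tumor"], z[grp == "normal"],
                  var.equal = TRUE)$statistic)
  })
  expect_equal(t0$t_mod, unname(classical), tolerance = 1e-12)

  prInf <- structure(list(d0 = Inf, s0_sq = 0.7), class = "variance_prior")
  tInf <- moderated_t(fits, prInf)
  expect_equal(tInf$t_mod, fits$gamma_hat / sqrt(0.7 * fits$delta),
               tolerance = 1e-12)
  expect_equal(tInf$p, 2 * pnorm(-abs(tInf$t_mod)), tolerance = 1e-12)
})

test_that("moderated t agrees with an established empirical-Bayes fit", {
  skip_if_not_installed("limma")
  sim <- simulate_expression(G = 500, n1 = 5, n2 = 5, pi_de = 0.1, lfc = 2,
                             n_datasets = 1, seed = 33)
  ds <- sim$datasets[[1]]
  design <- cbind(intercept = 1,
                  tumor = as.integer(ds$samples$group == "tumor"))
  ref <- limma::eBayes(limma::lmFit(ds$expr, design))
  fits <- fit_gene_models(ds)
  pr <- estimate_prior(fits)
  mt <- moderated_t(fits, pr)
  expect_equal(pr$d0, ref$df.prior, tolerance = 1e-4)
  expect_equal(pr$s0_sq, ref$s2.prior, tolerance = 1e-4)
  expect_equal(mt$t_mod, unname(ref$t[, "tumor"]), tolerance = 1e-6)
  expect_equal(mt$p, unname(ref$p.value[, "tumor"]), tolerance = 1e-6)
})

test_that("aLog2FC: paired and unpaired formulas, antisymmetry under group swap", {
  expr <- rbind(G1 = c(4, 2, 1, 3))
  ds <- toy_dataset(expr, c("tumor", "tumor", "normal", "normal"))
  expect_equal(unname(average_log2_fc(ds)), 1)            # (3 - 2)
  expect_equal(unname(average_log2_fc(ds, paired = TRUE)), 1)  # (3 + -1)/2

  shift <- rbind(A = c(3, 4, 2, 3), B = c(1, 1, 0, 0))
  ds2 <- toy_dataset(shift, c("tumor", "tumor", "normal", "normal"))
  expect_equal(unname(average_log2_fc(ds2)), c(1, 1))

  # antisymmetry: swapping group labels flips the sign
  ds_swap <- toy_dataset(shift, c("normal", "normal", "tumor", "tumor"))
  expect_equal(average_log2_fc(ds2), -average_log2_fc(ds_swap))

  expr3 <- rbind(G1 = c(4, 2, 6, 1, 3))
  ds3 <- toy_dataset(expr3, c("tumor", "tumor", "tumor", "normal", "normal"))
  expect_error(average_log2_fc(ds3, paired = TRUE), "equal group sizes")
})

test_that("BH adjustment matches the step-up oracle and validates input", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(-0.1)), "\\[0, 1\\]")
})

test_that("DEG calls and volcano categories follow their decision rules", {
  st <- data.frame(adj_p = c(0.005, 0.005, 0.005, 0.5),
                   alog2fc = c(1.5, -1.5, 0.5, 3))
  out <- call_degs(st, pipeline_config())
  expect_equal(out$call, c("up", "down", "ns", "ns"))

  vt <- data.frame(p = c(0.5, 0.01, 0.01, 0.3), alog2fc = c(0, 2, 0, 2))
  expect_equal(volcano_table(vt), c("NS", "both", "P-only", "FC-only"))
})

test_that("run_de collapses duplicate probes by smallest adjusted p", {
  set.seed(9)
  expr <- matrix(rnorm(12 * 6, mean = 8), 12, 6)
  expr[1, 1:3] <- expr[1, 1:3] + 4          # strong DE probe of gene A
  rownames(expr) <- c("A", "A", sprintf("B%02d", 1:10))
  ds <- toy_dataset(expr, rep(c("tumor", "normal"), each = 3))
  st <- run_de(ds)
  expect_equal(nrow(st), 11L)                # one row per gene
  a <- st[st$gene == "A", ]
  expect_gt(abs(a$alog2fc), 1)               # the strong probe won
})
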