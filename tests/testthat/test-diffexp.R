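test_that("group swap negates log2fc and preserves p-values", {
  set.seed(10)
  cfg <- sim_config(n_genes = 300, n_mirnas = 0, seed = 10)
  sim <- simulate_counts(cfg)
  a <- nb_test(sim$gene_counts, sim$design, "NL", "AR")
  b <- nb_test(sim$gene_counts, sim$design, "AR", "NL")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_value, b$p_value)
})

test_that("degenerate features are handled: all-zero and equal-mean", {
  cts <- toy_counts(c(0, 500, 500), c(0, 500, 500), c(0, 500, 500))
  des <- toy_design()
  calls <- nb_test(cts, des, "NL", "AR")
  expect_equal(calls$p_value[1], 1)
  expect_equal(calls$log2fc[1], 0)
  # identical groups in the deterministic mode: nothing significant
  deg <- call_de(calls, threshold_policy(), "gene")
  expect_false(any(deg$significant))
})

test_that("threshold gates follow the DEG/DEM policies", {
  calls <- fake_call(c("a", "b", "c"), "HY_vs_NL",
                     lfc = c(log2(1.5), log2(3), log2(1.1)),
                     p = c(0.005, 0.005, 0.04))
  gene <- call_de(calls, threshold_policy(), "gene")
  # p passes but the fold-change gate fails
  expect_false(gene$significant[1])
  expect_true(gene$significant[2])
  expect_equal(gene$direction[2], "up")
  expect_false(gene$significant[3])
  mirna <- call_de(calls, threshold_policy(), "mirna")
  # miRNAs have no fold-change gate, only p < 0.05
  expect_true(all(mirna$significant))
  expect_equal(mirna$direction[3], "up")
})

test_that("null simulation keeps the raw-p false-positive rate in band", {
  cfg <- sim_config(n_genes = 5000, n_mirnas = 0, seed = 21,
                    dispersion = 0.1,
                    pattern_proportions = c(conserved = 1))
  sim <- simulate_counts(cfg)
  calls <- nb_test(sim$gene_counts, sim$design, "NL", "AR")
  rate <- mean(calls$p_value < 0.01)
  expect_gte(rate, 0.002)
  expect_lte(rate, 0.03)
})

test_that("a 4-fold effect is detected with high power at DEG thresholds", {
  cfg <- sim_config(n_genes = 10000, n_mirnas = 0, seed = 22,
                    dispersion = 0.05, meanlog = log(500), sdlog = 0,
                    pattern_proportions = c(conserved = 0.9,
                                            ELD_NL_III = 0.1))
  sim <- simulate_counts(cfg)
  deg <- call_de(nb_test(sim$gene_counts, sim$design, "NL", "AR"),
                 threshold_policy(), "gene")
  true_de <- sim$gene_truth$category == "III"
  expect_gte(mean(deg$significant[true_de]), 0.9)
})

test_that("Wald p-values track an independent NB likelihood-ratio oracle", {
  set.seed(42)
  G <- 50
  lfc <- rnorm(G, 0, 0.5)
  cts <- toy_counts(500 * 2^lfc, rep(500, G), rep(500, G))
  des <- toy_design()
  set.seed(43)
  cts[] <- rnbinom(length(cts), mu = cts, size = 20)
  calls <- nb_test(cts, des, "NL", "AR")
  sf <- size_factors(cts)
  norm <- sweep(cts, 2, sf, "/")
  p_lrt <- vapply(seq_len(G), function(i)
    oracle_nb_lrt(norm[i, 1:3], norm[i, 4:6], calls$dispersion[i]),
    numeric(1))
  # same significance decisions at both working thresholds
  expect_identical(calls$p_value < 0.01, p_lrt < 0.01)
  expect_identical(calls$p_value < 0.05, p_lrt < 0.05)
  expect_gt(cor(calls$p_value, p_lrt, method = "spearman"), 0.99)
  # magnitudes agree within a factor of two (different asymptotic statistics)
  expect_true(all(pmax(calls$p_value, p_lrt) /
                    pmax(pmin(calls$p_value, p_lrt), 1e-300) < 2))
})

test_that("mid-parent test separates additive from overdominant features", {
  # deterministic mean injection against a conserved majority so that
  # median-of-ratios normalization is anchored
  mu_nl <- c(rep(400, 200), rep(800, 40))
  mu_ar <- c(rep(400, 200), rep(200, 40))
  mu_hy <- c(rep(400, 200), rep(500, 20), rep(3200, 20))
  cts <- toy_counts(mu_nl, mu_ar, mu_hy)
  res <- call_de(mpv_test(cts, toy_design()), threshold_policy(), "gene")
  expect_false(any(res$significant[201:220]))  # exactly mid-parent
  expect_true(all(res$significant[221:240]))   # 4x above the high parent
  expect_true(all(res$direction[221:240] == "up"))
})

test_that("mid-parent false-positive rate on noisy additive genes is bounded", {
  cfg <- sim_config(n_genes = 4000, n_mirnas = 0, seed = 31,
                    pattern_proportions = c(conserved = 0.8,
                                            additive_I = 0.1,
                                            additive_II = 0.1))
  sim <- simulate_counts(cfg)
  res <- mpv_test(sim$gene_counts, sim$design)
  add <- sim$gene_truth$group == "additive"
  expect_lte(mean(res$p_value[add] < 0.05), 2 * 0.05)
})

test_that("unequal parental replicate counts pair to the minimum with warning", {
  cts <- toy_counts(rep(400, 30), rep(400, 30), rep(400, 30))
  des <- toy_design()
  cts <- cts[, des$sample_id != "NL3"]
  des <- des[des$sample_id != "NL3", ]
  expect_warning(res <- mpv_test(cts, des), "unequal")
  expect_equal(nrow(res), 30)
})
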