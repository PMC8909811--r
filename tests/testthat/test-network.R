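toy_net_calls <- function() {
  # two miRNAs and three genes with known directions in both contrasts
  dem <- list(
    HY_vs_NL = fake_call(c("m1", "m2"), "HY_vs_NL", c(2, -2), c(1e-4, 1e-4),
                         sig = c(TRUE, TRUE)),
    HY_vs_AR = fake_call(c("m1", "m2"), "HY_vs_AR", c(2, 0.1), c(1e-4, 0.9),
                         sig = c(TRUE, FALSE)))
  deg <- list(
    HY_vs_NL = fake_call(c("g1", "g2", "g3"), "HY_vs_NL", c(-2, 2, -2),
                         c(1e-4, 1e-4, 0.8), sig = c(TRUE, TRUE, FALSE)),
    HY_vs_AR = fake_call(c("g1", "g2", "g3"), "HY_vs_AR", c(-2, 2, -2),
                         c(1e-4, 1e-4, 1e-4), sig = c(TRUE, TRUE, TRUE)))
  asg <- data.frame(feature_id = c("g1", "g2", "g3"),
                    category = c("IV", "III", "X"),
                    group = c("ELD_NL", "ELD_NL", "ELOD_down"),
                    non_additive = TRUE, stringsAsFactors = FALSE)
  list(dem = dem, deg = deg, asg = asg)
}

test_that("negativity rule retains opposite and drops concordant pairs", {
  tc <- toy_net_calls()
  targets <- data.frame(mirna_id = c("m1", "m1", "m2", "m2", "mX"),
                        gene_id = c("g1", "g2", "g2", "g3", "g1"),
                        score = 1:5)
  net <- build_network(tc$dem, tc$deg, tc$asg, targets)
  # m1 up / g1 down in both contrasts -> retained with both supports
  expect_true("g1" %in% net$gene_id[net$mirna_id == "m1"])
  row <- net[net$mirna_id == "m1" & net$gene_id == "g1", ]
  expect_equal(row$contrast, "HY_vs_NL,HY_vs_AR")
  expect_equal(row$pair_category, "ELD_NL")
  # m1 up / g2 up -> concordant, excluded
  expect_false("g2" %in% net$gene_id[net$mirna_id == "m1"])
  # m2 down / g2 up in HY_vs_NL -> retained
  expect_true("g2" %in% net$gene_id[net$mirna_id == "m2"])
  # m2 / g3: only shared significant contrast is none (m2 ns in HY_vs_AR)
  expect_false("g3" %in% net$gene_id[net$mirna_id == "m2"])
  # unknown miRNA rows are skipped and counted
  expect_equal(attr(net, "skipped"), 1L)
  # negativity invariant and bipartite structure
  expect_true(all(net$mirna_direction != net$gene_direction))
  expect_true(all(grepl("^m", net$mirna_id)) && all(grepl("^g", net$gene_id)))
})

test_that("empty target tables give empty networks and zero stats", {
  tc <- toy_net_calls()
  net <- build_network(tc$dem, tc$deg, tc$asg,
                       data.frame(mirna_id = character(0),
                                  gene_id = character(0)))
  expect_equal(nrow(net), 0)
  st <- network_stats(net)
  expect_equal(st$n_pairs, 0)
  expect_equal(st$pct_gene_up, 0)
})

test_that("network statistics match a brute-force recount", {
  set.seed(6)
  pairs <- data.frame(
    mirna_id = sample(paste0("m", 1:6), 20, TRUE),
    gene_id = paste0("g", 1:20),
    contrast = "HY_vs_NL",
    mirna_direction = sample(c("up", "down"), 20, TRUE),
    gene_direction = NA, pair_category = sample(c("ELD_NL", "ELD_AR"), 20,
                                                TRUE),
    score = NA_real_, stringsAsFactors = FALSE)
  pairs$gene_direction <- ifelse(pairs$mirna_direction == "up", "down", "up")
  st <- network_stats(pairs)
  expect_equal(st$n_pairs, 20)
  expect_equal(st$n_mirnas, length(unique(pairs$mirna_id)))
  expect_equal(st$n_genes, 20)
  expect_equal(st$pct_gene_up,
               round(100 * sum(pairs$gene_direction == "up") / 20, 1))
  for (g in unique(pairs$pair_category))
    expect_equal(st$per_group$n[st$per_group$group == g],
                 sum(pairs$pair_category == g))
  expect_lt(abs(sum(st$per_group$pct) - 100), 0.2)
})

test_that("removing a miRNA removes exactly its pairs", {
  cfg <- sim_config(n_genes = 800, n_mirnas = 80, seed = 12)
  sim <- simulate_counts(cfg)
  fitg <- heterosis(sim$gene_counts, sim$design, sim$gene_lengths, "gene")
  fitm <- heterosis(sim$mirna_counts, sim$design, NULL, "mirna")
  tg <- simulate_targets(sim, 4, 1.0, seed = 2)
  net <- build_network(fitm$calls[c("HY_vs_NL", "HY_vs_AR")],
                       fitg$calls[c("HY_vs_NL", "HY_vs_AR")],
                       fitg$assignments, tg)
  expect_gt(nrow(net), 0)
  drop <- net$mirna_id[1]
  dem2 <- lapply(fitm$calls[c("HY_vs_NL", "HY_vs_AR")], function(d) {
    d$significant[d$feature_id == drop] <- FALSE
    d$direction[d$feature_id == drop] <- "ns"
    d
  })
  net2 <- build_network(dem2, fitg$calls[c("HY_vs_NL", "HY_vs_AR")],
                        fitg$assignments, tg)
  expect_equal(net2, net[net$mirna_id != drop, ], ignore_attr = TRUE)
})
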