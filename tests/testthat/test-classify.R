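make_calls <- function(P, HN, HA, M) {
  # each argument: c(lfc, p)
  list(NL_vs_AR = fake_call("f1", "NL_vs_AR", P[1], P[2]),
       HY_vs_NL = fake_call("f1", "HY_vs_NL", HN[1], HN[2]),
       HY_vs_AR = fake_call("f1", "HY_vs_AR", HA[1], HA[2]),
       HY_vs_MPV = fake_call("f1", "HY_vs_MPV", M[1], M[2]))
}

test_that("decision table assigns the canonical single-feature cases", {
  sig <- 1e-6; ns <- 0.5
  # parents differ (NL > AR), HY equals NL, differs from AR -> ELD-NL (III)
  a <- classify_patterns(make_calls(c(2, sig), c(0, ns), c(2, sig),
                                    c(0.7, sig)))
  expect_equal(a$category, "III")
  expect_equal(a$group, "ELD_NL")
  expect_true(a$non_additive)
  # HY above both parents, parents equal -> overdominance (VIII)
  b <- classify_patterns(make_calls(c(0, ns), c(2, sig), c(2, sig),
                                    c(2, sig)))
  expect_equal(b$category, "VIII")
  expect_equal(b$group, "ELOD_up")
  # HY below both parents, NL > AR -> X
  x <- classify_patterns(make_calls(c(2, sig), c(-2, sig), c(-1, sig),
                                    c(-1.5, sig)))
  expect_equal(x$category, "X")
  expect_equal(x$group, "ELOD_down")
  # parents differ, HY at mid-parent -> additive (I), not non-additive
  d <- classify_patterns(make_calls(c(2, sig), c(-0.7, sig), c(1.3, sig),
                                    c(0, ns)))
  expect_equal(d$category, "I")
  expect_false(d$non_additive)
  # nothing significant -> conserved
  e <- classify_patterns(make_calls(c(0.1, ns), c(0, ns), c(0.1, ns),
                                    c(0, ns)))
  expect_equal(e$category, "conserved")
  # intermediate but mid-parent-inconsistent: ambiguous, still non-additive
  f <- classify_patterns(make_calls(c(2, sig), c(-0.7, sig), c(1.3, sig),
                                    c(0.3, 0.01)))
  expect_equal(f$category, "ambiguous")
  expect_true(f$non_additive)
  # only the mid-parent contrast significant: not conserved, flag kept
  g <- classify_patterns(make_calls(c(0.1, ns), c(0.2, ns), c(0.1, ns),
                                    c(0.4, 0.01)))
  expect_equal(g$category, "ambiguous")
  expect_true(g$non_additive)
})

test_that("every feature gets exactly one category and percentages sum", {
  cfg <- sim_config(n_genes = 2000, n_mirnas = 0, seed = 14)
  sim <- simulate_counts(cfg)
  fit <- heterosis(sim$gene_counts, sim$design, sim$gene_lengths)
  a <- fit$assignments
  expect_equal(nrow(a), 2000)
  expect_false(anyNA(a$category))
  expect_true(all(a$category %in% c(as.character(as.roman(1:12)),
                                    "conserved", "ambiguous")))
  s <- summarize_categories(a)
  expect_lt(abs(sum(s$group_pct) - 100), 0.2)
})

test_that("relabeling the parents mirrors the category assignment", {
  cfg <- sim_config(n_genes = 1300, n_mirnas = 0, seed = 15,
                    mean_injection = TRUE,
                    pattern_proportions = all_label_proportions())
  sim <- simulate_counts(cfg)
  fit <- heterosis(sim$gene_counts, sim$design, sim$gene_lengths)
  des2 <- sim$design
  des2$stock <- c(NL = "AR", AR = "NL", HY = "HY")[des2$stock]
  fit2 <- heterosis(sim$gene_counts, des2, sim$gene_lengths)
  map <- c(I = "II", II = "I", III = "V", IV = "VI", V = "III", VI = "IV",
           VII = "IX", VIII = "VIII", IX = "VII", X = "XII", XI = "XI",
           XII = "X", conserved = "conserved", ambiguous = "ambiguous")
  expect_equal(unname(map[fit$assignments$category]),
               fit2$assignments$category)
})

test_that("mean-injection classification equals ground truth exactly", {
  cfg <- sim_config(n_genes = 1300, n_mirnas = 0, seed = 16,
                    mean_injection = TRUE,
                    pattern_proportions = all_label_proportions())
  sim <- simulate_counts(cfg)
  expect_true(all(table(sim$gene_truth$label) > 0))
  fit <- heterosis(sim$gene_counts, sim$design, sim$gene_lengths)
  expect_identical(fit$assignments$category, sim$gene_truth$category)
})

test_that("category summaries compute shares, ratios and totals", {
  counts <- c(I = 60, II = 40, III = 20, IV = 10, V = 9, VI = 9,
              VII = 1, X = 1, conserved = 500)
  s <- summarize_categories(counts)
  expect_equal(s$total_classified, 150)
  expect_equal(unname(s$group_counts["additive"]), 100)
  expect_equal(unname(s$group_pct["additive"]), 66.7)
  expect_equal(s$within$ratio[s$within$group == "additive"], 1.5)
  expect_equal(s$within$pct_larger[s$within$group == "ELD_NL"], 66.7)
  expect_equal(s$non_additive_total, 50)
  # single populated category
  one <- summarize_categories(c(III = 7))
  expect_equal(unname(one$group_pct["ELD_NL"]), 100)
  expect_equal(sum(one$group_counts) - one$group_counts[["ELD_NL"]], 0)
  # empty input
  z <- summarize_categories(data.frame(feature_id = character(0),
                                       category = character(0),
                                       group = character(0),
                                       non_additive = logical(0)))
  expect_equal(z$total_classified, 0)
  expect_equal(sum(z$group_counts), 0)
})
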