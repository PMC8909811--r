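# End-to-end orchestration and set-overlap summaries.

#' Three-way overlap of differential feature sets
#'
#' Counts the seven exclusive regions of a three-set Venn diagram and the
#' pairwise overlap percentages (share of set i's members also in set j).
#'
#' @param sets named list of three character vectors of feature ids.
#' @return list with `regions` (named counts; names join the member sets
#'   with `&`, e.g. `"NL_vs_AR&HY_vs_AR"`), `sizes`, and `pairwise_pct`
#'   (matrix; entry \[i, j\] = 100 |i n j| / |i|, one decimal).
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 0)
    member <- matrix(logical(0), 0, 3, dimnames = list(NULL, nm))
  combos <- expand.grid(a = c(FALSE, TRUE), b = c(FALSE, TRUE),
                        c = c(FALSE, TRUE))[-1, ]
  regions <- apply(combos, 1, function(cm) {
    sum(member[, 1] == cm[1] & member[, 2] == cm[2] & member[, 3] == cm[3])
  })
  names(regions) <- apply(combos, 1, function(cm)
    paste(nm[as.logical(cm)], collapse = "&"))
  pair <- matrix(NA_real_, 3, 3, dimnames = list(nm, nm))
  for (i in 1:3) for (j in 1:3) if (i != j && length(sets[[i]]) > 0)
    pair[i, j] <- round_half_up(
      100 * length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]]), 1)
  list(regions = regions,
       sizes = vapply(sets, length, integer(1)),
       pairwise_pct = pair)
}

#' Run the full heterosis analysis pipeline
#'
#' Orchestrates every stage on a simulated dataset: count simulation,
#' quantification and model fit for genes and miRNAs, pattern
#' classification and category summaries, three-way DE overlaps, the
#' negative miRNA-mRNA network, hypergeometric enrichment of the
#' non-additive gene set, and growth phenotypes.  All randomness flows from
#' the seed in `config` (stage-specific seeds are derived from it), so a
#' rerun with the same configuration reproduces every output.
#'
#' @param config a [sim_config()].
#' @param policy a [threshold_policy()].
#' @param outdir optional directory; when given, every stage writes its TSV
#'   and a JSON run manifest.
#' @param targets_per_mirna,negative_fraction passed to [simulate_targets()].
#' @param n_fish,pheno_cv passed to [simulate_phenotypes()].
#' @param n_pathways passed to [simulate_annotation()].
#' @return invisibly, a list with the simulated data (`sim`, `targets`,
#'   `annotation`, `phenotypes`), the two fits (`fit_gene`, `fit_mirna`),
#'   their summaries, the network and its statistics, the enrichment table,
#'   the growth summary, and the run `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), policy = threshold_policy(),
                         outdir = NULL, targets_per_mirna = 5,
                         negative_fraction = 0.8, n_fish = 30,
                         pheno_cv = 0.1, n_pathways = 40) {
  seed <- config$seed
  sim <- simulate_counts(config)
  fit_gene <- heterosis(sim$gene_counts, sim$design, sim$gene_lengths,
                        "gene", policy)
  sum_gene <- summary(fit_gene)
  fit_mirna <- NULL; sum_mirna <- NULL
  if (!is.null(sim$mirna_counts)) {
    fit_mirna <- heterosis(sim$mirna_counts, sim$design, NULL, "mirna",
                           policy)
    sum_mirna <- summary(fit_mirna)
  }

  targets <- NULL; network <- NULL; net_stats <- NULL
  if (!is.null(fit_mirna)) {
    targets <- simulate_targets(sim, targets_per_mirna, negative_fraction,
                                seed = seed + 101L)
    network <- build_network(
      dem_calls = fit_mirna$calls[c("HY_vs_NL", "HY_vs_AR")],
      deg_calls = fit_gene$calls[c("HY_vs_NL", "HY_vs_AR")],
      assignments = fit_gene$assignments, targets = targets)
    net_stats <- network_stats(network)
  }

  neg_set <- fit_gene$assignments$feature_id[
    fit_gene$assignments$group %in% c("ELD_NL", "ELD_AR", "ELOD_up",
                                      "ELOD_down")]
  true_na <- sim$gene_truth$feature_id[sim$gene_truth$group != "none" &
                                         sim$gene_truth$group != "additive"]
  annotation <- simulate_annotation(rownames(sim$gene_counts),
                                    n_pathways = n_pathways,
                                    boost_set = true_na,
                                    seed = seed + 202L)
  expressed <- rownames(sim$gene_counts)[rowSums(sim$gene_counts) > 0]
  enrich <- hypergeom_enrich(neg_set, annotation, background = expressed)

  phenotypes <- simulate_phenotypes(n_fish = n_fish, cv = pheno_cv,
                                    seed = seed + 303L)
  growth <- stock_summary(growth_metrics(growth_records(phenotypes, 0, 45)))

  manifest <- list(
    package = "heteroseq",
    version = as.character(utils::packageVersion("heteroseq")),
    seed = seed,
    config = config[setdiff(names(config),
                            c("pattern_proportions",
                              "mirna_pattern_proportions"))],
    thresholds = unclass(policy),
    stages = list(
      n_genes = nrow(sim$gene_counts),
      n_mirnas = if (is.null(sim$mirna_counts)) 0L else
        nrow(sim$mirna_counts),
      deg_per_contrast = as.list(sum_gene$de_counts),
      dem_per_contrast = if (is.null(sum_mirna)) NULL else
        as.list(sum_mirna$de_counts),
      neg_total = sum_gene$categories$non_additive_total,
      nem_total = if (is.null(sum_mirna)) NULL else
        sum_mirna$categories$non_additive_total,
      network_pairs = if (is.null(net_stats)) NULL else net_stats$n_pairs,
      enriched_pathways = sum(enrich$p_value < 0.05)))

  out <- list(sim = sim, fit_gene = fit_gene, fit_mirna = fit_mirna,
              summary_gene = sum_gene, summary_mirna = sum_mirna,
              targets = targets, network = network, net_stats = net_stats,
              annotation = annotation, enrichment = enrich,
              phenotypes = phenotypes, growth = growth, manifest = manifest)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_sim_tsv(sim, file.path(outdir, "sim"))
    for (cn in names(fit_gene$calls))
      write_tsv(fit_gene$calls[[cn]],
                file.path(outdir, paste0("deg_", cn, ".tsv")))
    if (!is.null(fit_mirna))
      for (cn in names(fit_mirna$calls))
        write_tsv(fit_mirna$calls[[cn]],
                  file.path(outdir, paste0("dem_", cn, ".tsv")))
    write_tsv(fit_gene$assignments, file.path(outdir, "gene_patterns.tsv"))
    if (!is.null(fit_mirna))
      write_tsv(fit_mirna$assignments,
                file.path(outdir, "mirna_patterns.tsv"))
    if (!is.null(targets)) write_tsv(targets, file.path(outdir, "targets.tsv"))
    if (!is.null(network)) write_tsv(network, file.path(outdir, "network.tsv"))
    write_tsv(annotation, file.path(outdir, "annotation.tsv"))
    write_tsv(enrich, file.path(outdir, "enrichment.tsv"))
    write_tsv(phenotypes, file.path(outdir, "phenotypes.tsv"))
    tsvs <- list.files(outdir, "\\.tsv$", recursive = TRUE,
                       full.names = TRUE)
    manifest$file_digests <- as.list(tools::md5sum(tsvs))
    names(manifest$file_digests) <-
      sub(paste0("^", outdir, "/?"), "", names(manifest$file_digests))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest <- manifest
  }
  invisible(out)
}
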