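# Seeded synthetic-data generator: three stocks (NL, AR, HY) x replicated
# liver RNA libraries, negative-binomial counts with known ground-truth
# expression patterns, miRNA->target tables with controlled negative
# regulation, pathway annotations and growth phenotypes.

pattern_labels <- c(
  "conserved", "additive_I", "additive_II",
  "ELD_NL_III", "ELD_NL_IV", "ELD_AR_V", "ELD_AR_VI",
  "ELOD_up_parents_differ_NLhigh", "ELOD_up_parents_equal",
  "ELOD_up_parents_differ_ARhigh",
  "ELOD_down_parents_differ_NLhigh", "ELOD_down_parents_equal",
  "ELOD_down_parents_differ_ARhigh")

label_category_map <- c(
  conserved = "conserved", additive_I = "I", additive_II = "II",
  ELD_NL_III = "III", ELD_NL_IV = "IV", ELD_AR_V = "V", ELD_AR_VI = "VI",
  ELOD_up_parents_differ_NLhigh = "VII", ELOD_up_parents_equal = "VIII",
  ELOD_up_parents_differ_ARhigh = "IX",
  ELOD_down_parents_differ_NLhigh = "X", ELOD_down_parents_equal = "XI",
  ELOD_down_parents_differ_ARhigh = "XII")

# stock mean multipliers (NL, AR, HY) for base mean b and effect size e
pattern_means <- function(category, e) {
  switch(category,
    conserved = c(1, 1, 1),
    I = c(e, 1, (e + 1) / 2),
    II = c(1, e, (e + 1) / 2),
    III = c(e, 1, e),
    IV = c(1, e, 1),
    V = c(1, e, e),
    VI = c(e, 1, 1),
    VII = c(e, 1, e * e),
    VIII = c(1, 1, e),
    IX = c(1, e, e * e),
    X = c(e, 1, 1 / e),
    XI = c(1, 1, 1 / e),
    XII = c(1, e, 1 / e),
    stop("unknown category: ", category))
}

# ground-truth hybrid direction and the HY-vs-parent contrasts in which the
# feature is truly differential (ELD features differ from one parent only,
# ELOD features from both; additive/conserved have no single direction)
pattern_direction <- function(category) {
  switch(category,
    III = list(direction = "up", contrasts = "HY_vs_AR"),
    IV = list(direction = "down", contrasts = "HY_vs_AR"),
    V = list(direction = "up", contrasts = "HY_vs_NL"),
    VI = list(direction = "down", contrasts = "HY_vs_NL"),
    VII = , VIII = , IX =
      list(direction = "up", contrasts = c("HY_vs_NL", "HY_vs_AR")),
    X = , XI = , XII =
      list(direction = "down", contrasts = c("HY_vs_NL", "HY_vs_AR")),
    list(direction = NA_character_, contrasts = character(0)))
}

#' Default ground-truth pattern proportions
#'
#' Pattern mixes emulating a liver transcriptome/miRNAome of a two-parent
#' hybrid cross in which roughly a quarter of genes are differential in at
#' least one contrast, additivity is the most common differential mode, and
#' dominance toward the maternal stock exceeds dominance toward the paternal
#' stock; overdominance is rare.  Fractions sum to 1.
#'
#' @param type `"gene"` or `"mirna"`.
#' @return named numeric vector over the thirteen truth labels.
#' @export
default_pattern_proportions <- function(type = c("gene", "mirna")) {
  type <- match.arg(type)
  if (type == "gene") {
    counts <- c(conserved = 9903, additive_I = 750, additive_II = 749,
                ELD_NL_III = 569, ELD_NL_IV = 286,
                ELD_AR_V = 339, ELD_AR_VI = 288,
                ELOD_up_parents_differ_NLhigh = 13,
                ELOD_up_parents_equal = 13,
                ELOD_up_parents_differ_ARhigh = 13,
                ELOD_down_parents_differ_NLhigh = 26,
                ELOD_down_parents_equal = 26,
                ELOD_down_parents_differ_ARhigh = 25)
  } else {
    counts <- c(conserved = 198, additive_I = 20, additive_II = 20,
                ELD_NL_III = 27, ELD_NL_IV = 14,
                ELD_AR_V = 11, ELD_AR_VI = 9,
                ELOD_up_parents_differ_NLhigh = 0,
                ELOD_up_parents_equal = 1,
                ELOD_up_parents_differ_ARhigh = 0,
                ELOD_down_parents_differ_NLhigh = 0,
                ELOD_down_parents_equal = 0,
                ELOD_down_parents_differ_ARhigh = 0)
  }
  counts / sum(counts)
}

#' Simulation configuration
#'
#' Parameters of the synthetic three-stock (NL, AR, HY) expression design.
#' Defaults emulate the study system the package was built around: three
#' pooled replicates per stock, ~13k liver genes and ~300 miRNAs,
#' negative-binomial counts with variance \eqn{\mu + \phi\mu^2}, a 4-fold
#' effect between differing stock means, and expected library sizes jittered
#' \eqn{\pm}20\% around the nominal depth so that normalization matters.
#'
#' @param n_genes,n_mirnas feature counts.
#' @param n_replicates replicates per stock (>= 2).
#' @param dispersion NB dispersion \eqn{\phi \ge 0}.
#' @param phi_cv coefficient of variation of optional per-feature gamma
#'   jitter on the dispersion; 0 (default) keeps a single global value.
#' @param library_size,mirna_library_size expected total counts per sample
#'   for the gene and miRNA libraries.
#' @param libsize_jitter half-width of the uniform relative jitter on
#'   expected library sizes (0.2 = \eqn{\pm}20\%); ignored in mean-injection
#'   mode.
#' @param pattern_proportions,mirna_pattern_proportions named fractions over
#'   the thirteen truth labels, summing to 1.
#' @param effect_size multiplicative fold between differing stock means.
#' @param mean_min,meanlog,sdlog baseline per-feature mean expression is
#'   drawn lognormal(`meanlog`, `sdlog`) and floored at `mean_min`.
#' @param mean_injection logical; when `TRUE` counts are the rounded expected
#'   counts (no sampling, equal library sizes) -- a deterministic degenerate
#'   mode for exact regression tests.
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 13000, n_mirnas = 300, n_replicates = 3,
                       dispersion = 0.05, phi_cv = 0,
                       library_size = 4.5e7, mirna_library_size = 1.1e7,
                       libsize_jitter = 0.2,
                       pattern_proportions = default_pattern_proportions("gene"),
                       mirna_pattern_proportions =
                         default_pattern_proportions("mirna"),
                       effect_size = 4, mean_min = 200,
                       meanlog = log(1000), sdlog = 1,
                       mean_injection = FALSE, seed = 1L) {
  stopifnot(n_genes >= 1, n_mirnas >= 0, n_replicates >= 2,
            dispersion >= 0, phi_cv >= 0, library_size > 0,
            effect_size > 1, mean_min > 0,
            libsize_jitter >= 0, libsize_jitter < 1)
  for (pp in list(pattern_proportions, mirna_pattern_proportions)) {
    if (!all(names(pp) %in% pattern_labels) || is.null(names(pp)))
      stop("pattern proportions must be named by truth label")
    if (any(!is.finite(pp)) || any(pp < 0))
      stop("pattern proportions must be finite and non-negative")
    if (abs(sum(pp) - 1) > 1e-9)
      stop("pattern proportions must sum to 1")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    n_replicates = as.integer(n_replicates), dispersion = dispersion,
    phi_cv = phi_cv, library_size = library_size,
    mirna_library_size = mirna_library_size,
    libsize_jitter = libsize_jitter,
    pattern_proportions = pattern_proportions,
    mirna_pattern_proportions = mirna_pattern_proportions,
    effect_size = effect_size, mean_min = mean_min,
    meanlog = meanlog, sdlog = sdlog,
    mean_injection = isTRUE(mean_injection), seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config: %d genes, %d miRNAs, %d replicates/stock\n",
    "  dispersion phi = %g, effect size = %g, library size = %g\n",
    "  mode = %s, seed = %d\n"),
    x$n_genes, x$n_mirnas, x$n_replicates, x$dispersion, x$effect_size,
    x$library_size,
    if (x$mean_injection) "mean-injection (deterministic)" else "NB sampling",
    x$seed))
  invisible(x)
}

# assign truth labels by largest-remainder apportionment, then shuffle
assign_labels <- function(n, proportions) {
  full <- stats::setNames(numeric(length(pattern_labels)), pattern_labels)
  full[names(proportions)] <- proportions
  k <- apportion(n, full)
  labels <- rep(names(k), k)
  sample(labels)
}

simulate_feature_set <- function(n, proportions, prefix, cfg, lib) {
  labels <- assign_labels(n, proportions)
  category <- unname(label_category_map[labels])
  base <- pmax(cfg$mean_min, stats::rlnorm(n, cfg$meanlog, cfg$sdlog))
  mult <- t(vapply(category, pattern_means, numeric(3), e = cfg$effect_size))
  mu <- mult * base  # columns NL, AR, HY
  colnames(mu) <- stock_levels
  reps <- cfg$n_replicates
  samples <- paste0(rep(stock_levels, each = reps), seq_len(reps))
  stock_of <- rep(stock_levels, each = reps)
  phi <- if (cfg$phi_cv > 0 && cfg$dispersion > 0) {
    shape <- 1 / cfg$phi_cv^2
    cfg$dispersion * stats::rgamma(n, shape = shape, rate = shape)
  } else rep(cfg$dispersion, n)
  counts <- matrix(0, n, length(samples),
                   dimnames = list(sprintf("%s%05d", prefix, seq_len(n)),
                                   samples))
  for (j in seq_along(samples)) {
    mu_j <- mu[, stock_of[j]]
    expected <- mu_j / sum(mu_j) * lib[j]
    counts[, j] <-
      if (cfg$mean_injection) round(expected)
      else if (cfg$dispersion == 0 && cfg$phi_cv == 0)
        stats::rpois(n, expected)
      else stats::rnbinom(n, mu = expected, size = 1 / phi)
  }
  dirs <- lapply(category, pattern_direction)
  truth <- data.frame(
    feature_id = rownames(counts), label = labels, category = category,
    group = unname(category_group_map[category]),
    mu_NL = mu[, "NL"], mu_AR = mu[, "AR"], mu_HY = mu[, "HY"],
    dispersion = phi,
    direction = vapply(dirs, function(d) d$direction, character(1)),
    de_HY_vs_NL = vapply(dirs, function(d) "HY_vs_NL" %in% d$contrasts,
                         logical(1)),
    de_HY_vs_AR = vapply(dirs, function(d) "HY_vs_AR" %in% d$contrasts,
                         logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

#' Simulate a three-stock expression dataset with known truth
#'
#' Draws gene- and miRNA-level count matrices for the NL/AR/HY design from
#' negative-binomial distributions whose stock means encode the configured
#' expression-pattern labels: conserved features share one mean; additive
#' features place the hybrid exactly at the mid-parent value; ELD features
#' pin the hybrid to one parent; ELOD features place it `effect_size`-fold
#' above the higher (or below the lower) parent.  Identical seeds give
#' identical output.
#'
#' @param config a [sim_config()].
#' @return object of class `"heterosim"`: a list with `design` (sample_id,
#'   stock, replicate), `gene_counts`, `gene_lengths`, `gene_truth`,
#'   `mirna_counts`, `mirna_truth`, `lib_sizes`, and the `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    reps <- config$n_replicates
    samples <- paste0(rep(stock_levels, each = reps), seq_len(reps))
    design <- data.frame(sample_id = samples,
                         stock = rep(stock_levels, each = reps),
                         replicate = rep(seq_len(reps), 3),
                         stringsAsFactors = FALSE)
    jit <- function(nominal) {
      if (config$mean_injection) rep(nominal, length(samples))
      else nominal * stats::runif(length(samples),
                                  1 - config$libsize_jitter,
                                  1 + config$libsize_jitter)
    }
    glib <- jit(config$library_size)
    genes <- simulate_feature_set(config$n_genes, config$pattern_proportions,
                                  "gene", config, glib)
    gene_lengths <- stats::setNames(
      pmax(200, round(stats::rlnorm(config$n_genes, log(1500), 0.6))),
      rownames(genes$counts))
    mirnas <- NULL
    if (config$n_mirnas > 0) {
      mlib <- jit(config$mirna_library_size)
      mirnas <- simulate_feature_set(config$n_mirnas,
                                     config$mirna_pattern_proportions,
                                     "mir", config, mlib)
    }
    structure(list(
      design = design,
      gene_counts = genes$counts, gene_lengths = gene_lengths,
      gene_truth = genes$truth,
      mirna_counts = if (is.null(mirnas)) NULL else mirnas$counts,
      mirna_truth = if (is.null(mirnas)) NULL else mirnas$truth,
      lib_sizes = glib, config = config), class = "heterosim")
  })
}

#' @export
print.heterosim <- function(x, ...) {
  cat(sprintf("Synthetic heterosis dataset: %d genes, %d miRNAs, %d samples\n",
              nrow(x$gene_counts),
              if (is.null(x$mirna_counts)) 0L else nrow(x$mirna_counts),
              nrow(x$design)))
  print(x$config)
  invisible(x)
}

#' Simulate a miRNA -> target-gene table with controlled negative regulation
#'
#' Emits `targets_per_mirna` candidate target genes for every truly
#' differential (ELD/ELOD) miRNA.  A configurable fraction of rows is
#' constructed to be negatively regulated: the gene is drawn from features
#' sharing a hybrid-vs-parent contrast with the miRNA but with the opposite
#' true direction.  The remaining rows draw the gene direction at random
#' (opposite with probability 1/2), so with `negative_fraction = 0` about
#' half of the DE-DE pairs survive the downstream negativity filter, and with
#' `negative_fraction = 1` all of them do.
#'
#' @param sim a `"heterosim"` dataset from [simulate_counts()].
#' @param targets_per_mirna candidate targets per differential miRNA.
#' @param negative_fraction fraction of rows forced to be negative pairs.
#' @param seed RNG seed.
#' @return data.frame with `mirna_id`, `gene_id`, `score` (a miRanda-style
#'   alignment score) and the generator's `negative_truth` flag.
#' @export
simulate_targets <- function(sim, targets_per_mirna = 5,
                             negative_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(sim, "heterosim"),
            negative_fraction >= 0, negative_fraction <= 1,
            targets_per_mirna >= 0)
  if (targets_per_mirna > nrow(sim$gene_truth))
    stop("targets_per_mirna exceeds the number of genes")
  gt <- sim$gene_truth
  mt <- sim$mirna_truth
  if (is.null(mt)) stop("dataset has no miRNAs")
  mt <- mt[!is.na(mt$direction), , drop = FALSE]
  if (targets_per_mirna == 0 || nrow(mt) == 0)
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      score = numeric(0), negative_truth = logical(0),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    pool <- function(contrasts, direction, opposite) {
      want <- if (opposite) setdiff(c("up", "down"), direction) else direction
      share <- (gt$de_HY_vs_NL & "HY_vs_NL" %in% contrasts) |
        (gt$de_HY_vs_AR & "HY_vs_AR" %in% contrasts)
      gt$feature_id[share & !is.na(gt$direction) & gt$direction == want]
    }
    total <- nrow(mt) * targets_per_mirna
    n_neg <- round(negative_fraction * total)
    neg_flag <- sample(rep(c(TRUE, FALSE), c(n_neg, total - n_neg)))
    rows <- vector("list", nrow(mt))
    k <- 0L
    for (i in seq_len(nrow(mt))) {
      contrasts <- c("HY_vs_NL", "HY_vs_AR")[
        c(mt$de_HY_vs_NL[i], mt$de_HY_vs_AR[i])]
      flags <- neg_flag[k + seq_len(targets_per_mirna)]
      k <- k + targets_per_mirna
      used <- character(0)
      gid <- character(targets_per_mirna)
      isneg <- logical(targets_per_mirna)
      for (r in seq_len(targets_per_mirna)) {
        opp <- if (flags[r]) TRUE else stats::runif(1) < 0.5
        cand <- setdiff(pool(contrasts, mt$direction[i], opp), used)
        if (!length(cand)) {
          cand <- setdiff(pool(contrasts, mt$direction[i], !opp), used)
          opp <- !opp
        }
        if (!length(cand)) break
        gid[r] <- if (length(cand) == 1) cand else sample(cand, 1)
        isneg[r] <- opp
        used <- c(used, gid[r])
      }
      keep <- nzchar(gid)
      rows[[i]] <- data.frame(mirna_id = mt$feature_id[i], gene_id = gid[keep],
                              negative_truth = isneg[keep],
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$score <- round(stats::runif(nrow(out), 140, 200), 2)
    out[, c("mirna_id", "gene_id", "score", "negative_truth")]
  })
}

#' Simulate a gene -> pathway annotation table
#'
#' Random pathway memberships over the simulated genes, optionally biasing a
#' few pathways toward a chosen gene set so that downstream enrichment has
#' signal to find.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_pathways number of pathways.
#' @param mean_size expected genes per pathway.
#' @param boost_set optional gene ids to over-represent.
#' @param n_boosted number of pathways biased toward `boost_set`.
#' @param boost_weight fraction of a biased pathway's members drawn from
#'   `boost_set`.
#' @param seed RNG seed.
#' @return data.frame with `gene_id`, `pathway_id`, `pathway_name`.
#' @export
simulate_annotation <- function(gene_ids, n_pathways = 40, mean_size = 25,
                                boost_set = NULL, n_boosted = 3,
                                boost_weight = 0.7, seed = 1L) {
  stopifnot(length(gene_ids) > 0, n_pathways >= 1)
  with_seed(seed, {
    rows <- lapply(seq_len(n_pathways), function(p) {
      size <- min(length(gene_ids), 5 + stats::rpois(1, mean_size))
      boosted <- !is.null(boost_set) && p <= n_boosted
      members <- if (boosted) {
        nb <- min(length(boost_set), round(boost_weight * size))
        c(sample(boost_set, nb),
          sample(setdiff(gene_ids, boost_set), size - nb))
      } else sample(gene_ids, size)
      data.frame(gene_id = unique(members),
                 pathway_id = sprintf("path%03d", p),
                 pathway_name = sprintf("synthetic pathway %03d", p),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Default per-stock growth parameters
#'
#' Specific growth rates (%/day) over the two culture phases (days 0-45 and
#' 45-90) and initial body weight for each stock, chosen so the hybrid grows
#' ~1.46x faster than AR and ~1.27x faster than NL in phase one and retains a
#' smaller premium in phase two, as observed in pond-reared hybrid tilapia.
#'
#' @return data.frame with `stock`, `w0_g`, `sgr1`, `sgr2`.
#' @export
default_growth_params <- function() {
  data.frame(stock = c("NL", "AR", "HY"),
             w0_g = c(6, 6, 6),
             sgr1 = c(2.60 / 1.27, 2.60 / 1.46, 2.60),
             sgr2 = c(2.00 / 1.17, 2.00 / 1.33, 2.00),
             stringsAsFactors = FALSE)
}

#' Simulate longitudinal growth phenotypes
#'
#' Per-fish body weight (g), length (cm) and depth (cm) at the given
#' measurement days, grown exponentially at each stock's specific growth rate
#' with multiplicative lognormal measurement noise.  Length follows weight
#' isometrically (\eqn{W = 0.02 L^3}) and depth is 35\% of length.  With
#' `cv = 0` output is exact, so the specific growth rate recovered downstream
#' equals the configured one.
#'
#' @param n_fish fish per stock.
#' @param params per-stock growth parameters, as [default_growth_params()].
#' @param days measurement days; the first is the start of culture.
#' @param cv lognormal coefficient of variation of measurements.
#' @param seed RNG seed.
#' @return data.frame with `fish_id`, `stock`, `day`, `weight_g`,
#'   `length_cm`, `depth_cm`.
#' @export
simulate_phenotypes <- function(n_fish = 30, params = default_growth_params(),
                                days = c(0, 45, 90), cv = 0.1, seed = 1L) {
  stopifnot(n_fish >= 0, all(days >= 0), cv >= 0)
  if (n_fish == 0)
    return(data.frame(fish_id = character(0), stock = character(0),
                      day = numeric(0), weight_g = numeric(0),
                      length_cm = numeric(0), depth_cm = numeric(0),
                      stringsAsFactors = FALSE))
  if (any(params$w0_g <= 0)) stop("initial weights must be positive")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      st <- params$stock[i]
      w0 <- params$w0_g[i] *
        (if (cv > 0) stats::rlnorm(n_fish, 0, cv) else rep(1, n_fish))
      out <- lapply(days, function(d) {
        phase1 <- min(d, 45); phase2 <- max(0, d - 45)
        w <- w0 * exp((params$sgr1[i] * phase1 + params$sgr2[i] * phase2) / 100)
        noise <- function() if (cv > 0) stats::rlnorm(n_fish, 0, cv) else 1
        wmeas <- w * noise()
        l <- (wmeas / 0.02)^(1 / 3) * noise()^(1 / 3)
        data.frame(fish_id = sprintf("%s_f%03d", st, seq_len(n_fish)),
                   stock = st, day = d, weight_g = wmeas, length_cm = l,
                   depth_cm = 0.35 * l, stringsAsFactors = FALSE)
      })
      do.call(rbind, out)
    })
    do.call(rbind, rows)
  })
}

#' Write a simulated dataset as the pipeline's TSV dialects
#'
#' @param sim a `"heterosim"` dataset.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_sim_tsv <- function(sim, dir) {
  stopifnot(inherits(sim, "heterosim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths <<- c(paths, p)
  }
  counts_df <- function(m)
    data.frame(feature_id = rownames(m), m, check.names = FALSE,
               stringsAsFactors = FALSE)
  put(counts_df(sim$gene_counts), "gene_counts.tsv")
  put(data.frame(feature_id = names(sim$gene_lengths),
                 length_nt = unname(sim$gene_lengths)), "gene_lengths.tsv")
  put(sim$design, "design.tsv")
  put(sim$gene_truth, "gene_truth.tsv")
  if (!is.null(sim$mirna_counts)) {
    put(counts_df(sim$mirna_counts), "mirna_counts.tsv")
    put(sim$mirna_truth, "mirna_truth.tsv")
  }
  invisible(paths)
}
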