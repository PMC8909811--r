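# The central model fit: per-feature NB contrasts of a two-parent/hybrid
# design plus the pattern classification, packaged as a classed object with
# the usual modelling methods.

#' Fit the heterosis expression model to a three-stock count matrix
#'
#' Runs the full per-feature analysis of a two-parent/hybrid (NL, AR, HY)
#' RNA-seq design: median-of-ratios size factors, the three pairwise
#' negative-binomial Wald contrasts (NL vs AR, HY vs NL, HY vs AR), the
#' hybrid-vs-mid-parent non-additivity contrast, threshold-based DEG/DEM
#' calling, and classification of every feature into the twelve
#' additivity/dominance/overdominance categories.
#'
#' @param counts integer count matrix, features x samples, with dimnames.
#' @param design data.frame with columns `sample_id`, `stock` (NL, AR, HY)
#'   and optionally `replicate`.
#' @param lengths named feature lengths in nucleotides (needed for gene TPM;
#'   miRNAs default to unit length).
#' @param feature_type `"gene"` or `"mirna"`; selects the threshold set.
#' @param policy a [threshold_policy()].
#' @return an object of class `"heterosis"` with components `counts`,
#'   `design`, `feature_type`, `policy`, `size_factors`, `normalized`, `tpm`,
#'   `calls` (named list of the four contrasts, threshold-flagged),
#'   `assignments` (from [classify_patterns()]), `dispersion` (per-feature
#'   pooled within-stock moment estimate used by [residuals.heterosis()] and
#'   [simulate.heterosis()]), and `fitted_means` (features x stocks mean
#'   normalized counts).
#' @seealso [summary.heterosis()], [coef.heterosis()], [predict.heterosis()],
#'   [plot.heterosis()], [simulate.heterosis()], [residuals.heterosis()]
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, n_mirnas = 0, seed = 7))
#' fit <- heterosis(sim$gene_counts, sim$design, sim$gene_lengths)
#' fit
#' head(coef(fit))
#' @export
heterosis <- function(counts, design, lengths = NULL,
                      feature_type = c("gene", "mirna"),
                      policy = threshold_policy()) {
  feature_type <- match.arg(feature_type)
  check_counts(counts); check_design(design)
  if (!all(stock_levels %in% design$stock))
    stop("design must contain all three stocks (NL, AR, HY)")
  if (!setequal(design$sample_id, colnames(counts)))
    stop("design sample ids must match count matrix columns")
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)

  contrasts <- list(NL_vs_AR = c("NL", "AR"), HY_vs_NL = c("HY", "NL"),
                    HY_vs_AR = c("HY", "AR"))
  calls <- lapply(contrasts, function(g)
    call_de(nb_test(counts, design, g[1], g[2], sf = sf), policy,
            feature_type))
  calls$HY_vs_MPV <- call_de(mpv_test(counts, design, sf = sf), policy,
                             feature_type)
  assignments <- classify_patterns(calls, policy, feature_type)

  fitted_means <- vapply(stock_levels, function(s)
    rowMeans(norm[, design$sample_id[design$stock == s], drop = FALSE]),
    numeric(nrow(counts)))
  # pooled within-stock moment dispersion for residuals/simulation
  pooled <- Reduce(`+`, lapply(stock_levels, function(s)  {
    cols <- design$sample_id[design$stock == s]
    x <- norm[, cols, drop = FALSE]
    m <- rowMeans(x)
    v <- rowSums((x - m)^2)
    phi <- ifelse(m > 0, (v / (length(cols) - 1) - m) / m^2, 0)
    (length(cols) - 1) * pmax(0, ifelse(is.finite(phi), phi, 0))
  }))
  dispersion <- pooled / (nrow(design) - 3)

  structure(list(
    counts = counts, design = design, feature_type = feature_type,
    policy = policy, size_factors = sf, normalized = norm,
    tpm = tpm(counts, lengths), lengths = lengths, calls = calls,
    assignments = assignments, dispersion = dispersion,
    fitted_means = fitted_means), class = "heterosis")
}

de_ids <- function(fit, contrast) {
  d <- fit$calls[[contrast]]
  d$feature_id[d$significant]
}

#' @export
print.heterosis <- function(x, ...) {
  lab <- if (x$feature_type == "gene") "DEGs" else "DEMs"
  cat(sprintf("Heterosis expression fit: %d %ss, %d samples\n",
              nrow(x$counts), x$feature_type, ncol(x$counts)))
  for (cn in c("NL_vs_AR", "HY_vs_NL", "HY_vs_AR"))
    cat(sprintf("  %-9s: %4d %s\n", cn, length(de_ids(x, cn)), lab))
  cat(sprintf("  non-additive (vs mid-parent, p < %g): %d\n",
              x$policy$mpv_p, sum(x$calls$HY_vs_MPV$significant)))
  s <- summarize_categories(x$assignments)
  cat(sprintf("  categorized (I-XII): %d; ELD+ELOD total: %d\n",
              s$total_classified, s$non_additive_total))
  invisible(x)
}

#' Summarize a heterosis fit
#'
#' @param object a [heterosis()] fit.
#' @param ... unused.
#' @return list of class `"summary.heterosis"` with `de_counts` (significant
#'   features per contrast), `categories` (a [summarize_categories()]
#'   result), `venn` (three-way DE overlap from [venn_counts()]) and the
#'   non-additive total.
#' @export
summary.heterosis <- function(object, ...) {
  pair <- c("NL_vs_AR", "HY_vs_NL", "HY_vs_AR")
  sets <- lapply(stats::setNames(pair, pair), de_ids, fit = object)
  out <- list(feature_type = object$feature_type,
              de_counts = vapply(object$calls, function(d)
                sum(d$significant), integer(1)),
              categories = summarize_categories(object$assignments),
              venn = venn_counts(sets),
              n_non_additive = sum(object$calls$HY_vs_MPV$significant))
  class(out) <- "summary.heterosis"
  out
}

#' @export
print.summary.heterosis <- function(x, ...) {
  cat("Differential calls per contrast:\n")
  print(x$de_counts)
  print(x$categories)
  cat("Three-way DE overlap (7 Venn regions):\n")
  print(x$venn$regions)
  invisible(x)
}

#' Log2 fold changes of all contrasts
#'
#' @param object a [heterosis()] fit.
#' @param ... unused.
#' @return numeric matrix, features x contrasts.
#' @export
coef.heterosis <- function(object, ...) {
  m <- vapply(object$calls, function(d) d$log2fc,
              numeric(nrow(object$counts)))
  rownames(m) <- object$calls[[1]]$feature_id
  m
}

#' Fitted stock means
#'
#' @param object a [heterosis()] fit.
#' @param type `"normalized"` for mean normalized counts per stock, `"tpm"`
#'   for mean TPM per stock.
#' @param ... unused.
#' @return numeric matrix, features x stocks (NL, AR, HY).
#' @export
predict.heterosis <- function(object, type = c("normalized", "tpm"), ...) {
  type <- match.arg(type)
  if (type == "normalized") return(object$fitted_means)
  vapply(stock_levels, function(s)
    rowMeans(object$tpm[, object$design$sample_id[object$design$stock == s],
                        drop = FALSE]),
    numeric(nrow(object$tpm)))
}

#' Pearson residuals of the fitted NB means
#'
#' Residuals \eqn{(c_{ij} - \hat\mu_{ij}) / \sqrt{\hat\mu_{ij} +
#' \hat\phi_i \hat\mu_{ij}^2}} on the raw-count scale, where
#' \eqn{\hat\mu_{ij}} is the fitted stock mean rescaled by the sample's size
#' factor and \eqn{\hat\phi_i} the pooled within-stock dispersion.
#'
#' @param object a [heterosis()] fit.
#' @param ... unused.
#' @return numeric matrix with the dimensions of the count matrix.
#' @export
residuals.heterosis <- function(object, ...) {
  mu <- sweep(object$fitted_means[, object$design$stock, drop = FALSE], 2,
              object$size_factors[object$design$sample_id], "*")
  colnames(mu) <- object$design$sample_id
  v <- mu + object$dispersion * mu^2
  r <- (object$counts - mu) / sqrt(v)
  r[!is.finite(r)] <- 0
  r
}

#' Parametric simulation from a heterosis fit
#'
#' Draws new count matrices from the fitted model: NB with mean equal to the
#' fitted stock mean times the sample's size factor and the per-feature
#' pooled dispersion.
#'
#' @param object a [heterosis()] fit.
#' @param nsim number of replicate datasets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of `nsim` count matrices shaped like the original.
#' @importFrom stats simulate
#' @export
simulate.heterosis <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- sweep(object$fitted_means[, object$design$stock, drop = FALSE], 2,
              object$size_factors[object$design$sample_id], "*")
  colnames(mu) <- object$design$sample_id
  phi <- pmax(object$dispersion, 1e-8)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
    m
  }))
}

#' Pattern plot of a heterosis fit
#'
#' Scatter of the two hybrid-vs-parent log2 fold changes, colored by the
#' assigned pattern group: additive features fall along the minor diagonal,
#' ELD features hug one axis, overdominant features sit in the first or
#' third quadrant.
#'
#' @param x a [heterosis()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.heterosis <- function(x, ...) {
  groups <- c(none = "grey70", additive = "#4477AA", ELD_NL = "#228833",
              ELD_AR = "#CCBB44", ELOD_up = "#EE6677", ELOD_down = "#AA3377")
  g <- x$assignments$group
  graphics::plot(x$calls$HY_vs_NL$log2fc, x$calls$HY_vs_AR$log2fc,
                 col = groups[g], pch = 20, cex = 0.5,
                 xlab = "log2 FC HY vs NL", ylab = "log2 FC HY vs AR", ...)
  graphics::abline(h = 0, v = 0, col = "grey50", lty = 3)
  graphics::legend("topleft", legend = names(groups), col = groups,
                   pch = 20, cex = 0.7, bty = "n")
  invisible(x)
}
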