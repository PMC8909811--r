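#' Significance thresholds for differential calls
#'
#' Bundles the thresholds that define differentially expressed genes (DEGs),
#' differentially expressed miRNAs (DEMs), and non-additive features.  A gene
#' is a DEG when its raw p-value is below `gene_p` and its fold change exceeds
#' `gene_fc` (or is below `1/gene_fc`); a miRNA is a DEM on the p-value alone.
#' Non-additivity (hybrid vs mid-parent) is called at `mpv_p`.  Raw p-values
#' are gated by default; set `use_bh = TRUE` to gate on Benjamini-Hochberg
#' adjusted p-values instead.
#'
#' @param gene_p,gene_fc p-value and fold-change thresholds for genes.
#' @param mirna_p p-value threshold for miRNAs (no fold-change gate).
#' @param mirna_fc optional fold-change threshold for miRNAs; `NULL` disables
#'   the gate (the default).
#' @param mpv_p p-value threshold for the hybrid-vs-mid-parent contrast.
#' @param use_bh gate significance on BH-adjusted p-values.
#' @return an object of class `"threshold_policy"`.
#' @export
threshold_policy <- function(gene_p = 0.01, gene_fc = 2, mirna_p = 0.05,
                             mirna_fc = NULL, mpv_p = 0.05, use_bh = FALSE) {
  stopifnot(gene_p > 0, gene_p < 1, mirna_p > 0, mirna_p < 1,
            mpv_p > 0, mpv_p < 1, gene_fc > 1,
            is.null(mirna_fc) || mirna_fc > 1)
  structure(list(gene_p = gene_p, gene_fc = gene_fc, mirna_p = mirna_p,
                 mirna_fc = mirna_fc, mpv_p = mpv_p, use_bh = use_bh),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("Threshold policy\n")
  cat(sprintf("  genes : p < %g, fold change > %g or < %g\n",
              x$gene_p, x$gene_fc, 1 / x$gene_fc))
  cat(sprintf("  miRNAs: p < %g%s\n", x$mirna_p,
              if (is.null(x$mirna_fc)) "" else
                sprintf(", fold change > %g or < %g", x$mirna_fc, 1 / x$mirna_fc)))
  cat(sprintf("  mid-parent (non-additivity): p < %g\n", x$mpv_p))
  cat(sprintf("  gating on %s p-values\n",
              if (x$use_bh) "BH-adjusted" else "raw"))
  invisible(x)
}

# Moment-based NB Wald test on two matrices of normalized counts.
#
# xa, xb       features x replicates, already divided by size factors
# inv_wa/inv_wb mean reciprocal shot-noise weight per group (for ordinary
#              samples the weight is the size factor; pseudo mid-parent
#              samples carry a combined weight)
# phi_null     optional fixed dispersion overriding estimation (zero-noise
#              regression modes)
#
# Dispersion is estimated per feature by method of moments, pooled within the
# two groups, floored at zero and shrunk toward the across-feature median with
# weight n/(n+4) where n is the smaller per-group replicate count.  The Wald
# statistic is the difference of log group means (pseudo-count 0.5) over its
# delta-method standard error, referred to the standard normal.
nb_wald <- function(xa, xb, inv_wa = 1, inv_wb = 1, phi_null = NULL) {
  na <- ncol(xa); nb <- ncol(xb)
  if (na < 2 || nb < 2) stop("each group needs at least 2 replicates")
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  if (is.null(phi_null)) {
    va <- rowSums((xa - ma)^2) / (na - 1)
    vb <- rowSums((xb - mb)^2) / (nb - 1)
    phia <- ifelse(ma > 0, (va - ma * inv_wa) / ma^2, 0)
    phib <- ifelse(mb > 0, (vb - mb * inv_wb) / mb^2, 0)
    phi <- pmax(0, ((na - 1) * phia + (nb - 1) * phib) / (na + nb - 2))
    phi[!is.finite(phi)] <- 0
    expressed <- ma + mb > 0
    med <- if (any(expressed)) stats::median(phi[expressed]) else 0
    n_shr <- min(na, nb)
    w <- n_shr / (n_shr + 4)
    phi <- w * phi + (1 - w) * med
  } else {
    phi <- rep(phi_null, length(ma))
  }
  mua <- ma + 0.5
  mub <- mb + 0.5
  vla <- (mua * inv_wa + phi * mua^2) / (na * mua^2)
  vlb <- (mub * inv_wb + phi * mub^2) / (nb * mub^2)
  z <- (log(mua) - log(mub)) / sqrt(vla + vlb)
  p <- 2 * stats::pnorm(-abs(z))
  lfc <- log2(mua / mub)
  allzero <- ma == 0 & mb == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  z[allzero] <- 0
  data.frame(feature_id = rownames(xa), log2fc = lfc, stat = z, p_value = p,
             dispersion = phi, mean_a = ma, mean_b = mb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise negative-binomial Wald test between two stocks
#'
#' Tests each feature for differential expression between two stocks of a
#' three-stock (NL, AR, HY) design.  Counts are scaled by median-of-ratios
#' size factors computed on the full matrix; per-feature dispersion is
#' estimated by method of moments pooled within the two groups and shrunk
#' toward the across-feature median; the log2 ratio of pseudo-counted group
#' means is tested with a delta-method Wald statistic against the standard
#' normal.  All-zero features report `p_value = 1`, `log2fc = 0`.
#'
#' @param counts integer count matrix, features x samples.
#' @param design data.frame with columns `sample_id` and `stock`
#'   (values among NL, AR, HY) covering the columns of `counts`.
#' @param group_a,group_b the two stocks to contrast; the log2 fold change is
#'   `group_a` over `group_b`.
#' @param sf optional pre-computed size factors (named per sample).
#' @return data.frame with one row per feature: `feature_id`, `contrast`,
#'   `log2fc`, `stat`, `p_value`, `adj_p` (BH), `dispersion`, and the group
#'   means of normalized counts.
#' @seealso [mpv_test()] for the hybrid-vs-mid-parent contrast,
#'   [call_de()] to apply threshold gates.
#' @export
nb_test <- function(counts, design, group_a, group_b, sf = NULL) {
  check_counts(counts); check_design(design)
  for (g in c(group_a, group_b))
    if (!g %in% design$stock) stop("stock absent from design: ", g)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  sa <- design$sample_id[design$stock == group_a]
  sb <- design$sample_id[design$stock == group_b]
  res <- nb_wald(norm[, sa, drop = FALSE], norm[, sb, drop = FALSE],
                 inv_wa = mean(1 / sf[sa]), inv_wb = mean(1 / sf[sb]))
  res$contrast <- paste0(group_a, "_vs_", group_b)
  res$adj_p <- stats::p.adjust(res$p_value, "BH")
  res[, c("feature_id", "contrast", "log2fc", "stat", "p_value", "adj_p",
          "dispersion", "mean_a", "mean_b")]
}

#' Hybrid-vs-mid-parent non-additivity test
#'
#' Builds per-replicate pseudo-mid-parent samples
#' \eqn{m_r = (x_{NL,r} + x_{AR,r})/2} from size-factor-normalized parental
#' counts (replicates paired by order of appearance in the design) and applies
#' the negative-binomial Wald test of the hybrid replicates against them.  A
#' feature whose p-value falls below the policy's `mpv_p` is non-additively
#' expressed (a NEG or NEM).
#'
#' @inheritParams nb_test
#' @return data.frame as from [nb_test()], with contrast `"HY_vs_MPV"`.
#' @export
mpv_test <- function(counts, design, sf = NULL) {
  check_counts(counts); check_design(design)
  if (!all(stock_levels %in% design$stock))
    stop("mpv_test needs all three stocks (NL, AR, HY) in the design")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  snl <- design$sample_id[design$stock == "NL"]
  sar <- design$sample_id[design$stock == "AR"]
  shy <- design$sample_id[design$stock == "HY"]
  k <- min(length(snl), length(sar))
  if (length(snl) != length(sar))
    warning("unequal parental replicate counts; pairing the first ", k)
  snl <- snl[seq_len(k)]; sar <- sar[seq_len(k)]
  mpv <- (norm[, snl, drop = FALSE] + norm[, sar, drop = FALSE]) / 2
  colnames(mpv) <- paste0("MPV", seq_len(k))
  # a pseudo sample averages two libraries, so its shot-noise weight is the
  # harmonic combination of the parental size factors
  inv_w_mpv <- mean((1 / sf[snl] + 1 / sf[sar]) / 4)
  res <- nb_wald(norm[, shy, drop = FALSE], mpv,
                 inv_wa = mean(1 / sf[shy]), inv_wb = inv_w_mpv)
  res$contrast <- "HY_vs_MPV"
  res$adj_p <- stats::p.adjust(res$p_value, "BH")
  res[, c("feature_id", "contrast", "log2fc", "stat", "p_value", "adj_p",
          "dispersion", "mean_a", "mean_b")]
}

#' Apply significance thresholds to differential test results
#'
#' Flags each feature as significant according to the feature-type policy:
#' genes require the p-value gate and the fold-change gate; miRNAs the
#' p-value gate alone; the hybrid-vs-mid-parent contrast uses `mpv_p` with no
#' fold-change gate.  `direction` is `"up"`/`"down"` by the sign of the log2
#' fold change for significant features and `"ns"` otherwise.
#'
#' @param calls data.frame from [nb_test()] or [mpv_test()].
#' @param policy a [threshold_policy()].
#' @param feature_type `"gene"` or `"mirna"`.
#' @return `calls` with added logical `significant` and character `direction`.
#' @export
call_de <- function(calls, policy = threshold_policy(),
                    feature_type = c("gene", "mirna")) {
  feature_type <- match.arg(feature_type)
  stopifnot(inherits(policy, "threshold_policy"))
  p <- if (policy$use_bh) calls$adj_p else calls$p_value
  is_mpv <- calls$contrast == "HY_vs_MPV"
  if (feature_type == "gene") {
    p_thr <- policy$gene_p
    fc_thr <- policy$gene_fc
  } else {
    p_thr <- policy$mirna_p
    fc_thr <- policy$mirna_fc
  }
  fc_ok <- if (is.null(fc_thr)) TRUE else abs(calls$log2fc) > log2(fc_thr)
  sig <- ifelse(is_mpv, p < policy$mpv_p, p < p_thr & fc_ok)
  calls$significant <- sig
  calls$direction <- ifelse(!sig, "ns", ifelse(calls$log2fc > 0, "up", "down"))
  calls
}
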