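# Hypergeometric pathway over-representation.

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric over-representation of a gene set against a
#' gene -> pathway annotation table: for a pathway with \eqn{K} background
#' members, a set of size \eqn{n} drawn from a background of \eqn{N} genes,
#' and an overlap of \eqn{k}, the p-value is \eqn{P[X \ge k]} for
#' \eqn{X \sim} Hypergeometric\eqn{(N, K, n)} (so \eqn{k = 0} gives
#' \eqn{p = 1}).  Benjamini-Hochberg adjusted p-values are reported
#' alongside the raw ones.
#'
#' The background defaults to all annotated genes; pass `background` to
#' intersect with, e.g., the expressed features.  Set genes outside the
#' background are dropped; pathways with no background member are skipped.
#'
#' @param gene_set character vector of gene ids.
#' @param annotation data.frame with columns `gene_id`, `pathway_id` and
#'   optionally `pathway_name`.
#' @param background optional character vector of background gene ids.
#' @return data.frame sorted by p-value: `pathway_id`, `pathway_name`, `k`
#'   (overlap), `n` (set size in background), `K` (pathway size), `N`
#'   (background size), `p_value`, `adj_p`.
#' @export
hypergeom_enrich <- function(gene_set, annotation, background = NULL) {
  stopifnot(all(c("gene_id", "pathway_id") %in% names(annotation)))
  bg <- unique(annotation$gene_id)
  if (!is.null(background)) bg <- intersect(bg, unique(background))
  N <- length(bg)
  if (N == 0) stop("empty background")
  set <- intersect(unique(gene_set), bg)
  n <- length(set)
  ann <- annotation[annotation$gene_id %in% bg, , drop = FALSE]
  by_path <- split(ann$gene_id, ann$pathway_id)
  name_of <- if ("pathway_name" %in% names(ann))
    tapply(ann$pathway_name, ann$pathway_id, `[`, 1) else NULL
  res <- lapply(names(by_path), function(pid) {
    members <- unique(by_path[[pid]])
    K <- length(members)
    k <- length(intersect(set, members))
    data.frame(pathway_id = pid,
               pathway_name = if (is.null(name_of)) NA_character_ else
                 unname(name_of[pid]),
               k = k, n = n, K = K, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$pathway_id), ]
  rownames(out) <- NULL
  out
}
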