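# Negative miRNA-mRNA interaction network.

#' Build the negative miRNA-mRNA interaction network
#'
#' A candidate (miRNA, gene) pair from the target table is retained when both
#' members are significantly differential in at least one shared
#' hybrid-vs-parent contrast and their directions in that contrast are
#' opposite (the negativity rule).  Pairs are deduplicated on (miRNA, gene)
#' and annotated with every contrast supporting them and with the gene's
#' expression-pattern group.
#'
#' @param dem_calls named list with elements `HY_vs_NL` and `HY_vs_AR`: miRNA
#'   differential calls with significance flags (from [call_de()]).
#' @param deg_calls same structure for genes.
#' @param assignments gene pattern assignments from [classify_patterns()]
#'   (used to annotate `pair_category`); may be `NULL`.
#' @param targets data.frame with columns `mirna_id`, `gene_id` and optional
#'   `score`.  Rows referencing unknown features are skipped and counted.
#' @return data.frame of retained pairs: `mirna_id`, `gene_id`, `contrast`
#'   (comma-joined supporting contrasts), `mirna_direction`, `gene_direction`
#'   (directions in the first supporting contrast), `pair_category`, `score`.
#'   The number of skipped unknown-id rows is attached as attribute
#'   `"skipped"`.
#' @export
build_network <- function(dem_calls, deg_calls, assignments, targets) {
  need <- c("HY_vs_NL", "HY_vs_AR")
  stopifnot(all(need %in% names(dem_calls)), all(need %in% names(deg_calls)),
            all(c("mirna_id", "gene_id") %in% names(targets)))
  empty <- data.frame(mirna_id = character(0), gene_id = character(0),
                      contrast = character(0), mirna_direction = character(0),
                      gene_direction = character(0),
                      pair_category = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(targets) == 0) return(structure(empty, skipped = 0L))
  dir_of <- function(calls, ids, contrast)
    calls[[contrast]]$direction[match(ids, calls[[contrast]]$feature_id)]
  known <- targets$mirna_id %in% dem_calls$HY_vs_NL$feature_id &
    targets$gene_id %in% deg_calls$HY_vs_NL$feature_id
  skipped <- sum(!known)
  tg <- targets[known & !duplicated(targets[c("mirna_id", "gene_id")]), ,
                drop = FALSE]
  rows <- vector("list", length(need))
  for (ci in seq_along(need)) {
    cn <- need[ci]
    md <- dir_of(dem_calls, tg$mirna_id, cn)
    gd <- dir_of(deg_calls, tg$gene_id, cn)
    keep <- md != "ns" & gd != "ns" & md != gd
    rows[[ci]] <- data.frame(mirna_id = tg$mirna_id[keep],
                             gene_id = tg$gene_id[keep], contrast = cn,
                             mirna_direction = md[keep],
                             gene_direction = gd[keep],
                             score = if ("score" %in% names(tg))
                               tg$score[keep] else NA_real_,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (nrow(out) == 0) return(structure(empty, skipped = skipped))
  key <- paste(out$mirna_id, out$gene_id)
  first <- !duplicated(key)
  support <- vapply(split(out$contrast, key), paste, character(1),
                    collapse = ",")
  pairs <- out[first, , drop = FALSE]
  pairs$contrast <- unname(support[paste(pairs$mirna_id, pairs$gene_id)])
  pairs$pair_category <- if (is.null(assignments)) NA_character_ else
    assignments$group[match(pairs$gene_id, assignments$feature_id)]
  rownames(pairs) <- NULL
  structure(pairs[, c("mirna_id", "gene_id", "contrast", "mirna_direction",
                      "gene_direction", "pair_category", "score")],
            skipped = skipped)
}

#' Summary statistics of a miRNA-mRNA interaction network
#'
#' @param pairs data.frame from [build_network()].
#' @return list with `n_pairs`, `n_mirnas`, `n_genes`, `pct_gene_up` (share
#'   of pairs whose gene is up-regulated in the hybrid relative to the parent
#'   of its supporting contrast), and `per_group` (pair counts and
#'   percentages by the gene's pattern group).  Percentages are rounded
#'   half-up to one decimal.
#' @export
network_stats <- function(pairs) {
  if (nrow(pairs) == 0)
    return(list(n_pairs = 0L, n_mirnas = 0L, n_genes = 0L,
                pct_gene_up = 0,
                per_group = data.frame(group = character(0),
                                       n = integer(0), pct = numeric(0))))
  grp <- table(pairs$pair_category, useNA = "ifany")
  per_group <- data.frame(group = names(grp), n = as.integer(grp),
                          pct = round_half_up(100 * as.integer(grp) /
                                                nrow(pairs), 1),
                          stringsAsFactors = FALSE)
  list(n_pairs = nrow(pairs),
       n_mirnas = length(unique(pairs$mirna_id)),
       n_genes = length(unique(pairs$gene_id)),
       pct_gene_up = round_half_up(
         100 * mean(pairs$gene_direction == "up"), 1),
       per_group = per_group[order(-per_group$n), ])
}
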