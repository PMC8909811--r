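# Twelve-category expression-pattern classification for hybrid designs.

category_group_map <- c(
  I = "additive", II = "additive",
  III = "ELD_NL", IV = "ELD_NL",
  V = "ELD_AR", VI = "ELD_AR",
  VII = "ELOD_up", VIII = "ELOD_up", IX = "ELOD_up",
  X = "ELOD_down", XI = "ELOD_down", XII = "ELOD_down",
  conserved = "none", ambiguous = "none")

category_levels <- names(category_group_map)

#' Classify features into additivity / dominance / overdominance categories
#'
#' Given the four per-feature contrasts of a two-parent/hybrid design -- the
#' parental contrast P (NL vs AR), the two hybrid-parent contrasts
#' H_NL (HY vs NL) and H_AR (HY vs AR), and the hybrid-vs-mid-parent contrast
#' M -- each feature is assigned to one of twelve categories or to
#' `conserved`/`ambiguous`:
#'
#' * **ELOD_up** (VII, VIII, IX): HY significantly above both parents; the
#'   sub-category records the parental relation (NL > AR, no difference,
#'   NL < AR).
#' * **ELOD_down** (X, XI, XII): HY significantly below both parents, same
#'   parental sub-binning.
#' * **ELD_NL** (III, IV): parents differ, HY indistinguishable from NL and
#'   different from AR; III when NL > AR, IV otherwise.
#' * **ELD_AR** (V, VI): symmetric with NL; V when AR > NL, VI otherwise.
#' * **additive** (I, II): parents differ and HY is consistent with the
#'   mid-parent value (M not significant); I when NL > AR, II otherwise.
#' * **conserved**: no contrast significant.  **ambiguous**: any remaining
#'   combination.
#'
#' Rules are evaluated in that order; the first match wins.  Contrast
#' significance here is the p-value criterion alone (at the feature type's
#' threshold; `mpv_p` for M): the fold-change gate defines DEG set membership
#' for count summaries, not the statistical comparison of stock means (see the
#' package vignette).  `non_additive` is `TRUE` for every ELD/ELOD feature and
#' for any feature with a significant mid-parent contrast.
#'
#' @param calls named list with elements `NL_vs_AR`, `HY_vs_NL`, `HY_vs_AR`,
#'   `HY_vs_MPV`, each a data.frame from [nb_test()]/[mpv_test()] covering the
#'   same features.
#' @param policy a [threshold_policy()].
#' @param feature_type `"gene"` or `"mirna"`.
#' @return data.frame with `feature_id`, `category` (I--XII, conserved,
#'   ambiguous), `group` (additive, ELD_NL, ELD_AR, ELOD_up, ELOD_down, none)
#'   and logical `non_additive`.
#' @export
classify_patterns <- function(calls, policy = threshold_policy(),
                              feature_type = c("gene", "mirna")) {
  feature_type <- match.arg(feature_type)
  need <- c("NL_vs_AR", "HY_vs_NL", "HY_vs_AR", "HY_vs_MPV")
  if (!all(need %in% names(calls)))
    stop("calls must contain contrasts: ", paste(need, collapse = ", "))
  ids <- calls$NL_vs_AR$feature_id
  al <- lapply(calls[need], function(d) {
    if (!identical(d$feature_id, ids)) {
      d <- d[match(ids, d$feature_id), ]
      if (anyNA(d$feature_id)) stop("contrasts cover different feature sets")
    }
    d
  })
  p_thr <- if (feature_type == "gene") policy$gene_p else policy$mirna_p
  pv <- function(d) if (policy$use_bh) d$adj_p else d$p_value
  P_sig <- pv(al$NL_vs_AR) < p_thr
  HN_sig <- pv(al$HY_vs_NL) < p_thr
  HA_sig <- pv(al$HY_vs_AR) < p_thr
  M_sig <- pv(al$HY_vs_MPV) < policy$mpv_p
  P_up <- al$NL_vs_AR$log2fc > 0       # NL > AR
  HN_up <- al$HY_vs_NL$log2fc > 0
  HA_up <- al$HY_vs_AR$log2fc > 0

  # parental relation bins the ELOD sub-categories: NL>AR / ns / NL<AR
  rel <- ifelse(!P_sig, 2L, ifelse(P_up, 1L, 3L))

  n <- length(ids)
  category <- rep("ambiguous", n)
  done <- rep(FALSE, n)

  take <- function(cond, value) {
    hit <- !done & cond
    value <- rep_len(value, n)
    category[hit] <<- value[hit]
    done[hit] <<- TRUE
  }
  take(HN_sig & HA_sig & HN_up & HA_up,
       c("VII", "VIII", "IX")[rel])
  take(HN_sig & HA_sig & !HN_up & !HA_up,
       c("X", "XI", "XII")[rel])
  take(P_sig & !HN_sig & HA_sig, ifelse(P_up, "III", "IV"))
  take(P_sig & !HA_sig & HN_sig, ifelse(!P_up, "V", "VI"))  # V: AR > NL
  take(P_sig & !M_sig, ifelse(P_up, "I", "II"))
  take(!P_sig & !HN_sig & !HA_sig & !M_sig, "conserved")

  group <- unname(category_group_map[category])
  non_additive <- group %in% c("ELD_NL", "ELD_AR", "ELOD_up", "ELOD_down") |
    M_sig
  data.frame(feature_id = ids, category = category, group = group,
             non_additive = non_additive, stringsAsFactors = FALSE)
}

#' Summarize expression-pattern categories
#'
#' Tabulates category assignments the way hybrid-expression studies report
#' them: per-category counts, per-group totals, each group's percentage of all
#' categorized (I--XII) features, the larger-to-smaller count ratio and the
#' dominant share within each two-category group (and between ELOD_up and
#' ELOD_down), and the total number of non-additive features (the NEG/NEM
#' total, the sum of the ELD and ELOD groups).  Percentages are rounded
#' half-up to one decimal, ratios to two decimals.
#'
#' @param x either a data.frame from [classify_patterns()] or a named integer
#'   vector of per-category counts (names among I--XII, conserved, ambiguous).
#' @return object of class `"category_summary"`: a list with
#'   `category_counts`, `group_counts`, `group_pct`, `within` (a data.frame of
#'   within-group ratios and dominant shares), `non_additive_total`, and
#'   `total_classified`.
#' @export
summarize_categories <- function(x) {
  if (is.data.frame(x)) {
    counts <- table(factor(x$category, levels = category_levels))
    counts <- stats::setNames(as.integer(counts), category_levels)
  } else {
    if (is.null(names(x)) || !all(names(x) %in% category_levels))
      stop("counts must be named by category (I..XII, conserved, ambiguous)")
    counts <- stats::setNames(rep(0L, length(category_levels)), category_levels)
    counts[names(x)] <- as.integer(x)
  }
  groups <- c("additive", "ELD_NL", "ELD_AR", "ELOD_up", "ELOD_down")
  gcount <- vapply(groups, function(g)
    sum(counts[names(category_group_map)[category_group_map == g]]),
    integer(1))
  total <- sum(gcount)
  gpct <- if (total > 0) round_half_up(100 * gcount / total, 1) else
    stats::setNames(rep(0, length(groups)), groups)

  pair_stats <- function(a, b) {
    hi <- max(a, b); lo <- min(a, b)
    c(ratio = if (lo > 0) round_half_up(hi / lo, 2) else NA_real_,
      pct_larger = if (hi + lo > 0) round_half_up(100 * hi / (hi + lo), 1)
      else NA_real_)
  }
  within <- rbind(
    additive = pair_stats(counts[["I"]], counts[["II"]]),
    ELD_NL = pair_stats(counts[["III"]], counts[["IV"]]),
    ELD_AR = pair_stats(counts[["V"]], counts[["VI"]]),
    ELOD = pair_stats(gcount[["ELOD_up"]], gcount[["ELOD_down"]]))
  within <- data.frame(group = rownames(within), within,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(category_counts = counts, group_counts = gcount,
                 group_pct = gpct, within = within,
                 non_additive_total =
                   sum(gcount[c("ELD_NL", "ELD_AR", "ELOD_up", "ELOD_down")]),
                 total_classified = total),
            class = "category_summary")
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Expression-pattern summary (", x$total_classified,
      " categorized features)\n", sep = "")
  df <- data.frame(group = names(x$group_counts), count = x$group_counts,
                   pct = x$group_pct, row.names = NULL)
  print(df, row.names = FALSE)
  cat("non-additive (ELD + ELOD) total:", x$non_additive_total, "\n")
  w <- x$within[!is.na(x$within$ratio), ]
  if (nrow(w)) {
    cat("within-group dominant share / ratio:\n")
    print(w, row.names = FALSE)
  }
  invisible(x)
}
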