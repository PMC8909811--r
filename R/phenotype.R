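# Growth-trait metrics for longitudinal fish phenotypes.

#' Growth metrics from initial and final measurements
#'
#' Computes the four standard aquaculture growth characteristics per record:
#' weight gain rate \eqn{WGR = 100 (W_t - W_0)/W_0}, body length gain rate
#' \eqn{BLGR = 100 (L_t - L_0)/L_0}, body depth gain rate
#' \eqn{BDGR = 100 (D_t - D_0)/D_0}, and specific growth rate
#' \eqn{SGR = 100 (\ln W_t - \ln W_0)/t} in \%/day.
#'
#' @param records data.frame with columns `W0`, `Wt`, `L0`, `Lt`, `D0`, `Dt`
#'   (positive measurements) and `t` (experimental days, > 0); extra columns
#'   (e.g. `fish_id`, `stock`) are carried through.
#' @return `records` with added `WGR`, `BLGR`, `BDGR`, `SGR`.
#' @examples
#' growth_metrics(data.frame(W0 = 10, Wt = 20, L0 = 5, Lt = 7.5,
#'                           D0 = 2, Dt = 2.2, t = 45))
#' @export
growth_metrics <- function(records) {
  need <- c("W0", "Wt", "L0", "Lt", "D0", "Dt", "t")
  stopifnot(all(need %in% names(records)))
  with(records, {
    if (any(W0 <= 0) || any(L0 <= 0) || any(D0 <= 0) || any(t <= 0) ||
        any(Wt <= 0) || any(Lt <= 0) || any(Dt <= 0))
      stop("measurements and duration must be positive")
  })
  records$WGR <- 100 * (records$Wt - records$W0) / records$W0
  records$BLGR <- 100 * (records$Lt - records$L0) / records$L0
  records$BDGR <- 100 * (records$Dt - records$D0) / records$D0
  records$SGR <- 100 * (log(records$Wt) - log(records$W0)) / records$t
  records
}

#' Build growth records from a longitudinal phenotype table
#'
#' Pairs each fish's measurements at two days into a growth record suitable
#' for [growth_metrics()].
#'
#' @param pheno data.frame with columns `fish_id`, `stock`, `day`,
#'   `weight_g`, `length_cm`, `depth_cm` (as written by
#'   [simulate_phenotypes()]).
#' @param from_day,to_day the measurement days to compare.
#' @return data.frame with one row per fish present at both days.
#' @export
growth_records <- function(pheno, from_day = 0, to_day = 45) {
  a <- pheno[pheno$day == from_day, ]
  b <- pheno[pheno$day == to_day, ]
  m <- merge(a, b, by = c("fish_id", "stock"), suffixes = c("_0", "_t"))
  if (nrow(m) == 0) stop("no fish measured at both days")
  data.frame(fish_id = m$fish_id, stock = m$stock,
             W0 = m$weight_g_0, Wt = m$weight_g_t,
             L0 = m$length_cm_0, Lt = m$length_cm_t,
             D0 = m$depth_cm_0, Dt = m$depth_cm_t,
             t = to_day - from_day, stringsAsFactors = FALSE)
}

#' Per-stock growth summary and hybrid/parent ratios
#'
#' Means and standard deviations of each growth metric per stock, plus the
#' ratio of the hybrid's mean to each parent's mean (the classic heterosis
#' ratio, e.g. SGR(HY)/SGR(AR)).
#'
#' @param metrics data.frame from [growth_metrics()] including a `stock`
#'   column.
#' @return list with `by_stock` (stock x metric means and SDs) and `ratios`
#'   (metric x parent matrix of HY/parent mean ratios, when HY and the
#'   parent are present).
#' @export
stock_summary <- function(metrics) {
  stopifnot("stock" %in% names(metrics))
  vars <- c("WGR", "BLGR", "BDGR", "SGR")
  stopifnot(all(vars %in% names(metrics)))
  stocks <- unique(metrics$stock)
  by_stock <- do.call(rbind, lapply(stocks, function(s) {
    sub <- metrics[metrics$stock == s, vars, drop = FALSE]
    if (nrow(sub) == 0) stop("empty stock: ", s)
    data.frame(stock = s, metric = vars,
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, function(x)
                 if (length(x) > 1) stats::sd(x) else 0, numeric(1)),
               n = nrow(sub), row.names = NULL, stringsAsFactors = FALSE)
  }))
  ratios <- NULL
  if ("HY" %in% stocks) {
    parents <- intersect(c("NL", "AR"), stocks)
    if (length(parents)) {
      hy <- by_stock[by_stock$stock == "HY", ]
      ratios <- sapply(parents, function(p) {
        pm <- by_stock[by_stock$stock == p, ]
        hy$mean / pm$mean[match(hy$metric, pm$metric)]
      })
      rownames(ratios) <- hy$metric
      colnames(ratios) <- paste0("HY_over_", parents)
    }
  }
  list(by_stock = by_stock, ratios = ratios)
}
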