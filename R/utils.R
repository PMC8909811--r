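# Internal helpers shared across modules.

# round half away from zero, to match the fixed-decimal reporting style used
# throughout the summary tables (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation calls do not perturb the
# session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# largest-remainder apportionment of `n` items among fractions summing to 1;
# ties on the remainder broken by position (earlier name wins)
apportion <- function(n, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, -seq_along(raw), decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

stock_levels <- c("NL", "AR", "HY")

check_design <- function(design) {
  req <- c("sample_id", "stock")
  if (!is.data.frame(design) || !all(req %in% names(design)))
    stop("design must be a data.frame with columns sample_id and stock")
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design")
  bad <- setdiff(unique(design$stock), stock_levels)
  if (length(bad))
    stop("unknown stock label(s): ", paste(bad, collapse = ", "),
         " (expected NL, AR, HY)")
  invisible(design)
}

check_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature (row) and sample (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  invisible(counts)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
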