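# Shared fixtures and independent oracles for the test suite.

# small three-stock design
toy_design <- function(reps = 3) {
  data.frame(sample_id = paste0(rep(c("NL", "AR", "HY"), each = reps),
                                seq_len(reps)),
             stock = rep(c("NL", "AR", "HY"), each = reps),
             replicate = rep(seq_len(reps), 3),
             stringsAsFactors = FALSE)
}

# count matrix with the given per-stock means injected exactly (no noise)
toy_counts <- function(mu_nl, mu_ar, mu_hy, reps = 3, prefix = "g") {
  n <- length(mu_nl)
  m <- cbind(matrix(rep(mu_nl, reps), n), matrix(rep(mu_ar, reps), n),
             matrix(rep(mu_hy, reps), n))
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(n)),
                      toy_design(reps)$sample_id)
  round(m)
}

# hand-rolled median-of-ratios size factors (independent of the package path)
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1, function(r) all(r > 0))
  gm <- apply(counts[keep, , drop = FALSE], 1,
              function(r) prod(r)^(1 / length(r)))
  f <- apply(counts[keep, , drop = FALSE], 2,
             function(col) median(col / gm))
  f / prod(f)^(1 / length(f))
}

# NB likelihood-ratio test with fixed dispersion: the independent oracle for
# the Wald test (same model, different statistic)
oracle_nb_lrt <- function(xa, xb, phi) {
  phi <- max(phi, 1e-8)
  ll <- function(x, mu) sum(dnbinom(round(x), mu = mu, size = 1 / phi,
                                    log = TRUE))
  lr <- 2 * (ll(xa, mean(xa)) + ll(xb, mean(xb)) -
               ll(c(xa, xb), mean(c(xa, xb))))
  pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}

# exact upper-tail hypergeometric probability by direct enumeration
oracle_hyper_tail <- function(k, K, N, n) {
  i <- seq(max(k, 0), min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# construct a minimal DiffCall data.frame by hand
fake_call <- function(ids, contrast, lfc, p, sig = NULL) {
  d <- data.frame(feature_id = ids, contrast = contrast, log2fc = lfc,
                  stat = 0, p_value = p, adj_p = p.adjust(p, "BH"),
                  dispersion = 0.05, mean_a = 100, mean_b = 100,
                  stringsAsFactors = FALSE)
  if (!is.null(sig)) {
    d$significant <- sig
    d$direction <- ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down"))
  }
  d
}

# balanced pattern mix covering all 13 truth labels
all_label_proportions <- function() {
  lab <- c("conserved", "additive_I", "additive_II", "ELD_NL_III",
           "ELD_NL_IV", "ELD_AR_V", "ELD_AR_VI",
           "ELOD_up_parents_differ_NLhigh", "ELOD_up_parents_equal",
           "ELOD_up_parents_differ_ARhigh",
           "ELOD_down_parents_differ_NLhigh", "ELOD_down_parents_equal",
           "ELOD_down_parents_differ_ARhigh")
  p <- c(0.4, rep(0.6 / 12, 12))
  names(p) <- lab
  p
}
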