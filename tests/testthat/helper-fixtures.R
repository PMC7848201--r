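# shared small fixtures, built in code

small_sim <- function(seed = 1L, n_genes = 60L, ...) {
  cfg <- sim_config(seed = seed, n_genes = n_genes, ...)
  design <- gen_design(cfg)
  sim <- gen_counts(design, cfg)
  list(cfg = cfg, design = design, counts = sim$counts, truth = sim$truth,
       size_factors = sim$size_factors)
}

# brute-force two-sided Fisher exact p for a 2x2 table, by enumerating all
# tables with the same margins (hypergeometric oracle)
fisher_oracle <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # col 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct Pearson correlation formula
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
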