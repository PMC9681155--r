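# Small in-code fixtures shared across test files.

tiny_counts <- function() {
  cnt <- matrix(c(10, 20, 30, 40,
                  5, 5, 5, 5,
                  0, 1, 0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("f1", "f2", "f3"),
                                c("s1", "s2", "s3", "s4")))
  count_matrix(cnt, c(f1 = 1000, f2 = 2000, f3 = 500))
}

two_group_sheet <- function(n = 2, conditions = c("IVF", "SCNT")) {
  tibble::tibble(
    sample_id = paste0(rep(conditions, each = n), "_", rep(seq_len(n), 2)),
    condition = rep(conditions, each = n),
    replicate = rep(seq_len(n), 2)
  )
}

# A quick configuration for tests that need a full simulated data set.
quick_config <- function(...) {
  sim_config(n_te = 300, n_chrom = 1, chrom_length = 4e6, n_genes = 80,
             n_embryos_per_condition = 6, library_size_mean = 2e4, ...)
}

# Independent Welch t-test oracle (statistic + t CDF, hand-coded df).
welch_oracle_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# Independent Spearman oracle: explicit mid-ranks, then the Pearson
# product-moment formula written out.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(rx)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Independent two-sided Fisher oracle: hypergeometric enumeration, summing
# the probabilities of all tables as or less probable than the observed one.
fisher_oracle_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
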