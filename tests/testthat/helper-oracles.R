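# Independent oracles, written from first principles and kept free of any
# package internals so they can check the implementation.

# Step-by-step scalar evaluation of the Weir-Cockerham variance components
# from per-population (n_i, p_i, h_i); spreadsheet style, one quantity at a
# time.
oracle_wc_theta <- function(n, p, h) {
  r <- length(n)
  n_bar <- sum(n) / r
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Brute-force per-population allele counting straight off the dosage matrix.
oracle_freqs <- function(dosage_row, member_cols) {
  g <- dosage_row[member_cols]
  g <- g[!is.na(g)]
  list(n = length(g), p = sum(g) / (2 * length(g)), h = mean(g == 1))
}

# Exhaustive fixed-margin enumeration of the two-sided (minimum-likelihood)
# Fisher p for an overlap table, using factorials directly.
oracle_fisher_two_sided <- function(k, n_list, n_lrg, N) {
  lo <- max(0, n_list + n_lrg - N)
  hi <- min(n_list, n_lrg)
  prob_table <- function(x) {
    exp(lchoose(n_lrg, x) + lchoose(N - n_lrg, n_list - x) - lchoose(N, n_list))
  }
  probs <- vapply(lo:hi, prob_table, numeric(1))
  obs <- prob_table(k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# All-pairs Mann-Whitney U with half credit for ties.
oracle_u_statistic <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Weighted Pearson correlation evaluated term by term.
oracle_weighted_cor <- function(x, y, w) {
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  cxy <- sum(w * (x - mx) * (y - my)) / sum(w)
  cxx <- sum(w * (x - mx)^2) / sum(w)
  cyy <- sum(w * (y - my)^2) / sum(w)
  cxy / sqrt(cxx * cyy)
}

# Tiny genotype fixtures built in code -------------------------------------

# A wide genotype tibble from a plain dosage matrix.
make_genotypes <- function(m, chrom_class = rep("autosome", nrow(m)),
                           position = seq_len(nrow(m)) * 1000L,
                           ancestral = rep("A", nrow(m))) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("i%03d", seq_len(ncol(m)))
  dplyr::bind_cols(
    tibble::tibble(snp_id = rownames(m), chrom_class = chrom_class,
                   position = as.integer(position),
                   ancestral_allele = ancestral),
    tibble::as_tibble(m))
}

# Evenly split the columns of a genotype matrix into populations at given
# latitudes.
make_populations <- function(individuals, n_pops, latitudes) {
  split_idx <- split(individuals, rep(seq_len(n_pops), length.out = length(individuals)))
  population_table(sprintf("P%02d", seq_len(n_pops)), latitudes,
                   unname(split_idx))
}

random_dosage_matrix <- function(n_snp, n_ind, missing_rate = 0.05) {
  m <- matrix(sample(0:2, n_snp * n_ind, replace = TRUE), n_snp, n_ind,
              dimnames = list(sprintf("s%03d", seq_len(n_snp)),
                              sprintf("i%03d", seq_len(n_ind))))
  m[matrix(runif(n_snp * n_ind) < missing_rate, n_snp, n_ind)] <- NA_integer_
  m
}
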