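#' Weir-Cockerham fixation index, genome-wide
#'
#' Moment estimator of F_ST across populations, per SNP, from per-population
#' sample sizes `n_i`, ancestral-allele frequencies `p_i` and observed
#' heterozygote proportions `h_i`. Over the `r` populations with data for a
#' SNP:
#' \deqn{\bar n = \sum n_i / r,\quad
#'       n_c = \frac{r\bar n - \sum n_i^2/(r\bar n)}{r-1},\quad
#'       \bar p = \sum n_i p_i / (r\bar n)}
#' \deqn{s^2 = \sum n_i (p_i-\bar p)^2 / ((r-1)\bar n),\quad
#'       \bar h = \sum n_i h_i / (r\bar n)}
#' and the three variance components
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n-1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n-1}\left[\bar p(1-\bar p) -
#'   \frac{r-1}{r}s^2 - \frac{2\bar n-1}{4\bar n}\bar h\right],\qquad
#'   c = \bar h/2}
#' giving \eqn{\theta = a/(a+b+c)}. Monomorphic SNPs (\eqn{a+b+c = 0}) are
#' flagged undefined, as are SNPs observed in fewer than two populations.
#' Negative \eqn{\theta} values are retained, not clamped.
#'
#' @param freqs Long frequency tibble from [allele_frequencies()].
#' @param snp_ids SNPs to score; defaults to all SNPs in `freqs`, in their
#'   order of first appearance.
#' @return Tibble with one row per SNP: `snp_id`, `chrom_class`, `theta`,
#'   `a`, `b`, `c`, `r`, `n_bar`, `n_c`, `p_bar`, `s2`, `h_bar`,
#'   `undefined`.
#' @references Weir, B.S. and Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fst_scan <- function(freqs, snp_ids = NULL) {
  snp_ids <- snp_ids %||% unique(freqs$snp_id)
  f <- freqs |> filter(.data$snp_id %in% snp_ids)
  pops <- unique(f$pop_id)
  N <- long_to_matrix(f, "n", snp_ids, pops)
  P <- long_to_matrix(f, "p", snp_ids, pops)
  H <- long_to_matrix(f, "h", snp_ids, pops)
  class_map <- f |> distinct(.data$snp_id, .data$chrom_class)
  res <- wc_components(P, N, H)
  res$chrom_class <- class_map$chrom_class[match(res$snp_id, class_map$snp_id)]
  res |> select("snp_id", "chrom_class", dplyr::everything())
}

long_to_matrix <- function(freqs, value, snp_ids, pops) {
  m <- matrix(NA_real_, length(snp_ids), length(pops),
              dimnames = list(snp_ids, pops))
  m[cbind(match(freqs$snp_id, snp_ids), match(freqs$pop_id, pops))] <-
    freqs[[value]]
  m
}

# Vectorised variance-component arithmetic on SNP x population matrices;
# NA marks a population without data for that SNP.
wc_components <- function(P, N, H) {
  obs <- !is.na(N) & N > 0
  N[!obs] <- NA_real_
  r <- rowSums(obs)
  sum_n <- rowSums(N, na.rm = TRUE)
  n_bar <- sum_n / r
  sum_n2 <- rowSums(N * N, na.rm = TRUE)      # n_i integer: exact in doubles
  n_c <- (sum_n - sum_n2 / sum_n) / (r - 1)
  equal_n <- rowSums(obs * (N != n_bar), na.rm = TRUE) == 0
  n_c[equal_n] <- n_bar[equal_n]              # degenerate case, no cancellation
  p_bar <- rowSums(N * P, na.rm = TRUE) / sum_n
  s2 <- rowSums(N * (P - p_bar)^2, na.rm = TRUE) / ((r - 1) * n_bar)
  h_bar <- rowSums(N * H, na.rm = TRUE) / sum_n
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  theta <- ifelse(denom != 0, a / denom, NA_real_)
  undefined <- r < 2 | denom == 0 | !is.finite(theta)
  theta[undefined] <- NA_real_
  tibble(snp_id = rownames(P), theta = unname(theta), a = unname(a),
         b = unname(b), c = unname(cc), r = unname(as.integer(r)),
         n_bar = unname(n_bar), n_c = unname(n_c), p_bar = unname(p_bar),
         s2 = unname(s2), h_bar = unname(h_bar),
         undefined = unname(undefined))
}

#' Weir-Cockerham fixation index for one SNP
#'
#' Single-SNP convenience wrapper around the same variance-component
#' arithmetic as [fst_scan()]; errors on fewer than two populations with
#' data.
#'
#' @param freqs Long frequency tibble from [allele_frequencies()].
#' @param snp_id The SNP to score.
#' @return One-row tibble as in [fst_scan()].
#' @export
wc_fst <- function(freqs, snp_id) {
  f <- freqs[freqs$snp_id == snp_id & freqs$n > 0, , drop = FALSE]
  if (nrow(f) < 2) {
    abort(sprintf("SNP '%s': fewer than 2 populations with data", snp_id))
  }
  fst_scan(f, snp_ids = snp_id)
}
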