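#' Weighted correlation of allele frequency with absolute latitude
#'
#' For each SNP, the Pearson correlation between the per-population
#' ancestral-allele frequency \eqn{y_i = p_i} and the absolute latitude
#' \eqn{x_i = |lat_i|}, weighted by population sample size \eqn{w_i}:
#' \deqn{\mu_w(v) = \sum w_i v_i / \sum w_i, \qquad
#'       \mathrm{cov}_w(x,y) = \sum w_i (x_i-\mu_w(x))(y_i-\mu_w(y)) / \sum w_i}
#' \deqn{r_w = \mathrm{cov}_w(x,y) / \sqrt{\mathrm{cov}_w(x,x)\,
#'       \mathrm{cov}_w(y,y)}}
#' Weighting avoids over-weighting frequencies estimated in small
#' populations. The selection statistic is \eqn{|r_w|}, so allele
#' orientation and the hemisphere sign of latitude are immaterial. SNPs
#' with zero weighted variance in `x` or `y`, or with fewer than three
#' populations with data, are flagged undefined.
#'
#' @param freqs Long frequency tibble from [allele_frequencies()].
#' @param populations Population tibble (supplies latitude and size).
#' @param snp_ids SNPs to score; defaults to all SNPs in `freqs`.
#' @param weight_mode `"population"` (default): the fixed population sample
#'   size weights every SNP; `"per_snp"`: the per-SNP non-missing count `n`
#'   is used instead.
#' @return Tibble with one row per SNP: `snp_id`, `chrom_class`, `r_w`,
#'   `abs_r`, `n_pops_used`, `undefined`.
#' @export
cline_scan <- function(freqs, populations, snp_ids = NULL,
                       weight_mode = c("population", "per_snp")) {
  weight_mode <- match.arg(weight_mode)
  snp_ids <- snp_ids %||% unique(freqs$snp_id)
  f <- freqs |> filter(.data$snp_id %in% snp_ids)
  pops <- populations$pop_id
  P <- long_to_matrix(f, "p", snp_ids, pops)
  N <- long_to_matrix(f, "n", snp_ids, pops)
  obs <- !is.na(P)
  W <- if (weight_mode == "population") {
    matrix(populations$size, nrow(P), ncol(P), byrow = TRUE)
  } else {
    N
  }
  W[!obs] <- NA_real_
  x <- abs(populations$latitude)
  X <- matrix(x, nrow(P), ncol(P), byrow = TRUE)
  X[!obs] <- NA_real_
  sw <- rowSums(W, na.rm = TRUE)
  mx <- rowSums(W * X, na.rm = TRUE) / sw
  my <- rowSums(W * P, na.rm = TRUE) / sw
  cxx <- rowSums(W * (X - mx)^2, na.rm = TRUE) / sw
  cyy <- rowSums(W * (P - my)^2, na.rm = TRUE) / sw
  cxy <- rowSums(W * (X - mx) * (P - my), na.rm = TRUE) / sw
  # a variable constant over the observed populations has zero weighted
  # variance by definition; detect that exactly, not through rounding
  cxx[row_range_zero(X)] <- 0
  cyy[row_range_zero(P)] <- 0
  n_pops <- rowSums(obs)
  r_w <- ifelse(cxx > 0 & cyy > 0, cxy / sqrt(cxx * cyy), NA_real_)
  undefined <- n_pops < 3 | !is.finite(r_w)
  r_w[undefined] <- NA_real_
  class_map <- f |> distinct(.data$snp_id, .data$chrom_class)
  tibble(snp_id = snp_ids,
         chrom_class = class_map$chrom_class[match(snp_ids, class_map$snp_id)],
         r_w = unname(r_w), abs_r = unname(abs(r_w)),
         n_pops_used = unname(as.integer(n_pops)),
         undefined = unname(undefined))
}

row_range_zero <- function(m) {
  lo <- suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  hi <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  is.finite(lo) & is.finite(hi) & lo == hi
}

#' Weighted correlation for a single SNP
#'
#' As [cline_scan()] for one SNP, erroring on fewer than three populations
#' with data; additionally returns the weights used.
#'
#' @inheritParams cline_scan
#' @param snp_id The SNP to score.
#' @return One-row tibble as in [cline_scan()] plus a `weights` list-column
#'   (named per contributing population).
#' @export
weighted_abs_correlation <- function(freqs, populations, snp_id,
                                     weight_mode = c("population", "per_snp")) {
  weight_mode <- match.arg(weight_mode)
  f <- freqs[freqs$snp_id == snp_id & freqs$n > 0, , drop = FALSE]
  if (nrow(f) < 3) {
    abort(sprintf("SNP '%s': fewer than 3 populations with data", snp_id))
  }
  res <- cline_scan(f, populations, snp_ids = snp_id,
                    weight_mode = weight_mode)
  used <- populations$pop_id %in% f$pop_id
  w <- if (weight_mode == "population") {
    populations$size[used]
  } else {
    f$n[match(populations$pop_id[used], f$pop_id)]
  }
  res$weights <- list(setNames(as.numeric(w), populations$pop_id[used]))
  res
}
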