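#' Fisher's exact overlap test against a fixed gene universe
#'
#' Given an overlap of `k` genes between a list of size `n_list` and a
#' selected set of size `n_lrg` drawn from a universe of `N` symbols, builds
#' the 2x2 table `[[k, n_list-k], [n_lrg-k, N-n_list-n_lrg+k]]` and computes
#' the exact hypergeometric p-value. `sided = "two"` uses the
#' minimum-likelihood rule (sum of the probabilities of all fixed-margin
#' tables whose point probability does not exceed that of the observed
#' table); `sided = "greater"` is the upper tail (enrichment only). The
#' odds ratio is the sample cross-product ratio.
#'
#' @param k Overlap count.
#' @param n_list Size of the gene list.
#' @param n_lrg Size of the selected gene set.
#' @param N Universe size; default 21463 (distinct RefSeq gene symbols).
#' @param sided `"two"` (default) or `"greater"`.
#' @param label Optional list label carried into the output.
#' @return One-row tibble: `label`, `k`, `n_list`, `n_lrg`, `universe`,
#'   `list_only`, `lrg_only`, `neither`, `odds_ratio`, `p_value`, `sided`.
#' @export
fisher_overlap <- function(k, n_list, n_lrg, N = 21463,
                           sided = c("two", "greater"), label = NA_character_) {
  sided <- match.arg(sided)
  if (k < 0 || n_list < 0 || n_lrg < 0 || N < 1) {
    abort("counts must be non-negative and N >= 1")
  }
  if (k > min(n_list, n_lrg)) {
    abort(sprintf("inconsistent counts: k (%d) > min(n_list, n_lrg) (%d)",
                  k, min(n_list, n_lrg)))
  }
  if (n_list + n_lrg - k > N) {
    abort(sprintf("inconsistent counts: n_list + n_lrg - k (%d) > N (%d)",
                  n_list + n_lrg - k, N))
  }
  b <- n_list - k; c_ <- n_lrg - k; d <- N - n_list - n_lrg + k
  p <- hyper_overlap_p(k, n_list, n_lrg, N, sided)
  tibble(label = label, k = as.integer(k), n_list = as.integer(n_list),
         n_lrg = as.integer(n_lrg), universe = as.integer(N),
         list_only = as.integer(b), lrg_only = as.integer(c_),
         neither = as.integer(d),
         odds_ratio = (k * d) / (b * c_),
         p_value = p, sided = sided)
}

# Exact hypergeometric p at fixed margins. Support of k is
# max(0, n_list + n_lrg - N) .. min(n_list, n_lrg).
hyper_overlap_p <- function(k, n_list, n_lrg, N, sided) {
  if (sided == "greater") {
    return(phyper(k - 1, n_lrg, N - n_lrg, n_list, lower.tail = FALSE))
  }
  lo <- max(0, n_list + n_lrg - N)
  hi <- min(n_list, n_lrg)
  dens <- dhyper(lo:hi, n_lrg, N - n_lrg, n_list)
  obs <- dens[k - lo + 1]
  # relative tolerance guards against ties broken by rounding alone
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Bonferroni adjustment
#'
#' @param p_raw Raw p-value(s).
#' @param m Number of tests, at least 1.
#' @return `min(1, m * p_raw)`, vectorised over `p_raw`.
#' @export
bonferroni <- function(p_raw, m) {
  stopifnot(m >= 1)
  pmin(1, m * p_raw)
}

#' Overlap enrichment of several gene lists against a selected set
#'
#' Each list is first reconciled to the universe (symbols outside it are
#' dropped, with a message), then tested with [fisher_overlap()];
#' Bonferroni `m` defaults to the number of lists in the batch. Matching is
#' exact, case-sensitive string comparison.
#'
#' @param lrg Character vector of selected gene symbols.
#' @param gene_lists Named list of character vectors.
#' @param universe Character vector of universe symbols, or `NULL` to use a
#'   bare universe size `N`.
#' @param N Universe size when `universe` is `NULL`; default 21463.
#' @param sided Passed to [fisher_overlap()].
#' @param m Number of tests for Bonferroni; default `length(gene_lists)`.
#' @return Tibble with one row per list, sorted by raw p-value, with
#'   `n_input`, `n_used` (post-reconciliation size), the [fisher_overlap()]
#'   columns, `m_tests` and `p_adjusted`. Lists empty after reconciliation
#'   get an `NA` p-value and a warning.
#' @export
batch_enrichment <- function(lrg, gene_lists, universe = NULL, N = 21463,
                             sided = c("two", "greater"),
                             m = length(gene_lists)) {
  sided <- match.arg(sided)
  if (is.null(names(gene_lists)) || any(!nzchar(names(gene_lists)))) {
    abort("gene_lists must be a named list")
  }
  if (!is.null(universe)) {
    universe <- unique(universe)
    N <- length(universe)
    n_out <- sum(!(lrg %in% universe))
    if (n_out > 0) {
      inform(sprintf("%d selected gene(s) outside the universe dropped", n_out))
    }
    lrg <- intersect(lrg, universe)
  }
  lrg <- unique(lrg)
  rows <- purrr::imap(gene_lists, function(symbols, lab) {
    symbols <- unique(symbols)
    n_input <- length(symbols)
    if (!is.null(universe)) {
      dropped <- sum(!(symbols %in% universe))
      if (dropped > 0) {
        inform(sprintf("list '%s': %d symbol(s) outside the universe dropped",
                       lab, dropped))
      }
      symbols <- intersect(symbols, universe)
    }
    if (length(symbols) == 0) {
      warn(sprintf("list '%s' is empty after reconciliation: no test", lab))
      return(tibble(label = lab, n_input = n_input, n_used = 0L,
                    k = NA_integer_, n_list = 0L, n_lrg = length(lrg),
                    universe = as.integer(N), odds_ratio = NA_real_,
                    p_value = NA_real_, sided = sided))
    }
    res <- fisher_overlap(length(intersect(symbols, lrg)), length(symbols),
                          length(lrg), N, sided = sided, label = lab)
    res |> mutate(n_input = n_input, n_used = length(symbols)) |>
      select("label", "n_input", "n_used", "k", "n_list", "n_lrg",
             "universe", "odds_ratio", "p_value", "sided")
  })
  bind_rows(rows) |>
    mutate(m_tests = as.integer(m),
           p_adjusted = bonferroni(.data$p_value, m)) |>
    arrange(.data$p_value)
}

#' Venn decomposition of gene lists
#'
#' Sizes and members of every exclusive region of the Venn diagram of two
#' or more lists, plus each full pairwise/multi-way intersection.
#'
#' @param lists Named list of at least two character vectors.
#' @return Tibble with columns `region` (e.g. `"A&B"`), `exclusive_size`
#'   and `exclusive_symbols` (members in exactly those lists),
#'   `intersection_size` and `intersection_symbols` (members in at least
#'   those lists).
#' @export
multiway_overlap <- function(lists) {
  if (length(lists) < 2) abort("need at least 2 lists")
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    abort("lists must be named")
  }
  lists <- lapply(lists, unique)
  symbols <- unique(unlist(lists))
  member <- vapply(lists, function(l) symbols %in% l,
                   logical(length(symbols)))
  if (length(symbols) == 1) member <- matrix(member, nrow = 1)
  combos <- purrr::map(seq_along(lists), ~ utils::combn(names(lists), .x,
                                                        simplify = FALSE))
  combos <- purrr::flatten(combos)
  rows <- purrr::map(combos, function(cmb) {
    in_cmb <- rowSums(member[, cmb, drop = FALSE]) == length(cmb)
    excl <- in_cmb & rowSums(member[, setdiff(names(lists), cmb),
                                    drop = FALSE]) == 0
    tibble(region = paste(cmb, collapse = "&"),
           exclusive_size = sum(excl),
           exclusive_symbols = list(sort(symbols[excl])),
           intersection_size = sum(in_cmb),
           intersection_symbols = list(sort(symbols[in_cmb])))
  })
  bind_rows(rows)
}

#' Non-synonymous excess among selected SNPs
#'
#' Cross-tabulates selected vs non-selected SNPs against non-synonymous vs
#' other functional class, tests the table with [fisher_overlap()] and
#' reports the excess ratio: the non-synonymous fraction among selected
#' SNPs over that among the rest, minus 1. A positive excess among
#' high-differentiation SNPs is read as a signature of selection rather
#' than drift.
#'
#' @param selected_ids Selected SNP ids.
#' @param all_ids The full analysed SNP universe (selected included).
#' @param annotation Annotation tibble with `func_class` per SNP.
#' @param sided Passed to [fisher_overlap()].
#' @return One-row tibble: counts of the 2x2 table, `excess_ratio`,
#'   `odds_ratio`, `p_value`.
#' @export
nonsyn_enrichment <- function(selected_ids, all_ids, annotation,
                              sided = c("two", "greater")) {
  sided <- match.arg(sided)
  fc <- annotation$func_class[match(all_ids, annotation$snp_id)]
  if (anyNA(fc)) {
    abort(sprintf("SNP '%s' has no functional class",
                  all_ids[which(is.na(fc))[1]]))
  }
  is_sel <- all_ids %in% selected_ids
  is_ns <- fc == "nonsynonymous"
  sel_ns <- sum(is_sel & is_ns); sel_tot <- sum(is_sel)
  rest_ns <- sum(!is_sel & is_ns); rest_tot <- sum(!is_sel)
  if (sel_ns + rest_ns == 0) {
    warn("no non-synonymous SNPs at all: excess ratio undefined")
    ratio <- NA_real_
  } else {
    ratio <- (sel_ns / sel_tot) / (rest_ns / rest_tot) - 1
  }
  ft <- fisher_overlap(sel_ns, sel_tot, sel_ns + rest_ns,
                       length(all_ids), sided = sided)
  tibble(selected_nonsyn = sel_ns, selected_total = sel_tot,
         rest_nonsyn = rest_ns, rest_total = rest_tot,
         excess_ratio = ratio, odds_ratio = ft$odds_ratio,
         p_value = ft$p_value, sided = sided)
}

#' Gene-length bias check (Mann-Whitney)
#'
#' Longer genes harbour more genotyped SNPs, so a selected-gene set could
#' be biased toward long genes; this compares selected and remaining gene
#' lengths with the exact-U Mann-Whitney test. `U` counts, over all pairs,
#' how often a selected-gene length exceeds a remaining-gene length, with
#' 0.5 credit for ties. The two-sided p uses the exact null distribution
#' when the samples are tie-free and `n1 * n2 <= 10000`, and the normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param lrg_lengths Lengths of the selected genes (base pairs).
#' @param other_lengths Lengths of the remaining universe genes.
#' @return One-row tibble: `u`, `p_value`, `median_lrg`, `median_other`,
#'   `n_lrg`, `n_other`, `method`.
#' @export
gene_length_bias <- function(lrg_lengths, other_lengths) {
  if (length(lrg_lengths) == 0 || length(other_lengths) == 0) {
    abort("both samples must be non-empty")
  }
  n1 <- length(lrg_lengths); n2 <- length(other_lengths)
  rk <- rank(c(lrg_lengths, other_lengths))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 10000) {
    p <- if (u > n1 * n2 / 2) {
      pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      pwilcox(u, n1, n2)
    }
    p <- min(1, 2 * p)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) {
      p <- 1        # every observation tied: no evidence either way
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal_tie_corrected"
  }
  tibble(u = u, p_value = p,
         median_lrg = median(lrg_lengths),
         median_other = median(other_lengths),
         n_lrg = n1, n_other = n2, method = method)
}
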