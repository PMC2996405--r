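#' Per-population allele frequencies and heterozygosity
#'
#' For every SNP x population cell, counts the non-missing diploid
#' individuals `n`, the ancestral-allele frequency `p` and the observed
#' heterozygote proportion `h`. Populations with no called genotype for a
#' SNP are absent from the output for that SNP.
#'
#' @param genotypes A genotype tibble (see [read_genotypes()]).
#' @param populations A population tibble (see [read_populations()]).
#' @return Long tibble: `snp_id`, `chrom_class`, `pop_id`, `n`, `p`, `h`,
#'   one row per SNP x population with `n > 0`.
#' @export
allele_frequencies <- function(genotypes, populations) {
  m <- genotype_matrix(genotypes)
  present <- intersect(unlist(populations$members), colnames(m))
  missing_pop <- purrr::map_lgl(populations$members,
                                ~ !any(.x %in% colnames(m)))
  if (any(missing_pop)) {
    abort(sprintf("population '%s' has no member in the genotype matrix",
                  populations$pop_id[missing_pop][1]))
  }
  out <- purrr::map(seq_len(nrow(populations)), function(i) {
    cols <- intersect(populations$members[[i]], colnames(m))
    sub <- m[, cols, drop = FALSE]
    n <- rowSums(!is.na(sub))
    anc <- rowSums(sub, na.rm = TRUE)
    het <- rowSums(sub == 1L, na.rm = TRUE)
    tibble(snp_id = genotypes$snp_id,
           chrom_class = genotypes$chrom_class,
           pop_id = populations$pop_id[i],
           n = as.integer(n),
           p = ifelse(n > 0, anc / (2 * n), NA_real_),
           h = ifelse(n > 0, het / n, NA_real_))
  })
  bind_rows(out) |> filter(.data$n > 0)
}

#' Minor-allele-frequency filter
#'
#' With `mode = "all"` (default), a SNP is removed only when its minor
#' allele frequency is below `threshold` in every population where it is
#' observed; a single population clearing the threshold retains the SNP.
#' `mode = "any"` is the stricter alternative (removed if any population
#' fails). SNPs observed in no population are removed.
#'
#' @param freqs Long frequency tibble from [allele_frequencies()].
#' @param snp_ids SNP universe to filter; defaults to all SNPs in `freqs`.
#' @param threshold MAF threshold, in (0, 0.5); default 0.05.
#' @param mode `"all"` or `"any"`.
#' @return Tibble `snp_id`, `retained`, `reason` (`NA` when retained).
#' @export
maf_filter <- function(freqs, snp_ids = NULL, threshold = 0.05,
                       mode = c("all", "any")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 0.5)
  snp_ids <- snp_ids %||% unique(freqs$snp_id)
  per_snp <- freqs |>
    mutate(maf = pmin(.data$p, 1 - .data$p)) |>
    group_by(.data$snp_id) |>
    summarise(low_all = all(.data$maf < threshold),
              low_any = any(.data$maf < threshold), .groups = "drop")
  res <- tibble(snp_id = snp_ids) |>
    left_join(per_snp, by = "snp_id") |>
    mutate(
      reason = dplyr::case_when(
        is.na(.data$low_all) ~ "unobserved",
        mode == "all" & .data$low_all ~ "maf_below_threshold_all_pops",
        mode == "any" & .data$low_any ~ "maf_below_threshold_some_pop",
        TRUE ~ NA_character_),
      retained = is.na(.data$reason)) |>
    select("snp_id", "retained", "reason")
  n_unobs <- sum(res$reason == "unobserved", na.rm = TRUE)
  if (n_unobs > 0) {
    inform(sprintf("maf_filter: %d SNP(s) observed in no population, removed",
                   n_unobs))
  }
  res
}

#' Intragenic filter
#'
#' Keeps SNPs assigned to at least one gene and drops Y-class SNPs (too few
#' to analyse as a separate class).
#'
#' @param annotation Annotation tibble (see [snp_annotation()]).
#' @param snp_info Tibble with `snp_id` and `chrom_class` (e.g. the genotype
#'   tibble).
#' @return Tibble `snp_id`, `retained`, `reason` over the SNPs of
#'   `snp_info`; SNPs absent from the annotation count as gene-less.
#' @export
intragenic_filter <- function(annotation, snp_info) {
  ann <- tibble(snp_id = annotation$snp_id,
                n_genes = lengths(annotation$genes))
  snp_info |>
    select("snp_id", "chrom_class") |>
    left_join(ann, by = "snp_id") |>
    mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      reason = dplyr::case_when(
        .data$chrom_class == "Y" ~ "y_linked",
        .data$n_genes == 0 ~ "intergenic",
        TRUE ~ NA_character_),
      retained = is.na(.data$reason)) |>
    select("snp_id", "retained", "reason")
}

#' Assign SNPs to genes within a window
#'
#' A SNP at position `q` is assigned to a gene spanning `[start, end]`
#' (1-based, inclusive) iff `start - window <= q <= end + window`. Multiple
#' assignments are allowed. When both tables carry a `chrom` column,
#' assignment additionally requires matching `chrom`.
#'
#' @param snp_positions Tibble with `snp_id`, `position` (and optionally
#'   `chrom`).
#' @param gene_intervals Tibble with `gene`, `start`, `end` (and optionally
#'   `chrom`).
#' @param window Flanking window in base pairs; default 2000.
#' @return Tibble `snp_id`, `gene`, one row per assignment.
#' @export
map_snps_to_genes <- function(snp_positions, gene_intervals, window = 2000) {
  if (any(gene_intervals$end < gene_intervals$start)) {
    bad <- gene_intervals$gene[gene_intervals$end < gene_intervals$start][1]
    abort(sprintf("malformed interval for gene '%s': end < start", bad))
  }
  use_chrom <- "chrom" %in% names(snp_positions) &&
    "chrom" %in% names(gene_intervals)
  chrom_snp <- if (use_chrom) snp_positions$chrom else rep("", nrow(snp_positions))
  chrom_gene <- if (use_chrom) gene_intervals$chrom else rep("", nrow(gene_intervals))
  out <- purrr::map(unique(chrom_gene), function(ch) {
    gi <- gene_intervals[chrom_gene == ch, , drop = FALSE]
    sp <- snp_positions[chrom_snp == ch, , drop = FALSE]
    if (nrow(gi) == 0 || nrow(sp) == 0) return(NULL)
    lo <- gi$start - window
    hi <- gi$end + window
    hits <- purrr::map(seq_len(nrow(gi)), function(j) {
      idx <- which(sp$position >= lo[j] & sp$position <= hi[j])
      if (length(idx) == 0) return(NULL)
      tibble(snp_id = sp$snp_id[idx], gene = gi$gene[j])
    })
    bind_rows(hits)
  })
  bind_rows(out) |> arrange(.data$snp_id, .data$gene)
}

#' Fold a SNP-gene assignment into an annotation table
#'
#' @param snp_info Tibble with `snp_id` (defines the SNP universe and order).
#' @param assignments Tibble `snp_id`, `gene` from [map_snps_to_genes()].
#' @param func_class Functional class per SNP of `snp_info`; defaults to
#'   `"other"`.
#' @return Annotation tibble (see [snp_annotation()]).
#' @export
build_annotation <- function(snp_info, assignments,
                             func_class = rep("other", nrow(snp_info))) {
  by_snp <- split(assignments$gene, assignments$snp_id)
  genes <- lapply(snp_info$snp_id, function(s) {
    g <- by_snp[[s]]
    if (is.null(g)) character(0) else sort(unique(g))
  })
  snp_annotation(snp_info$snp_id, genes, func_class)
}
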