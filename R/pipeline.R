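#' Run the full latitude-adaptation scan
#'
#' Orchestrates the stages in analysis order: per-population allele
#' frequencies, MAF filter, intragenic/Y filter, Weir-Cockerham F_ST scan,
#' weighted frequency-latitude correlation scan, two-step top-decile
#' selection per chromosome class, collapse of selected SNPs to the
#' latitude-related gene (LRG) set, and (when `gene_lists` is supplied)
#' overlap enrichment with Bonferroni adjustment. Record counts at every
#' filter, thresholds, warnings and an input checksum are kept in the
#' returned object so a run is fully reproducible from its report.
#'
#' @param genotypes Genotype tibble ([read_genotypes()]).
#' @param populations Population tibble ([read_populations()]).
#' @param annotation Annotation tibble ([snp_annotation()]).
#' @param gene_lists Optional named list of gene symbol vectors to test for
#'   enrichment against the LRG set.
#' @param q Upper-tail fraction of the two-step selection; default 0.10.
#' @param maf_threshold,maf_mode Passed to [maf_filter()].
#' @param weight_mode Passed to [cline_scan()].
#' @param sided Passed to the enrichment tests.
#' @param universe,universe_size Enrichment universe: a symbol vector, or a
#'   bare size (default 21463 when neither is given).
#' @param alpha Significance threshold applied to ADJUSTED p-values when
#'   flagging enrichment rows (raw values are always reported alongside);
#'   default 0.001.
#' @return An object of class `lrg_scan`; see [tidy.lrg_scan()],
#'   [glance.lrg_scan()], [autoplot.lrg_scan()] and [write_run_report()].
#' @export
run_latitude_scan <- function(genotypes, populations, annotation,
                              gene_lists = NULL, q = 0.10,
                              maf_threshold = 0.05,
                              maf_mode = c("all", "any"),
                              weight_mode = c("population", "per_snp"),
                              sided = c("two", "greater"),
                              universe = NULL, universe_size = NULL,
                              alpha = 0.001) {
  maf_mode <- match.arg(maf_mode)
  weight_mode <- match.arg(weight_mode)
  sided <- match.arg(sided)
  warnings <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  counts <- list(snps_input = nrow(genotypes))
  freqs <- allele_frequencies(genotypes, populations)

  maf <- wh(maf_filter(freqs, snp_ids = genotypes$snp_id,
                       threshold = maf_threshold, mode = maf_mode))
  keep_maf <- maf$snp_id[maf$retained]
  counts$snps_after_maf <- length(keep_maf)

  intr <- intragenic_filter(annotation,
                            genotypes |> filter(.data$snp_id %in% keep_maf))
  keep <- intr$snp_id[intr$retained]
  counts$snps_after_intragenic <- length(keep)

  freqs_kept <- freqs |> filter(.data$snp_id %in% keep)
  fst <- fst_scan(freqs_kept, snp_ids = keep)
  cline <- cline_scan(freqs_kept, populations, snp_ids = keep,
                      weight_mode = weight_mode)
  counts$snps_fst_defined <- sum(!fst$undefined)
  counts$snps_corr_defined <- sum(!cline$undefined)

  selection <- wh(two_step_selection(fst, cline, q = q))
  counts$snps_selected <- nrow(selection$selected)
  lrg_genes <- collapse_to_genes(selection, annotation)
  counts$lrg_genes <- length(lrg_genes)

  enrichment <- NULL
  if (!is.null(gene_lists)) {
    if (is.null(universe) && is.null(universe_size)) universe_size <- 21463
    enrichment <- wh(batch_enrichment(
      lrg_genes, gene_lists, universe = universe,
      N = universe_size %||% length(unique(universe)), sided = sided))
    enrichment <- enrichment |>
      mutate(significant = !is.na(.data$p_adjusted) & .data$p_adjusted < alpha)
  }

  structure(list(
    freqs = freqs, fst = fst, cline = cline, selection = selection,
    lrg_genes = lrg_genes, enrichment = enrichment,
    counts = counts, warnings = warnings,
    params = list(q = q, maf_threshold = maf_threshold, maf_mode = maf_mode,
                  weight_mode = weight_mode, sided = sided, alpha = alpha,
                  universe_size = if (!is.null(universe))
                    length(unique(universe)) else universe_size),
    input_checksums = list(genotypes = rlang::hash(genotypes),
                           populations = rlang::hash(populations),
                           annotation = rlang::hash(annotation),
                           gene_lists = rlang::hash(gene_lists))),
    class = "lrg_scan")
}

#' @export
print.lrg_scan <- function(x, ...) {
  cat("Latitude-adaptation scan\n")
  cat(sprintf("  SNPs: %d input -> %d after MAF -> %d intragenic non-Y\n",
              x$counts$snps_input, x$counts$snps_after_maf,
              x$counts$snps_after_intragenic))
  print(x$selection$thresholds)
  cat(sprintf("  %d SNPs selected; %d latitude-related genes\n",
              x$counts$snps_selected, x$counts$lrg_genes))
  if (!is.null(x$enrichment)) {
    cat("Enrichment (raw and Bonferroni-adjusted p):\n")
    print(x$enrichment |>
            select("label", "k", "n_used", "odds_ratio", "p_value",
                   "p_adjusted", "significant"))
  }
  if (length(x$warnings) > 0) {
    cat(sprintf("%d warning(s) recorded\n", length(x$warnings)))
  }
  invisible(x)
}

#' Tidy per-SNP results of a scan
#'
#' @param x An `lrg_scan` object.
#' @param ... Unused.
#' @return Tibble with one row per analysed SNP: `snp_id`, `chrom_class`,
#'   `theta`, `abs_r`, `r_w`, `selected`.
#' @method tidy lrg_scan
#' @export
tidy.lrg_scan <- function(x, ...) {
  x$fst |>
    select("snp_id", "chrom_class", "theta") |>
    inner_join(x$cline |> select("snp_id", "r_w", "abs_r"), by = "snp_id") |>
    mutate(selected = .data$snp_id %in% x$selection$selected$snp_id)
}

#' One-row summary of a scan
#'
#' @param x An `lrg_scan` object.
#' @param ... Unused.
#' @return One-row tibble of stage counts and parameters.
#' @method glance lrg_scan
#' @export
glance.lrg_scan <- function(x, ...) {
  as_tibble(x$counts) |>
    mutate(q = x$params$q,
           n_warnings = length(x$warnings))
}

#' Write a machine-readable run report
#'
#' JSON report carrying the effective parameters, per-stage record counts,
#' class thresholds, the LRG gene list, the enrichment table, recorded
#' warnings and input checksums: the report fully determines re-execution.
#'
#' @param scan An `lrg_scan` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(scan, path) {
  report <- list(
    params = scan$params,
    counts = scan$counts,
    thresholds = scan$selection$thresholds,
    selected_snps = scan$selection$selected,
    lrg_genes = scan$lrg_genes,
    enrichment = scan$enrichment,
    warnings = scan$warnings,
    input_checksums = scan$input_checksums)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
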