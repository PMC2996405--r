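#' Plot a two-step selection
#'
#' Scatter of per-SNP F_ST against the absolute weighted correlation,
#' faceted by chromosome class, with the class thresholds drawn as dashed
#' lines; selected SNPs (strictly above both) are highlighted.
#'
#' @param object An `lrg_selection` from [two_step_selection()].
#' @param fst_table,cline_table The scan tables the selection was built
#'   from (for background points); defaults to the selected SNPs only.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lrg_selection
#' @export
autoplot.lrg_selection <- function(object, fst_table = NULL,
                                   cline_table = NULL, ...) {
  if (!is.null(fst_table) && !is.null(cline_table)) {
    d <- fst_table |>
      select("snp_id", "chrom_class", "theta") |>
      inner_join(cline_table |> select("snp_id", "abs_r"), by = "snp_id") |>
      mutate(selected = .data$snp_id %in% object$selected$snp_id)
  } else {
    d <- object$selected |> mutate(selected = TRUE)
  }
  d <- d |> filter(.data$chrom_class %in% object$thresholds$chrom_class,
                   is.finite(.data$theta), is.finite(.data$abs_r))
  ggplot2::ggplot(d, ggplot2::aes(.data$theta, .data$abs_r,
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(data = object$thresholds,
                        ggplot2::aes(xintercept = .data$fst_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = object$thresholds,
                        ggplot2::aes(yintercept = .data$corr_threshold),
                        linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom_class)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#D55E00")) +
    ggplot2::labs(x = expression(F[ST] ~ "(Weir-Cockerham)"),
                  y = "|weighted correlation with |latitude||",
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.lrg_selection
#' @method autoplot lrg_scan
#' @export
autoplot.lrg_scan <- function(object, ...) {
  autoplot.lrg_selection(object$selection, fst_table = object$fst,
                         cline_table = object$cline)
}

#' Plot one SNP's frequency-latitude cline
#'
#' Ancestral-allele frequency per population against absolute latitude,
#' point size proportional to the population sample size (the correlation
#' weight), with a weighted least-squares trend line.
#'
#' @param freqs Long frequency tibble from [allele_frequencies()].
#' @param populations Population tibble.
#' @param snp_id SNP to display.
#' @return A ggplot object.
#' @export
plot_cline <- function(freqs, populations, snp_id) {
  d <- freqs[freqs$snp_id == snp_id, , drop = FALSE] |>
    inner_join(populations |> select("pop_id", "latitude", "size"),
               by = "pop_id") |>
    mutate(abs_lat = abs(.data$latitude))
  if (nrow(d) == 0) abort(sprintf("no frequencies for SNP '%s'", snp_id))
  ggplot2::ggplot(d, ggplot2::aes(.data$abs_lat, .data$p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$size), alpha = 0.7) +
    ggplot2::geom_smooth(ggplot2::aes(weight = .data$size), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "#0072B2") +
    ggplot2::labs(title = snp_id, x = "|latitude| (degrees)",
                  y = "ancestral-allele frequency", size = "sample size") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' Bars of -log10 raw p per list, ordered by significance, with the
#' Bonferroni-adjusted significance calls as fill.
#'
#' @param enrichment Tibble from [batch_enrichment()] (with `p_adjusted`).
#' @param alpha Significance threshold on adjusted p; default 0.001.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.001) {
  d <- enrichment |>
    filter(!is.na(.data$p_value)) |>
    mutate(label = stats::reorder(.data$label, -.data$p_value),
           significant = .data$p_adjusted < alpha)
  ggplot2::ggplot(d, ggplot2::aes(.data$label, -log10(.data$p_value),
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#D55E00")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  fill = sprintf("adj. p < %g", alpha)) +
    ggplot2::theme_minimal()
}
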