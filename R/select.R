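#' Empirical upper-tail threshold
#'
#' Nearest-order-statistic empirical quantile: the threshold for upper-tail
#' fraction `q` over `N` finite values is the `ceiling((1-q) * N)`-th
#' smallest value. Selection downstream keeps values strictly greater than
#' the threshold, which makes tie behaviour deterministic.
#'
#' @param values Numeric vector; at least 2 finite values required (the
#'   class-level selection additionally requires 10, see
#'   [two_step_selection()]).
#' @param q Upper-tail fraction, in (0, 1); default 0.10.
#' @return The threshold value.
#' @export
top_decile_threshold <- function(values, q = 0.10) {
  stopifnot(q > 0, q < 1)
  v <- values[is.finite(values)]
  if (length(v) < 2) {
    abort(sprintf("need at least 2 finite values, got %d", length(v)))
  }
  if (length(unique(v)) == 1) {
    warn("all values identical: strict-greater selection will be empty")
  }
  sort(v)[ceiling((1 - q) * length(v))]
}

#' Two-step top-decile selection of latitude-related SNPs
#'
#' Per chromosome class (autosomes and X handled separately, their F_ST and
#' correlation distributions differ): step 1 keeps SNPs with F_ST strictly
#' greater than the class's upper-`q` empirical threshold; step 2 computes
#' the correlation threshold on the step-1 survivors of that class and
#' keeps survivors with `abs_r` strictly greater than it. The union over
#' classes is the selected SNP set. A class with fewer than 10 usable
#' values at either step is skipped with a warning.
#'
#' @param fst_table Output of [fst_scan()].
#' @param cline_table Output of [cline_scan()] over the same SNP universe.
#' @param q Upper-tail fraction for both steps; default 0.10.
#' @param classes Chromosome classes selected from; default
#'   `c("autosome", "X")`.
#' @return An object of class `lrg_selection`: list with `selected`
#'   (tibble `snp_id`, `chrom_class`, `theta`, `abs_r`), `thresholds`
#'   (tibble per class with both thresholds and stage counts) and `q`.
#'   [tidy()] returns the selected SNPs, [glance()] a one-row summary.
#' @export
two_step_selection <- function(fst_table, cline_table, q = 0.10,
                               classes = c("autosome", "X")) {
  if (!setequal(fst_table$snp_id, cline_table$snp_id)) {
    abort("fst_table and cline_table must cover the same SNP universe")
  }
  d <- fst_table |>
    select("snp_id", "chrom_class", "theta") |>
    inner_join(cline_table |> select("snp_id", "abs_r"), by = "snp_id")
  sel <- list(); thr <- list()
  for (cl in classes) {
    dc <- d |> filter(.data$chrom_class == cl)
    t1 <- dc$theta[is.finite(dc$theta)]
    if (length(t1) < 10) {
      warn(sprintf("class '%s': fewer than 10 SNPs with defined F_ST, skipped", cl))
      next
    }
    fst_thr <- top_decile_threshold(t1, q)
    s1 <- dc |> filter(is.finite(.data$theta), .data$theta > fst_thr)
    r1 <- s1$abs_r[is.finite(s1$abs_r)]
    if (nrow(s1) < 10 || length(r1) < 10) {
      warn(sprintf(
        "class '%s': fewer than 10 step-1 survivors with defined correlation, skipped",
        cl))
      thr[[cl]] <- tibble(chrom_class = cl, fst_threshold = fst_thr,
                          corr_threshold = NA_real_,
                          n_class = nrow(dc), n_step1 = nrow(s1),
                          n_selected = 0L)
      next
    }
    corr_thr <- top_decile_threshold(r1, q)
    s2 <- s1 |> filter(is.finite(.data$abs_r), .data$abs_r > corr_thr)
    sel[[cl]] <- s2
    thr[[cl]] <- tibble(chrom_class = cl, fst_threshold = fst_thr,
                        corr_threshold = corr_thr,
                        n_class = nrow(dc), n_step1 = nrow(s1),
                        n_selected = nrow(s2))
  }
  empty <- tibble(snp_id = character(), chrom_class = character(),
                  theta = double(), abs_r = double())
  structure(list(selected = bind_rows(c(list(empty), sel)),
                 thresholds = bind_rows(thr),
                 q = q),
            class = "lrg_selection")
}

#' @export
print.lrg_selection <- function(x, ...) {
  cat(sprintf("Two-step top-%d%% selection\n", round(100 * x$q)))
  print(x$thresholds)
  cat(sprintf("%d SNPs selected in total\n", nrow(x$selected)))
  invisible(x)
}

#' @rdname two_step_selection
#' @param x An `lrg_selection` object.
#' @param ... Unused.
#' @method tidy lrg_selection
#' @export
tidy.lrg_selection <- function(x, ...) {
  x$selected
}

#' @rdname two_step_selection
#' @method glance lrg_selection
#' @export
glance.lrg_selection <- function(x, ...) {
  tibble(q = x$q,
         n_classes = nrow(x$thresholds),
         n_selected = nrow(x$selected))
}

#' Collapse selected SNPs to their gene set
#'
#' Union of gene assignments over the selected SNPs, de-duplicated; genes
#' reachable from several SNPs or from both chromosome classes are counted
#' once.
#'
#' @param selection An `lrg_selection` object, or a tibble/character vector
#'   of selected SNP ids.
#' @param annotation Annotation tibble covering all selected SNPs.
#' @return Sorted character vector of unique gene symbols.
#' @export
collapse_to_genes <- function(selection, annotation) {
  ids <- if (inherits(selection, "lrg_selection")) {
    selection$selected$snp_id
  } else if (is.data.frame(selection)) {
    selection$snp_id
  } else {
    as.character(selection)
  }
  if (length(ids) == 0) return(character(0))
  idx <- match(ids, annotation$snp_id)
  if (anyNA(idx)) {
    abort(sprintf("selected SNP '%s' absent from the annotation",
                  ids[which(is.na(idx))[1]]))
  }
  genes <- annotation$genes[idx]
  empty <- lengths(genes) == 0
  if (any(empty)) {
    abort(sprintf(
      "selected SNP '%s' has no gene assignment (was the intragenic filter applied?)",
      ids[empty][1]))
  }
  sort(unique(unlist(genes)))
}
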