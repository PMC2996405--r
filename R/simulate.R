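#' Configuration for the synthetic panel generator
#'
#' Defaults emulate a worldwide diversity panel: 51 populations with
#' heterogeneous sample sizes (log-normal around 16 diploid individuals,
#' clamped to 5-50), latitudes uniform over -35 to 65 degrees, mostly
#' drift-structured SNPs (Balding-Nichols differentiation `f_drift`) plus a
#' minority with latitude-clinal frequencies, autosome/X/Y labels, a tiled
#' gene map and controllable missingness.
#'
#' @param n_pops Number of populations.
#' @param latitude_range Signed degrees; latitudes drawn uniformly.
#' @param size_meanlog,size_sdlog,size_range Log-normal parameters and
#'   clamp for per-population diploid sample sizes.
#' @param n_snps Total SNP count.
#' @param fraction_x,fraction_y Expected fraction of SNPs labelled X / Y.
#' @param f_drift Balding-Nichols differentiation parameter for neutral
#'   SNPs, in (0, 1).
#' @param n_clinal Number of planted clinal SNPs (placed on non-Y SNPs).
#' @param n_clinal_genes Size of the clinal target-gene pool: planted SNPs
#'   are positioned inside genes drawn from this pool, so selection signals
#'   cluster at loci instead of scattering uniformly.
#' @param beta Cline slope in frequency units per degree of absolute
#'   latitude, realised at the cline midpoint; the cline itself is logistic
#'   in `|latitude|` so frequencies stay inside (0, 1). Sign per SNP is
#'   random (clines run in either direction).
#' @param alpha Clinal ancestral-allele frequency at the equator.
#' @param clinal_noise_factor Residual Balding-Nichols noise of clinal SNPs
#'   as a fraction of `f_drift`; default 1/5.
#' @param n_genes,gene_span Gene count and mean span (bp) of the tiled map.
#' @param intragenic_target Fraction of coordinate space covered by genes
#'   plus their `window` flanks (controls the intragenic SNP fraction).
#' @param window SNP-to-gene assignment window in bp.
#' @param prop_nonsyn,prop_syn Marginal probabilities of the non-synonymous
#'   and synonymous functional classes.
#' @param nonsyn_clinal_boost Multiplier on the non-synonymous probability
#'   for clinal SNPs (1 = no preference).
#' @param missing_rate Per-genotype missingness probability.
#' @param seed Integer seed; fixes the whole panel byte-for-byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 51,
                       latitude_range = c(-35, 65),
                       size_meanlog = log(16), size_sdlog = 0.45,
                       size_range = c(5, 50),
                       n_snps = 5000,
                       fraction_x = 0.03, fraction_y = 0.01,
                       f_drift = 0.10,
                       n_clinal = round(0.05 * n_snps),
                       n_clinal_genes = 50,
                       beta = 0.008, alpha = 0.5,
                       clinal_noise_factor = 0.2,
                       n_genes = 600, gene_span = 15000,
                       intragenic_target = 0.35, window = 2000,
                       prop_nonsyn = 0.03, prop_syn = 0.05,
                       nonsyn_clinal_boost = 1,
                       missing_rate = 0.005,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$f_drift > 0, cfg$f_drift < 1,
            cfg$fraction_x >= 0, cfg$fraction_y >= 0,
            cfg$fraction_x + cfg$fraction_y < 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$intragenic_target > 0, cfg$intragenic_target < 1,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            cfg$n_pops >= 3, cfg$n_snps >= 1, cfg$n_clinal_genes >= 1)
  if (cfg$n_clinal > cfg$n_snps) {
    abort("infeasible config: more clinal SNPs than SNPs")
  }
  structure(cfg, class = "sim_config")
}

# Balding-Nichols draw: per-population frequency around mean `pm` with
# differentiation F, i.e. Beta(pm * (1-F)/F, (1-pm) * (1-F)/F).
rbn <- function(n, pm, f) {
  th <- (1 - f) / f
  rbeta(n, pmax(pm * th, 1e-8), pmax((1 - pm) * th, 1e-8))
}

#' Simulate a multi-population SNP panel with planted latitudinal clines
#'
#' Neutral SNPs: a global ancestral frequency is drawn uniform(0.05, 0.95)
#' and per-population frequencies follow the Balding-Nichols model at
#' `f_drift`. Clinal SNPs: the per-population expected frequency is
#' logistic in absolute latitude, with residual Balding-Nichols noise at
#' `clinal_noise_factor * f_drift`; the logit-scale slope is
#' `beta / (alpha * (1 - alpha))`, so the frequency-scale slope at the
#' midpoint equals `beta` per degree. Genotypes are Binomial(2, p_i)
#' (Hardy-Weinberg within population). Genes are tiled over a per-class
#' linear coordinate so that the intragenic SNP fraction is controllable,
#' and truth labels record which SNPs and genes carry a planted cline.
#'
#' @param cfg A [sim_config()].
#' @return A `lat_panel` list: `genotypes`, `populations`, `annotation`,
#'   `gene_intervals` (tibble `gene`, `chrom`, `start`, `end`), `truth`
#'   (tibble `snp_id`, `clinal`, `direction`), `clinal_genes`, `config`.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  pops <- population_table(
    pop_id = sprintf("POP%02d", seq_len(cfg$n_pops)),
    latitude = runif(cfg$n_pops, cfg$latitude_range[1], cfg$latitude_range[2]),
    members = local({
      sizes <- pmin(pmax(round(rlnorm(cfg$n_pops, cfg$size_meanlog,
                                      cfg$size_sdlog)),
                         cfg$size_range[1]), cfg$size_range[2])
      ends <- cumsum(sizes)
      purrr::map2(ends - sizes + 1, ends,
                  ~ sprintf("IND%05d", seq(.x, .y)))
    }))

  snp_id <- sprintf("snp%06d", seq_len(cfg$n_snps))
  chrom_class <- sample(c("autosome", "X", "Y"), cfg$n_snps, replace = TRUE,
                        prob = c(1 - cfg$fraction_x - cfg$fraction_y,
                                 cfg$fraction_x, cfg$fraction_y))
  clinal <- rep(FALSE, cfg$n_snps)
  non_y <- which(chrom_class != "Y")
  if (cfg$n_clinal > length(non_y)) {
    abort("infeasible config: more clinal SNPs than non-Y SNPs")
  }
  clinal[sample(non_y, cfg$n_clinal)] <- TRUE
  direction <- ifelse(clinal, sample(c(-1, 1), cfg$n_snps, replace = TRUE), 0)

  # per-class gene map and SNP placement on a linear coordinate
  gene_intervals <- list(); position <- integer(cfg$n_snps)
  for (cl in unique(chrom_class)) {
    idx <- which(chrom_class == cl)
    n_g <- max(1L, round(cfg$n_genes * length(idx) / cfg$n_snps))
    spans <- pmax(round(stats::rexp(n_g, 1 / cfg$gene_span)), 2000L)
    genome_len <- ceiling(sum(spans + 2 * cfg$window) / cfg$intragenic_target)
    starts <- sort(round(runif(n_g, 1, genome_len - max(spans))))
    gene_intervals[[cl]] <- tibble(
      gene = sprintf("G_%s_%04d", substr(cl, 1, 1), seq_len(n_g)),
      chrom = cl, start = as.integer(starts),
      end = as.integer(starts + spans - 1L))
    position[idx] <- as.integer(round(runif(length(idx), 1, genome_len)))
  }
  gene_intervals <- bind_rows(gene_intervals)

  # planted SNPs are re-placed inside genes from a limited target pool, so
  # the latitude signal concentrates at loci (as selection does) rather
  # than scattering over the whole map
  if (cfg$n_clinal > 0) {
    pool_genes <- gene_intervals |> filter(.data$chrom != "Y")
    n_pool <- min(cfg$n_clinal_genes, nrow(pool_genes))
    pool <- pool_genes[sample(nrow(pool_genes), n_pool), , drop = FALSE]
    which_clinal <- which(clinal)
    tgt <- sample(nrow(pool), length(which_clinal), replace = TRUE)
    chrom_class[which_clinal] <- pool$chrom[tgt]
    position[which_clinal] <- as.integer(round(
      runif(length(which_clinal), pool$start[tgt], pool$end[tgt])))
  }

  # per-population frequencies
  abs_lat <- abs(pops$latitude)
  P <- matrix(NA_real_, cfg$n_snps, cfg$n_pops)
  p0 <- runif(cfg$n_snps, 0.05, 0.95)
  slope <- cfg$beta / (cfg$alpha * (1 - cfg$alpha))
  f_cl <- cfg$clinal_noise_factor * cfg$f_drift
  for (i in seq_len(cfg$n_pops)) {
    pm <- ifelse(clinal,
                 stats::plogis(stats::qlogis(cfg$alpha) +
                                 direction * slope * abs_lat[i]),
                 p0)
    f <- ifelse(clinal, f_cl, cfg$f_drift)
    P[, i] <- rbn(cfg$n_snps, pm, f)
  }

  # genotypes: Binomial(2, p_i) per individual, with missingness
  dos <- matrix(NA_integer_, cfg$n_snps, sum(pops$size))
  colnames(dos) <- unlist(pops$members)
  for (i in seq_len(cfg$n_pops)) {
    cols <- pops$members[[i]]
    g <- rbinom(cfg$n_snps * length(cols), 2L, rep(P[, i], length(cols)))
    dos[, cols] <- matrix(as.integer(g), cfg$n_snps, length(cols))
  }
  if (cfg$missing_rate > 0) {
    dos[runif(length(dos)) < cfg$missing_rate] <- NA_integer_
  }

  genotypes <- bind_cols(
    tibble(snp_id = snp_id, chrom_class = chrom_class,
           position = position,
           ancestral_allele = sample(c("A", "C", "G", "T"), cfg$n_snps,
                                     replace = TRUE)),
    as_tibble(dos))

  assignments <- map_snps_to_genes(
    tibble(snp_id = snp_id, position = position, chrom = chrom_class),
    gene_intervals, window = cfg$window)
  p_ns <- pmin(1, cfg$prop_nonsyn *
                 ifelse(clinal, cfg$nonsyn_clinal_boost, 1))
  u <- runif(cfg$n_snps)
  func_class <- ifelse(u < p_ns, "nonsynonymous",
                       ifelse(u < p_ns + cfg$prop_syn, "synonymous", "other"))
  annotation <- build_annotation(genotypes, assignments, func_class)

  truth <- tibble(snp_id = snp_id, clinal = clinal, direction = direction)
  clinal_genes <- sort(unique(assignments$gene[
    assignments$snp_id %in% snp_id[clinal]]))

  structure(list(genotypes = genotypes, populations = pops,
                 annotation = annotation, gene_intervals = gene_intervals,
                 truth = truth, clinal_genes = clinal_genes, config = cfg),
            class = "lat_panel")
}

#' @export
print.lat_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic SNP panel: %d SNPs x %d individuals in %d populations\n",
    nrow(x$genotypes), sum(x$populations$size), nrow(x$populations)))
  cat(sprintf("  %d planted clinal SNPs over %d genes (%d clinal genes)\n",
              sum(x$truth$clinal), nrow(x$gene_intervals),
              length(x$clinal_genes)))
  invisible(x)
}

#' Gene universe of a synthetic panel
#'
#' @param panel A `lat_panel`.
#' @return Character vector of all gene symbols in the panel's gene map.
#' @export
panel_universe <- function(panel) {
  sort(unique(panel$gene_intervals$gene))
}

#' Plant gene lists with a controlled overlap with clinal genes
#'
#' Each list draws `round(size * overlap)` symbols from the panel's clinal
#' genes and the remainder uniformly from the rest of the gene universe.
#' `overlap = 0` produces pure-null lists statistically independent of any
#' latitude-related gene set.
#'
#' @param panel A `lat_panel` from [simulate_panel()].
#' @param n_lists Number of lists to draw.
#' @param size List size (recycled over lists).
#' @param overlap Fraction drawn from clinal genes (recycled).
#' @param labels Optional list names; default `list1`, `list2`, ...
#' @return Named list of character vectors.
#' @export
plant_gene_lists <- function(panel, n_lists = 1, size = 100, overlap = 0,
                             labels = NULL) {
  universe <- panel_universe(panel)
  clinal <- panel$clinal_genes
  size <- rep_len(size, n_lists)
  overlap <- rep_len(overlap, n_lists)
  labels <- labels %||% sprintf("list%d", seq_len(n_lists))
  out <- purrr::map(seq_len(n_lists), function(i) {
    n_cl <- round(size[i] * overlap[i])
    if (n_cl > length(clinal)) {
      abort(sprintf(
        "requested overlap (%d genes) exceeds available clinal genes (%d)",
        n_cl, length(clinal)))
    }
    planted <- if (n_cl > 0) sample(clinal, n_cl) else character(0)
    rest <- sample(setdiff(universe, planted), size[i] - n_cl)
    sort(c(planted, rest))
  })
  setNames(out, labels)
}

#' Write a synthetic panel to a directory
#'
#' Emits the full fixture set as plain text: genotypes TSV, populations
#' TSV, annotation TSV, gene intervals TSV, truth table TSV and a YAML echo
#' of the generator configuration. Everything re-reads losslessly through
#' the package's readers.
#'
#' @param panel A `lat_panel`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(panel$genotypes, file.path(dir, "genotypes.tsv"))
  write_populations(panel$populations, file.path(dir, "populations.tsv"))
  write_annotation(panel$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(panel$gene_intervals, file.path(dir, "gene_intervals.tsv"),
                   progress = FALSE)
  readr::write_tsv(panel$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  yaml::write_yaml(unclass(panel$config), file.path(dir, "config.yml"))
  invisible(dir)
}
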