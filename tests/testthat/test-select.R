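test_that("nearest-order-statistic threshold with strict-greater selection", {
  expect_equal(top_decile_threshold(1:10, q = 0.10), 9)
  expect_equal((1:10)[1:10 > top_decile_threshold(1:10, 0.10)], 10)
  expect_equal(top_decile_threshold(c(1, 2, 3, 4), q = 0.5), 2)
  expect_equal(c(1, 2, 3, 4)[c(1, 2, 3, 4) > 2], c(3, 4))
  expect_error(top_decile_threshold(c(NA_real_, 3)), "at least 2")
  expect_warning(top_decile_threshold(rep(2, 15)), "identical")
})

test_that("tie-straddling thresholds match brute-force rule application", {
  set.seed(60)
  for (i in 1:20) {
    vals <- sample(round(runif(40, 0, 5), 1))  # heavy ties
    q <- sample(c(0.1, 0.25, 0.5), 1)
    thr <- top_decile_threshold(vals, q)
    expect_equal(thr, sort(vals)[ceiling((1 - q) * length(vals))])
    expect_setequal(which(vals > thr),
                    which(vals > sort(vals)[ceiling((1 - q) * length(vals))]))
  }
})

make_score_tables <- function(n_auto = 1000, n_x = 100, seed = 1) {
  set.seed(seed)
  n <- n_auto + n_x
  tibble::tibble(
    snp_id = sprintf("s%04d", 1:n),
    chrom_class = rep(c("autosome", "X"), c(n_auto, n_x)),
    theta = stats::rbeta(n, 2, 15),
    abs_r = abs(stats::rnorm(n, 0, 0.25)),
    undefined = FALSE)
}

test_that("two-step selection equals the brute-force double filter per class", {
  d <- make_score_tables()
  fst <- d |> dplyr::select(snp_id, chrom_class, theta, undefined)
  cl <- d |> dplyr::select(snp_id, chrom_class, abs_r, undefined)
  sel <- two_step_selection(fst, cl, q = 0.10)
  for (cls in c("autosome", "X")) {
    dc <- d[d$chrom_class == cls, ]
    thr1 <- sort(dc$theta)[ceiling(0.9 * nrow(dc))]
    s1 <- dc[dc$theta > thr1, ]
    thr2 <- sort(s1$abs_r)[ceiling(0.9 * nrow(s1))]
    s2 <- s1[s1$abs_r > thr2, ]
    got <- sel$selected[sel$selected$chrom_class == cls, ]
    expect_setequal(got$snp_id, s2$snp_id)
    th <- sel$thresholds[sel$thresholds$chrom_class == cls, ]
    expect_equal(th$fst_threshold, thr1)
    expect_equal(th$corr_threshold, thr2)
    # counts near q^2 * N, up to ties at the thresholds
    expect_lte(abs(nrow(s1) - ceiling(0.1 * nrow(dc))), 1 +
                 sum(dc$theta == thr1))
    expect_lte(abs(nrow(s2) - ceiling(0.1 * nrow(s1))), 1 +
                 sum(s1$abs_r == thr2))
  }
  expect_equal(glance(sel)$n_selected, nrow(tidy(sel)))
})

test_that("decreasing q never adds SNPs to the selection", {
  d <- make_score_tables(seed = 9)
  fst <- d |> dplyr::select(snp_id, chrom_class, theta, undefined)
  cl <- d |> dplyr::select(snp_id, chrom_class, abs_r, undefined)
  prev <- two_step_selection(fst, cl, q = 0.20)$selected$snp_id
  for (q in c(0.15, 0.10, 0.05)) {
    cur <- suppressWarnings(two_step_selection(fst, cl, q = q))$selected$snp_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("small or all-undefined classes are skipped with a warning", {
  d <- make_score_tables(n_auto = 200, n_x = 5, seed = 3)
  fst <- d |> dplyr::select(snp_id, chrom_class, theta, undefined)
  cl <- d |> dplyr::select(snp_id, chrom_class, abs_r, undefined)
  expect_warning(sel <- two_step_selection(fst, cl), "skipped")
  expect_false("X" %in% sel$selected$chrom_class)

  d2 <- make_score_tables(n_auto = 200, n_x = 100, seed = 3)
  cl2 <- d2 |> dplyr::select(snp_id, chrom_class, abs_r) |>
    dplyr::mutate(abs_r = ifelse(chrom_class == "X", NA_real_, abs_r),
                  undefined = chrom_class == "X")
  fst2 <- d2 |> dplyr::select(snp_id, chrom_class, theta, undefined)
  expect_warning(sel2 <- two_step_selection(fst2, cl2), "skipped")
  expect_false("X" %in% sel2$selected$chrom_class)
  expect_equal(sel2$thresholds$n_selected[sel2$thresholds$chrom_class == "X"], 0L)
})

test_that("selection requires both tables to cover the same SNPs", {
  d <- make_score_tables(n_auto = 50, n_x = 0)
  fst <- d |> dplyr::select(snp_id, chrom_class, theta, undefined)
  cl <- d[-1, ] |> dplyr::select(snp_id, chrom_class, abs_r, undefined)
  expect_error(two_step_selection(fst, cl), "same SNP universe")
})

test_that("collapse_to_genes unions and de-duplicates gene assignments", {
  ann <- snp_annotation(c("s1", "s2", "s3", "s4"),
                        list("A", c("A", "B"), "C", character(0)),
                        rep("other", 4))
  expect_equal(collapse_to_genes(c("s1", "s2", "s3"), ann), c("A", "B", "C"))
  expect_equal(collapse_to_genes(character(0), ann), character(0))
  expect_error(collapse_to_genes("s4", ann), "no gene assignment")
  expect_error(collapse_to_genes("missing", ann), "absent from the annotation")
  # random fixture vs brute-force union
  set.seed(21)
  ids <- sample(c("s1", "s2", "s3"), 2)
  expect_setequal(collapse_to_genes(ids, ann),
                  unique(unlist(ann$genes[match(ids, ann$snp_id)])))
})

test_that("selection enriches for planted clinal SNPs", {
  panel <- simulate_panel(sim_config(n_pops = 25, n_snps = 2000,
                                     f_drift = 0.05, n_clinal = 200,
                                     missing_rate = 0, seed = 42))
  f <- allele_frequencies(panel$genotypes, panel$populations)
  fst <- fst_scan(f)
  cl <- cline_scan(f, panel$populations)
  sel <- suppressWarnings(two_step_selection(fst, cl))
  frac_selected <- mean(sel$selected$snp_id %in%
                          panel$truth$snp_id[panel$truth$clinal])
  frac_overall <- mean(panel$truth$clinal)
  expect_gt(frac_selected / frac_overall, 5)
})

test_that("pure-drift panels show no enrichment for random gene lists", {
  panel <- simulate_panel(sim_config(n_pops = 20, n_snps = 1500,
                                     n_clinal = 0, n_genes = 400,
                                     intragenic_target = 0.6,
                                     missing_rate = 0, seed = 77))
  scan <- suppressWarnings(run_latitude_scan(
    panel$genotypes, panel$populations, panel$annotation))
  universe <- panel_universe(panel)
  set.seed(78)
  lists <- purrr::map(1:100, ~ sample(universe, 150))
  names(lists) <- sprintf("null%03d", 1:100)
  enr <- suppressWarnings(batch_enrichment(scan$lrg_genes, lists,
                                           N = length(universe)))
  expect_gt(median(enr$p_value), 0.2)
  expect_lt(median(enr$p_value), 0.9)
})
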