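test_that("overlap p equals exhaustive fixed-margin enumeration (small universes)", {
  set.seed(91)
  for (i in 1:60) {
    N <- sample(5:60, 1)
    n_list <- sample.int(N, 1)
    n_lrg <- sample.int(N, 1)
    support <- max(0, n_list + n_lrg - N):min(n_list, n_lrg)
    k <- support[sample.int(length(support), 1)]
    got <- fisher_overlap(k, n_list, n_lrg, N)
    expect_equal(got$p_value,
                 oracle_fisher_two_sided(k, n_list, n_lrg, N),
                 tolerance = 1e-10)
    # independent library cross-check of the minimum-likelihood rule
    tab <- matrix(c(k, n_list - k, n_lrg - k, N - n_list - n_lrg + k), 2)
    expect_equal(got$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("overlap p is invariant to swapping the two lists", {
  set.seed(17)
  for (i in 1:20) {
    N <- sample(20:200, 1)
    n_list <- sample.int(N, 1); n_lrg <- sample.int(N, 1)
    support <- max(0, n_list + n_lrg - N):min(n_list, n_lrg)
    k <- support[sample.int(length(support), 1)]
    expect_equal(fisher_overlap(k, n_list, n_lrg, N)$p_value,
                 fisher_overlap(k, n_lrg, n_list, N)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("a table at the hypergeometric mode has two-sided p = 1", {
  N <- 100; n_list <- 20; n_lrg <- 30
  mode_k <- which.max(dhyper(0:20, n_lrg, N - n_lrg, n_list)) - 1
  expect_equal(fisher_overlap(mode_k, n_list, n_lrg, N)$p_value, 1)
})

test_that("inconsistent overlap counts are rejected with the violated bound", {
  expect_error(fisher_overlap(10, 5, 20, 100), "k \\(10\\) > min")
  expect_error(fisher_overlap(0, 80, 80, 100), "> N")
})

test_that("Bonferroni multiplies, never decreases, and caps at 1", {
  expect_equal(bonferroni(0.075, 4), 0.3)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_error(bonferroni(0.1, 0))
  p <- runif(20)
  expect_true(all(bonferroni(p, 3) >= p))
  expect_true(all(bonferroni(p, 3) <= 1))
})

test_that("batch enrichment reconciles to the universe and adjusts once per batch", {
  universe <- sprintf("G%03d", 1:200)
  lrg <- universe[1:40]
  lists <- list(hit = c(universe[1:20], "NOT_IN_UNIVERSE"),
                null = universe[101:140],
                gone = c("X1", "X2"))
  suppressMessages(suppressWarnings(
    enr <- batch_enrichment(lrg, lists, universe = universe)))
  expect_equal(nrow(enr), 3)
  expect_equal(enr$m_tests, rep(3L, 3))
  expect_equal(enr$n_used[enr$label == "hit"], 20L)  # outside symbol dropped
  expect_true(is.na(enr$p_value[enr$label == "gone"]))
  expect_equal(enr$p_adjusted, pmin(1, 3 * enr$p_value))
  expect_equal(enr$p_value, sort(enr$p_value, na.last = TRUE))
  # a list identical to the selected set is the extreme overlap
  self <- suppressMessages(batch_enrichment(lrg, list(self = lrg),
                                            universe = universe))
  expect_equal(self$k, 40L)
  expect_lt(self$p_value, 1e-20)
})

test_that("Venn decomposition matches brute-force set algebra", {
  lists <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  ov <- multiway_overlap(lists)
  expect_equal(ov$intersection_symbols[[which(ov$region == "A&B&C")]], "c")
  expect_equal(ov$exclusive_symbols[[which(ov$region == "A&B")]], "b")
  expect_equal(ov$exclusive_size[[which(ov$region == "A")]], 1)

  disjoint <- multiway_overlap(list(A = c("a", "b"), B = c("c"), C = c("d")))
  expect_true(all(disjoint$intersection_size[grepl("&", disjoint$region)] == 0))

  set.seed(55)
  pool <- sprintf("g%02d", 1:40)
  rl <- purrr::map(1:3, ~ sample(pool, 15)); names(rl) <- c("A", "B", "C")
  ov2 <- multiway_overlap(rl)
  expect_equal(ov2$intersection_size[ov2$region == "A&B"],
               length(intersect(rl$A, rl$B)))
  expect_equal(ov2$intersection_size[ov2$region == "A&B&C"],
               length(Reduce(intersect, rl)))
  expect_equal(sum(ov2$exclusive_size), length(unique(unlist(rl))))
})

test_that("non-synonymous excess ratio and p behave on constructed tables", {
  # equal fractions: ratio 0, modal table -> p = 1
  ann_eq <- snp_annotation(sprintf("s%03d", 1:110),
                           list_of_empty <- replicate(110, "G", simplify = FALSE),
                           c(rep("nonsynonymous", 1), rep("other", 9),
                             rep("nonsynonymous", 10), rep("other", 90)))
  res_eq <- nonsyn_enrichment(sprintf("s%03d", 1:10), sprintf("s%03d", 1:110),
                              ann_eq)
  expect_equal(res_eq$excess_ratio, 0)
  expect_equal(res_eq$p_value, 1)

  # constructed 30% excess: 130/1000 selected vs 1000/10000 rest
  ids <- sprintf("t%05d", 1:11000)
  fc <- c(rep("nonsynonymous", 130), rep("other", 870),
          rep("nonsynonymous", 1000), rep("other", 9000))
  ann <- snp_annotation(ids, replicate(11000, "G", simplify = FALSE), fc)
  res <- nonsyn_enrichment(ids[1:1000], ids, ann)
  expect_equal(res$excess_ratio, 0.3, tolerance = 1e-12)
  expect_equal(res$p_value,
               oracle_fisher_two_sided(130, 1000, 1130, 11000),
               tolerance = 1e-9)
  expect_warning(
    nonsyn_enrichment("s1", c("s1", "s2"),
                      snp_annotation(c("s1", "s2"), list("G", "G"),
                                     c("other", "other"))),
    "undefined")
})

test_that("clinal SNPs planted as preferentially non-synonymous are detected", {
  panel <- simulate_panel(sim_config(n_pops = 25, n_snps = 2000,
                                     f_drift = 0.05, n_clinal = 200,
                                     prop_nonsyn = 0.05,
                                     nonsyn_clinal_boost = 8,
                                     missing_rate = 0, seed = 13))
  f <- allele_frequencies(panel$genotypes, panel$populations)
  sel <- suppressWarnings(
    two_step_selection(fst_scan(f), cline_scan(f, panel$populations)))
  res <- nonsyn_enrichment(sel$selected$snp_id, panel$genotypes$snp_id,
                           panel$annotation)
  expect_gt(res$excess_ratio, 0)
  expect_lt(res$p_value, 0.05)
})

test_that("Mann-Whitney U equals the all-pairs brute force", {
  set.seed(2)
  for (i in 1:15) {
    x <- sample(0:30, sample(3:20, 1), replace = TRUE)  # ties likely
    y <- sample(0:30, sample(3:20, 1), replace = TRUE)
    expect_equal(gene_length_bias(x, y)$u, oracle_u_statistic(x, y))
  }
  # identical multisets sit at the null centre
  x <- c(5, 8, 8, 13)
  expect_equal(gene_length_bias(x, x)$u, length(x)^2 / 2)
})

test_that("Mann-Whitney exact p: complete separation of 3 vs 3 gives 0.1", {
  res <- gene_length_bias(c(101, 102, 103), c(1, 2, 3))
  expect_equal(res$u, 9)
  expect_equal(res$p_value, 2 / choose(6, 3))
  expect_equal(res$method, "exact")
  # independent library check on a tie-free sample
  set.seed(3)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  expect_equal(gene_length_bias(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # tied large samples use the tie-corrected normal approximation
  xl <- sample(1:50, 150, replace = TRUE); yl <- sample(1:50, 150, replace = TRUE)
  res_l <- gene_length_bias(xl, yl)
  expect_equal(res_l$method, "normal_tie_corrected")
  expect_equal(res_l$p_value,
               stats::wilcox.test(xl, yl, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("null overlap tests have close-to-nominal type-I error", {
  set.seed(123)
  universe <- sprintf("G%04d", 1:2000)
  lrg <- sample(universe, 300)
  p <- purrr::map_dbl(1:400, function(i) {
    lst <- sample(universe, 250)
    fisher_overlap(length(intersect(lst, lrg)), 250, 300, 2000)$p_value
  })
  # conservative by discreteness, but within binomial noise of 5%
  frac <- mean(p < 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(frac, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
})
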