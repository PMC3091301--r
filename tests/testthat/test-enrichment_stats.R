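test_that("hypergeometric tail equals full enumeration on small universes", {
  # all-5-of-5 draw: 1/C(10,5)
  expect_equal(hypergeom_tail(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 5, 10), 1)
  set.seed(41)
  for (i in 1:40) {
    N <- sample(4:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), oracle_hypergeom_tail(k, K, n, N),
                 tolerance = 1e-12, info = sprintf("k=%d K=%d n=%d N=%d",
                                                   k, K, n, N))
  }
  # complement identity and extreme tails stay finite and positive
  expect_equal(hypergeom_tail(30, 100, 40, 6000) +
                 stats::phyper(29, 100, 5900, 40), 1, tolerance = 1e-12)
  expect_gt(hypergeom_tail(384, 995, 1049, 6000), 0)
  expect_error(hypergeom_tail(6, 5, 5, 10), "inconsistent")
})

test_that("2x2 chi-square matches the textbook formula and the printed case", {
  # targets among up-regulated proteins: 11/28 vs 254/1175
  res <- chi_square_2x2(matrix(c(11, 254, 17, 921), 2, 2))
  expect_gt(res$p, 0.025)
  expect_lt(res$p, 0.026)
  # identical row proportions -> statistic 0, p 1
  flat <- chi_square_2x2(matrix(c(10, 20, 30, 60), 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # direct O/E recomputation on random tables
  set.seed(17)
  for (i in 1:60) {
    tab <- matrix(sample(5:80, 4, replace = TRUE), 2, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_2x2(tab)$statistic, sum((tab - E)^2 / E),
                 tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("chi-square and Fisher agree in rejection on well-filled tables", {
  set.seed(53)
  agree <- 0L; total <- 0L
  while (total < 100L) {
    tab <- matrix(sample(10:120, 4, replace = TRUE), 2, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(E < 10)) next
    total <- total + 1L
    res <- chi_square_2x2(tab)
    if ((res$p < 0.05) == (res$fisher_p < 0.05)) agree <- agree + 1L
  }
  expect_gte(agree / total, 0.95)
})

test_that("Bonferroni caps at 1 and respects an explicit test count", {
  expect_equal(bonferroni(c(0.01, 0.5), m = 2), c(0.02, 1.0))
  expect_equal(bonferroni(0), 0)
  expect_equal(bonferroni(0.03), 0.03)  # single test unchanged
  expect_error(bonferroni(1.2), "p_values")
})

test_that("GO enrichment ranks a planted term first and needs a universe", {
  uni <- gene_set("u", "", sprintf("g%03d", 1:200))
  query <- gene_set("q", "", sprintf("g%03d", 1:20))
  ann <- list(hit = gene_set("hit", "", sprintf("g%03d", 1:20)),
              miss1 = gene_set("miss1", "", sprintf("g%03d", 101:140)),
              miss2 = gene_set("miss2", "", sprintf("g%03d", 150:200)))
  res <- go_enrichment(query, ann, uni)
  expect_equal(res$query_name[1], "hit")
  expect_lt(res$p_raw[1], 1e-10)
  expect_true(all(res$p_raw[-1] > 0.5))
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 3))
  expect_error(go_enrichment(gene_set("q", "", "alien"), ann, uni), "subset")
  expect_error(go_enrichment(query, ann, gene_set("u", "", character())),
               "empty universe")

  # planted enriched term in simulated annotations ranks first
  set.seed(4)
  genes <- sprintf("g%03d", 1:300)
  targ <- sample(genes, 60)
  ann2 <- c(list(planted = gene_set("planted", "",
                                    c(sample(targ, 25),
                                      sample(setdiff(genes, targ), 10)))),
            lapply(1:10, function(i)
              gene_set(sprintf("rand%02d", i), "", sample(genes, 35))))
  names(ann2) <- vapply(ann2, `[[`, "", "name")
  res2 <- go_enrichment(gene_set("t", "", targ), ann2,
                        gene_set("u", "", genes))
  expect_equal(res2$query_name[1], "planted")
})

test_that("GO enrichment is null-calibrated for uniform random queries", {
  set.seed(99)
  genes <- sprintf("g%03d", 1:400)
  ann <- lapply(1:20, function(i)
    gene_set(sprintf("t%02d", i), "", sample(genes, 40)))
  names(ann) <- vapply(ann, `[[`, "", "name")
  uni <- gene_set("u", "", genes)
  hits <- 0L; tests <- 0L
  for (s in 1:50) {
    q <- gene_set("q", "", sample(genes, 50))
    res <- go_enrichment(q, ann, uni)
    hits <- hits + sum(res$p_raw < 0.05)
    tests <- tests + nrow(res)
  }
  # hypergeometric p is discrete, so the realized rate sits at or below 5%
  expect_lte(hits / tests, 0.07)
  expect_gte(hits / tests, 0.005)
})

test_that("mHG equals exhaustive enumeration on small ranked lists", {
  # all 3 term genes leading a list of 10
  term <- gene_set("t", "", c("a", "b", "c"))
  ranked <- c("a", "b", "c", paste0("x", 1:7))
  res <- ranked_enrichment_mhg(ranked, term)
  expect_equal(res$mhg_stat, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$p_exact, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(res$n_star, 3L)
  expect_equal(res$b_star, 3L)
  expect_equal(res$enrichment_ratio, (3 / 3) / (3 / 10))

  # maximal dispersion -> p near 1
  ranked2 <- c("x1", "x2", "a", "x3", "x4", "b", "x5", "x6", "c", "x7")
  expect_gt(ranked_enrichment_mhg(ranked2, term)$p_exact, 0.5)

  # random placements vs full enumeration, N = 10
  set.seed(7)
  for (i in 1:15) {
    B <- sample(2:4, 1)
    ids <- sprintf("g%02d", 1:10)
    members <- sample(ids, B)
    res <- ranked_enrichment_mhg(ids, gene_set("t", "", members))
    orc <- oracle_mhg_exact(ids %in% members)
    expect_equal(res$mhg_stat, orc$mhg_stat, tolerance = 1e-12)
    expect_equal(res$p_exact, orc$p, tolerance = 1e-9)
  }
  expect_error(ranked_enrichment_mhg(ids, gene_set("t", "", "zz")), "no genes")
})

test_that("mHG p respects its bounds and matches permutations at N=30", {
  set.seed(19)
  ids <- sprintf("g%02d", 1:30)
  for (i in 1:10) {
    members <- sample(ids, 5)
    res <- ranked_enrichment_mhg(ids, gene_set("t", "", members))
    expect_gte(res$p_exact, res$mhg_stat - 1e-12)
    expect_lte(res$p_exact, min(1, 30 * res$mhg_stat) + 1e-12)
    # 20k-permutation Monte-Carlo agreement within 3 standard errors
    B <- 5; nperm <- 20000L
    hits <- 0L
    for (j in seq_len(nperm)) {
      lab <- logical(30); lab[sample.int(30, B)] <- TRUE
      b <- cumsum(lab)
      mt <- min(stats::phyper(b - 1, B, 25, 1:30, lower.tail = FALSE))
      if (mt <= res$mhg_stat + 1e-12) hits <- hits + 1L
    }
    phat <- hits / nperm
    se <- sqrt(max(phat * (1 - phat), 1 / nperm) / nperm)
    expect_lt(abs(res$p_exact - phat), 3 * se + 2 / nperm)
  }
})

test_that("overlap matrix reproduces planted overlaps and drops small sets", {
  sim <- simulate_geneset_overlap(universe_size = 6000, ref_set_size = 995,
                                  query_sizes = c(1049, 200, 7),
                                  overlap_fractions = c(384 / 1049, 0, 0.5),
                                  seed = 2)
  expect_message(
    res <- overlap_matrix(sim$reference, sim$queries, sim$universe),
    "dropping")
  expect_equal(nrow(res), 2L)  # the size-7 query is excluded
  nsr <- res[res$query_name == "query01", ]
  expect_equal(nsr$overlap_count, 384L)
  expect_equal(round(100 * nsr$fraction, 1), 36.6)
  expect_lt(nsr$p_bonferroni, 0.01)
  disj <- res[res$query_name == "query02", ]
  expect_equal(disj$overlap_count, 0L)
  expect_gt(disj$p_raw, 0.5)

  # query identical to the reference: maximal overlap, minimal p
  res2 <- overlap_matrix(sim$reference, list(self = sim$reference),
                         sim$universe)
  expect_equal(res2$overlap_count, 995L)
  expect_equal(res2$fraction, 1)
  expect_equal(res2$p_raw, hypergeom_tail(995, 995, 995, 6000))
})

test_that("overlap generator validates feasibility and determinism", {
  expect_error(simulate_geneset_overlap(100, 50, 60, 1.0, seed = 1),
               "infeasible")
  a <- simulate_geneset_overlap(500, 100, c(50, 80), c(0.2, 0.6), seed = 3)
  b <- simulate_geneset_overlap(500, 100, c(50, 80), c(0.2, 0.6), seed = 3)
  expect_identical(a, b)
  expect_equal(length(intersect(a$queries[[1]]$members,
                                a$reference$members)), 10L)
  expect_equal(length(intersect(a$queries[[2]]$members,
                                a$reference$members)), 48L)
})
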