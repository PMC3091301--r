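mk_matrix <- function(X, cls) {
  dimnames(X) <- list(sprintf("f%02d", seq_len(nrow(X))),
                      sprintf("a%d", seq_len(ncol(X))))
  ratio_matrix(X, cls)
}

test_that("QC filter masks cells by the strict >snr rule and drops features", {
  sim <- simulate_ripchip(n_features = 10, n_ip = 3, n_mock = 5,
                          snr_model = function(n) rep(5, n), seed = 1)
  m <- sim$matrix
  # snr 1.79 in the input channel -> masked; 1.81 -> kept
  m$snr1[1, 1] <- 1.79
  m$snr1[2, 1] <- 1.81
  f <- filter_features(m, snr_min = 1.8, snr_channels = "input_only")
  expect_true(is.na(f$matrix$log2_ratio[1, 1]))
  expect_false(is.na(f$matrix$log2_ratio[2, 1]))
  expect_equal(f$report$cells_masked_snr, 1L)
  # exactly at the threshold is NOT > threshold
  m$snr1[3, 2] <- 1.8
  expect_true(is.na(filter_features(m, 1.8)$matrix$log2_ratio[3, 2]))

  # expression mode: regression correlation 0.6 masked, <0.5 retained
  m2 <- sim$matrix
  m2$regression_cor[4, 1] <- 0.6
  m2$regression_cor[5, 1] <- 0.4
  f2 <- filter_features(m2, snr_min = 1.5, snr_channels = "both",
                        regression_min = 0.5)
  expect_true(is.na(f2$matrix$log2_ratio[4, 1]))
  expect_false(is.na(f2$matrix$log2_ratio[5, 1]))

  # all QC at +Inf leaves the matrix untouched
  m3 <- sim$matrix
  m3$snr1[] <- Inf; m3$snr2[] <- Inf
  expect_equal(filter_features(m3, 1.8)$matrix$log2_ratio, m3$log2_ratio)

  # feature retained on <2 arrays per class is dropped entirely
  m4 <- sim$matrix
  m4$snr1[1, 1:2] <- 1  # leaves only 1 IP cell for feature 1
  f4 <- filter_features(m4, 1.8)
  expect_equal(f4$report$features_dropped, 1L)
  expect_false("f00001" %in% rownames(f4$matrix$log2_ratio))

  # everything masked -> explicit error
  m5 <- sim$matrix
  m5$snr1[] <- 1
  expect_error(filter_features(m5, 1.8), "no features pass")
})

test_that("median centering zeroes every array median and is idempotent", {
  X <- rbind(c(1, 5, 0), c(2, 6, 2), c(3, 9, 4), c(7, 1, 8))
  m <- mk_matrix(cbind(X, X[, 3] + 1), c("IP", "IP", "mock", "mock"))
  cen <- median_center(m)
  expect_equal(unname(apply(cen$log2_ratio, 2, stats::median)), rep(0, 4))
  expect_equal(median_center(cen)$log2_ratio, cen$log2_ratio)

  # medians over present cells only, checked against direct recomputation
  sim <- simulate_ripchip(n_features = 40, seed = 4)
  mm <- sim$matrix
  mm$log2_ratio[cbind(1:10, rep(1:4, length.out = 10))] <- NA
  cen2 <- median_center(mm)
  for (j in seq_len(ncol(mm$log2_ratio))) {
    expect_equal(cen2$log2_ratio[, j],
                 mm$log2_ratio[, j] - stats::median(mm$log2_ratio[, j],
                                                    na.rm = TRUE))
  }
  mm$log2_ratio[, 2] <- NA
  expect_error(median_center(mm), "IP2")
})

test_that("SAM enumerates all 56 label assignments for a 3-vs-5 design", {
  sim <- simulate_ripchip(n_features = 20, n_ip = 3, n_mock = 5, seed = 2)
  res <- sam_two_class(sim$matrix, sam_config(n_permutations = "all"))
  expect_equal(res$permutation_count, choose(8, 3))
  expect_equal(sort(res$features$feature_id),
               sort(rownames(sim$matrix$log2_ratio)))
  expect_true(all(res$features$q >= 0 & res$features$q <= 1))
})

test_that("SAM d=0 and q=1 when class means are identical everywhere", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 6), nrow = 4, byrow = TRUE)
  m <- mk_matrix(X, c("IP", "IP", "IP", "mock", "mock", "mock"))
  res <- sam_two_class(m, sam_config(s0_method = "fixed", s0_fixed = 1))
  expect_equal(res$features$d, rep(0, 4))
  expect_equal(res$features$q, rep(1, 4))
  # all-zero variance with s0 = 0 is refused
  expect_error(sam_two_class(m, sam_config(s0_method = "fixed", s0_fixed = 0)),
               "s0")
})

test_that("SAM q-values equal the brute-force enumeration oracle", {
  for (seed in c(3, 17)) {
    sim <- simulate_ripchip(n_features = 20, n_ip = 3, n_mock = 5,
                            target_fraction = 0.25, effect_size_delta = 1.5,
                            seed = seed)
    res <- sam_two_class(sim$matrix,
                         sam_config(s0_method = "fixed", s0_fixed = 0.2))
    orc <- oracle_sam_q(sim$matrix$log2_ratio, sim$matrix$class_label,
                        s0 = 0.2)
    expect_equal(res$features$d, unname(orc$d), tolerance = 1e-12)
    expect_equal(res$pi0, orc$pi0, tolerance = 1e-12)
    expect_equal(res$features$q, unname(orc$q), tolerance = 1e-9)
  }
})

test_that("q is monotone in d on the positive side; d monotone under shifts", {
  sim <- simulate_ripchip(n_features = 50, seed = 6)
  res <- sam_two_class(sim$matrix, sam_config())
  o <- order(res$features$d, decreasing = TRUE)
  expect_true(all(diff(res$features$q[o]) >= -1e-12))

  # raising all class-1 values of one feature never lowers its d
  m <- sim$matrix
  cfg <- sam_config(s0_method = "fixed", s0_fixed = 0.3)
  d0 <- sam_two_class(m, cfg)$features$d[7]
  m$log2_ratio[7, m$class_label == "IP"] <-
    m$log2_ratio[7, m$class_label == "IP"] + 1
  expect_gte(sam_two_class(m, cfg)$features$d[7], d0)
})

test_that("SAM results are reproducible under a fixed seed when sampling", {
  sim <- simulate_ripchip(n_features = 30, n_ip = 4, n_mock = 4, seed = 8)
  cfg <- sam_config(n_permutations = 100, seed = 11)
  # C(8,4)=70 <= 100 so enumeration kicks in; force sampling with more arrays
  sim2 <- simulate_ripchip(n_features = 30, n_ip = 6, n_mock = 6, seed = 8)
  r1 <- sam_two_class(sim2$matrix, cfg)
  r2 <- sam_two_class(sim2$matrix, cfg)
  expect_identical(r1, r2)
  expect_equal(r1$permutation_count, 100L)
  r3 <- sam_two_class(sim$matrix, cfg)
  expect_equal(r3$permutation_count, 70L)
})

test_that("target calling applies the q<cutoff rule and reports the share", {
  sim <- simulate_ripchip(n_features = 200, target_fraction = 0.1,
                          effect_size_delta = 2, noise_sd = 0.5, seed = 5)
  res <- sam_two_class(sim$matrix, sam_config())
  calls <- call_targets(res, 0.05)
  expect_equal(calls$n_called, sum(res$features$q < 0.05))
  expect_equal(calls$n_analyzed, 200L)
  expect_equal(calls$percent,
               percent_report(calls$n_called, 200L, 1))
  # cutoff ~0 -> empty; cutoff 1 -> everything
  expect_equal(call_targets(res, 1e-12)$n_called, 0L)
  expect_equal(call_targets(res, 1)$n_called, 200L)
})

test_that("one-sample fold-change test applies both the 1.5-fold and p rules", {
  res <- one_sample_fold_change_test(list(
    up = c(1.0, 0.8, 0.9),        # mean 0.9, p ~ 0.004 -> up
    small = c(0.3, 0.2, 0.4),     # mean below log2(1.5) -> unchanged
    flat = c(0.6, 0.6),           # zero variance -> degenerate, not called
    down = c(-1.0, -0.9, -1.1)))
  expect_equal(res$called, c("up", "unchanged", "unchanged", "down"))
  expect_true(res$degenerate[3])
  expect_false(any(res$degenerate[-3]))
  # hand-computed t: t = 0.9/(0.1/sqrt(3)), df = 2
  expect_equal(res$p_value[1], 2 * stats::pt(-0.9 / (0.1 / sqrt(3)), df = 2),
               tolerance = 1e-12)
  expect_lt(res$p_value[1], 0.05)
  expect_error(one_sample_fold_change_test(list(one = 0.5)), "2 replicates")
})

test_that("SAM handles missing cells by per-class present-value statistics", {
  sim <- simulate_ripchip(n_features = 15, seed = 10)
  m <- sim$matrix
  m$log2_ratio[1, 1] <- NA  # still 2 IP values left
  res <- sam_two_class(m, sam_config(s0_method = "fixed", s0_fixed = 0.2))
  x <- m$log2_ratio[1, m$class_label == "IP"]
  y <- m$log2_ratio[1, m$class_label == "mock"]
  x <- x[!is.na(x)]
  sp <- sqrt((1 / length(x) + 1 / length(y)) *
               (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
               (length(x) + length(y) - 2))
  expect_equal(res$features$d[1], (mean(x) - mean(y)) / (sp + 0.2),
               tolerance = 1e-12)
  # a feature left with <2 values in a class is refused
  m$log2_ratio[2, 1:2] <- NA
  expect_error(sam_two_class(m, sam_config()), "filter_features")
})
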