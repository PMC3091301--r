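# Two-class SAM-style target calling: the moderated relative difference
# d = (mean1 - mean2)/(s + s0) with the pooled two-sample standard error s,
# the fudge factor s0 chosen by percentile search, and q-values from
# permutation of the class labels with a pi0-scaled FDR estimate. Also the
# per-array QC filters, median centering, and the 1.5-fold / P<0.05
# one-sample t-test rule for differential expression.

#' SAM configuration
#'
#' @param n_permutations `"all"` to enumerate every distinct class-label
#'   assignment (used whenever their number does not exceed a sampled
#'   request), or an integer >= 100 of sampled assignments.
#' @param side `"positive"` (enrichment only, the default for RIP data),
#'   `"negative"`, or `"both"`.
#' @param s0_method `"percentile_search"` (candidate s0 at every 5th
#'   percentile of the s values, pick the one minimising the coefficient of
#'   variation of window-wise MADs of d across 100 s-quantile windows) or
#'   `"fixed"`.
#' @param s0_fixed Non-negative s0 when `s0_method = "fixed"`.
#' @param fdr_cutoff Default calling cutoff (0.05).
#' @param pi0 `"estimate"` (central-quantile estimator) or a fixed numeric in
#'   (0, 1] — `pi0 = 1` gives the naive unscaled FDR.
#' @param seed Seed for sampled permutations.
#' @return A `sam_config` list.
#' @export
sam_config <- function(n_permutations = "all",
                       side = c("positive", "negative", "both"),
                       s0_method = c("percentile_search", "fixed"),
                       s0_fixed = 0, fdr_cutoff = 0.05, pi0 = "estimate",
                       seed = 1L) {
  side <- match.arg(side)
  s0_method <- match.arg(s0_method)
  if (!identical(n_permutations, "all")) {
    n_permutations <- as.integer(n_permutations)
    if (n_permutations < 100L) stop("sampled permutations must be >= 100")
  }
  if (s0_method == "fixed" && (!is.numeric(s0_fixed) || s0_fixed < 0))
    stop("s0_fixed must be a non-negative number")
  if (is.numeric(pi0) && (pi0 <= 0 || pi0 > 1)) stop("fixed pi0 must be in (0,1]")
  stopifnot(fdr_cutoff > 0, fdr_cutoff <= 1)
  structure(list(n_permutations = n_permutations, side = side,
                 s0_method = s0_method, s0_fixed = s0_fixed,
                 fdr_cutoff = fdr_cutoff, pi0 = pi0, seed = as.integer(seed)),
            class = "sam_config")
}

#' QC-filter a ratio matrix
#'
#' A cell is retained only if its signal-over-background exceeds `snr_min` in
#' the input channel (`snr_channels = "input_only"`, the RIP setting) or in
#' both channels (`"both"`, the expression setting), and — when
#' `regression_min` is given — its regression correlation is below
#' `regression_min`. Masked cells become missing. A feature is dropped
#' entirely when it retains fewer than 2 cells in either class.
#'
#' @param matrix A [ratio_matrix()].
#' @param snr_min Strict lower bound on signal over background (> 0).
#' @param snr_channels `"input_only"` or `"both"`.
#' @param regression_min Strict upper bound on the regression correlation, or
#'   `NULL` to skip that rule.
#' @return List with `matrix` (the filtered [ratio_matrix()]) and `report`
#'   (cells masked per rule, features dropped).
#' @export
filter_features <- function(matrix, snr_min = 1.8,
                            snr_channels = c("input_only", "both"),
                            regression_min = NULL) {
  stopifnot(inherits(matrix, "ratio_matrix"), snr_min > 0)
  snr_channels <- match.arg(snr_channels)
  keep_snr <- matrix$snr1 > snr_min
  if (snr_channels == "both") keep_snr <- keep_snr & matrix$snr2 > snr_min
  keep_reg <- if (is.null(regression_min)) TRUE else
    matrix$regression_cor < regression_min
  present <- !is.na(matrix$log2_ratio)
  masked_snr <- sum(present & !keep_snr)
  masked_reg <- if (is.null(regression_min)) 0L else
    sum(present & keep_snr & !keep_reg)
  X <- matrix$log2_ratio
  X[!(keep_snr & keep_reg)] <- NA_real_
  cls <- matrix$class_label
  ok <- rep(TRUE, nrow(X))
  for (cl in unique(cls))
    ok <- ok & rowSums(!is.na(X[, cls == cl, drop = FALSE])) >= 2L
  if (!any(ok)) stop("no features pass filters")
  out <- matrix
  out$log2_ratio <- X[ok, , drop = FALSE]
  out$snr1 <- matrix$snr1[ok, , drop = FALSE]
  out$snr2 <- matrix$snr2[ok, , drop = FALSE]
  out$regression_cor <- matrix$regression_cor[ok, , drop = FALSE]
  list(matrix = out,
       report = list(cells_masked_snr = masked_snr,
                     cells_masked_regression = masked_reg,
                     features_dropped = sum(!ok),
                     features_retained = sum(ok)))
}

#' Median-center each array of a ratio matrix
#'
#' Subtracts every array's median over its non-missing cells, so each array's
#' median becomes exactly 0. Idempotent.
#'
#' @param matrix A [ratio_matrix()].
#' @return The centered [ratio_matrix()].
#' @export
median_center <- function(matrix) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  X <- matrix$log2_ratio
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    if (all(is.na(v)))
      stop(sprintf("array '%s' has no non-missing values", colnames(X)[j]))
    X[, j] <- v - stats::median(v, na.rm = TRUE)
  }
  matrix$log2_ratio <- X
  matrix
}

# d, s and numerator for one class assignment (logical over arrays = class 1)
sam_d_stats <- function(X, P, X0, sel1, s0) {
  n1 <- as.vector(P %*% sel1)
  n2 <- as.vector(P %*% (1 - sel1))
  bad <- n1 < 1 | n2 < 1 | (n1 + n2) < 3
  m1 <- as.vector(X0 %*% sel1) / n1
  m2 <- as.vector(X0 %*% (1 - sel1)) / n2
  ss <- as.vector((X0 * X0) %*% sel1) - n1 * m1^2 +
    as.vector((X0 * X0) %*% (1 - sel1)) - n2 * m2^2
  s <- sqrt((1 / n1 + 1 / n2) * pmax(ss, 0) / (n1 + n2 - 2))
  r <- m1 - m2
  d <- r / (s + s0)
  d[bad] <- NA_real_
  list(d = d, s = s, r = r)
}

sam_s0_search <- function(r, s) {
  cand <- unique(stats::quantile(s, probs = seq(0, 1, by = 0.05), type = 7,
                                 names = FALSE))
  breaks <- unique(stats::quantile(s, probs = seq(0, 1, length.out = 101),
                                   type = 7, names = FALSE))
  win <- if (length(breaks) > 1)
    cut(s, breaks = breaks, include.lowest = TRUE) else factor(rep(1, length(s)))
  cv <- vapply(cand, function(s0) {
    dd <- r / (s + s0)
    mads <- tapply(dd, win, stats::mad)
    mads <- mads[!is.na(mads)]
    mu <- mean(mads)
    if (!length(mads) || mu == 0) return(Inf)
    stats::sd(mads) / mu
  }, 0)
  cand[which.min(cv)]
}

#' Two-class SAM analysis
#'
#' Computes the relative difference d = (mean1 - mean2)/(s + s0) per feature
#' (class 1 is the first class in the design order, e.g. IP) with the pooled
#' two-sample standard error s, then estimates a q-value for every feature by
#' permutation of the class labels: all distinct label assignments are
#' enumerated when feasible, otherwise assignments are sampled with the
#' configured seed. The FDR at a threshold is pi0 x (mean permuted calls)/
#' (observed calls); a feature's q-value is the minimum FDR over the
#' thresholds at which it is called, which makes q monotone in d on the
#' called side. Thresholds are the observed d values themselves (ties share a
#' threshold).
#'
#' Features must have at least 2 non-missing values per class (use
#' [filter_features()] first); means and standard errors use the non-missing
#' cells. Assignments that leave a feature without values in one class
#' contribute no permuted call for that feature.
#'
#' @param matrix A [ratio_matrix()].
#' @param config A [sam_config()].
#' @return Object of class `sam_result`: data.frame `features` (feature_id,
#'   d, s, q), plus `s0`, `pi0`, `permutation_count`, `side`.
#' @export
sam_two_class <- function(matrix, config = sam_config()) {
  stopifnot(inherits(matrix, "ratio_matrix"), inherits(config, "sam_config"))
  X <- matrix$log2_ratio
  cls <- matrix$class_label
  classes <- unique(cls)
  counts <- table(factor(cls, levels = classes))
  if (any(counts < 2L)) stop("SAM needs at least 2 arrays per class")
  P <- (!is.na(X)) * 1
  for (cl in classes)
    if (any(rowSums(P[, cls == cl, drop = FALSE]) < 2L))
      stop("every feature needs >= 2 non-missing values per class; run filter_features() first")
  if (!nrow(X)) stop("no features to analyze")
  X0 <- X
  X0[is.na(X0)] <- 0
  sel1_obs <- as.numeric(cls == classes[1])
  obs0 <- sam_d_stats(X, P, X0, sel1_obs, s0 = 0)
  s0 <- switch(config$s0_method,
               fixed = config$s0_fixed,
               percentile_search = sam_s0_search(obs0$r, obs0$s))
  if (all(obs0$s == 0) && s0 == 0)
    stop("all features have zero variance; a positive s0 is required")
  obs <- sam_d_stats(X, P, X0, sel1_obs, s0)
  n_arrays <- ncol(X)
  n1 <- sum(sel1_obs)
  n_all <- choose(n_arrays, n1)
  use_all <- identical(config$n_permutations, "all") ||
    n_all <= config$n_permutations
  if (use_all) {
    sel_list <- utils::combn(n_arrays, n1, simplify = FALSE)
  } else {
    sel_list <- with_seed(config$seed,
                          replicate(config$n_permutations,
                                    sample.int(n_arrays, n1),
                                    simplify = FALSE))
  }
  perm_d <- vapply(sel_list, function(ix) {
    sel <- numeric(n_arrays)
    sel[ix] <- 1
    sam_d_stats(X, P, X0, sel, s0)$d
  }, numeric(nrow(X)))
  perm_d <- matrix(perm_d, nrow = nrow(X))
  pi0 <- if (is.numeric(config$pi0)) config$pi0 else {
    qs <- stats::quantile(perm_d, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    min(1, sum(obs$d >= qs[1] & obs$d <= qs[2]) / (0.5 * nrow(X)))
  }
  stat <- switch(config$side, positive = obs$d, negative = -obs$d,
                 both = abs(obs$d))
  perm_stat <- switch(config$side, positive = perm_d, negative = -perm_d,
                      both = abs(perm_d))
  q <- sam_q_values(stat, perm_stat, pi0)
  res <- list(features = data.frame(feature_id = rownames(X), d = obs$d,
                                    s = obs$s, q = q,
                                    stringsAsFactors = FALSE),
              s0 = s0, pi0 = pi0, permutation_count = length(sel_list),
              side = config$side)
  class(res) <- "sam_result"
  res
}

# q-values from an observed statistic vector and a feature x permutation
# matrix of permuted statistics (larger = more extreme on the called side)
sam_q_values <- function(stat, perm_stat, pi0) {
  n_perm <- ncol(perm_stat)
  thr <- sort(unique(stat), decreasing = TRUE)
  perm_all <- perm_stat[!is.na(perm_stat)]
  fdr <- vapply(thr, function(t) {
    obs_count <- sum(stat >= t)
    perm_mean <- sum(perm_all >= t) / n_perm
    min(1, pi0 * perm_mean / obs_count)
  }, 0)
  q_thr <- rev(cummin(rev(fdr)))
  q_thr[match(stat, thr)]
}

#' @export
print.sam_result <- function(x, ...) {
  cat(sprintf("<sam_result: %d features, %d permutations, s0=%.4g, pi0=%.3f, side=%s>\n",
              nrow(x$features), x$permutation_count, x$s0, x$pi0, x$side))
  invisible(x)
}

#' Call targets from a SAM result at an FDR cutoff
#'
#' Features with q below the cutoff on the configured side. A cutoff of 1
#' disables filtering and returns every analyzed feature.
#'
#' @param result A `sam_result`.
#' @param fdr_cutoff FDR cutoff in (0, 1\].
#' @param name Name for the returned gene set.
#' @return List with `set` (a [gene_set()]), `n_called`, `n_analyzed`, and
#'   `percent` (share of analyzed features, 1 decimal, via
#'   [percent_report()]).
#' @export
call_targets <- function(result, fdr_cutoff = 0.05, name = "sam_targets") {
  stopifnot(inherits(result, "sam_result"), fdr_cutoff > 0, fdr_cutoff <= 1)
  called <- if (fdr_cutoff >= 1) rep(TRUE, nrow(result$features)) else
    result$features$q < fdr_cutoff
  ids <- result$features$feature_id[called]
  list(set = structure(list(name = name,
                            description = sprintf("SAM calls at FDR<%g (%s side)",
                                                  fdr_cutoff, result$side),
                            members = ids), class = "gene_set"),
       n_called = length(ids), n_analyzed = nrow(result$features),
       percent = if (nrow(result$features) > 0)
         percent_report(length(ids), nrow(result$features), 1) else NA_character_)
}

#' One-sample fold-change + t-test differential expression calls
#'
#' A gene is called up (down) only when BOTH its mean log2 ratio is at or
#' above log2(`fold_threshold`) (at or below the negative) AND the two-sided
#' one-sample t-test against 0 gives p below `alpha`. Genes with zero
#' replicate variance have no defined p; they are flagged degenerate and
#' never called.
#'
#' @param replicate_log2 Named list: per gene, a numeric vector of >= 2
#'   replicate log2 ratios.
#' @param fold_threshold Fold-change threshold (default 1.5, i.e. |mean
#'   log2| >= 0.585).
#' @param alpha Significance level (default 0.05).
#' @return data.frame with `gene_id`, `n`, `mean_log2`, `p_value`,
#'   `degenerate`, `called` (`"up"`, `"down"`, `"unchanged"`).
#' @export
one_sample_fold_change_test <- function(replicate_log2, fold_threshold = 1.5,
                                        alpha = 0.05) {
  stopifnot(is.list(replicate_log2), length(replicate_log2) > 0,
            !is.null(names(replicate_log2)), fold_threshold > 1, alpha > 0)
  lthr <- log2(fold_threshold)
  rows <- lapply(names(replicate_log2), function(g) {
    v <- replicate_log2[[g]][!is.na(replicate_log2[[g]])]
    if (length(v) < 2L)
      stop(sprintf("gene '%s': one-sample t-test needs >= 2 replicates", g))
    m <- mean(v)
    degenerate <- stats::sd(v) == 0
    p <- if (degenerate) NA_real_ else stats::t.test(v, mu = 0)$p.value
    called <- "unchanged"
    if (!degenerate && p < alpha) {
      if (m >= lthr) called <- "up" else if (m <= -lthr) called <- "down"
    }
    data.frame(gene_id = g, n = length(v), mean_log2 = m, p_value = p,
               degenerate = degenerate, called = called,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
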