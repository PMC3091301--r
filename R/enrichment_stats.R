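# Set-level statistics: hypergeometric overlap, 2x2 association, Bonferroni,
# GO-term enrichment over an annotation map, ranked-list minimum-hypergeometric
# (mHG) enrichment, and the multi-RBP overlap matrix. The enrichment universe
# is always an explicit argument; it is never inferred from the inputs.

#' Upper-tail hypergeometric overlap probability
#'
#' P(X >= k) where X is the overlap between a reference set of size `K` and a
#' query of size `n` drawn without replacement from a universe of size `N`.
#' Computed through [stats::phyper()] on the upper tail, which works in log
#' space internally, so extreme tails (p ~ 1e-300) are returned without
#' flooring to zero.
#'
#' @param k Observed overlap count.
#' @param K Reference set size.
#' @param n Query set size.
#' @param N Universe size.
#' @return The upper-tail probability, a single number in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (anyNA(c(k, K, n, N)) || k < 0 || K < 0 || n < 0 || N < 1 ||
      K > N || n > N || k > min(K, n))
    stop(sprintf("inconsistent hypergeometric counts: k=%s K=%s n=%s N=%s",
                 k, K, n, N))
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' One-degree-of-freedom Pearson chi-square without continuity correction by
#' default, plus Fisher's exact p as companion output for small cells.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @param continuity Apply Yates' continuity correction (default `FALSE`).
#' @return List with `statistic`, `p`, and `fisher_p`.
#' @export
chi_square_2x2 <- function(table, continuity = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table; use the Fisher companion instead")
  ch <- suppressWarnings(stats::chisq.test(table, correct = continuity))
  fi <- stats::fisher.test(round(table))
  list(statistic = unname(ch$statistic), p = ch$p.value, fisher_p = fi$p.value)
}

#' Bonferroni correction
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; defaults to `length(p_values)`.
#' @return `pmin(1, m * p_values)`.
#' @export
bonferroni <- function(p_values, m = NULL) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  if (is.null(m)) m <- length(p_values)
  pmin(1, m * p_values)
}

overlap_result <- function(query_name, overlap_count, query_size,
                           reference_size, universe_size, p_raw,
                           p_bonferroni = p_raw) {
  data.frame(query_name = query_name, overlap_count = overlap_count,
             query_size = query_size, reference_size = reference_size,
             universe_size = universe_size,
             fraction = ifelse(query_size > 0, overlap_count / query_size, NA),
             p_raw = p_raw, p_bonferroni = p_bonferroni,
             stringsAsFactors = FALSE)
}

#' GO-term enrichment of a query set over an annotation map
#'
#' One upper-tail hypergeometric test per annotation term, with the term's
#' members intersected with the stated universe first, and Bonferroni
#' correction over the terms actually tested. The universe must be supplied;
#' the query must lie inside it.
#'
#' @param query A [gene_set()] (the foreground).
#' @param annotation Named list of [gene_set()] objects (GO term -> members).
#' @param universe A [gene_set()]; the background population.
#' @param min_term_size Terms with fewer members in the universe are skipped.
#' @return data.frame of overlap results (one row per tested term), sorted by
#'   raw p-value.
#' @export
go_enrichment <- function(query, annotation, universe, min_term_size = 3L) {
  if (!length(universe$members)) stop("empty universe")
  if (!all(query$members %in% universe$members))
    stop("query must be a subset of the universe")
  N <- length(universe$members)
  n <- length(query$members)
  rows <- lapply(annotation, function(term) {
    term_u <- intersect(term$members, universe$members)
    K <- length(term_u)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(term_u, query$members))
    overlap_result(term$name, k, n, K, N, hypergeom_tail(k, K, n, N))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(overlap_result(character(), integer(), integer(),
                                           integer(), integer(), numeric()))
  res <- do.call(rbind, rows)
  res$p_bonferroni <- bonferroni(res$p_raw)
  res[order(res$p_raw), , drop = FALSE]
}

#' Minimum-hypergeometric (mHG) enrichment of a term in a ranked list
#'
#' For a ranked gene list, the mHG statistic is the minimum over all list
#' prefixes of the upper-tail hypergeometric probability of the term count in
#' the prefix. Its exact p-value is computed by the path-counting dynamic
#' program over the B x (N-B) lattice, zeroing every lattice cell whose tail
#' probability is at or below the observed minimum; for lists longer than
#' `exact_cap` a seeded permutation estimate (with add-one correction) is used
#' instead. The reported `enrichment_ratio` is (b/n)/(B/N) at the optimal
#' prefix.
#'
#' @param ranked_ids Character vector of unique gene ids, best rank first.
#' @param term A [gene_set()]; must intersect the list.
#' @param exact_cap Maximum list length for the exact dynamic program
#'   (default 2000).
#' @param n_permutations Permutations used beyond the cap (default 10000).
#' @param seed Seed for the permutation fallback.
#' @return List with `term_name`, `N`, `B`, `n_star`, `b_star`, `mhg_stat`,
#'   `p_exact`, `enrichment_ratio`, and `method` ("exact" or "permutation").
#' @export
ranked_enrichment_mhg <- function(ranked_ids, term, exact_cap = 2000L,
                                  n_permutations = 10000L, seed = 1L) {
  if (anyDuplicated(ranked_ids)) stop("ranked_ids must be unique")
  N <- length(ranked_ids)
  lab <- ranked_ids %in% term$members
  B <- sum(lab)
  if (B == 0L) stop(sprintf("term '%s' has no genes in the ranked list",
                            term$name))
  tails <- mhg_prefix_tails(lab, B, N)
  n_star <- which.min(tails)
  mhg_stat <- tails[n_star]
  b_star <- cumsum(lab)[n_star]
  if (N <= exact_cap) {
    p <- mhg_exact_p(mhg_stat, B, N)
    method <- "exact"
  } else {
    stopifnot(n_permutations >= 10000L)
    hits <- with_seed(seed, {
      h <- 0L
      for (i in seq_len(n_permutations)) {
        perm <- logical(N)
        perm[sample.int(N, B)] <- TRUE
        if (min(mhg_prefix_tails(perm, B, N)) <= mhg_tol(mhg_stat)) h <- h + 1L
      }
      h
    })
    p <- (1 + hits) / (1 + n_permutations)
    method <- "permutation"
  }
  # exact DP can land a hair under the statistic through rounding; clamp to
  # the proven bounds mhg_stat <= p <= min(1, N * mhg_stat)
  p <- min(max(p, mhg_stat), 1, N * mhg_stat)
  list(term_name = term$name, N = N, B = B, n_star = n_star, b_star = b_star,
       mhg_stat = mhg_stat, p_exact = p,
       enrichment_ratio = (b_star / n_star) / (B / N), method = method)
}

# numerical tie tolerance: mathematically equal tails computed at different
# (n, b) lattice cells can differ in their last floating-point bits, and ties
# belong inside the rejection region
mhg_tol <- function(crit) crit * (1 + 1e-9) + 1e-300

# upper-tail probabilities for every prefix length 1..N of a logical vector
mhg_prefix_tails <- function(lab, B, N) {
  b <- cumsum(lab)
  n <- seq_len(N)
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

# Exact mHG p-value: probability that a uniformly random arrangement of B ones
# among N slots attains a prefix tail <= crit somewhere. DP over (n, b) states
# carrying the probability of reaching each state without having entered the
# rejection region.
mhg_exact_p <- function(crit, B, N) {
  W <- N - B
  # M[b + 1] = P(b ones in first n slots, no rejection so far)
  M <- c(1, rep(0, B))
  for (n in seq_len(N)) {
    bmax <- min(n, B)
    bmin <- max(0L, n - W)
    bs <- bmin:bmax
    # survival check for states at prefix length n
    tail_n <- stats::phyper(bs - 1, B, W, n, lower.tail = FALSE)
    newM <- rep(0, B + 1)
    # ones placed so far before step n: transition from (n-1, b) and (n-1, b-1)
    prev <- M
    for (b in bs) {
      stay <- if (b <= min(n - 1, B) && b >= max(0L, n - 1 - W))
        prev[b + 1] * (W - (n - 1 - b)) / (N - n + 1) else 0
      step <- if (b >= 1 && (b - 1) >= max(0L, n - 1 - W) && (b - 1) <= min(n - 1, B))
        prev[b] * (B - (b - 1)) / (N - n + 1) else 0
      newM[b + 1] <- stay + step
    }
    # zero out rejected states (tail at or below the observed minimum)
    newM[bs + 1][tail_n <= mhg_tol(crit)] <- 0
    M <- newM
  }
  1 - M[B + 1]
}

#' Overlap of a reference target set with a panel of query sets
#'
#' For each query set of at least `min_query_size` members: the overlap count
#' with the reference, the fraction of the query overlapping, the upper-tail
#' hypergeometric p over the stated universe, and Bonferroni correction over
#' the retained queries. Undersized queries are dropped with a message.
#'
#' @param reference A [gene_set()] (e.g. the RBP's called targets).
#' @param queries Named list of [gene_set()] objects (other RBPs' targets).
#' @param universe A [gene_set()].
#' @param min_query_size Minimum query size retained (default 8).
#' @return data.frame of overlap results, one row per retained query.
#' @export
overlap_matrix <- function(reference, queries, universe, min_query_size = 8L) {
  N <- length(universe$members)
  K <- length(intersect(reference$members, universe$members))
  keep <- vapply(queries, function(q) length(q$members) >= min_query_size, TRUE)
  if (any(!keep))
    message(sprintf("overlap_matrix: dropping %d quer%s below %d members: %s",
                    sum(!keep), if (sum(!keep) == 1) "y" else "ies",
                    min_query_size,
                    paste(vapply(queries[!keep], `[[`, "", "name"),
                          collapse = ",")))
  queries <- queries[keep]
  rows <- lapply(queries, function(q) {
    qm <- intersect(q$members, universe$members)
    k <- length(intersect(qm, reference$members))
    overlap_result(q$name, k, length(qm), K, N,
                   hypergeom_tail(k, K, length(qm), N))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$p_bonferroni <- bonferroni(res$p_raw)
  res
}
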