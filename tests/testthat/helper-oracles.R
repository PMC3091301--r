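# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (naive loops, full enumeration) and share no code
# with the package internals they check.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  W = c("A", "U"), S = c("C", "G"), R = c("A", "G"), Y = c("C", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

# greedy sliding-window scanner: checks every start position, extends by
# whole triplets, keeps only runs that cannot be extended left in-phase
oracle_scan_runs <- function(sequence, pattern, min_run) {
  chars <- strsplit(toupper(chartr("Tt", "Uu", sequence)), "")[[1]]
  pat <- strsplit(toupper(pattern), "")[[1]]
  matches_at <- function(i) {  # 0-based triplet start
    if (i < 0 || i + 3 > length(chars)) return(FALSE)
    for (j in 1:3) {
      ch <- chars[i + j]
      if (ch == "N" || !(ch %in% ORACLE_IUPAC[[pat[j]]])) return(FALSE)
    }
    TRUE
  }
  out <- data.frame(start = integer(), run_length = integer())
  for (i in 0:max(0, length(chars) - 3)) {
    if (!matches_at(i)) next
    if (matches_at(i - 3)) next  # not maximal on the left in this phase
    k <- 1L
    while (matches_at(i + 3L * k)) k <- k + 1L
    if (k >= min_run) out <- rbind(out, data.frame(start = i, run_length = k))
  }
  out[order(out$start), , drop = FALSE]
}

# full-enumeration two-class SAM: every label assignment, naive per-feature
# statistics, FDR evaluated at every observed threshold
oracle_sam_q <- function(X, classes, s0, side = "positive", pi0 = NULL) {
  cls1 <- unique(classes)[1]
  d_for <- function(lab1) {
    apply(X, 1, function(v) {
      x <- v[lab1]; y <- v[!lab1]
      sp <- sqrt((1 / length(x) + 1 / length(y)) *
                   (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
                   (length(x) + length(y) - 2))
      (mean(x) - mean(y)) / (sp + s0)
    })
  }
  obs <- d_for(classes == cls1)
  n1 <- sum(classes == cls1)
  combos <- utils::combn(length(classes), n1, simplify = FALSE)
  perm <- sapply(combos, function(ix) {
    lab <- rep(FALSE, length(classes)); lab[ix] <- TRUE
    d_for(lab)
  })
  if (is.null(pi0)) {
    qs <- stats::quantile(perm, c(0.25, 0.75), names = FALSE)
    pi0 <- min(1, sum(obs >= qs[1] & obs <= qs[2]) / (0.5 * nrow(X)))
  }
  stat <- switch(side, positive = obs, negative = -obs, both = abs(obs))
  pstat <- switch(side, positive = perm, negative = -perm, both = abs(perm))
  q <- numeric(length(stat))
  for (i in seq_along(stat)) {
    fdrs <- c()
    for (t in stat[stat <= stat[i]]) {  # thresholds at which i is called
      obs_count <- sum(stat >= t)
      perm_mean <- mean(colSums(pstat >= t))
      fdrs <- c(fdrs, min(1, pi0 * perm_mean / obs_count))
    }
    q[i] <- min(fdrs)
  }
  list(d = obs, q = q, pi0 = pi0, n_perm = length(combos))
}

# hypergeometric upper tail by enumerating every possible query draw
oracle_hypergeom_tail <- function(k, K, n, N) {
  universe <- seq_len(N)
  ref <- seq_len(K)
  draws <- utils::combn(N, n, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, ref)) >= k, TRUE))
}

# exact two-sided Mann-Whitney by enumerating all group assignments
oracle_mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  m <- length(x)
  u_stat <- function(ix) {
    a <- pool[ix]; b <- pool[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(seq_len(m))
  us <- vapply(utils::combn(length(pool), m, simplify = FALSE), u_stat, 0)
  mu <- m * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exhaustive mHG p: enumerate every placement of B ones among N slots
oracle_mhg_exact <- function(lab) {
  N <- length(lab); B <- sum(lab)
  min_tail <- function(v) {
    b <- cumsum(v)
    min(stats::phyper(b - 1, B, N - B, seq_len(N), lower.tail = FALSE))
  }
  obs <- min_tail(lab)
  placements <- utils::combn(N, B, simplify = FALSE)
  p <- mean(vapply(placements, function(ix) {
    v <- logical(N); v[ix] <- TRUE
    min_tail(v) <= obs + 1e-12
  }, TRUE))
  list(mhg_stat = obs, p = p)
}

# random sequence helper
random_seq <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

make_records <- function(seqs, utr5 = 0, utr3 = 0) {
  lapply(seq_along(seqs), function(i) {
    n <- nchar(seqs[i])
    transcript_record(sprintf("tx%03d", i), seqs[i],
                      utr5 = c(0, utr5), cds = c(utr5, n - utr3),
                      utr3 = c(n - utr3, n))
  })
}
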