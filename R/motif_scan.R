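# Maximal degenerate trinucleotide-repeat scanning with region and codon-frame
# resolution. Matching is IUPAC-degenerate on the canonical A,C,G,U,N alphabet;
# N in a sequence matches nothing, N in a pattern matches any real base. Runs
# are maximal per phase (a run may start at any offset; extending it by one
# triplet on either side in the same phase must break the match), and runs
# never cross region boundaries.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = c("U"),
  W = c("A", "U"), S = c("C", "G"), R = c("A", "G"), Y = c("C", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"))

#' Construct a degenerate triplet pattern
#'
#' @param triplet Three-character string over the IUPAC codes
#'   A,C,G,U/T,W,S,R,Y,K,M,B,D,H,V,N (T is treated as U).
#' @param label Display label; defaults to the triplet itself.
#' @return Object of class `triplet_pattern` with the per-position base sets.
#' @export
triplet_pattern <- function(triplet, label = triplet) {
  stopifnot(is.character(triplet), length(triplet) == 1L)
  triplet <- chartr("t", "u", tolower(triplet))
  triplet <- toupper(triplet)
  chars <- strsplit(triplet, "")[[1]]
  if (length(chars) != 3L)
    stop(sprintf("pattern '%s' must be exactly 3 characters", triplet))
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC code(s) in pattern '%s': %s", triplet,
                 paste(bad, collapse = ",")))
  structure(list(triplet = triplet, label = label,
                 sets = IUPAC_SETS[chars],
                 n_degenerate = sum(lengths(IUPAC_SETS[chars]) > 1L)),
            class = "triplet_pattern")
}

#' @export
print.triplet_pattern <- function(x, ...) {
  cat(sprintf("<triplet_pattern %s (%s)>\n", x$triplet, x$label))
  invisible(x)
}

# logical vector: does the triplet starting at each position (1..L-2) match?
triplet_match_vector <- function(chars, pattern) {
  L <- length(chars)
  if (L < 3L) return(logical(0))
  m1 <- chars %in% pattern$sets[[1]]
  m2 <- chars %in% pattern$sets[[2]]
  m3 <- chars %in% pattern$sets[[3]]
  m1[seq_len(L - 2L)] & m2[seq_len(L - 2L) + 1L] & m3[seq_len(L - 2L) + 2L]
}

#' Scan a sequence for maximal triplet-repeat runs
#'
#' Finds every maximal run of consecutive matching triplets (stride 3) with at
#' least `min_run` repeats, at every phase offset. Runs within one phase are
#' non-overlapping by maximality; runs in different phases may overlap and are
#' reported separately.
#'
#' @param sequence Nucleotide string over the canonical alphabet (T
#'   accepted and normalised to U).
#' @param pattern A [triplet_pattern()] (or a string coerced to one).
#' @param min_run Minimum number of consecutive matching triplets (>= 1).
#' @return data.frame with columns `start` (0-based offset) and `run_length`
#'   (triplets), in ascending start order.
#' @export
scan_runs <- function(sequence, pattern, min_run = 1L) {
  stopifnot(min_run >= 1L)
  if (!inherits(pattern, "triplet_pattern")) pattern <- triplet_pattern(pattern)
  chars <- strsplit(normalize_sequence(sequence), "")[[1]]
  m <- triplet_match_vector(chars, pattern)
  out <- list(start = integer(), run_length = integer())
  if (length(m)) {
    for (ph in 0:2) {
      idx <- seq.int(ph + 1L, length(m), by = 3L)
      if (idx[1] > length(m)) next
      r <- rle(m[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_run
      if (any(keep)) {
        out$start <- c(out$start, idx[starts[keep]] - 1L)
        out$run_length <- c(out$run_length, r$lengths[keep])
      }
    }
  }
  o <- order(out$start)
  data.frame(start = out$start[o], run_length = out$run_length[o])
}

#' Scan one transcript's regions for motif runs
#'
#' Each of the 5'UTR, CDS and 3'UTR subsequences is scanned independently, so
#' a repeat spanning a region boundary is reported only as its (possibly
#' shorter) within-region parts. CDS hits are annotated with the codon frame
#' `start %% 3` (0 = first codon position); UTR hits get `NA`.
#'
#' @param record A [transcript_record()].
#' @param pattern A [triplet_pattern()].
#' @param min_run Minimum run length in triplets.
#' @return data.frame of motif hits: `transcript_id`, `region`, `start`
#'   (0-based within the region), `run_length`, `frame`.
#' @export
scan_transcript <- function(record, pattern, min_run = 1L) {
  if (!inherits(pattern, "triplet_pattern")) pattern <- triplet_pattern(pattern)
  cds_len <- record$cds[2] - record$cds[1]
  if (record$cds_non_triplet && cds_len > 0L)
    warning(sprintf("transcript '%s': CDS length %d is not a multiple of 3; frames are relative to the annotated CDS start",
                    record$transcript_id, cds_len))
  rows <- lapply(c("utr5", "cds", "utr3"), function(region) {
    runs <- scan_runs(region_sequence(record, region), pattern, min_run)
    if (!nrow(runs)) return(NULL)
    data.frame(transcript_id = record$transcript_id, region = region,
               start = runs$start, run_length = runs$run_length,
               frame = if (region == "cds") runs$start %% 3L else NA_integer_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(transcript_id = character(), region = character(),
                      start = integer(), run_length = integer(),
                      frame = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Scan a collection of transcripts
#' @param records List of [transcript_record()] objects.
#' @inheritParams scan_transcript
#' @return One data.frame of motif hits over all transcripts.
#' @export
scan_transcripts <- function(records, pattern, min_run = 1L) {
  if (!inherits(pattern, "triplet_pattern")) pattern <- triplet_pattern(pattern)
  hits <- lapply(records, scan_transcript, pattern = pattern,
                 min_run = min_run)
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Region-by-run-length motif count table with target enrichment
#'
#' For each run-length threshold `k` and region, counts transcripts bearing at
#' least one run of `>= k` triplets in that region, the number of such maximal
#' runs (occurrences; one maximal run of length L counts once in every row
#' `k <= L`), the intersection with a target set, and the upper-tail
#' hypergeometric enrichment p of targets among motif bearers over the stated
#' universe.
#'
#' @param records List of [transcript_record()] objects.
#' @param pattern A [triplet_pattern()].
#' @param k_values Ascending integer run-length thresholds.
#' @param target_set,universe [gene_set()] objects, target inside universe.
#' @return data.frame with one row per (k, region): `pattern`, `k`, `region`,
#'   `n_transcripts_with_motif`, `n_motif_occurrences`, `n_in_target_set`,
#'   `enrichment_p`.
#' @export
region_count_table <- function(records, pattern, k_values, target_set,
                               universe) {
  stopifnot(!is.unsorted(k_values))
  if (!all(target_set$members %in% universe$members))
    stop("target set must be a subset of the universe")
  if (!inherits(pattern, "triplet_pattern")) pattern <- triplet_pattern(pattern)
  hits <- suppressWarnings(scan_transcripts(records, pattern,
                                            min_run = min(k_values)))
  K <- length(target_set$members)
  N <- length(universe$members)
  grid <- expand.grid(k = k_values, region = c("utr5", "cds", "utr3"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$k[i]; region <- grid$region[i]
    sel <- hits$region == region & hits$run_length >= k
    bearers <- unique(hits$transcript_id[sel])
    in_universe <- intersect(bearers, universe$members)
    n_in_target <- length(intersect(bearers, target_set$members))
    data.frame(pattern = pattern$label, k = k, region = region,
               n_transcripts_with_motif = length(bearers),
               n_motif_occurrences = sum(sel),
               n_in_target_set = n_in_target,
               enrichment_p = hypergeom_tail(
                 length(intersect(in_universe, target_set$members)), K,
                 length(in_universe), N),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Codon-frame distribution of CDS motif hits
#'
#' @param hits data.frame of motif hits restricted to the CDS (error
#'   otherwise).
#' @return data.frame with rows frame 0/1/2: `count` and `percent` (integer
#'   percent, rounded half away from zero; `NA` when there are no hits).
#' @export
frame_distribution <- function(hits) {
  if (nrow(hits) && any(hits$region != "cds"))
    stop("frame_distribution expects CDS hits only")
  counts <- vapply(0:2, function(f) sum(hits$frame == f), 0L)
  total <- sum(counts)
  data.frame(frame = 0:2, count = counts,
             percent = if (total > 0)
               round_half_away(100 * counts / total) else rep(NA_real_, 3))
}

#' Gene set of transcripts bearing a qualifying motif run
#'
#' @param records List of [transcript_record()] objects.
#' @param pattern A [triplet_pattern()].
#' @param k Minimum run length in triplets.
#' @param region `"utr5"`, `"cds"`, `"utr3"`, or `"any"`.
#' @return A [gene_set()] of qualifying transcript ids (possibly empty; empty
#'   motif gene sets are legal internally even though GMT round-trips reject
#'   them).
#' @export
motif_gene_set <- function(records, pattern, k,
                           region = c("any", "utr5", "cds", "utr3")) {
  region <- match.arg(region)
  if (!inherits(pattern, "triplet_pattern")) pattern <- triplet_pattern(pattern)
  hits <- suppressWarnings(scan_transcripts(records, pattern, min_run = k))
  if (region != "any") hits <- hits[hits$region == region, , drop = FALSE]
  structure(list(name = sprintf("%s_%d_%s", pattern$label, k, region),
                 description = sprintf(
                   "transcripts with >=1 (%s)%d run in region %s",
                   pattern$triplet, k, region),
                 members = unique(hits$transcript_id)),
            class = "gene_set")
}

#' Rank candidate triplet-repeat motifs by target enrichment
#'
#' Exhaustive scoring of every degenerate triplet over the supplied
#' per-position code alphabet (minus the all-N pattern): each candidate is
#' scored by the upper-tail hypergeometric enrichment of candidate-bearing
#' transcripts (any region, run length >= `min_run`) among the targets versus
#' the combined target + background population. Candidates are ranked by
#' ascending p; ties prefer the more specific pattern (fewer degenerate
#' positions), then lexicographic order.
#'
#' @param target_records,background_records Lists of [transcript_record()]
#'   objects; targets must be non-empty and disjoint ids are not required.
#' @param min_run Minimum run length (triplets) a transcript must carry.
#' @param candidate_alphabet Character vector of IUPAC codes allowed at each
#'   position (default `c("A","C","G","U","W","S","R","Y","N")`).
#' @return data.frame ranked best-first: `pattern`, `n_degenerate`,
#'   `n_bearing`, `n_bearing_targets`, `p_raw`, `p_bonferroni`.
#' @export
discover_repeat_motifs <- function(target_records, background_records,
                                   min_run = 4L,
                                   candidate_alphabet = c("A", "C", "G", "U",
                                                          "W", "S", "R", "Y",
                                                          "N")) {
  if (!length(target_records)) stop("empty target set")
  bad <- setdiff(candidate_alphabet, names(IUPAC_SETS))
  if (length(bad))
    stop(sprintf("invalid IUPAC code(s): %s", paste(bad, collapse = ",")))
  target_ids <- vapply(target_records, `[[`, "", "transcript_id")
  bg_ids <- vapply(background_records, `[[`, "", "transcript_id")
  all_records <- c(target_records,
                   background_records[!(bg_ids %in% target_ids)])
  all_ids <- vapply(all_records, `[[`, "", "transcript_id")
  # precompute each transcript once as a character vector
  charsets <- lapply(all_records, function(r) strsplit(r$sequence, "")[[1]])
  has_run <- function(pattern) {
    vapply(charsets, function(chars) {
      m <- triplet_match_vector(chars, pattern)
      L <- length(m) - 3L * (min_run - 1L)
      if (L < 1L) return(FALSE)
      z <- m[seq_len(L)]
      for (j in seq_len(min_run - 1L)) z <- z & m[seq_len(L) + 3L * j]
      any(z)
    }, TRUE)
  }
  combos <- expand.grid(p1 = candidate_alphabet, p2 = candidate_alphabet,
                        p3 = candidate_alphabet, stringsAsFactors = FALSE)
  trip <- paste0(combos$p1, combos$p2, combos$p3)
  trip <- trip[trip != "NNN"]
  N <- length(all_ids)
  K <- length(target_ids)
  rows <- lapply(trip, function(tp) {
    pat <- triplet_pattern(tp)
    bearing <- all_ids[has_run(pat)]
    k <- length(intersect(bearing, target_ids))
    data.frame(pattern = tp, n_degenerate = pat$n_degenerate,
               n_bearing = length(bearing), n_bearing_targets = k,
               p_raw = hypergeom_tail(k, K, length(bearing), N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- bonferroni(res$p_raw)
  res[order(res$p_raw, res$n_degenerate, res$pattern), , drop = FALSE]
}
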