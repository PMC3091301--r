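# Seeded generators that emulate the data structures the analysis assumes:
# transcriptomes with UTR/CDS architecture and planted in-frame triplet
# repeats, two-class RIP ratio matrices with planted enrichment, expression
# tables with GO-linked target-subset shifts, and gene-set panels with exact
# planted overlaps. Every generator returns its ground truth, and every
# random draw flows from the single seed argument (no global RNG state
# leaks: the caller's RNG is saved and restored).

#' Simulate a transcriptome with planted triplet-repeat runs
#'
#' Background sequence is i.i.d. uniform over A,C,G,U. A chosen fraction of
#' transcripts receives one planted run of the pattern: a concrete
#' instantiation of `run_length` consecutive matching triplets placed in a
#' region drawn from `region_probs`, in-frame (start divisible by 3) with
#' probability `in_frame_prob` when the region is the CDS. A run-breaking
#' base is written immediately before and after the run (first base of the
#' adjacent same-phase triplet), so the planted run is maximal and its
#' ground-truth length exact. UTR lengths are Poisson around their means;
#' CDS lengths are positive multiples of 3.
#'
#' @param n_transcripts Number of transcripts.
#' @param length_model List with mean lengths `utr5`, `cds`, `utr3` (nt).
#' @param plant List: `pattern` (IUPAC triplet string), `run_lengths`
#'   (integer vector sampled uniformly, or with `run_length_probs`),
#'   `region_probs` (named numeric over utr5/cds/utr3, summing to 1),
#'   `in_frame_prob` in \[0,1\], `fraction` of transcripts planted.
#' @param seed Integer seed.
#' @return List with `records` (named list of [transcript_record()]) and
#'   `truth` (list: `planted_hits` data.frame with transcript_id, region,
#'   start, run_length, frame; `pattern`; `seed`).
#' @export
simulate_transcriptome <- function(n_transcripts = 100L,
                                   length_model = list(utr5 = 60, cds = 600,
                                                       utr3 = 120),
                                   plant = list(pattern = "GAN",
                                                run_lengths = 7L,
                                                run_length_probs = NULL,
                                                region_probs = c(utr5 = 0,
                                                                 cds = 1,
                                                                 utr3 = 0),
                                                in_frame_prob = 1,
                                                fraction = 0.2),
                                   seed = 1L) {
  stopifnot(n_transcripts >= 1)
  pattern <- triplet_pattern(plant$pattern)
  rp <- plant$region_probs[c("utr5", "cds", "utr3")]
  if (anyNA(rp) || abs(sum(rp) - 1) > 1e-9)
    stop("plant$region_probs must cover utr5/cds/utr3 and sum to 1")
  if (plant$in_frame_prob < 0 || plant$in_frame_prob > 1)
    stop("plant$in_frame_prob must be in [0,1]")
  if (plant$fraction < 0 || plant$fraction > 1)
    stop("plant$fraction must be in [0,1]")
  # a base that breaks a match at the first non-fully-degenerate position
  brk_pos <- which(lengths(pattern$sets) < 4L)[1]
  brk_base <- if (is.na(brk_pos)) "N" else
    setdiff(c("A", "C", "G", "U"), pattern$sets[[brk_pos]])[1]
  if (is.na(brk_pos)) brk_pos <- 1L
  with_seed(seed, {
    ids <- sprintf("t%04d", seq_len(n_transcripts))
    utr5_len <- stats::rpois(n_transcripts, length_model$utr5)
    utr3_len <- stats::rpois(n_transcripts, length_model$utr3)
    cds_len <- 3L * pmax(1L, stats::rpois(n_transcripts,
                                          length_model$cds / 3))
    n_plant <- round(plant$fraction * n_transcripts)
    planted_idx <- if (n_plant > 0) sort(sample.int(n_transcripts, n_plant))
      else integer()
    hits <- list()
    records <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      total <- utr5_len[i] + cds_len[i] + utr3_len[i]
      chars <- sample(c("A", "C", "G", "U"), total, replace = TRUE)
      if (i %in% planted_idx) {
        region <- sample(c("utr5", "cds", "utr3"), 1L, prob = rp)
        reg_len <- switch(region, utr5 = utr5_len[i], cds = cds_len[i],
                          utr3 = utr3_len[i])
        reg_off <- switch(region, utr5 = 0L, cds = utr5_len[i],
                          utr3 = utr5_len[i] + cds_len[i])
        L <- if (length(plant$run_lengths) == 1L) plant$run_lengths else
          sample(plant$run_lengths, 1L, prob = plant$run_length_probs)
        if (3L * L > reg_len)
          stop(sprintf(
            "planted run of %d triplets does not fit region %s (length %d) of %s",
            L, region, reg_len, ids[i]))
        max_start <- reg_len - 3L * L
        cand <- 0:max_start
        if (region == "cds") {
          want_frame <- if (stats::runif(1) < plant$in_frame_prob) 0L else
            sample(1:2, 1L)
          fcand <- cand[cand %% 3L == want_frame]
          # fall back to any start when the region is too short for the frame
          if (!length(fcand)) fcand <- cand
          start <- if (length(fcand) == 1L) fcand else sample(fcand, 1L)
        } else {
          start <- if (length(cand) == 1L) cand else sample(cand, 1L)
        }
        run <- unlist(lapply(seq_len(L), function(j)
          vapply(pattern$sets, function(s)
            if (length(s) == 1L) s else sample(s, 1L), "")))
        a <- reg_off + start  # 0-based absolute start
        chars[(a + 1L):(a + 3L * L)] <- run
        # run-breaking bases in the adjacent same-phase triplets
        if (start >= 3L) chars[a - 3L + brk_pos] <- brk_base
        if (start + 3L * L + 3L <= reg_len)
          chars[a + 3L * L + brk_pos] <- brk_base
        hits[[length(hits) + 1L]] <- data.frame(
          transcript_id = ids[i], region = region, start = start,
          run_length = L,
          frame = if (region == "cds") start %% 3L else NA_integer_,
          stringsAsFactors = FALSE)
      }
      records[[i]] <- transcript_record(
        ids[i], paste(chars, collapse = ""),
        utr5 = c(0L, utr5_len[i]),
        cds = c(utr5_len[i], utr5_len[i] + cds_len[i]),
        utr3 = c(utr5_len[i] + cds_len[i], total))
    }
    names(records) <- ids
    planted <- if (length(hits)) do.call(rbind, hits) else
      data.frame(transcript_id = character(), region = character(),
                 start = integer(), run_length = integer(), frame = integer(),
                 stringsAsFactors = FALSE)
    list(records = records,
         truth = list(planted_hits = planted, pattern = pattern$triplet,
                      seed = as.integer(seed)))
  })
}

#' Simulate a two-class RIP-chip ratio matrix with planted targets
#'
#' Non-target features have i.i.d. Normal(0, `noise_sd`) log2 ratios on every
#' array; planted targets get `effect_size_delta` added on the IP arrays
#' only. Per-cell signal-over-background values are drawn from `snr_model`
#' for both channels, so a downstream `>snr_min` filter removes a
#' controllable fraction of cells.
#'
#' @param n_features Number of array features.
#' @param n_ip,n_mock Arrays per class (both >= 2; 3 and 5 by default,
#'   matching the assay design the pipeline targets).
#' @param target_fraction Fraction of features planted as targets, in \[0,1\].
#' @param effect_size_delta Log2 enrichment added to target IP cells.
#' @param noise_sd Ratio noise standard deviation (log2 units).
#' @param snr_model Function `n -> n` positive draws; the default lognormal
#'   (median 5, sdlog 0.5) leaves roughly 2% of cells below the 1.8 filter.
#' @param seed Integer seed.
#' @return List with `matrix` (a [ratio_matrix()], IP arrays first) and
#'   `truth` (list: `planted_target_ids`, `seed`).
#' @export
simulate_ripchip <- function(n_features = 1000L, n_ip = 3L, n_mock = 5L,
                             target_fraction = 0.1, effect_size_delta = 2,
                             noise_sd = 0.5,
                             snr_model = function(n) stats::rlnorm(n, log(5),
                                                                   0.5),
                             seed = 1L) {
  if (n_ip < 2L || n_mock < 2L) stop("need at least 2 arrays per class")
  if (target_fraction < 0 || target_fraction > 1)
    stop("target_fraction must be in [0,1]")
  with_seed(seed, {
    ids <- sprintf("f%05d", seq_len(n_features))
    arrays <- c(sprintf("IP%d", seq_len(n_ip)),
                sprintf("mock%d", seq_len(n_mock)))
    cls <- c(rep("IP", n_ip), rep("mock", n_mock))
    X <- matrix(stats::rnorm(n_features * length(arrays), 0, noise_sd),
                n_features, length(arrays), dimnames = list(ids, arrays))
    n_t <- round(target_fraction * n_features)
    targets <- if (n_t > 0) sort(sample.int(n_features, n_t)) else integer()
    X[targets, seq_len(n_ip)] <- X[targets, seq_len(n_ip)] + effect_size_delta
    snr1 <- matrix(snr_model(length(X)), n_features, length(arrays),
                   dimnames = dimnames(X))
    snr2 <- matrix(snr_model(length(X)), n_features, length(arrays),
                   dimnames = dimnames(X))
    rm <- ratio_matrix(X, cls, snr1 = snr1, snr2 = snr2,
                       regression_cor = matrix(0, n_features, length(arrays),
                                               dimnames = dimnames(X)))
    list(matrix = rm,
         truth = list(planted_target_ids = ids[targets],
                      seed = as.integer(seed)))
  })
}

#' Simulate matched mRNA/protein expression with GO-linked subset shifts
#'
#' Baseline log2 ratios are Normal(0, `noise_sd`) for mRNA (all genes) and
#' protein (a `protein_coverage` fraction of genes, sampled). Each entry of
#' `planted_shifts` adds its mRNA/protein shift to the genes carrying that GO
#' term — by default only to genes that are ALSO targets (`shift_mode =
#' "targets_only"`, the target-specific regulation regime); `"whole_term"`
#' shifts every term member.
#'
#' @param gene_ids Character vector of gene ids.
#' @param go_map Named list of [gene_set()] objects (GO term -> members).
#' @param target_set A [gene_set()] of target genes.
#' @param planted_shifts Named list: GO term -> numeric `c(mrna=, protein=)`
#'   log2 shifts. Terms must exist in `go_map`.
#' @param noise_sd Baseline noise standard deviation (log2 units).
#' @param protein_coverage Fraction of genes with protein data, in (0, 1\].
#' @param shift_mode `"targets_only"` or `"whole_term"`.
#' @param seed Integer seed.
#' @return List with `table` (an [expression_table()]) and `truth` (list:
#'   `planted_shifts`, `shifted_genes` per term, `seed`).
#' @export
simulate_expression <- function(gene_ids, go_map, target_set,
                                planted_shifts = list(), noise_sd = 0.3,
                                protein_coverage = 1,
                                shift_mode = c("targets_only", "whole_term"),
                                seed = 1L) {
  shift_mode <- match.arg(shift_mode)
  if (protein_coverage <= 0 || protein_coverage > 1)
    stop("protein_coverage must be in (0,1]")
  unknown <- setdiff(names(planted_shifts), names(go_map))
  if (length(unknown))
    stop(sprintf("unknown GO term(s) in planted_shifts: %s",
                 paste(unknown, collapse = ",")))
  n <- length(gene_ids)
  ann <- lapply(gene_ids, function(g)
    names(go_map)[vapply(go_map, function(s) g %in% s$members, TRUE)])
  with_seed(seed, {
    mrna <- stats::rnorm(n, 0, noise_sd)
    prot <- stats::rnorm(n, 0, noise_sd)
    has_prot <- logical(n)
    has_prot[sample.int(n, round(protein_coverage * n))] <- TRUE
    prot[!has_prot] <- NA_real_
    is_target <- gene_ids %in% target_set$members
    shifted <- list()
    for (term in names(planted_shifts)) {
      members <- gene_ids %in% go_map[[term]]$members
      sel <- if (shift_mode == "targets_only") members & is_target else members
      sh <- planted_shifts[[term]]
      mrna[sel] <- mrna[sel] + if (!is.na(sh["mrna"])) sh[["mrna"]] else 0
      prot[sel] <- prot[sel] + if (!is.na(sh["protein"])) sh[["protein"]] else 0
      shifted[[term]] <- gene_ids[sel]
    }
    list(table = expression_table(gene_ids, mrna, prot, is_target, ann),
         truth = list(planted_shifts = planted_shifts,
                      shifted_genes = shifted, shift_mode = shift_mode,
                      seed = as.integer(seed)))
  })
}

#' Simulate gene-set panels with exact planted overlaps
#'
#' Builds a universe, one reference set, and a panel of query sets whose
#' realized overlap with the reference equals exactly
#' `round(overlap_fraction * query_size)` members.
#'
#' @param universe_size,ref_set_size Sizes (reference <= universe).
#' @param query_sizes Integer vector of query sizes.
#' @param overlap_fractions Numeric vector (same length) of the fraction of
#'   each query overlapping the reference.
#' @param seed Integer seed.
#' @return List with `universe`, `reference` ([gene_set()]s), `queries`
#'   (named list of [gene_set()]s), and `truth` (data.frame of requested
#'   overlap counts).
#' @export
simulate_geneset_overlap <- function(universe_size, ref_set_size, query_sizes,
                                     overlap_fractions, seed = 1L) {
  stopifnot(ref_set_size <= universe_size,
            length(query_sizes) == length(overlap_fractions),
            all(query_sizes <= universe_size))
  counts <- as.integer(round_half_away(overlap_fractions * query_sizes))
  bad <- counts > pmin(ref_set_size, query_sizes) |
    (query_sizes - counts) > (universe_size - ref_set_size)
  if (any(bad))
    stop(sprintf("infeasible overlap for query %s",
                 paste(which(bad), collapse = ",")))
  with_seed(seed, {
    uni <- sprintf("g%06d", seq_len(universe_size))
    ref <- sort(sample(uni, ref_set_size))
    nonref <- setdiff(uni, ref)
    queries <- lapply(seq_along(query_sizes), function(i) {
      inside <- if (counts[i] > 0) sample(ref, counts[i]) else character()
      outside <- if (query_sizes[i] - counts[i] > 0)
        sample(nonref, query_sizes[i] - counts[i]) else character()
      gene_set(sprintf("query%02d", i),
               sprintf("planted overlap %d of %d", counts[i], query_sizes[i]),
               c(inside, outside))
    })
    names(queries) <- vapply(queries, `[[`, "", "name")
    list(universe = gene_set("universe", "simulated universe", uni),
         reference = gene_set("reference", "simulated reference targets", ref),
         queries = queries,
         truth = data.frame(query_name = names(queries),
                            query_size = as.integer(query_sizes),
                            overlap = counts, seed = as.integer(seed)))
  })
}
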