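test_that("triplet patterns validate IUPAC codes and track degeneracy", {
  p <- triplet_pattern("GWW")
  expect_equal(p$sets[[2]], c("A", "U"))
  expect_equal(p$n_degenerate, 2L)
  expect_equal(triplet_pattern("gtt")$triplet, "GUU")  # T/U interchangeable
  expect_error(triplet_pattern("GW"), "3 characters")
  expect_error(triplet_pattern("GXW"), "invalid IUPAC")
})

test_that("scan_runs finds the printed repeat probes correctly", {
  # ten GWW triplets: (GAUGAA)x5 is one maximal run of 10
  r <- scan_runs(strrep("GAUGAA", 5), "GWW", min_run = 3)
  expect_equal(r, data.frame(start = 0L, run_length = 10L))
  # (GUGGUG)x5: third position G never matches W
  expect_equal(nrow(scan_runs(strrep("GUGGUG", 5), "GWW", 1)), 0L)
  # (GAA)x7 with non-matching flanks, GAN pattern
  s <- paste0("CCU", strrep("GAA", 7), "UCC")
  r2 <- scan_runs(s, "GAN", min_run = 7)
  expect_equal(r2$start, 3L)
  expect_equal(r2$run_length, 7L)
  # phase completeness: run starting off-frame at offset 1
  r3 <- scan_runs("AGAAGAAGAAG", "GAN", 1)
  expect_true(any(r3$start == 1L & r3$run_length == 3L))
  # N in the sequence matches nothing, even against pattern N
  expect_equal(nrow(scan_runs("GANGAAGAA", "GAN", 3)), 0L)
  expect_error(scan_runs("ACGU", "GXX", 1), "invalid")
})

test_that("scanner equals the greedy sliding-window oracle on random input", {
  set.seed(202)
  patterns <- c("GWW", "GAN", "GSS", "NNN")
  for (i in 1:250) {
    s <- random_seq(sample(10:80, 1), c("A", "C", "G", "U", "N"))
    for (pat in patterns) {
      got <- scan_runs(s, pat, min_run = 2)
      want <- oracle_scan_runs(s, pat, min_run = 2)
      expect_equal(got$start, want$start, info = paste(pat, s))
      expect_equal(got$run_length, want$run_length, info = paste(pat, s))
    }
  }
})

test_that("region scanning splits at boundaries and annotates codon frame", {
  # CDS starts at 6; runs planted at CDS offsets 12 and 13 in two transcripts
  mk <- function(cds_off) {
    cds <- paste0(strrep("C", cds_off), strrep("GAA", 4),
                  strrep("C", 30 - cds_off - 12))  # CDS length 30
    transcript_record("t1", paste0(strrep("C", 6), cds),
                      utr5 = c(0, 6), cds = c(6, 36), utr3 = c(36, 36))
  }
  h0 <- scan_transcript(mk(12), triplet_pattern("GAN"), 4)
  expect_equal(h0$frame, 0L)
  expect_equal(h0$start, 12L)
  h1 <- scan_transcript(mk(13), triplet_pattern("GAN"), 4)
  expect_equal(h1$frame, 1L)

  # a run crossing the CDS/3'UTR junction is reported split per region
  seq <- paste0(strrep("GAA", 4), strrep("GAA", 3))
  rec <- transcript_record("t2", seq, c(0, 0), c(0, 12), c(12, 21))
  h <- scan_transcript(rec, triplet_pattern("GAN"), 1)
  expect_equal(h$region, c("cds", "utr3"))
  expect_equal(h$run_length, c(4L, 3L))
  expect_true(is.na(h$frame[2]))
})

test_that("region count table counts transcripts and occurrences per k", {
  # 10 transcripts with one CDS run of exactly 5 triplets each
  seqs <- vapply(1:10, function(i)
    paste0("CCC", strrep("GAA", 5), "CCC"), "")
  recs <- make_records(seqs)
  ids <- vapply(recs, `[[`, "", "transcript_id")
  uni <- gene_set("u", "", ids)
  targ <- gene_set("t", "", ids[1:4])
  ct <- region_count_table(recs, triplet_pattern("GAN"), 3:6, targ, uni)
  cds <- ct[ct$region == "cds", ]
  expect_equal(cds$n_transcripts_with_motif[cds$k %in% 3:5], rep(10L, 3))
  expect_equal(cds$n_motif_occurrences[cds$k %in% 3:5], rep(10L, 3))
  expect_equal(cds$n_transcripts_with_motif[cds$k == 6], 0L)
  expect_equal(cds$n_in_target_set[cds$k == 4], 4L)

  # two separate runs (4 and 6) in one transcript: 1 transcript, 2 occurrences
  s2 <- paste0(strrep("GAA", 4), "CCC", strrep("GAA", 6))
  ct2 <- region_count_table(make_records(s2), triplet_pattern("GAN"), c(4L, 6L),
                            gene_set("t", "", "tx001"),
                            gene_set("u", "", "tx001"))
  r4 <- ct2[ct2$region == "cds" & ct2$k == 4, ]
  expect_equal(r4$n_transcripts_with_motif, 1L)
  expect_equal(r4$n_motif_occurrences, 2L)
  expect_equal(ct2[ct2$region == "cds" & ct2$k == 6, ]$n_motif_occurrences, 1L)

  # counts are monotone non-increasing in k, occurrences >= transcripts
  sim <- simulate_transcriptome(200, plant = list(
    pattern = "GWW", run_lengths = 3:8, run_length_probs = NULL,
    region_probs = c(utr5 = 0.1, cds = 0.8, utr3 = 0.1),
    in_frame_prob = 0.8, fraction = 0.5), seed = 12)
  uni2 <- gene_set("u", "", names(sim$records))
  ct3 <- region_count_table(sim$records, triplet_pattern("GWW"), 3:8,
                            gene_set("t", "", names(sim$records)[1:50]), uni2)
  for (reg in unique(ct3$region)) {
    sub <- ct3[ct3$region == reg, ]
    expect_true(all(diff(sub$n_transcripts_with_motif) <= 0))
    expect_true(all(diff(sub$n_motif_occurrences) <= 0))
    expect_true(all(sub$n_motif_occurrences >= sub$n_transcripts_with_motif))
    expect_true(all(sub$n_in_target_set <= sub$n_transcripts_with_motif))
  }
  expect_error(region_count_table(recs, triplet_pattern("GAN"), 3,
                                  gene_set("t", "", "stranger"), uni),
               "subset")
})

test_that("planted-truth simulation counts match ground truth exactly", {
  sim <- simulate_transcriptome(150, plant = list(
    pattern = "GAN", run_lengths = 7:9, run_length_probs = NULL,
    region_probs = c(utr5 = 0, cds = 1, utr3 = 0), in_frame_prob = 1,
    fraction = 0.4), seed = 5)
  ph <- sim$truth$planted_hits
  hits <- scan_transcripts(sim$records, triplet_pattern("GAN"), min_run = 7)
  hits <- hits[hits$region == "cds", ]
  got <- merge(ph, hits, by = c("transcript_id", "region", "start",
                                "run_length", "frame"))
  expect_equal(nrow(got), nrow(ph))       # every planted hit found exactly
  expect_equal(nrow(hits), nrow(ph))      # and nothing >=7 beyond them
})

test_that("frame distribution reproduces the integer-percent convention", {
  hits <- data.frame(region = "cds",
                     frame = c(rep(0L, 416), rep(1L, 20), rep(2L, 10)))
  fd <- frame_distribution(hits)
  expect_equal(fd$count[1], 416L)
  expect_equal(fd$percent[1], 93)  # 416/446 = 93.27 -> 93
  fd2 <- frame_distribution(data.frame(region = "cds", frame = rep(0L, 7)))
  expect_equal(fd2$percent, c(100, 0, 0))
  fd3 <- frame_distribution(data.frame(region = character(),
                                       frame = integer()))
  expect_true(all(is.na(fd3$percent)))
  expect_equal(fd3$count, rep(0L, 3))
  expect_error(frame_distribution(data.frame(region = "utr3", frame = NA)),
               "CDS")
})

test_that("motif gene sets pick the qualifying transcripts per region", {
  sim <- simulate_transcriptome(120, plant = list(
    pattern = "GAN", run_lengths = 7L, run_length_probs = NULL,
    region_probs = c(utr5 = 0, cds = 1, utr3 = 0), in_frame_prob = 1,
    fraction = 0.3), seed = 9)
  gs <- motif_gene_set(sim$records, triplet_pattern("GAN"), 7, "cds")
  expect_setequal(gs$members, unique(sim$truth$planted_hits$transcript_id))
  # k beyond every run present -> empty
  expect_length(motif_gene_set(sim$records, triplet_pattern("GAN"), 40,
                               "any")$members, 0)
  # unrelated strong-base pattern on a GAN-planted transcriptome: the
  # planted runs themselves never qualify
  gss <- motif_gene_set(sim$records, triplet_pattern("GSS"), 7, "cds")
  expect_length(intersect(gss$members,
                          unique(sim$truth$planted_hits$transcript_id)), 0)
})

test_that("motif discovery recovers a planted GAN repeat and calibrates", {
  sim <- simulate_transcriptome(60, length_model = list(utr5 = 0, cds = 240,
                                                        utr3 = 0),
                                plant = list(
    pattern = "GAN", run_lengths = 7L, run_length_probs = NULL,
    region_probs = c(utr5 = 0, cds = 1, utr3 = 0), in_frame_prob = 1,
    fraction = 0.5), seed = 9)
  planted <- unique(sim$truth$planted_hits$transcript_id)
  targets <- sim$records[planted]
  background <- sim$records[setdiff(names(sim$records), planted)]
  rank <- discover_repeat_motifs(targets, background, min_run = 7)
  # winner is GAN or an equally supported more specific sub-pattern of it
  top <- triplet_pattern(rank$pattern[1])
  expect_true(all(top$sets[[1]] %in% "G"))
  expect_true(all(top$sets[[2]] %in% "A"))
  expect_lt(rank$p_bonferroni[1], 0.05)

  # background == targets: no enrichment possible anywhere
  rank2 <- discover_repeat_motifs(targets, targets, min_run = 7)
  expect_true(all(rank2$p_raw == 1))
  expect_error(discover_repeat_motifs(list(), background), "empty target")
})

test_that("motif discovery stays null-calibrated on unplanted data", {
  set.seed(33)
  n_sig <- 0L
  for (rep in 1:12) {
    seqs <- vapply(1:40, function(i) random_seq(150), "")
    recs <- make_records(seqs)
    targ_idx <- sample(40, 15)
    rank <- discover_repeat_motifs(recs[targ_idx], recs[-targ_idx],
                                   min_run = 3)
    if (any(rank$p_bonferroni < 0.05)) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2L)
})
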