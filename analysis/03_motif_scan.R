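#!/usr/bin/env Rscript
# Scan the transcriptome for degenerate trinucleotide repeats: GAN hits per
# region with codon frame, the region-by-run-length count table with target
# enrichment, the codon-frame distribution, and an unbiased ranking of
# candidate triplet patterns by target enrichment.

suppressMessages(library(regulonscan))

data_dir <- "results/demo_data"
records <- read_transcripts(file.path(data_dir, "transcripts.fa"),
                            file.path(data_dir, "regions.tsv"))
targets <- read_gene_sets("results/targets.gmt")[[1]]
universe <- gene_set("universe", "all transcripts", names(records))

hits <- scan_transcripts(records, triplet_pattern("GAN"), min_run = 3)
regulonscan:::write_tsv_checked(hits, "results/hits.tsv")
cat(sprintf("GAN runs (>=3 triplets): %d in %d transcripts\n",
            nrow(hits), length(unique(hits$transcript_id))))

ct <- region_count_table(records, triplet_pattern("GAN"), 3:8,
                         gene_set(targets$name, "",
                                  intersect(targets$members,
                                            universe$members)),
                         universe)
regulonscan:::write_tsv_checked(ct, "results/table1.tsv")
cds <- ct[ct$region == "cds", ]
cat("CDS rows of the count table (k, transcripts, occurrences, targets, p):\n")
for (i in seq_len(nrow(cds)))
  cat(sprintf("  k=%d: %4d  %4d  %4d  %.3g\n", cds$k[i],
              cds$n_transcripts_with_motif[i], cds$n_motif_occurrences[i],
              cds$n_in_target_set[i], cds$enrichment_p[i]))

fd <- frame_distribution(hits[hits$region == "cds", ])
cat(sprintf("codon frame of CDS runs: frame0 %d (%g%%), frame1 %d, frame2 %d\n",
            fd$count[1], fd$percent[1], fd$count[2], fd$count[3]))

# motif-bearing gene set usable for cross-species style prediction
gs <- motif_gene_set(records, triplet_pattern("GAN"), 7, "cds")
cat(sprintf("(GAN)7-bearing CDS transcripts: %d; %d among called targets\n",
            length(gs$members),
            length(intersect(gs$members, targets$members))))

# unbiased repeat-motif discovery on the top-called targets
target_recs <- records[intersect(targets$members, names(records))]
bg_recs <- records[setdiff(names(records), targets$members)]
rank <- discover_repeat_motifs(target_recs, bg_recs, min_run = 4)
regulonscan:::write_tsv_checked(utils::head(rank, 25),
                                "results/motif_ranking.tsv")
cat(sprintf("top discovered pattern: %s (Bonferroni p = %.3g)\n",
            rank$pattern[1], rank$p_bonferroni[1]))
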