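#!/usr/bin/env Rscript
# Set-level statistics on the called targets: hypergeometric GO enrichment
# over the annotation panel, minimum-hypergeometric enrichment on the full
# SAM-ranked list (cutoff-free), and the RBP overlap panel with Bonferroni
# control.

suppressMessages(library(regulonscan))

data_dir <- "results/demo_data"
records <- read_transcripts(file.path(data_dir, "transcripts.fa"),
                            file.path(data_dir, "regions.tsv"))
go <- read_gene_sets(file.path(data_dir, "go.gmt"))
rbp <- read_gene_sets(file.path(data_dir, "rbp.gmt"))
targets <- read_gene_sets("results/targets.gmt")[[1]]
universe <- gene_set("universe", "all transcripts", names(records))
targ_u <- gene_set("targets", "", intersect(targets$members,
                                            universe$members))

res <- go_enrichment(targ_u, go, universe, min_term_size = 3)
regulonscan:::write_tsv_checked(res, "results/enrich.tsv")
cat("top GO terms by hypergeometric enrichment:\n")
top <- utils::head(res, 4)
for (i in seq_len(nrow(top)))
  cat(sprintf("  %s: %d/%d in term, p = %.3g (Bonferroni %.3g)\n",
              top$query_name[i], top$overlap_count[i], top$reference_size[i],
              top$p_raw[i], top$p_bonferroni[i]))

# cutoff-free check on the SAM ranking for the best term
sam_tab <- regulonscan:::read_tsv_checked("results/targets.tsv")
ranked <- sam_tab$feature_id[order(sam_tab$d, decreasing = TRUE)]
best <- go[[res$query_name[1]]]
mhg <- ranked_enrichment_mhg(ranked, best)
cat(sprintf(
  "mHG on the SAM-ranked list, term %s: b*=%d at n*=%d, ratio %.2f, p = %.3g\n",
  mhg$term_name, mhg$b_star, mhg$n_star, mhg$enrichment_ratio, mhg$p_exact))

ov <- overlap_matrix(targ_u, rbp, universe, min_query_size = 8)
regulonscan:::write_tsv_checked(ov, "results/overlap.tsv")
cat("RBP overlap panel (query, overlap, fraction, Bonferroni p):\n")
for (i in seq_len(nrow(ov)))
  cat(sprintf("  %s: %3d  %s  %.3g\n", ov$query_name[i], ov$overlap_count[i],
              percent_report(ov$overlap_count[i], ov$query_size[i], 1),
              ov$p_bonferroni[i]))
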