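#!/usr/bin/env Rscript
# Regulon expression analysis: how target subsets inside GO terms shift at
# the mRNA and protein level (Mann-Whitney + Welch t, box-whisker summary),
# the global mRNA-protein correlation, and target overrepresentation among
# fold-changed genes.

suppressMessages(library(regulonscan))

data_dir <- "results/demo_data"
expr <- read_expression_table(file.path(data_dir, "expression.tsv"))
targets <- read_gene_sets("results/targets.gmt")[[1]]

corr <- mrna_protein_correlation(expr)
cat(sprintf("mRNA-protein Pearson r = %.3f over %d complete pairs\n",
            corr$pearson_r, corr$n_pairs))

rows <- list()
for (term in c("GO:0000001", "GO:0000002")) for (col in c("mrna", "protein")) {
  r <- subset_shift_test(expr, term, targets, col)
  rows[[length(rows) + 1L]] <- as.data.frame(
    r[c("go_term", "value_column", "n", "median", "q1", "q3", "p10", "p90",
        "mean_log2", "mw_p_vs_all", "mw_p_vs_nontargets", "welch_p_vs_all",
        "stars", "underpowered")])
  cat(sprintf(
    "  %s / %s: n=%d, mean log2 = %+.2f, MW vs all p = %.2g (%s)\n",
    term, col, r$n, r$mean_log2, r$mw_p_vs_all, r$stars))
}
shifts <- do.call(rbind, rows)
regulonscan:::write_tsv_checked(shifts, "results/fig6.tsv")

measured <- gene_set("measured", "", expr$gene_id[!is.na(expr$mrna_log2)])
thr <- log2(1.5)
up <- gene_set("up", "", expr$gene_id[!is.na(expr$mrna_log2) &
                                        expr$mrna_log2 >= thr])
down <- gene_set("down", "", expr$gene_id[!is.na(expr$mrna_log2) &
                                            expr$mrna_log2 <= -thr])
for (set in list(up, down)) {
  if (!length(set$members)) next
  ov <- changed_set_overrepresentation(set, set$name, targets, measured)
  cat(sprintf(
    "  %s-changed mRNAs: %d, of which %d targets (%s); chi-square p = %.3g\n",
    ov$direction_label, ov$n_changed, ov$n_changed_targets,
    ov$percent_targets, ov$p))
}
cat("wrote results/fig6.tsv\n")
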