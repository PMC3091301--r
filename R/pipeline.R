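# End-to-end orchestration: load inputs, SAM target calling, motif scanning
# and the region count table, set enrichment and the RBP overlap panel, the
# regulon expression-shift analysis, and a plain-text report. All outputs are
# TSV/text, written deterministically (no timestamps), so a rerun with the
# same config and seed is byte-identical.

#' Run the full analysis pipeline
#'
#' Stages: `load` (transcripts, ratio matrix, gene sets, expression table)
#' -> `sam` (QC filter, median centering, two-class SAM, target calling)
#' -> `scan` (motif hits, region count table) -> `enrich` (GO enrichment of
#' targets, RBP overlap matrix) -> `regulon` (subset shift tests, mRNA/
#' protein correlation, changed-set overrepresentation) -> `report`.
#' A failing stage aborts with the stage name; outputs of completed stages
#' are preserved.
#'
#' @param config Named list (see [make_demo()] for a complete example) or a
#'   path to a YAML config file.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return Invisibly, a list with the principal in-memory results
#'   (`sam`, `targets`, `hits`, `count_table`, `go_enrichment`, `overlap`,
#'   `shifts`, `correlation`, `overrep`, `report_lines`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  stopifnot(!is.null(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  seed <- config$seed %||% 1L

  inputs <- stage("load", {
    for (p in unlist(config$paths))
      if (!file.exists(p)) stop(sprintf("missing input file: %s", p))
    list(records = read_transcripts(config$paths$transcripts_fasta,
                                    config$paths$regions),
         ratios = read_ratio_matrix(config$paths$ratios,
                                    config$paths$design),
         go = read_gene_sets(config$paths$go_gmt),
         rbp = read_gene_sets(config$paths$rbp_gmt),
         expr = read_expression_table(config$paths$expression))
  })
  universe <- gene_set("universe", "all assayed transcripts",
                       names(inputs$records))

  sam_out <- stage("sam", {
    filt <- filter_features(inputs$ratios,
                            snr_min = config$sam$snr_min %||% 1.8,
                            snr_channels = config$sam$snr_channels %||%
                              "input_only")
    centered <- median_center(filt$matrix)
    cfg <- sam_config(n_permutations = config$sam$permutations %||% "all",
                      side = config$sam$side %||% "positive",
                      fdr_cutoff = config$sam$fdr %||% 0.05,
                      seed = stage_seed(seed, "sam"))
    res <- sam_two_class(centered, cfg)
    calls <- call_targets(res, cfg$fdr_cutoff, name = "called_targets")
    tab <- res$features
    tab$called <- tab$feature_id %in% calls$set$members
    write_tsv_checked(tab, file.path(out_dir, "targets.tsv"))
    list(result = res, calls = calls, filter_report = filt$report)
  })
  targets <- sam_out$calls$set

  scan_out <- stage("scan", {
    pattern <- (config$scan$patterns %||% list("GAN"))[[1]]
    k_values <- config$scan$k_values %||% 3:8
    hits <- suppressWarnings(
      scan_transcripts(inputs$records, triplet_pattern(pattern),
                       min_run = min(k_values)))
    write_tsv_checked(hits, file.path(out_dir, "hits.tsv"))
    targ_u <- gene_set(targets$name, targets$description,
                       intersect(targets$members, universe$members))
    ct <- region_count_table(inputs$records, triplet_pattern(pattern),
                             k_values, targ_u, universe)
    write_tsv_checked(ct, file.path(out_dir, "table1.tsv"))
    list(hits = hits, count_table = ct, pattern = pattern)
  })

  enrich_out <- stage("enrich", {
    targ_u <- gene_set(targets$name, targets$description,
                       intersect(targets$members, universe$members))
    go <- go_enrichment(targ_u, inputs$go, universe,
                        min_term_size = config$enrichment$min_term_size %||% 3L)
    write_tsv_checked(go, file.path(out_dir, "enrich.tsv"))
    ov <- overlap_matrix(targ_u, inputs$rbp, universe,
                         min_query_size = config$enrichment$min_query_size %||%
                           8L)
    write_tsv_checked(ov, file.path(out_dir, "overlap.tsv"))
    list(go = go, overlap = ov)
  })

  regulon_out <- stage("regulon", {
    terms <- config$regulon$terms %||% names(inputs$go)
    cols <- config$regulon$value_columns %||% c("mrna", "protein")
    rows <- list()
    for (term in terms) for (col in cols) {
      r <- tryCatch(subset_shift_test(inputs$expr, term, targets, col),
                    error = function(e) NULL)
      if (!is.null(r))
        rows[[length(rows) + 1L]] <-
          as.data.frame(r[c("go_term", "value_column", "n", "median", "q1",
                            "q3", "p10", "p90", "mean_log2", "mw_p_vs_all",
                            "mw_p_vs_nontargets", "welch_p_vs_all", "stars",
                            "underpowered")])
    }
    shifts <- do.call(rbind, rows)
    write_tsv_checked(shifts, file.path(out_dir, "fig6.tsv"))
    corr <- mrna_protein_correlation(inputs$expr)
    thr <- log2(config$regulon$fold_threshold %||% 1.5)
    expr_universe <- gene_set("measured", "genes with mRNA data",
                              inputs$expr$gene_id[!is.na(inputs$expr$mrna_log2)])
    up <- gene_set("up", "mRNA up-changed",
                   inputs$expr$gene_id[!is.na(inputs$expr$mrna_log2) &
                                         inputs$expr$mrna_log2 >= thr])
    overrep <- if (length(up$members) >= 1)
      changed_set_overrepresentation(up, "up", targets, expr_universe)
      else NULL
    list(shifts = shifts, correlation = corr, overrep = overrep)
  })

  report_lines <- stage("report", {
    lines <- c(
      sprintf("targets called: %d of %d analyzed features (%s) at FDR<%g",
              sam_out$calls$n_called, sam_out$calls$n_analyzed,
              sam_out$calls$percent, config$sam$fdr %||% 0.05),
      sprintf("QC filter: %d cells masked by snr, %d features dropped",
              sam_out$filter_report$cells_masked_snr,
              sam_out$filter_report$features_dropped))
    cds_hits <- scan_out$hits[scan_out$hits$region == "cds", , drop = FALSE]
    if (nrow(cds_hits)) {
      fd <- frame_distribution(cds_hits)
      lines <- c(lines, sprintf(
        "frame 0 (first codon position): %d of %d CDS motif runs (%s)",
        fd$count[1], sum(fd$count), percent_report(fd$count[1],
                                                   sum(fd$count), 0L)))
    }
    if (!is.null(regulon_out$overrep)) {
      ov <- regulon_out$overrep
      lines <- c(lines, sprintf(
        "targets among up-changed mRNAs: %d of %d (%s), chi-square p = %.3g",
        ov$n_changed_targets, ov$n_changed, ov$percent_targets, ov$p))
    }
    lines <- c(lines, sprintf("mRNA-protein Pearson r = %.3f over %d pairs",
                              regulon_out$correlation$pearson_r,
                              regulon_out$correlation$n_pairs))
    writeLines(lines, file.path(out_dir, "report.txt"))
    lines
  })

  stage("manifest", {
    cfg_str <- yaml::as.yaml(config)
    writeLines(c(
      sprintf("package: regulonscan %s",
              as.character(utils::packageVersion("regulonscan"))),
      sprintf("seed: %d", seed),
      sprintf("config_md5: %s", config_md5(cfg_str)),
      sprintf("pattern: %s", scan_out$pattern)),
      file.path(out_dir, "manifest.txt"))
  })

  invisible(list(sam = sam_out$result, targets = targets,
                 hits = scan_out$hits, count_table = scan_out$count_table,
                 go_enrichment = enrich_out$go, overlap = enrich_out$overlap,
                 shifts = regulon_out$shifts,
                 correlation = regulon_out$correlation,
                 overrep = regulon_out$overrep,
                 report_lines = report_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_md5 <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Write a self-contained synthetic demo dataset and config
#'
#' Generates a coherent dataset exercising every stage: a transcriptome with
#' planted in-frame GAN repeats, a 3-IP vs 5-mock ratio matrix whose planted
#' targets are exactly the repeat-bearing transcripts, 20 GO terms (two of
#' them target-enriched), 5 RBP target panels with graded overlaps, and a
#' matched mRNA/protein expression table with planted GO-linked target
#' shifts (a protein-only +0.9 "motor" shift and an mRNA -0.5 repression
#' shift).
#'
#' @param dir Directory to create the dataset in.
#' @param seed Global seed (default 42); fanned out per stage via
#'   [stage_seed()].
#' @return Invisibly, the config list (also written to `config.yaml`); the
#'   ground truth is written to `truth_*.tsv` files.
#' @export
make_demo <- function(dir, seed = 42L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_tx <- 1000L
  sim_tx <- simulate_transcriptome(
    n_transcripts = n_tx,
    length_model = list(utr5 = 60, cds = 600, utr3 = 120),
    plant = list(pattern = "GAN", run_lengths = 4:9,
                 run_length_probs = NULL,
                 region_probs = c(utr5 = 0.05, cds = 0.9, utr3 = 0.05),
                 in_frame_prob = 0.9, fraction = 0.25),
    seed = stage_seed(seed, "transcriptome"))
  write_transcripts(sim_tx$records, file.path(dir, "transcripts.fa"),
                    file.path(dir, "regions.tsv"))
  ids <- names(sim_tx$records)
  planted_tx <- unique(sim_tx$truth$planted_hits$transcript_id)

  sim_rip <- simulate_ripchip(n_features = n_tx, n_ip = 3L, n_mock = 5L,
                              target_fraction = length(planted_tx) / n_tx,
                              effect_size_delta = 2, noise_sd = 0.5,
                              seed = stage_seed(seed, "ripchip"))
  # align the planted RIP targets with the repeat-bearing transcripts so the
  # downstream enrichment has signal: targets get the planted transcript ids
  rip <- sim_rip$matrix
  f_ids <- rownames(rip$log2_ratio)
  is_t <- f_ids %in% sim_rip$truth$planted_target_ids
  new_ids <- character(n_tx)
  new_ids[is_t] <- planted_tx[seq_len(sum(is_t))]
  new_ids[!is_t] <- setdiff(ids, new_ids[is_t])[seq_len(sum(!is_t))]
  for (f in c("log2_ratio", "snr1", "snr2", "regression_cor"))
    rownames(rip[[f]]) <- new_ids
  write_ratio_matrix(rip, file.path(dir, "ratios.tsv"),
                     file.path(dir, "design.tsv"))
  target_ids <- new_ids[is_t]

  go <- with_seed(stage_seed(seed, "gosets"), {
    sets <- list()
    for (i in 1:20) {
      nm <- sprintf("GO:%07d", i)
      size <- sample(15:80, 1)
      members <- if (i <= 2) {
        # two planted target-enriched terms
        c(sample(target_ids, round(0.7 * size)),
          sample(setdiff(ids, target_ids), size - round(0.7 * size)))
      } else sample(ids, size)
      sets[[nm]] <- gene_set(nm, sprintf("synthetic term %d", i),
                             unique(members))
    }
    sets
  })
  write_gene_sets(go, file.path(dir, "go.gmt"))

  rbp <- with_seed(stage_seed(seed, "rbpsets"), {
    sizes <- c(100L, 150L, 220L, 300L, 60L)
    fracs <- c(0.5, 0.3, 0.1, 0.05, 0.4)
    sets <- list()
    for (i in seq_along(sizes)) {
      k <- round(fracs[i] * sizes[i])
      sets[[sprintf("RBP%d", i)]] <- gene_set(
        sprintf("RBP%d", i), sprintf("synthetic RBP panel %d", i),
        c(sample(target_ids, k), sample(setdiff(ids, target_ids),
                                        sizes[i] - k)))
    }
    sets
  })
  write_gene_sets(rbp, file.path(dir, "rbp.gmt"))

  sim_expr <- simulate_expression(
    gene_ids = ids, go_map = go,
    target_set = gene_set("targets", "planted targets", target_ids),
    planted_shifts = list("GO:0000001" = c(mrna = -0.5, protein = -0.5),
                          "GO:0000002" = c(mrna = 0, protein = 0.9)),
    noise_sd = 0.3, protein_coverage = 0.27,
    seed = stage_seed(seed, "expression"))
  write_expression_table(sim_expr$table, file.path(dir, "expression.tsv"))

  write_tsv_checked(sim_tx$truth$planted_hits,
                    file.path(dir, "truth_planted_hits.tsv"))
  write_tsv_checked(data.frame(gene_id = target_ids),
                    file.path(dir, "truth_targets.tsv"))

  config <- list(
    seed = as.integer(seed),
    out_dir = file.path(dir, "results"),
    paths = list(transcripts_fasta = file.path(dir, "transcripts.fa"),
                 regions = file.path(dir, "regions.tsv"),
                 ratios = file.path(dir, "ratios.tsv"),
                 design = file.path(dir, "design.tsv"),
                 go_gmt = file.path(dir, "go.gmt"),
                 rbp_gmt = file.path(dir, "rbp.gmt"),
                 expression = file.path(dir, "expression.tsv")),
    sam = list(snr_min = 1.8, snr_channels = "input_only", fdr = 0.05,
               permutations = "all", side = "positive"),
    scan = list(patterns = list("GAN"), k_values = 3:8),
    enrichment = list(min_term_size = 3L, min_query_size = 8L),
    regulon = list(terms = c("GO:0000001", "GO:0000002"),
                   value_columns = c("mrna", "protein"),
                   fold_threshold = 1.5))
  yaml::write_yaml(config, file.path(dir, "config.yaml"))
  invisible(config)
}
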