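#' @keywords internal
"_PACKAGE"

# Canonical nucleotide alphabet. T and U are interchangeable on input and
# normalised to U internally; N is allowed but never matches any pattern.
CANONICAL_ALPHABET <- c("A", "C", "G", "U", "N")

#' Construct a transcript record
#'
#' A transcript record carries one spliced transcript sequence together with
#' its 5'UTR/CDS/3'UTR spans. All coordinates are 0-based half-open intervals
#' on the transcript itself (not the genome); the three spans must be ordered,
#' disjoint and jointly cover the whole sequence. UTR spans may be empty.
#'
#' @param transcript_id Single non-empty string.
#' @param sequence Nucleotide string over A,C,G,T/U,N (case-insensitive;
#'   T is normalised to U).
#' @param utr5,cds,utr3 Integer vectors `c(start, end)`, 0-based half-open.
#' @return An object of class `transcript_record` with fields
#'   `transcript_id`, `sequence`, `utr5`, `cds`, `utr3` and a logical flag
#'   `cds_non_triplet` set when the CDS length is not a positive multiple of 3
#'   (such records load, but frame analysis warns).
#' @export
transcript_record <- function(transcript_id, sequence, utr5, cds, utr3) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id))
  sequence <- normalize_sequence(sequence, transcript_id)
  spans <- list(utr5 = as.integer(utr5), cds = as.integer(cds),
                utr3 = as.integer(utr3))
  n <- nchar(sequence)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2L || anyNA(sp) || sp[1] > sp[2] || sp[1] < 0L || sp[2] > n)
      stop(sprintf("transcript '%s': invalid %s span [%s)", transcript_id, nm,
                   paste(sp, collapse = ",")))
  }
  if (!(spans$utr5[2] == spans$cds[1] && spans$cds[2] == spans$utr3[1] &&
        spans$utr5[1] == 0L && spans$utr3[2] == n))
    stop(sprintf(
      "transcript '%s': spans must be ordered utr5<cds<utr3 and cover [0,%d)",
      transcript_id, n))
  cds_len <- spans$cds[2] - spans$cds[1]
  rec <- list(transcript_id = transcript_id, sequence = sequence,
              utr5 = spans$utr5, cds = spans$cds, utr3 = spans$utr3,
              cds_non_triplet = (cds_len == 0L || cds_len %% 3L != 0L))
  class(rec) <- "transcript_record"
  rec
}

normalize_sequence <- function(sequence, id = "<seq>") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("t", "u", tolower(sequence))
  s <- toupper(s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), CANONICAL_ALPHABET)
  if (length(bad))
    stop(sprintf("transcript '%s': disallowed characters: %s", id,
                 paste(bad, collapse = ",")))
  s
}

#' Extract a region subsequence from a transcript record
#' @param record A `transcript_record`.
#' @param region One of `"utr5"`, `"cds"`, `"utr3"`.
#' @return The region's sequence (possibly empty string).
#' @export
region_sequence <- function(record, region = c("utr5", "cds", "utr3")) {
  region <- match.arg(region)
  sp <- record[[region]]
  if (sp[2] == sp[1]) return("")
  substr(record$sequence, sp[1] + 1L, sp[2])
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record %s: %d nt; utr5 %d, cds %d, utr3 %d%s>\n",
              x$transcript_id, nchar(x$sequence),
              x$utr5[2] - x$utr5[1], x$cds[2] - x$cds[1], x$utr3[2] - x$utr3[1],
              if (x$cds_non_triplet) "; non-triplet CDS" else ""))
  invisible(x)
}

#' Construct a gene set
#'
#' @param name Non-empty set name.
#' @param description Free-text description (may be empty).
#' @param members Character vector of member identifiers; duplicates are
#'   collapsed with a warning.
#' @return Object of class `gene_set` with unique `members`.
#' @export
gene_set <- function(name, description = "", members = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warning(sprintf("gene set '%s': duplicate members collapsed", name))
    members <- unique(members)
  }
  structure(list(name = name, description = description, members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set %s: %d members>\n", x$name, length(x$members)))
  invisible(x)
}

# ---- sentinel-protected TSV dialect ---------------------------------------
# All tabular files the pipeline writes are UTF-8, tab-delimited, with a
# header row, '#' comment lines and a final '#eof' sentinel so that partial
# (truncated) files are always rejected rather than silently half-loaded.

write_tsv_checked <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  writeLines("#eof", con)
  invisible(path)
}

read_tsv_checked <- function(path, colClasses = NA) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop(sprintf("empty file: %s", path))
  if (lines[length(lines)] != "#eof")
    stop(sprintf("file '%s' is truncated or foreign: missing '#eof' sentinel",
                 path))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("file '%s' has no header row", path))
  # field count via tab count (strsplit would drop trailing empty fields)
  nfield <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  ncol_header <- nfield[1]
  if (any(nfield != ncol_header))
    stop(sprintf("file '%s': ragged row(s) at line %s", path,
                 paste(which(nfield != ncol_header), collapse = ",")))
  utils::read.delim(text = lines, sep = "\t", header = TRUE,
                    na.strings = "", colClasses = colClasses,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

# ---- transcripts -----------------------------------------------------------

#' Read transcripts from FASTA plus a region-coordinate table
#'
#' The FASTA file holds the spliced transcript sequences; the regions TSV has
#' columns `transcript_id, utr5_start, utr5_end, cds_start, cds_end,
#' utr3_start, utr3_end` (0-based half-open). Identifiers must match between
#' the two files; any id present in only one of them is an error (this is also
#' what makes truncated inputs detectable).
#'
#' @param fasta_path Path to the FASTA file.
#' @param regions_path Path to the regions TSV.
#' @return Named list of [transcript_record()] objects.
#' @export
read_transcripts <- function(fasta_path, regions_path) {
  if (!file.exists(fasta_path)) stop(sprintf("file not found: %s", fasta_path))
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (!length(seqs)) stop(sprintf("empty FASTA file: %s", fasta_path))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ",")))
  reg <- read_tsv_checked(regions_path)
  needed <- c("transcript_id", "utr5_start", "utr5_end", "cds_start",
              "cds_end", "utr3_start", "utr3_end")
  if (!all(needed %in% names(reg)))
    stop(sprintf("regions table missing column(s): %s",
                 paste(setdiff(needed, names(reg)), collapse = ",")))
  miss_fa <- setdiff(reg$transcript_id, ids)
  miss_rg <- setdiff(ids, reg$transcript_id)
  if (length(miss_fa) || length(miss_rg))
    stop(sprintf(
      "transcript ids do not match: %d missing from FASTA (%s), %d missing from regions (%s)",
      length(miss_fa), paste(utils::head(miss_fa, 3), collapse = ","),
      length(miss_rg), paste(utils::head(miss_rg, 3), collapse = ",")))
  reg <- reg[match(ids, reg$transcript_id), ]
  recs <- lapply(seq_along(ids), function(i) {
    transcript_record(ids[i], as.character(seqs[[i]]),
                      utr5 = c(reg$utr5_start[i], reg$utr5_end[i]),
                      cds = c(reg$cds_start[i], reg$cds_end[i]),
                      utr3 = c(reg$utr3_start[i], reg$utr3_end[i]))
  })
  names(recs) <- ids
  recs
}

#' Write transcripts to FASTA plus a region-coordinate table
#' @param records List of [transcript_record()] objects.
#' @param fasta_path,regions_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcripts <- function(records, fasta_path, regions_path) {
  stopifnot(length(records) > 0)
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  reg <- data.frame(
    transcript_id = names(seqs),
    utr5_start = vapply(records, function(r) r$utr5[1], 0L),
    utr5_end = vapply(records, function(r) r$utr5[2], 0L),
    cds_start = vapply(records, function(r) r$cds[1], 0L),
    cds_end = vapply(records, function(r) r$cds[2], 0L),
    utr3_start = vapply(records, function(r) r$utr3[1], 0L),
    utr3_end = vapply(records, function(r) r$utr3[2], 0L))
  write_tsv_checked(reg, regions_path)
  invisible(c(fasta_path, regions_path))
}

# ---- gene sets (GMT dialect) ----------------------------------------------

#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member TAB ...`.
#' Lines starting with `#` are comments; files written by [write_gene_sets()]
#' end with a `#eof` sentinel which, when present, is required to be intact
#' (protects against truncation).
#'
#' @param gmt_path Path to the GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(gmt_path) {
  if (!file.exists(gmt_path)) stop(sprintf("file not found: %s", gmt_path))
  lines <- readLines(gmt_path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop(sprintf("empty GMT file: %s", gmt_path))
  if (lines[length(lines)] != "#eof")
    stop(sprintf("file '%s' is truncated: missing '#eof' sentinel", gmt_path))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stop(sprintf("GMT file '%s' contains no sets", gmt_path))
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || !nzchar(f[1]))
      stop(sprintf("malformed GMT line %d in '%s'", i, gmt_path))
    gene_set(f[1], f[2], f[-(1:2)])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of [gene_set()] objects.
#' @param gmt_path Output path.
#' @export
write_gene_sets <- function(sets, gmt_path) {
  stopifnot(length(sets) > 0)
  lines <- vapply(sets, function(s) {
    if (!length(s$members)) stop(sprintf("gene set '%s' is empty", s$name))
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(c(lines, "#eof"), gmt_path, useBytes = TRUE)
  invisible(gmt_path)
}

# ---- ratio matrices --------------------------------------------------------

#' Construct a two-class log2 ratio matrix
#'
#' Container for features-by-arrays log2 ratios with per-cell quality metrics
#' and a two-class array design, as produced by two-color arrays (IP vs mock,
#' or treated vs control). Missing cells stay `NA`; they are never imputed.
#'
#' @param log2_ratio Numeric matrix, rows = features (rownames required),
#'   columns = arrays (colnames required). `NA` marks missing cells.
#' @param class_label Character vector (one per array) with exactly two
#'   distinct values, e.g. `"IP"`/`"mock"`.
#' @param snr1,snr2 Non-negative matrices, signal over background for channel
#'   1 (total-RNA/input channel) and channel 2; same shape as `log2_ratio`.
#' @param regression_cor Matrix of per-cell regression correlations in
#'   \[-1, 1\]; same shape.
#' @return Object of class `ratio_matrix`.
#' @export
ratio_matrix <- function(log2_ratio, class_label,
                         snr1 = NULL, snr2 = NULL, regression_cor = NULL) {
  stopifnot(is.matrix(log2_ratio), !is.null(rownames(log2_ratio)),
            !is.null(colnames(log2_ratio)))
  if (length(class_label) != ncol(log2_ratio))
    stop("class_label must have one entry per array")
  classes <- unique(class_label)
  if (length(classes) != 2L)
    stop(sprintf("class labels must cover exactly two classes, got: %s",
                 paste(classes, collapse = ",")))
  counts <- table(class_label)
  if (any(counts < 2L))
    warning(sprintf("class '%s' has fewer than 2 arrays; SAM will refuse",
                    names(counts)[which.min(counts)]))
  shape_ok <- function(m) is.null(m) ||
    (is.matrix(m) && all(dim(m) == dim(log2_ratio)))
  if (!shape_ok(snr1) || !shape_ok(snr2) || !shape_ok(regression_cor))
    stop("QC matrices must match the ratio matrix dimensions")
  fill <- function(m, default) {
    if (is.null(m)) m <- matrix(default, nrow(log2_ratio), ncol(log2_ratio))
    dimnames(m) <- dimnames(log2_ratio)
    m
  }
  structure(list(log2_ratio = log2_ratio,
                 class_label = stats::setNames(as.character(class_label),
                                               colnames(log2_ratio)),
                 snr1 = fill(snr1, Inf), snr2 = fill(snr2, Inf),
                 regression_cor = fill(regression_cor, 0)),
            class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  tab <- table(x$class_label)
  cat(sprintf("<ratio_matrix: %d features x %d arrays (%s); %d missing cells>\n",
              nrow(x$log2_ratio), ncol(x$log2_ratio),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              sum(is.na(x$log2_ratio))))
  invisible(x)
}

#' Read a ratio matrix from data and design TSVs
#'
#' The data TSV has one feature per row with columns `feature_id`, then for
#' each array four columns `<array>.log2`, `<array>.snr1`, `<array>.snr2`,
#' `<array>.regcor`. The design TSV maps `array_id` to `class`. Arrays present
#' in one file but not the other are an error. Missing ratio cells are empty
#' fields and stay missing.
#'
#' @param tsv_path,design_path Paths to the data and design tables.
#' @return A [ratio_matrix()].
#' @export
read_ratio_matrix <- function(tsv_path, design_path) {
  design <- read_tsv_checked(design_path)
  if (!all(c("array_id", "class") %in% names(design)))
    stop("design file must have columns array_id, class")
  if (anyDuplicated(design$array_id)) stop("duplicate array_id in design")
  if (length(unique(design$class)) != 2L)
    stop(sprintf("design must define exactly two classes, got: %s",
                 paste(unique(design$class), collapse = ",")))
  dat <- read_tsv_checked(tsv_path)
  if (names(dat)[1] != "feature_id") stop("first data column must be feature_id")
  suffixes <- c("log2", "snr1", "snr2", "regcor")
  cols <- names(dat)[-1]
  arr <- unique(sub("\\.(log2|snr1|snr2|regcor)$", "", cols))
  expected <- as.vector(outer(arr, suffixes, function(a, s) paste0(a, ".", s)))
  if (!setequal(cols, expected))
    stop("data columns must be <array>.{log2,snr1,snr2,regcor} for each array")
  extra <- setdiff(arr, design$array_id)
  missing <- setdiff(design$array_id, arr)
  if (length(extra))
    stop(sprintf("array(s) in data but not in design: %s",
                 paste(extra, collapse = ",")))
  if (length(missing))
    stop(sprintf("array(s) in design but not in data: %s",
                 paste(missing, collapse = ",")))
  arr <- design$array_id
  get <- function(sfx) {
    m <- as.matrix(dat[paste0(arr, ".", sfx)])
    dimnames(m) <- list(dat$feature_id, arr)
    storage.mode(m) <- "double"
    m
  }
  ratio_matrix(get("log2"),
               class_label = design$class,
               snr1 = get("snr1"), snr2 = get("snr2"),
               regression_cor = get("regcor"))
}

#' Write a ratio matrix to data and design TSVs
#' @param x A [ratio_matrix()].
#' @param tsv_path,design_path Output paths.
#' @export
write_ratio_matrix <- function(x, tsv_path, design_path) {
  stopifnot(inherits(x, "ratio_matrix"))
  arr <- colnames(x$log2_ratio)
  out <- data.frame(feature_id = rownames(x$log2_ratio))
  for (a in arr) {
    out[[paste0(a, ".log2")]] <- x$log2_ratio[, a]
    out[[paste0(a, ".snr1")]] <- x$snr1[, a]
    out[[paste0(a, ".snr2")]] <- x$snr2[, a]
    out[[paste0(a, ".regcor")]] <- x$regression_cor[, a]
  }
  write_tsv_checked(out, tsv_path)
  write_tsv_checked(data.frame(array_id = arr, class = unname(x$class_label)),
                    design_path)
  invisible(c(tsv_path, design_path))
}

# ---- expression tables -----------------------------------------------------

#' Construct an expression table
#'
#' Per-gene mRNA and protein log2 ratios with target membership and GO
#' annotations; the input to the regulon expression-shift analysis.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param mrna_log2,protein_log2 Numeric vectors (NA = not measured); each
#'   gene needs at least one of the two.
#' @param is_target Logical vector.
#' @param annotations List of character vectors of GO term ids (one per gene).
#' @return A data.frame of class `expression_table` with a list-column
#'   `annotations`.
#' @export
expression_table <- function(gene_id, mrna_log2 = NA_real_,
                             protein_log2 = NA_real_, is_target = FALSE,
                             annotations = NULL) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  mrna_log2 <- rep_len(as.numeric(mrna_log2), n)
  protein_log2 <- rep_len(as.numeric(protein_log2), n)
  is_target <- rep_len(as.logical(is_target), n)
  if (is.null(annotations)) annotations <- rep(list(character()), n)
  if (length(annotations) != n) stop("annotations must have one entry per gene")
  if (any(is.na(mrna_log2) & is.na(protein_log2)))
    stop("each gene needs at least one of mrna_log2/protein_log2")
  df <- data.frame(gene_id = as.character(gene_id), mrna_log2 = mrna_log2,
                   protein_log2 = protein_log2, is_target = is_target,
                   stringsAsFactors = FALSE)
  df$annotations <- lapply(annotations, as.character)
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Read an expression table from TSV
#'
#' Columns: `gene_id, mrna_log2, protein_log2, is_target, annotations` with
#' annotations as a `;`-separated GO-id list (possibly empty).
#' @param tsv_path Path.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(tsv_path) {
  dat <- read_tsv_checked(tsv_path)
  needed <- c("gene_id", "mrna_log2", "protein_log2", "is_target", "annotations")
  if (!all(needed %in% names(dat)))
    stop(sprintf("expression table missing column(s): %s",
                 paste(setdiff(needed, names(dat)), collapse = ",")))
  ann <- strsplit(ifelse(is.na(dat$annotations), "", dat$annotations), ";",
                  fixed = TRUE)
  ann <- lapply(ann, function(a) a[nzchar(a)])
  expression_table(dat$gene_id, dat$mrna_log2, dat$protein_log2,
                   as.logical(dat$is_target), ann)
}

#' Write an expression table to TSV
#' @param x An [expression_table()].
#' @param tsv_path Output path.
#' @export
write_expression_table <- function(x, tsv_path) {
  out <- data.frame(gene_id = x$gene_id, mrna_log2 = x$mrna_log2,
                    protein_log2 = x$protein_log2, is_target = x$is_target,
                    annotations = vapply(x$annotations, paste, "",
                                         collapse = ";"))
  write_tsv_checked(out, tsv_path)
  invisible(tsv_path)
}
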