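# Expression-shift analysis of target subsets within GO terms: two-sided
# Mann-Whitney (exact for small groups, tie-corrected normal approximation
# with continuity correction otherwise) and Welch-t comparisons of the
# targets-in-term subset against all measured features and against the
# non-target members of the term; mRNA-protein correlation; chi-square
# overrepresentation of targets among changed genes; and the percent
# reporting convention used throughout.

#' Format a percentage the way the results are printed
#'
#' 100 * numerator / denominator, rounded half away from zero to `decimals`
#' places, with a percent sign.
#'
#' @param numerator,denominator Non-negative integers, numerator <=
#'   denominator, denominator > 0.
#' @param decimals Decimal places (default 0).
#' @return A string such as `"13.6%"`.
#' @export
percent_report <- function(numerator, denominator, decimals = 0L) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must be in [0, denominator]")
  sprintf(paste0("%.", decimals, "f%%"),
          round_half_away(100 * numerator / denominator, decimals))
}

#' Distribution summary used for the box-and-whisker panels
#'
#' Median, quartiles, 10th/90th percentiles (whisker convention) and mean.
#' Percentiles use linear interpolation between order statistics (inclusive,
#' [stats::quantile()] type 7).
#'
#' @param values Numeric vector with at least one non-missing value.
#' @return Named list: `median`, `q1`, `q3`, `p10`, `p90`, `mean`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values")
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                       names = FALSE)
  list(median = q[3], q1 = q[2], q3 = q[4], p10 = q[1], p90 = q[5],
       mean = mean(values))
}

# significance stars; boundary values fall to the weaker category
p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

# two-sided Mann-Whitney: exact enumeration when both groups <= 8 and no
# ties, else normal approximation with tie correction and 0.5 continuity
# correction (stats::wilcox.test implements exactly this pair of paths)
mann_whitney_p <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = TRUE)$p.value)
}

#' Expression shift of the target subset within one GO term
#'
#' Compares the chosen log2 value column for targets annotated to the term
#' against (a) all measured features (inclusive background by default, the
#' global reference distribution) and (b) the non-target members of the same
#' term, with a two-sided Mann-Whitney test and a Welch t companion. Returns
#' the whisker-convention summary statistics and a star label driven by the
#' vs-all Mann-Whitney p.
#'
#' @param table An [expression_table()].
#' @param go_term GO term id; must occur in the table's annotations.
#' @param target_set A [gene_set()] of target genes.
#' @param value_column `"mrna"` or `"protein"`.
#' @param background `"inclusive"` (subset kept in the all-features
#'   reference) or `"exclusive"`.
#' @return List with `go_term`, `value_column`, `n`, summary percentiles,
#'   `mean_log2`, `mw_p_vs_all`, `mw_p_vs_nontargets`, `welch_p_vs_all`,
#'   `stars`, and `underpowered` (TRUE when the subset has < 3 values).
#' @export
subset_shift_test <- function(table, go_term, target_set,
                              value_column = c("mrna", "protein"),
                              background = c("inclusive", "exclusive")) {
  value_column <- match.arg(value_column)
  background <- match.arg(background)
  in_term <- vapply(table$annotations, function(a) go_term %in% a, TRUE)
  if (!any(in_term))
    stop(sprintf("GO term '%s' absent from the table annotations", go_term))
  vals <- if (value_column == "mrna") table$mrna_log2 else table$protein_log2
  is_target <- table$gene_id %in% target_set$members
  sub <- vals[in_term & is_target & !is.na(vals)]
  nont <- vals[in_term & !is_target & !is.na(vals)]
  all_vals <- if (background == "inclusive") vals[!is.na(vals)] else
    vals[!(in_term & is_target) & !is.na(vals)]
  underpowered <- length(sub) < 3
  if (!length(sub))
    stop(sprintf("no measured %s values for targets in term '%s'",
                 value_column, go_term))
  mw_all <- mann_whitney_p(sub, all_vals)
  mw_nt <- mann_whitney_p(sub, nont)
  welch <- if (length(sub) >= 2 && length(all_vals) >= 2 &&
               (stats::sd(sub) > 0 || stats::sd(all_vals) > 0))
    stats::t.test(sub, all_vals, var.equal = FALSE)$p.value else NA_real_
  c(list(go_term = go_term, value_column = value_column, n = length(sub)),
    boxplot_summary(sub),
    list(mean_log2 = mean(sub), mw_p_vs_all = mw_all,
         mw_p_vs_nontargets = mw_nt, welch_p_vs_all = welch,
         stars = p_stars(mw_all), underpowered = underpowered))
}

#' Pearson correlation between mRNA and protein changes
#'
#' Computed over genes with both values present only.
#'
#' @param table An [expression_table()].
#' @return List with `n_pairs` and `pearson_r`.
#' @export
mrna_protein_correlation <- function(table) {
  ok <- !is.na(table$mrna_log2) & !is.na(table$protein_log2)
  if (sum(ok) < 3) stop("need at least 3 complete mRNA/protein pairs")
  list(n_pairs = sum(ok),
       pearson_r = stats::cor(table$mrna_log2[ok], table$protein_log2[ok],
                              method = "pearson"))
}

#' Overrepresentation of targets among changed genes
#'
#' Builds the 2x2 table (changed vs not) x (target vs not) over the stated
#' universe and tests association with the Pearson chi-square (Fisher exact
#' as companion). Also reports the integer percent of targets among the
#' changed genes.
#'
#' @param changed A [gene_set()] of changed genes (subset of the universe).
#' @param direction_label Label carried through (e.g. `"up"`).
#' @param target_set,universe [gene_set()] objects.
#' @return List with `direction_label`, `n_changed`, `n_changed_targets`,
#'   `percent_targets`, `table`, `statistic`, `p`, `fisher_p`.
#' @export
changed_set_overrepresentation <- function(changed, direction_label,
                                           target_set, universe) {
  if (!all(changed$members %in% universe$members))
    stop("changed set must be a subset of the universe")
  targ <- intersect(target_set$members, universe$members)
  a <- length(intersect(changed$members, targ))
  b <- length(changed$members) - a
  c_ <- length(targ) - a
  d <- length(universe$members) - a - b - c_
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(changed = c("yes", "no"),
                                target = c("yes", "no")))
  ch <- chi_square_2x2(tab)
  list(direction_label = direction_label, n_changed = length(changed$members),
       n_changed_targets = a,
       percent_targets = percent_report(a, length(changed$members), 0L),
       table = tab, statistic = ch$statistic, p = ch$p,
       fisher_p = ch$fisher_p)
}
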