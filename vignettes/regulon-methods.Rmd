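---
title: "Methods: from RIP-chip ratios to an RNA regulon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RIP-chip ratios to an RNA regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscan)
```

This vignette explains the statistical machinery of the package, the
assumptions behind it, the choices we made where the methods literature
leaves room, and what the synthetic-data tests do and do not establish
about real data.

## The data model

A RIP-chip experiment compares RNA co-purifying with a tagged RNA-binding
protein (IP arrays) against mock isolations from untagged cells, on
two-color arrays whose per-feature log2 median ratios measure relative
enrichment. The canonical design here is 3 IP vs 5 mock arrays. Every
downstream sequence statement lives on spliced transcript coordinates:
each transcript is a sequence over A,C,G,U,N partitioned into 5'UTR, CDS
and 3'UTR spans (0-based, half-open, jointly covering the sequence; UTRs
may be empty). T and U are interchangeable on input; only the sense strand
is ever scanned. Missing ratio cells stay missing — nothing is imputed at
IO time.

## Target calling: SAM with permutation FDR

Features are first QC-filtered: a RIP cell is kept only when signal over
background exceeds 1.8 in the channel measuring total (input) RNA;
expression-profiling data instead require > 1.5 in both channels plus the
per-spot regression-correlation rule. A feature must keep at least two
cells per class or it is dropped. Arrays are then median-centered
(idempotent; medians over present cells).

The per-feature statistic is the moderated relative difference
$d_i = (\bar{x}_{i1} - \bar{x}_{i2}) / (s_i + s_0)$ with $s_i$ the pooled
two-sample standard error. The fudge factor $s_0$ guards against small-
variance features dominating the ranking; it is chosen by the standard
percentile search — candidates at every 5th percentile of $\{s_i\}$,
picking the one that minimises the coefficient of variation of window-wise
median absolute deviations of $d$ across 100 $s$-quantile windows — or can
be fixed (the fixed mode is what the enumeration oracles in the tests
use, so the permutation machinery is checked independently of the search).

Significance comes from permuting class labels. With $n$ arrays and $n_1$
in class 1 there are $\binom{n}{n_1}$ distinct assignments (56 for 3 vs 5);
all are enumerated whenever that count does not exceed the requested
permutation number, otherwise assignments are sampled under the configured
seed. With calling thresholds taken at the observed $d$ values themselves
(ties share one threshold, processed in decreasing order), the FDR at a
threshold is $\pi_0 \times$ (mean permuted call count)/(observed call
count), where $\pi_0 = \min(1, \#\{d_i \in \text{central permuted 50%}\} /
(0.5 m))$; a feature's q-value is the minimum FDR over thresholds at which
it is called, which makes q monotone in $d$ on the called side. Calling is
one-sided positive by default — an affinity experiment enriches targets,
it does not deplete them — with two-sided and negative modes available.
Features with missing cells use per-class present-value statistics;
permuted assignments that empty a class for some feature contribute no
permuted call for it.

Differential expression from replicate log2 ratios uses the two-rule
convention: called up (down) only when the mean is at or beyond
$\pm\log_2 1.5 = \pm 0.585$ **and** the two-sided one-sample t-test gives
p < 0.05. Genes with zero replicate variance have no defined t statistic;
they are flagged degenerate and never called, avoiding p = 0 artifacts on
constant replicates.

## Repeat scanning and codon frame

A triplet pattern is three IUPAC codes (GAN, GWW, GSS, ...). A *maximal
run* is a stretch of consecutive matching triplets, stride 3, that cannot
be extended by one triplet on either side *in the same phase*; runs may
start at any offset, and overlapping runs in different phases are reported
separately (phase-agnostic matching without double-counting within a
phase). N in a sequence matches nothing; N in a pattern matches any real
base. Regions are scanned independently, so a repeat spanning a region
junction is reported as its within-region parts — each motif belongs to
exactly one region. CDS hits carry frame = start mod 3, with 0 meaning the
run is aligned with codon boundaries ("first codon position").

Counting convention for the region × run-length table: one maximal run of
$L$ triplets counts once in every row $k \le L$, for both the occurrence
count and the transcript count. This reconciles the two counting units a
reader meets in such tables (occurrences ≥ transcripts, both monotone
non-increasing in $k$). Target enrichment per row is the upper-tail
hypergeometric probability over an explicitly supplied universe.

The motif-discovery stand-in scores *every* degenerate triplet over a
configurable code alphabet (default $\{A,C,G,U,W,S,R,Y,N\}^3$ minus NNN,
728 candidates) by hypergeometric enrichment of pattern-bearing transcripts
among targets, ranking by p with ties broken toward fewer degenerate
positions, then lexicographically. It is exhaustive rather than heuristic:
for a triplet-repeat hypothesis the candidate space is small enough that
nothing needs EM.

## Set statistics

Every enrichment test takes its universe as an explicit argument — the
background population is an analysis decision (annotation versions differ),
never something to infer silently. Tails are computed through
`stats::phyper`, which works in log space, so $p \sim 10^{-300}$ is
reported rather than floored to zero. The overlap panel across many RBP
target sets keeps queries with at least 8 members and applies Bonferroni
across retained queries (Bonferroni, not BH, to match the conservative
convention for that panel; BH can be applied downstream if wanted).

For cutoff-free enrichment on a ranked list we use the minimum
hypergeometric (mHG) statistic: the minimum over all prefixes $n$ of the
upper hypergeometric tail of the term count $b(n)$. Its exact p-value is
the probability that a uniformly random placement of the $B$ term genes
attains a prefix tail at or below the observed minimum, computed by the
standard path-counting dynamic program over the $B \times (N-B)$ lattice
with rejected cells zeroed — $O(NB)$ time, used up to $N = 2000$ — and by
at least 10,000 seeded permutations beyond. Two numerical points worth
stating: mathematically equal tails reached at different lattice cells can
differ in their last floating-point bits, so the rejection region uses a
relative tie tolerance of $10^{-9}$ (ties are "as extreme" and belong
inside); and the result is clamped to the provable envelope
$\text{mHG} \le p \le \min(1, N \cdot \text{mHG})$.

## Regulon expression shifts

The question is not whether targets move globally (they typically do not;
mRNA and protein changes are nearly uncorrelated in this kind of
short-induction design) but whether *functionally coherent subsets* of
targets move. For a GO term and a value column (mRNA or protein), the
targets-in-term values are compared against all measured features and
against the non-target term members, with a two-sided Mann-Whitney test
and a Welch t companion. The Mann-Whitney variant is exact enumeration
when both groups have ≤ 8 values and no ties — the regime of the small
protein subsets this analysis cares about — and otherwise the normal
approximation with tie correction and 0.5 continuity correction.
Summaries follow the box-whisker convention (median, quartiles, and
10th/90th percentiles as whiskers), with percentiles by inclusive linear
interpolation between order statistics (type 7); stated explicitly because
p10/p90 on n = 3 is convention-sensitive. Stars map p < 0.001/0.01/0.05 to
***/**/*, with boundary values assigned to the weaker category (p = 0.05
is "ns").

The "vs all features" background *includes* the tested subset, mirroring
the convention of comparing a subset against the global reference
distribution; an exclusive mode exists. The inclusive comparison is
conservative under the null (the subset is part of its own reference), and
the tests quantify this: the independent-groups comparison against
non-target term members holds type-I error at the nominal 5%, while the
inclusive vs-all comparison sits below it. Printed percentages round half
away from zero (so 12.5% prints as 13%), the convention that reproduces
every printed share in this literature, e.g. 1,102/8,132 → 13.6% and
416/446 → 93%.

## The synthetic generators: what they emulate, and what not

The generators produce data with the *structure* the analysis assumes,
plus exact ground truth:

- `simulate_transcriptome()` — i.i.d. uniform background sequence with one
  planted repeat run per selected transcript: region drawn from stated
  probabilities, in-frame with stated probability when in the CDS, and a
  run-breaking base written into the adjacent same-phase triplet on both
  sides so the planted run is maximal and its recorded length exact. The
  uniform background is deliberate: it makes chance-run rates analytically
  checkable (a GAN triplet matches a random triplet with probability 1/16,
  so chance runs of ≥ 7 are vanishingly rare and planted-hit recovery can
  be asserted exactly).
- `simulate_ripchip()` — Normal(0, σ) ratios, targets shifted by +δ on the
  IP arrays only, per-cell signal/background drawn from a stated model
  (default lognormal, median 5, leaving ~2% of cells below the 1.8
  filter). Normality of array noise is an assumption of the generator, not
  a claim about real arrays.
- `simulate_expression()` — Normal baseline for mRNA and (for a stated
  coverage fraction, e.g. the 27% protein coverage typical of qMS) protein,
  with shifts added to GO-term members that are *also* targets
  (target-specific regulation) or, optionally, to whole terms — both
  regimes are needed to test the target-vs-non-target contrast.
- `simulate_geneset_overlap()` — exact planted overlap counts between a
  reference set and query panels.

Every draw flows from the single seed argument through one saved-and-
restored RNG scope, and per-stage seeds are fanned out by hashing stage
names, so adding a stage never perturbs another stage's stream.

What the generators do **not** emulate: codon usage and GC content,
dye-bias or spatial array artifacts, correlated noise between arrays,
mRNA-protein coupling, or GO-term overlap structure. Passing tests
therefore demonstrate that the machinery is correct and calibrated under
its stated model — recall on planted targets, exact FDR behaviour under
the null, exact repeat recovery — not that real arrays meet those
assumptions.

## Problem sizes and numerical choices

The bundled study design uses 1,000 transcripts / 1,000 features with 250
planted targets, 3 IP vs 5 mock arrays (+2 log2 effect, noise sd 0.5), 20
GO terms and 5 RBP panels; null calibration uses 100–200 delta-zero
datasets of 300 features and 500 expression-null seeds; frame-bias
recovery uses 2,000 planted runs. These sizes give Monte-Carlo error well
inside the asserted tolerances while keeping a full run in minutes on one
CPU. Degenerate inputs are handled explicitly rather than silently:
all-missing arrays, all-zero variance with s₀ = 0, empty gene sets,
zero-variance replicate sets, sub-3-member shift subsets (flagged
underpowered), and infeasible planted overlaps all raise or flag.

## Known limitations

- SAM here implements the standard percentile-search s₀ and central-
  quantile π₀ estimator; other SAM builds differ in s₀ details, so exact
  q-values can differ across implementations even on identical input
  (rankings are far more stable).
- The scanner's per-region independence means a repeat genuinely spanning
  an annotated junction is undercounted by design.
- The mHG exact DP is quadratic; beyond N = 2000 the permutation fallback
  trades exactness for a seeded Monte-Carlo estimate with add-one
  correction.
- The one-sided positive default for target calling reflects the
  enrichment design; analyses of depletion must opt into the other sides.
- GO annotations are taken as given (no true-path propagation); supplying
  pre-propagated sets is the caller's responsibility.
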