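# regulonscan

An R package and analysis workflow for defining the **RNA regulon** of an
RNA-binding protein (RBP) from RIP-chip data and downstream sequence and
expression evidence. It covers the full chain that turns two-color array
ratios into a regulon description:

1. **Target calling (SAM).** From a features × arrays matrix of
   log2(IP/input) ratios with an IP class and a mock-control class, each
   feature gets the moderated relative difference

   d = (x̄₁ − x̄₂) / (s + s₀)

   with *s* the pooled two-sample standard error and *s₀* a fudge factor
   chosen by percentile search. q-values (FDRs) come from permutation of the
   class labels — all C(8,3) = 56 distinct assignments are enumerated for the
   canonical 3-vs-5 design — with the FDR at a threshold estimated as
   π₀ · (mean permuted calls)/(observed calls). Features with q < 0.05 are
   called targets. Upstream: per-cell QC filtering (signal/background > 1.8
   in the input channel for RIP data; > 1.5 in both channels plus a
   regression-correlation rule for expression data) and per-array median
   centering. A 1.5-fold / one-sample-t (p < 0.05) rule calls differential
   expression from replicate log2 ratios.

2. **Degenerate trinucleotide-repeat scanning.** Maximal runs of IUPAC
   triplet patterns such as GAN or GWW (W = A/U) are found at every phase
   offset in the 5'UTR, CDS and 3'UTR of each transcript independently. CDS
   hits carry their codon frame (start mod 3; 0 = first codon position).
   Region × run-length count tables with hypergeometric target enrichment,
   frame distributions, motif-bearing gene sets, and an exhaustive
   enrichment ranking over all degenerate triplets (a motif-discovery
   stand-in) build on the scanner.

3. **Set statistics.** Upper-tail hypergeometric overlap tests with an
   always-explicit universe, Bonferroni control, GO-term enrichment over an
   annotation map, an RBP-panel overlap matrix, and exact
   minimum-hypergeometric (mHG) enrichment on ranked lists: the mHG
   statistic is min over prefixes n of P(X ≥ b(n)), its exact p-value
   computed by the path-counting dynamic program; the enrichment ratio
   (b/n)/(B/N) is reported at the optimal prefix.

4. **Regulon expression shifts.** For matched mRNA/protein log2-ratio
   tables: Mann-Whitney (exact for small groups, tie- and
   continuity-corrected otherwise) and Welch-t comparisons of
   targets-within-a-GO-term against all measured features and against
   non-target term members, 10th/90th-percentile whisker summaries, Pearson
   mRNA-protein correlation over complete pairs, and chi-square
   overrepresentation of targets among fold-changed genes.

Because real RIP-chip data needs external downloads, the package ships
**seeded synthetic generators** with exact ground truth (planted targets,
planted in-frame repeats with run-breaking flanks, planted GO-linked
expression shifts, exact planted set overlaps), so every stage is testable
end to end.

## Worked example

The numbered scripts under `analysis/` run the whole study on the bundled
synthetic design (seed 42): `Rscript analysis/01_simulate.R` through
`analysis/05_regulon.R`. Script 02 prints, for the planted 3-vs-5 design
with 250 true targets among 1,000 features:

```
SAM: 56 permutations, s0 = 0.732, pi0 = 0.738
targets: 244 of 1000 analyzed features (24.4%) at FDR<5%
planted-truth recovery: recall 0.976, precision 1.000
```

i.e. SAM recovers 97.6% of the planted targets with no false calls at this
effect size (+2 log2 units, noise sd 0.5). Script 03 then finds the planted
repeat motif without being told it:

```
codon frame of CDS runs: frame0 246 (70%), frame1 51, frame2 52
top discovered pattern: GAN (Bonferroni p = 5.58e-215)
```

(the 70% in-frame share at minimum run length 3 mixes the 90%-in-frame
planted runs with chance background runs), and script 05 detects the
planted protein-only +0.9 log2 shift on a target subset while the mRNA side
stays flat:

```
GO:0000002 / mrna:    n=43, mean log2 = -0.10, MW vs all p = 0.16    (ns)
GO:0000002 / protein: n=14, mean log2 = +0.93, MW vs all p = 1.1e-07 (***)
```

Equivalently, `make_demo()` + `run_pipeline()` run the same flow in one
call and write `targets.tsv`, `hits.tsv`, `table1.tsv`, `enrich.tsv`,
`overlap.tsv`, `fig6.tsv`, `report.txt` and a manifest, byte-identically on
rerun.

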