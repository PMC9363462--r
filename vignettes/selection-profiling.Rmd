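---
title: "Profiling peptide display selections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling peptide display selections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(pepselect)
```

## The experiment this package analyses

A display selection couples each peptide in a combinatorial library to its
coding DNA, exposes the pool to a selective pressure — here, an enzyme
(a transglutaminase) that biotinylates peptides carrying a reactive
glutamine so they can be pulled down on streptavidin beads — and sequences
the pool before and after selection. A peptide's fitness under the
selection is summarized by its **enrichment factor (EF)**: the quotient of
its total-normalized read frequencies after and before selection,

$$EF(x) = \frac{c_{after}(x)/N_{after}}{c_{before}(x)/N_{before}},$$

so EF > 1 marks enrichment. The same quotient applied to residue classes —
all peptides sharing residue $a$ at a randomized position $r$ — gives the
position-EF matrix behind the enrichment heatmaps, and the per-position
argmax of that matrix gives a heatmap-derived consensus sequence.

The package covers two library layouts built on a 12-mer backbone with a
reactive glutamine at position 2: a control library randomizing only the
reactive position (`LibQ`), and a library randomizing the four positions
around it, relative positions $-1, +1, +2, +3$ (`Lib4`). Both use NNK
degenerate codons: the 32 codons with third base G or T, which encode all
20 amino acids (1–3 codons per residue) plus the single amber stop TAG.

## Read processing

`count_peptides()` turns raw paired-end FASTQ into peptide counts through a
fixed chain, tallying every dropped pair under exactly one reason so that
accepted + rejected always equals the input:

1. optional 3' adapter trimming (substitution-tolerant suffix/prefix
   overlap, no indels);
2. mean-quality filter: a read passes when its mean Phred score is at
   least the threshold (default 25, inclusive); a pair is kept only when
   both mates pass. The named threshold follows the common average-quality
   semantics of command-line filters; the statistic is configurable.
3. tag demultiplexing when the design carries in-read 10-nt sample tags:
   nearest tag within one substitution, ties unassigned;
4. anchor-based extraction of the coding region from read 1, tolerating
   one substitution per anchor (no indels — the error model of the
   platform emulated here is substitution-only); the reverse complement of
   read 2 is a fallback when read 1 fails. No overlap merging is
   performed: the constructs are short enough that anchor search on one
   mate suffices.
5. translation with the standard genetic code, stops rendered in-band as
   `*`;
6. design filters: peptides must carry glutamine at any fixed backbone
   position expected to hold the reactive glutamine (active for Lib4,
   where that position is fixed; skipped for LibQ, where it is itself
   randomized), and must be stop-free. Backbone variants away from the
   reactive position are deliberately retained — they carry the reactive
   glutamine and can be genuine substrates.

## Enrichment statistics

`peptide_ef()` implements the EF quotient; peptides absent before
selection have no defined ratio and are flagged `zero_before` rather than
reported as infinite (an optional pseudocount, typically 0.5, defines them
for exploratory use). `rank_top()` filters to peptides with at least
`min_count_after` reads after selection (default 100; a count equal to the
threshold is eligible), sorts by EF and breaks ties deterministically by
higher after-count, then peptide lexicographically. `position_aa_ef()`
aggregates the same quotient over residue classes; by default it uses all
filtered reads rather than only ranked peptides (the larger-n choice; the
input table is an argument, so either population can be supplied).
`heatmap_consensus()` takes the per-position maximum among defined
entries, breaking ties alphabetically and flagging them.

EF orientation is fixed throughout as after/before, so that "enriched"
always means EF > 1.

## The selection simulator

No raw sequencing data accompanies the study system this package targets,
so every stage is verified against simulated experiments with known ground
truth. The generator has three parts:

* **Library sampling** (`sample_library()`): backbone codons fixed, each
  randomized position drawing uniformly from the 32 NNK codons — residue
  frequencies are NNK codon multiplicities over 32, the amber stop appears
  at 1/32 per site.
* **Capture** (`capture_probability()`, `simulate_selection()`): each
  molecule is captured independently with probability
  $p = \beta + (1-\beta)\,\sigma(b_0 + \sum_r W[r, a_r])$, a
  logistic-additive position-weight model. The logistic link is the
  simplest monotone map from additive position effects to a probability;
  no kinetic mechanism is claimed. Stop-bearing peptides, and peptides
  without the reactive glutamine where it is required, fall back to the
  nonspecific background $\beta$. An optional artifact rule adds capture
  probability to peptides matching a motif, emulating His/Trp-rich
  bead-binding false positives. Selection is a single round — the
  experimental protocol emulated here performs one.
* **Sequencing** (`emit_fastq()`): reads allocated to molecules by a
  multinomial draw; each read 1 is tag + upstream anchor + coding DNA +
  downstream anchor, read 2 its reverse complement with independent
  errors; substitution errors at a uniform per-base rate (default 0.5%)
  and Phred qualities from a discretized normal (default mean 36, sd 3).
  No indels, no quality-by-cycle decay, no PCR bias or chimeras: the
  extraction step is anchor-based and substitution-tolerant, so these
  are the error modes it must withstand, and passing tests therefore says
  nothing about indel-heavy platforms.

Default ground-truth conditions for the shipped Lib4 model plant a strong
glutamine preference at $-1$ (weight $+2$, the Gln-Gln motif), moderate
preferences for isoleucine and valine at $+3$ ($+1$ each), a penalty for
phenylalanine at $+2$ ($-1.5$), baseline $b_0 = -2$ and background
$\beta = 0.002$. The baseline and background are exercise parameters — the
experiment provides no quantitative capture efficiency — chosen so that a
realistic minority of the pool is captured and a visible but small
fraction of captures is nonspecific.

`true_position_ef()` computes the *expected* position-EF matrix under any
model by exact enumeration over the NNK-induced residue distribution
(conditioned on stop-free peptides, the population the filters retain).
It is the oracle the pipeline's empirical heatmaps are compared against in
the parameter-recovery tests.

## Random-forest importance

`one_hot_encode()` maps each peptide to indicator columns (position ×
residue, deterministic order); `fit_rf_cv()` trains k-fold
cross-validated regression forests (ranger); `permutation_importance()`
measures, for every feature, the mean increase in held-out MSE when that
column is permuted in the held-out fold, averaged over folds × repeats,
and attaches a sign from the Pearson correlation of the raw column with
the response. `hypertune_rf()` offers a seeded randomized search over
`mtry`, node size and depth, scored by CV MSE.

Defaults worth knowing:

* `mtry = floor(p/3)` — the classical regression-forest default, closer
  to the all-features regression default of other ecosystems than to the
  $\sqrt{p}$ classification rule.
* The pipeline's analyze stage trains on $\log$ EF computed with a
  pseudocount of 0.5, excluding peptides unseen before selection. This
  choice matters at desk-scale coverage: with roughly one molecule and
  one read per library member, restricting the training set to peptides
  with a nonzero after-count truncates the response in a way that couples
  it to NNK codon multiplicity — residues with three codons (Leu, Arg,
  Ser) have systematically higher before-counts, and the truncation turns
  that into a spurious negative association at every position, strong
  enough to outrank genuine moderate effects. The pseudocount removes the
  truncation (every peptide keeps a defined, positive EF) and the log
  tames the heavy tail of small-count ratios. At high coverage the raw
  and pseudocount responses agree; both, plus the log switch, are exposed
  in the configuration (`analyze$pseudocount`, `analyze$log_response`).
* Group comparisons (`hydrophobic_count_analysis()`,
  `polarity_by_position()`) use the raw enrichment factors, Welch's
  unequal-variance t-test at $\alpha = 0.01$, with p-values reported raw
  (a Bonferroni adjustment is a one-liner on the returned table). The
  hydrophobic set is {A, V, L, I, M, F, W, C} and the polar set
  {S, T, Y, N, Q, C, D, E, K, R, H}; the literature draws these
  boundaries differently (cysteine legitimately sits in both), so both
  sets are arguments.

## Numerical and scale choices

* Degenerate Welch tests (both samples constant) return p = 1 for equal
  means by convention; positions with an empty polar or nonpolar side are
  skipped with a notice rather than tested.
* All ranking and consensus ties break deterministically (after-count
  then lexicographic; alphabetical), so outputs are reproducible across
  runs and platforms.
* Every stochastic stage derives its seed from the run's master seed
  hashed with the stage name; identical configurations reproduce every
  table byte for byte.
* The parameter-recovery studies simulate $2 \times 10^5$ molecules and
  $2.5 \times 10^5$ read pairs per sample at 0.5% per-base error, and the
  forest analyses train on subsamples of 2500 peptides with depth-8
  trees (200 trees, 10 folds, 10 permutation repeats). These sizes were
  chosen as the smallest at which the planted effects are recovered
  stably; at this coverage individual peptide EFs are extremely noisy
  (one or two reads each), which is exactly the regime the pseudocount
  response above is designed for.
* Position-EF comparisons against the enumeration oracle are made on
  residue classes backed by at least $10^4$ after-selection reads,
  averaged across simulation replicates: below that, class-level binomial
  noise alone exceeds the comparison tolerance.

## Known limitations

* Substitution-only error model end to end; indel-tolerant extraction is
  out of scope.
* Single selection round; multi-round composition would be a loop over
  `simulate_selection()` but is untested.
* The shipped backbone completes a partially published sequence: residues
  1–7 are literature-confirmed, 8–12 are a literature-derived completion,
  and the anchor/tag DNA of the presets is synthetic — real analyses
  should configure the construct actually used. Nothing in the logic
  depends on the completed residues.
* No significance testing of individual EFs, no alternative learners, no
  sequence-logo rendering (the frequency matrix is exported for external
  logo tools).
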