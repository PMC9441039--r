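---
title: "Inferring lncRNA–miRNA–mRNA ceRNA networks with cernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA–miRNA–mRNA ceRNA networks with cernet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

Competing endogenous RNA (ceRNA) regulation rests on a simple titration
argument: a long non-coding RNA (lncRNA) that carries binding sites for a
miRNA can sponge that miRNA away from its mRNA targets, derepressing them.
Three observable signatures follow for a genuine sponge pair
(lncRNA, mRNA):

1. the two transcripts share miRNA binding sites — more of them than two
   random target sets of the same sizes would share;
2. the shared miRNA is anti-correlated with both transcripts across
   samples;
3. the two transcripts are positively correlated with each other.

`cernet` scores candidate pairs on all three signatures, restricted to
transcripts and miRNAs that are differentially expressed (DE) between two
groups of samples (the package's group labels default to CC and GC, for
cumulus and granulosa cells, the two ovarian somatic cell populations of
the motivating two-group design; any two labels work).

### Shared-miRNA overlap test

For a pair whose partners are targeted by $K$ and $n$ of the $N$ miRNAs in
the universe, sharing $k$, the evidence against independent target sets is
the upper tail of the hypergeometric distribution:

$$P = \sum_{j=k}^{\min(K,n)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}.$$

The universe $N$ is the set of distinct DE miRNAs with at least one
predicted interaction among the DE transcripts. This is the smallest
defensible universe: miRNAs that target nothing in the analysis carry no
information about overlap. Larger universes (all DE miRNAs, all annotated
miRNAs) make every overlap look more surprising; users who prefer them can
filter the interaction table accordingly before scoring. p-values are
BH-adjusted across all scored pairs (one family; adjusting per-lncRNA is a
defensible alternative but fragments the family into tiny sets at typical
scales).

### Correlation screens and the two regimes

Correlations are computed on normalized expression (FPKM for mRNA/lncRNA,
tags-per-million for miRNA) across all samples pooled over groups. Two
named threshold regimes are built in:

| gate | lenient (default) | strict |
|---|---|---|
| Spearman's rho, miRNA vs each partner | ≤ −0.7 | ≤ −0.95 |
| Pearson's r, lncRNA vs mRNA | ≥ 0.9 | ≥ 0.95 |
| hypergeometric p | < 0.05 | < 0.01 |
| hypergeometric BH FDR | — | < 0.01 |

The strict thresholds are nested inside the lenient ones, so the strict
network is always a subgraph of the lenient network — an invariant the
test suite asserts on every synthetic dataset it touches. Lenient is the
construction regime, strict the reporting regime.

A shared miRNA counts as screening evidence only when **both** of its arms
(miRNA–lncRNA and miRNA–mRNA) pass the Spearman gate; the sponge mechanism
requires repression on both sides. An either-arm variant is available via
`cerna_params(both_arms = FALSE)` for sensitivity analyses.

Two caveats belong next to these screens. First, with three replicates
per group a pooled-sample correlation over six points is fragile: any two
transcripts that shift in the same direction between groups correlate
strongly regardless of mechanism, so the correlation screens mostly
separate direction patterns, not mechanisms. Second, Spearman's rho at
$n = 6$ takes only a coarse grid of values; the −0.95 strict gate is close
to demanding perfect anti-ranking, and on the synthetic benchmark the
strict regime passes very few pairs. Both are properties of the design
being modelled, not of the implementation.

### Target prediction

Interactions are predicted by canonical seed matching: the seed is miRNA
nucleotides 2–8, and a transcript site is an exact sense-strand match to
the reverse complement of the relevant seed span, optionally followed by
an A opposite miRNA position 1 (site classes 6mer, 7mer-A1, 7mer-m8, 8mer
in increasing strength; no G:U wobble; no conservation, context or
free-energy scoring). A lower-priority site wholly contained in a
higher-priority one is suppressed, so a planted 8mer is one 8mer, not five
overlapping records. Full transcript sequences are scanned because
lncRNAs have no 3′ UTR; a UTR-restricted scan can be emulated by passing
trimmed sequences.

`predict_targets()` defaults to counting sites of class 7mer-A1 and
stronger, the conventional gate. The *pipeline* default is stricter —
8mer only — for a statistical reason: without conservation or context
filtering, a specific 7mer occurs by chance about once per 16 kb, so
0.5–2 kb transcripts accumulate enough chance 7mer "targets" that the
shared-miRNA universe becomes dense and the overlap test loses both
sensitivity (true overlaps drown in incidental ones) and specificity.
The 8mer class keeps the chance rate an order of magnitude lower. With
externally supplied, conservation-filtered interaction tables the 7mer
gate is appropriate.

### Differential expression

Expression is normalized the way the corresponding libraries are built:

* mRNA/lncRNA: FPKM, $10^9 C_{is} / (N_s L_i)$ with $N_s$ the sample's
  total counts and $L_i$ the transcript length;
* miRNA: tags per million, $10^6 C_{is} / N_s$, length-free because small
  RNA tags are sequenced whole.

Gates: mRNA and lncRNA are DE when $|\log_2 \mathrm{FC}| \ge 1$ and BH
FDR < 0.05; miRNAs when $|\log_2 \mathrm{FC}| \ge 1$ and raw p < 0.05
(small-RNA families are smaller and the raw-p convention for miRNAs is
retained from the design being modelled). Fold changes are oriented
B-versus-A, where A is the first group in the sample annotation.

The test behind the p-values is deliberately pluggable. `de_test()`
offers two methods on $\log_2(\text{normalized} + 1)$ values:

* `"welch"` — an ordinary Welch two-sample t-test, the simplest honest
  default, and the exported baseline;
* `"moderated"` — limma's empirical-Bayes moderated t on the same logged
  values, the **pipeline default**.

The moderated default is a considered deviation from "simplest possible":
at 3-vs-3 the Welch denominator has about four degrees of freedom, so its
p-values are bounded away from the extremes that a BH correction over
thousands of transcripts demands — in simulation, genuine four-fold
shifts produce Welch p-values around $10^{-4}$–$10^{-3}$ while the BH
cutoff sits near $2.5 \times 10^{-4}$ when discoveries are few, and
recall collapses. Sharing variance information across transcripts is the
standard remedy at this replication level and is precisely why dedicated
count-model tools exist. Users with externally computed DE tables
(e.g. from a count model) can feed `id`/`log2fc`/`p_value` tibbles
straight into `filter_de()` and bypass `de_test()` entirely.

## The synthetic benchmark

`simulate_cerna_dataset()` builds a fully self-contained study: sequences
(FASTA-writable), count matrices, and machine-readable ground truth. It
emulates a two-group design with `n_samples_per_group = 3` per group, the
replication level of the motivating study.

* **Counts** are negative-binomial, $\mathrm{Var} = \mu + \phi\mu^2$,
  around per-transcript log-normal baselines (log-mean `log(200)`,
  log-sd 1). The default dispersion $\phi = 0.005$ models cultured,
  fairly homogeneous cell populations; tissue-level designs warrant
  $\phi$ of 0.05 or more, and the benchmark results degrade accordingly
  (deliberately — that is what the knob is for). mRNA/lncRNA means scale
  with transcript length so FPKM is meaningful; miRNA means do not.
* **Planted sponge units**: consecutive groups of `mirnas_per_sponge = 5`
  triples share one lncRNA–mRNA pair. Real ceRNA pairs share several
  miRNAs, and a single shared miRNA is statistically invisible to the
  overlap test (with $k = 1$ the upper-tail p can rarely fall below
  0.05), so planting one miRNA per pair would benchmark the test on a
  signal it cannot carry. Unit direction is random: the lncRNA and mRNA
  are DE in the same direction at `planted_fold_change = 4` (split
  symmetrically across groups), the unit's miRNAs in the opposite
  direction — the canonical sponge pattern.
* **Within-group coupling**: each unit has a latent per-sample factor
  entering the two ceRNAs with positive sign and the miRNAs with negative
  sign, log-scale sd `0.08 * planted_corr_strength`. The scale trades
  off two uses of the same variance: larger values strengthen the
  within-group rank coupling the Spearman screen rewards, but inflate the
  within-group variance the DE test must overcome. 0.08 was fixed once,
  after a pilot grid over candidate scales and background-DE fractions,
  at the setting where both planted DE recovery and pair recovery hold
  with margin; it was not adjusted afterwards.
* **Background DE** (`decoy_de_fraction = 0.01`): a small fraction of
  non-planted transcripts per class receives a direction-random
  four-fold shift. These decoys give the BH step-up a realistic
  discovery set and create the hard negatives for precision: two decoys
  shifted in the same direction correlate strongly across six pooled
  samples and are indistinguishable from sponge partners by correlation
  alone — only the overlap test separates them. Raising the fraction
  toward tissue-like levels (the motivating study called ~30% of its
  transcriptome DE) makes precision degrade; the default keeps ground
  truth dominant so recovery metrics measure the screens, not the
  background.
* **Sequences**: miRNAs are 21–23 nt RNA; transcripts 500–2000 nt DNA
  (uniform). Each triple's 8mer site (reverse complement of seed 2–8
  plus a 3′ A) is written into both partners at recorded,
  non-overlapping positions. Decoys get no planted sites, but incidental
  matches occur and are intentionally left in: the truth table, not
  sequence content, defines ground truth, mirroring the false-positive
  rate of real target prediction.
* **Library sizes** are not separately varied; column totals inherit the
  natural variation of the baselines. Depth variation is a free
  parameter of real designs that the benchmark does not model.

What passing benchmarks do **not** show: performance on real data. The
generator has no shared-sequence homology between transcripts, no
batch structure, no dispersion–mean trend beyond the NB form, no
mapping/assembly noise, and its planted effects are cleanly bimodal. The
benchmark validates that the screens find exactly the structure they are
defined to find, at the study's scale and replication — nothing more.

Determinism: a configuration's `seed` fixes sequences (stream seeded with
`seed`) and counts (stream seeded with `seed + 1`) independently, so
identical configurations give bit-identical datasets and identical
written files.

## Numerical choices and degenerate inputs

* Hypergeometric tail via `stats::phyper(k − 1, …, lower.tail = FALSE)`,
  clamped to [0, 1]; `k = 0` returns exactly 1. Verified against
  exhaustive subset enumeration for every universe up to $N = 12$ at
  $10^{-12}$ relative tolerance.
* BH via `stats::p.adjust(method = "BH")`, verified against a
  brute-force step-up implementation.
* Correlations on constant vectors return `NA` with a warning — never a
  silent 0 — and a shared miRNA with an undefined arm contributes no
  screening evidence.
* Ties in Spearman's rho get average ranks.
* A Welch row with zero variance in both groups reports p = 1 at equal
  means and p = 0 otherwise, keeping degenerate rows defined.
* Zero library-size columns are an error, not a division by zero.
* Pipeline scale: the recovery benchmark (2000 mRNA / 500 lncRNA /
  300 miRNA / 50 triples, 3-vs-3) runs in roughly ten seconds per seed;
  the test suite's 20-seed panel and the acceptance script's single run
  both use this scale.

## The network

Passing pairs assemble into a tripartite graph: `lnc_mi` and `mi_m`
interaction edges (only for the miRNAs a pair actually shares, so every
competing edge is backed by a lncRNA–miRNA–mRNA path) and `ceRNA`
competing edges carrying the pair statistics. Node attributes record the
DE call and the conventional Cytoscape shapes — circles for mRNA,
triangles for miRNA, diamonds for lncRNA. Exports: SIF (one
`source relation target` line per edge), GraphML (full attributes, via
igraph), and an edge-table TSV; SIF and GraphML re-import losslessly for
ids, types and edge sets. `extract_subnetwork()` produces the
gene-centred views used to report how many miRNAs and lncRNAs converge on
a focus gene. Transcript ids are opaque strings throughout; gene symbols
are display attributes, never keys.

## qPCR validation

`relative_expression()` implements the comparative-Ct method: technical
replicates are averaged on the Ct scale, $\Delta Ct = Ct_{target} -
Ct_{reference}$ per sample, $\Delta\Delta Ct$ is the difference of group
means against the calibrator group, and relative expression is
$2^{-\Delta\Delta Ct}$. Amplification efficiency is fixed at 100% (the
pure Livak model; no Pfaffl correction), and averaging before
$\Delta Ct$ is the conventional order. The result is exactly invariant
to global Ct offsets, and the calibrator against itself is exactly 1.
`qpcr_concordance()` compares RNA-seq and qPCR fold changes by per-target
sign agreement plus Spearman's rho across targets.

## A worked run

```{r run, eval = FALSE}
library(cernet)

cfg <- cerna_config(simulate = list(seed = 1))
run <- run_cerna_pipeline(cfg, out_dir = "cerna_run")

run$recovery$lenient
glance(run$networks$lenient)
autoplot(run$networks$lenient)
```

The run directory contains the per-class DE tables, the interaction
table, pair tables per regime, SIF/GraphML/TSV network exports, a summary
JSON whose counts match recounts from the emitted tables, a log of every
threshold used, and a YAML echo of the effective configuration. Runs are
byte-identical under a fixed seed.

## Known limitations

* The DE stand-ins (Welch or moderated t on logged normalized values)
  are not count models; at very low counts their behaviour differs from
  negative-binomial GLMs. The `filter_de()` interface accepts external
  DE tables for exactly this reason.
* Seed matching alone over-predicts targets relative to
  conservation-aware tools; the 8mer pipeline default compensates
  statistically but discards genuine weaker sites.
* Pooled-sample correlations at n = 6 cannot distinguish co-regulation
  from sponging; the package reports the screens' outcome, not a causal
  claim. Partial-correlation or conditional ceRNA scores are out of
  scope.
* The hypergeometric test conditions on the predicted interaction table;
  errors in target prediction propagate into $K$, $n$ and $k$
  unmodelled.
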