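---
title: "Analysing BioID proximity-labeling screens with bioidflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing BioID proximity-labeling screens with bioidflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioidflow)
```

## The analysis problem

In a BioID experiment a promiscuous biotin ligase (BirA\*) is fused to a bait
protein and expressed in cells; proteins within roughly 10 nm of the bait are
biotinylated in vivo, captured on streptavidin, and identified by label-free
LC–MS. Every run also captures two classes of systematic false positives —
sticky background proteins and endogenously biotinylated carboxylases — and
keratins enter during sample handling. The analytical task is to separate
genuine bait-proximal proteins from this background using only (i) per-protein
unique-peptide counts and LFQ abundances from bait-fusion runs and ligase-only
control runs, and (ii) curated exclusion lists.

`bioidflow` implements that full analysis: within-batch normalization,
bait/control biotinylation ratios, a deterministic candidate-selection
cascade with an audit trail, cross-condition overlap and ratio matrices,
hypergeometric GO over-representation with Benjamini–Hochberg control, and a
ratio-weighted interaction network. A synthetic-data generator with a
ground-truth manifest makes every stage testable by parameter recovery.

## The enrichment statistic and the filter cascade

For a protein $p$ in one *experiment* (a cell line × biotin time ×
treatment combination, quantified as one batch), the **biotinylation ratio**
is a ratio of condition means,

$$ r_p \;=\; \frac{\tfrac1{B}\sum_{b=1}^{B} a_{pb}^{\text{bait}}}
                 {\tfrac1{C}\sum_{c=1}^{C} a_{pc}^{\text{ctrl}}}, $$

computed on normalized abundances; replicates in which the protein was not
detected contribute 0, and the ratio is *undefined* (flagged, never imputed)
when the control mean is 0. Ratio-of-means rather than mean-of-ratios was
chosen because it matches condition averaging in label-free quantification
software and is robust to single-replicate dropout.

Normalization rescales each run in a batch by a single factor: the median,
over proteins quantified in both runs, of reference/run abundance, with the
reference being the run quantifying the most proteins (ties broken by run
id). A single multiplicative factor per run is exactly invertible, which is
what makes the rescaling-invariance property testable to numerical precision.

Candidates are then selected by four rules applied in a fixed order, each
recording the first stage that removed a protein:

1. **Peptide floor** — more than 3 unique peptides on the bait side *and* at
   least 1 on the control side, in at least one experiment. Both bounds are
   deliberately strict/inclusive as written: bait = 3 fails, control = 1
   passes.
2. **Direction** — an experiment where control peptides strictly exceed bait
   peptides cannot support the protein.
3. **Exclusion lists** — keratins (symbol prefix `KRT`, case-insensitive) and
   endogenously biotinylated carboxylases (ACACA, ACACB, PC, PCCA, PCCB,
   MCCC1, MCCC2). The bait's own gene is exempt. These proteins are removed
   *whatever their ratio*: carboxylases bind streptavidin regardless of
   proximity labeling, so their enrichment carries no interaction signal.
4. **Ratio threshold** — a defined ratio strictly above 1.5 (a 50% abundance
   increase) in at least one experiment; the qualifying experiments are
   recorded and define the per-condition candidate lists.

The cascade is idempotent and monotone in its thresholds, and the two
exclusion sub-rules commute; the test suite checks all three properties.

## Over-representation analysis

For a query of $n$ candidate genes against a background of $N$ annotated
genes, a term with $K$ annotated genes and $k$ query hits is scored by the
hypergeometric upper tail $P(X \ge k)$, accumulated in log space. Adjustment
is Benjamini–Hochberg, applied separately within each GO namespace (the
three aspects are distinct test families). A term is *reported* only when
$k \ge 3$ and adjusted $p < 0.01$ — a reporting gate on top of the
statistics, not part of them. The background is the annotation set's own
gene universe: the only background this artifact can know, which is also why
externally published per-term p-values from web services with proprietary
backgrounds are not comparable quantities.

Annotations are used as given; propagation up the GO graph is out of scope.
Box summaries of per-term ratios use Tukey hinges (the inclusive-median
quartile convention, fixed here because box conventions differ between
tools), whiskers at 1.5 × IQR clipped to the data, and the bait excluded by
default — its self-biotinylation ratio would dominate any distribution.

## What the simulator emulates

`generate_experiment()` builds a complete experiment grid (2 cell lines ×
{6, 24} h biotin × {vehicle, stress} × {bait fusion, control} × 3
replicates) over a protein population with five classes: one bait, true
interactors, background, keratins, and endogenously biotinylated proteins.

* **Abundance.** Baseline abundance is log-normal (natural-log mean
  `log(1e6)`, sd 1.2 — arbitrary LFQ units, a realistic dynamic range for a
  pulldown). Each run observes `baseline × effect × exp(N(0, 0.2))`.
* **Labeling effects.** Interactors carry a 5-fold bait-vs-control
  enrichment; the bait carries a 30-fold self-biotinylation effect, so it
  tops every ranking, as the fusion protein does in practice.
* **ER stress.** Stress shrinks each interactor's effect towards 1 *on the
  log scale*: the stressed effect is `effect^(1 - stress_shrinkage)`.
  Multiplicative effects live on the log scale, so this is the natural
  shrinkage operator: `0` leaves labeling untouched, `1` erases it. The
  default 0.9 leaves a residual 1.2-fold effect that rarely crosses the 1.5
  threshold, reproducing the near-total collapse of the candidate list that
  a translation-initiation bait shows under ER stress, while the bait's
  self-labeling is never shrunk (the ligase still labels its own fusion).
* **Dropout.** Detection probability is logistic in log abundance with slope
  4 and midpoint 3.5 baseline sd below the mean, confining missingness to
  the lowest-abundance tail — the intensity-dependent pattern of LFQ data.
  The slope and midpoint were set so that dropout does not create
  ratio artifacts in the quantifiable range, where missingness would
  otherwise masquerade as enrichment.
* **Peptide counts.** Detected proteins draw
  `1 + Poisson(2 · max(0, log1p(a) − x₀))` unique peptides, anchored at the
  detection midpoint `x₀`: counts collapse to single peptides at the
  detection limit (where the unique-peptide filters must do their work) and
  grow with log abundance above it.
* **Contaminants.** Keratins and carboxylases have *equal* abundance in both
  constructs (ratio ≈ 1) and keratins a 5-fold abundance boost, so they
  carry convincing peptide counts yet must be removed by the exclusion
  lists, not the ratio filter — both removal paths are exercised.

The default population is 120 proteins (1 bait, 10 interactors, 8 keratins,
7 carboxylases, 94 background) — a deliberately desk-scale stand-in for the
thousand-plus proteins of a real screen that keeps the full test suite in
seconds while preserving the class structure the filters act on. What
passing recovery tests show is that the *pipeline* is correct under its own
generative assumptions; they cannot show that real MS data satisfies those
assumptions (no retention-time structure, no peptide-level identity, no
correlated batch effects, no compositional normalization artifacts).

## Numerical and design choices

* Ratios are undefined, never infinite or imputed, when the control mean is
  0; undefined cells survive into the ratio matrix as `NA`, distinct from a
  low ratio.
* The hypergeometric tail is summed in log space with a log-sum-exp guard;
  `k = 0` returns exactly 1.
* Known-interaction import applies an inclusive confidence floor of 0.5 on
  the unit scale (STRING-style 0–1000 scores are rescaled). "Selectivity" of
  graph-tool imports has no published formula; a transparent confidence
  floor reproduces its observable effect — restricting which reference edges
  are admitted.
* The network never expands beyond candidates ∪ bait: reference edges
  annotate the candidate set rather than growing it, and isolated candidates
  are kept deliberately.
* Exports are byte-stable (lexicographic node/edge/row ordering) so
  determinism can be asserted on file contents.
* All randomness flows from one integer seed; identical configuration and
  seed reproduce identical outputs byte for byte.

## Known limitations

* The peptide floor's "at least one experiment" semantics is the permissive
  reading of a per-experiment rule; a require-all variant is available via
  `cascade_config(peptide_rule = "all")`.
* Ratios may be computed on raw rather than normalized abundances
  (`method = "none"`), but normalized is the default and the tested path.
* GO annotations are taken at face value; no DAG propagation, no evidence
  code filtering.
* The enrichment background is the annotation universe, not a proteome; with
  small custom annotation sets the test family is correspondingly small.
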