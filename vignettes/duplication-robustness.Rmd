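---
title: "Simulating and analysing directed evolution of duplicated fluorescent genes"
author: "dupevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing directed evolution of duplicated fluorescent genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupevol)
```

## The question and the system

Ohno's hypothesis holds that gene duplication buys a redundant copy freedom
from purifying selection, increasing mutational robustness and, eventually,
the chance of evolving new functions. Its standing objection — Ohno's
dilemma — is that deleterious mutations usually inactivate the spare copy
first. A direct way to test this is directed evolution of a fluorescent
protein carried in exactly one or exactly two copies per plasmid: mutagenize,
sort the brightest cells by FACS, regrow, repeat, and read out both phenotype
(per-cell fluorescence) and genotype (full-length amplicon sequencing that
preserves the linkage between the two copies).

`dupevol` implements that entire computational loop: a forward simulator of
the evolution experiment, the sequence-processing stages that turn
palindromic two-copy amplicon reads into per-copy mutation calls, a
rule-based activity classifier, the population statistics used to compare
single- and double-copy designs, and the differential-enrichment test
between selection regimes.

## The simulated experiment

One plasmid carries two convergently oriented copies of a 232-codon
fluorescent-protein gene separated by a 50-nt spacer (the only asymmetric
context on the amplicon). The *double* design starts with two intact copies;
the *single* design carries one intact copy plus a partner inactivated by
three engineered chromophore substitutions (Q74A/Y75S/G76A) — same plasmid
size, same expressed protein dose, which is what makes the comparison fair.

Each generation applies, in order:

1. **Mutagenesis.** Every nucleotide of both copies (the engineered-inactive
   copy included) substitutes independently with probability $\mu$,
   uniformly over the three alternatives. $\mu$ is calibrated by
   `calibrate_nucleotide_rate()` so one round yields on average two
   nonsynonymous amino-acid changes per gene copy:
   $\mu = m / (L f_{ns})$, with $f_{ns}$ the nonsynonymous fraction of all
   $3L$ single-nucleotide mutants of the ancestor (enumerated exactly).
2. **Inactivation.** Each new nonsynonymous substitution on an active copy
   destroys its fluorescence with probability $q = 0.668$, chosen as
   $-\ln(1-0.737)/2$ so that one round inactivates a single copy with
   probability $1 - e^{-2q} = 0.737$ — the robustness arithmetic the
   experimental design rests on ($100 \times 0.74^2 = 55\%$ predicted
   double-copy loss). Substitutions that visibly break the protein —
   chromophore residue 75 outside {W, F, Y}, residue 76 not glycine, or a
   premature stop at codons 1–220 — inactivate deterministically; all other
   nonsynonymous substitutions use
   $q_{gen} = (q - \rho)/(1 - \rho)$, with $\rho$ the rule-violating
   fraction of nonsynonymous single-nucleotide changes of the ancestor
   ($\rho \approx 0.065$). The marginal probability per nonsynonymous
   substitution remains exactly $q$, so the calibration is untouched, while
   the truth tables can never contradict the sequence rules. Inactivation is
   absorbing: later mutations never resurrect a dead copy.
3. **Phenotype.** A cell's green (blue) fluorescence is autofluorescence
   plus the sum over induced, *active* copies of a base level times the
   multiplicative factors of any key mutations the copy carries, each term
   under mean-one lognormal noise (CV 0.3). The default effect table —
   G147S (green ×2, blue ×0.5), V162D (×3, ×0.3), L98M (×1.5 both) — gives
   the color-tuning and stabilising substitutions plausible magnitudes;
   these are model defaults, not measurements, and nothing quantitative
   downstream depends on them. The noise also applies to the
   autofluorescence term so that a non-induced negative control yields a
   continuous distribution to gate against (a point-mass control would make
   quantile gates degenerate).
4. **Selection.** FACS gates are modelled as truncation selection
   (`select_survivors()`): keep the top `round(fraction * n)` cells by the
   regime's channel, ties broken randomly. The schedule is the
   experimental one — 60%, 1%, then 0.01% from generation 3 on.
   `green_and_blue` ranks by the worse of a cell's two channel ranks, the
   exact-count analogue of intersecting two truncation gates. `green_only`
   and `blue_only` first restrict to cells *below* the opposite channel's
   negative-control threshold.
5. **Regrowth and re-cloning.** Survivors are resampled with replacement to
   the full library size (multinomial regrowth of the sorted cells), and
   with probability 0.5 each plasmid's two copies exchange promoters,
   mimicking bidirectional re-insertion of the cassette.

Per generation the simulator emits the pre-selection flow-event table with a
matched negative control (robustness is "% of cells outside the
negative-control gate", measured before sorting), and a sequenced sample:
full amplicons on uniformly random strands with per-copy truth tables, so
the read-processing stage can be validated read by read.

### What the defaults mean, and what the simulator does not model

Defaults: library size 10^4 (drift negligible at the experimental scale,
as in the study whose libraries exceeded 10^4), 5 generations, mean 2
nonsynonymous substitutions/gene/round, q = 0.668, swap probability 0.5,
noise CV 0.3, autofluorescence 0.05, gate quantile 0.999.

Deliberate simplifications: substitutions only (no indels by default — the
caller and classifier carry a frameshift path, but the mutagenesis model
does not produce them); a binary active/inactive fitness readout rather
than a quantitative stability landscape; no stabilising mutations that
*increase* robustness (the experiment's late-generation robustness recovery,
attributed to stabilising substitutions like L98M becoming fixed, is outside
the model — simulated robustness can only plateau, which is why the
qualitative robustness check compares generations 1 and 2); additive dosage
with no expression saturation, so an intact double copy fluoresces 2.0× a
single one rather than the ~1.5× observed experimentally — reproducing 1.5
would require a saturation model the data do not constrain; fixed plasmid
copy number per cell. Passing tests on these synthetic data therefore show
the pipeline recovers what this model generates, not that the model captures
every feature of the real system.

### Counter-selection and absorbing inactivation

Because the ancestor is equally bright in both colors, *no* expressing
variant passes a counter-gate set at the negative control's quantile: cells
"below the blue gate" are, at the start, exclusively cells with an inactive
copy. Combined with absorbing inactivation this makes `green_only` and
`blue_only` populations collapse into permanent darkness unless a strong
color trade-off variant arises on a still-active copy in generation 1 and
survives the early bottlenecks. The analysis workflow therefore runs those
regimes at the full 2×10^4 library scale, where the mutational supply makes
establishment frequent, and gives the trade-off variants at the
color-tuning residue 147 off-channel factors low enough (0.01) to clear the
counter-gate. This is a model *variant* used only for that demonstration;
the default effect table stays as above.

## Sequence processing

Reads are full amplicons on random strands. `process_amplicons()` aligns
each read and its reverse complement globally (Needleman–Wunsch, affine
gaps, EMBOSS-needle-style scoring: match 5, mismatch −4, gap open 10,
extend 0.5 — a gap of length $L$ costs $10 + 0.5L$) against the reference
amplicon and keeps the higher-scoring orientation. The two gene copies are
nearly identical, so the decision rests on the spacer; an exact score tie
(a perfectly palindromic read) carries no orientation information and the
read is flagged and excluded. Reads must align with full query coverage
(the contamination filter); covered reads are split gap-aware at the
reference layout boundaries, copy 2 is reverse-complemented back to coding
orientation, and mutations are called codon-by-codon against the ancestor —
one amino-acid-level call per changed codon, multi-nucleotide codon changes
collapsing to a single call, stops reported as `*` and counted
nonsynonymous. Positions are 1-based protein coordinates throughout
(Q74/Y75/G76, L98, G147, V162); nucleotide intervals are handled 0-based
half-open internally.

The round-trip property — simulate, emit random-strand FASTA, orient,
split, call, compare with truth — must hold *exactly* in substitution-only
mode, and the test suite enforces that.

## Activity classification

A called copy is inactive iff residue 75 ∉ {W, F, Y}, residue 76 ≠ G, a
stop occurs at codons 1–220, or the copy is frameshift-flagged. These rules
see only what sequence can see: simulator inactivations through the generic
fold channel (the majority) leave no signature, so classifier sensitivity
against simulator truth is below one *by construction* — mirroring the
experimental situation, where deleterious mutations outside the chromophore
cannot be recognised from sequence either. Specificity, in contrast, is
exact in substitution-only mode: a rule-violating substitution always
inactivates in truth, so the classifier makes no false inactivation calls,
and the tests assert zero false positives under synonymous-only evolution.

## Population statistics

* `mean_mutations()` — mean amino-acid mutation burden per gene copy
  (nonsynonymous by default), with an `exclude` filter to discount the
  engineered Q74A/Y75S/G76A calls when summarising the single-copy
  control's inactive partner. Because truth tables and variant calls are
  both referenced to the *active* ancestor, the engineered substitutions
  appear as ordinary calls; whether double-copy means pool both copies or
  condition on activity is a reporting choice, so the workflow computes and
  labels the scopes separately (`single_active`, `single_inactive`,
  `double_both`).
* `avg_pairwise_distance()` — $\frac{1}{n(n-1)}\sum_i\sum_{j\ne i}
  \delta_{ij}$ over amino-acid sequences. Computed exactly via per-site
  letter counts (algebraically identical to the double sum) up to
  $n(n-1) \le 2\cdot$`max_pairs`; beyond that, by uniform pair subsampling,
  whose estimator is unbiased for the exact value.
* `count_sites()` / `dnds()` — Nei–Gojobori (NG86) site counting on the
  ancestor with stop-introducing changes counted nonsynonymous, and the raw
  pooled-count ratio $(\#N/N_{sites})/(\#S/S_{sites})$ with no multiple-hit
  correction (observed burdens are a few calls per gene, so the correction
  would be negligible). The terminal stop codon is excluded from sites and
  calls alike, keeping numerator and denominator consistent. Under this
  convention a selection-free uniform-substitution simulation gives
  dN/dS = 1 up to a small (+2–3%) bias from multiple hits within codons at
  five rounds of divergence — inside the ±0.05 band the neutrality check
  uses. NG86 is a choice: the counting convention behind the study's
  printed formula is not recorded, and NG86 is the standard that makes the
  neutral expectation exact.
* `allele_trajectories()` — per-copy carrier frequencies of single
  mutations and same-copy combinations (`"V162D/L98M"`), by generation and
  replicate; combination frequency can never exceed any component.
* `gate_and_summarize()` — negative-control quantile gating (default
  0.999, the strictest gate that is still stable at a few thousand control
  events) and median fluorescence, the robustness readout.
* `predicted_double_copy_loss()` and `duplicate_hit_ratio()` — the two
  closed-form robustness quantities: $100(1-p)^2$ and
  $[1-(1-p)^2]/p \to 2$.

## Differential enrichment

`enrichment_scan()` reproduces the regime-comparison analysis: restrict to
mutations at ≥5% frequency (inclusive) in at least one final-generation
replicate of either regime; pool replicates into regime-level counts; test
each candidate with `lrt_binomial()` — the closed-form binomial
likelihood-ratio statistic, identical to the analysis-of-deviance of a
logit-link GLM with regime as the only predictor (the tests verify the
equality against `glm()`/`anova()` and against a numeric
likelihood-maximisation oracle); Bonferroni-adjust over the candidate
count; call direction at adjusted p < 0.05. Replicates are pooled because
the regime-only GLM has no replicate term; the workflow's demonstration
notes the consequence — frequency differences fixed by drift in bottlenecked
replicates can reach significance, which is a property of the method, not a
bug of the implementation. The scan refuses double-copy tables unless
explicitly overridden, since a double-copy cell's fluorescence cannot be
attributed to one variant.

## Numerical and design choices

* Integer-encoded sequence matrices (one row per copy) make mutagenesis,
  translation, and truth-calling whole-population vectorised operations; a
  10^5-gene round runs in seconds.
* Binomial-count-then-place sampling of mutation sites is exactly
  equivalent to independent per-site Bernoulli draws.
* The global aligner is `Biostrings::pairwiseAlignment()`; its affine gap
  convention (length-$L$ gap costs open $+ L\cdot$extend) was verified and
  matched by the exhaustive-enumeration oracle in the tests. Traceback tie
  resolution is the library's; only scores and gap-aware coordinates are
  consumed downstream.
* All per-run randomness derives from one seed; identical seeds give
  byte-identical outputs, and the test suite asserts it.
* Degenerate inputs have defined behaviour: zero mutation rate is the
  identity; empty induction is the negative control; `fraction = 1` keeps
  everyone; a zero-synonymous-count dN/dS returns flagged `Inf` with a
  warning rather than a silent number; `duplicate_hit_ratio(0)` returns the
  limit 2 with a flag.

## Problem sizes used by the checks

The acceptance computations use 10^5 single-copy variants for the one-round
retention fraction (reported to two decimals) and 10^4 genes × 5 rounds for
the neutral dN/dS; the robustness comparison runs three seeded replicates
of the full default library (10^4 plasmids) for two generations in both
copy modes. The workflow scripts under `analysis/` run a scaled study —
4×10^3 plasmids and 100 sequenced clones per generation for the green
regime, 2×10^4 for the counter-selection regimes, with the 0.01% gates
relaxed to 0.1% so a gate never keeps fewer than a handful of cells — sizes
chosen so the whole workflow completes in minutes while every population
fraction it reports remains scale-free.

## Known limitations

Beyond the modelling simplifications above: the classifier's sensitivity is
validated only against the simulator's own mechanism mix (no external gold
standard exists for fold-breaking mutations); `needle`-style scoring
parameters are conventional defaults, and a different scheme could place
rare gaps differently; the green-and-blue joint gate is one formalisation
of a drawn 2-D gate; and sequencing error is not modelled — reads are
noise-free consensus sequences, so variant frequencies here lack the error
floor real amplicon sequencing would add.
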