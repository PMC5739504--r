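---
title: "Scoring mitochondrial tRNA variants: model, tuning and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring mitochondrial tRNA variants: model, tuning and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnascore)
```

## The problem

Mitochondrial tRNA genes are a disproportionate source of disease-causing
mtDNA variants, yet most variants observed in patients are rare or novel,
with no functional work-up available. Confirming pathogenicity properly
requires cybrid studies or single-fiber heteroplasmy analysis; a
bioinformatic prior is therefore valuable at the diagnostic stage.
`trnascore` ranks every possible single-base substitution and single-base
deletion in annotated mt-tRNA genes by combining three complementary signals:

1. **Variant history and conservation (VHC).** What is already known about
   this exact variant (population observation counts, curated pathogenicity
   reports) and how conserved the position is across a species panel.
2. **Position score.** How dangerous the *structurally analogous* position
   has proven to be in the other mt-tRNAs, via a generic cloverleaf
   alignment.
3. **Secondary-structure score.** The steric consequence of the change for
   stem base-pairing, weighted toward the ends of stems.

The total is a weighted sum,

$$ S = w_{vhc}\,\mathrm{VHC} + w_{pos}\,\mathrm{Pos} + w_{ss}\,\mathrm{SS}, $$

with six tunable scaling factors in all (`var_hx_scal`, `cons_scal` and
`base_scal` act inside VHC; `var_hx_cons_scal`, `Pos_scal`, `SS_scal` are
the outer weights above).

## The VHC decision tree

For a variant with evidence `(genbank_count, reports)` at a position with
conservation column `counts`:

* **Branch 1 — reported pathogenic.** `var_hx_scal * path + cons_scal * cons`,
  where `path` is the maximum stratum weight over the variant's reports:
  confirmed & heteroplasmic 1.0, confirmed & homoplasmic 0.8, unconfirmed &
  heteroplasmic 0.6, unconfirmed & homoplasmic 0.4. Heteroplasmic reports
  outrank homoplasmic ones because pathogenic mt-tRNA variants are typically
  heteroplasmic; experimental confirmation (single-fiber or cybrid) outranks
  unconfirmed association.
* **Branch 2 — observed, never reported.** `var_hx_scal * (pop - 1) +
  cons_scal * cons`. `pop` is one minus the percentile rank (divided by 100)
  of the variant's observation count within the benign count distribution,
  so frequently observed variants earn a negative history term — presence in
  many healthy-population sequences is evidence of tolerance.
* **Branch 3 — novel.** `base_scal + cons_scal * cons`. Absence from a large
  population panel is itself informative: the base score penalises
  unobserved variants, and the conservation term scales the penalty by how
  invariant the position is.

**Percentile convention.** The rank is strictly-below with tied counts
sharing the mean rank, with one explicit boundary rule: a count at or above
the distribution maximum takes percentile 100 (score 0), and a count below
every entry takes percentile 0 (score 1). This keeps `pop` monotone
non-increasing in the count and pins both endpoints.

**Conservation.** With `k` panel species carrying the alternate base out of
`N`, `cons = 1 - log(1 + k)/log(1 + N)`: 1 when no species carries the
alternate base, 0 when all do, strictly decreasing in `k`. The logarithm
base cancels in the ratio; the natural log is used and documented only for
bit-reproducibility. Deletions are never a panel base, so they always take
`k = 0`.

The benign count distribution that anchors the percentile is the set of
observation counts of report-free variants seen at least once.

## The generic cloverleaf alignment

The cross-tRNA alignment is anchored on the four stems (acceptor, D,
anticodon, TψC) and on the anticodon triplet itself; these are the regions
whose geometry is comparable across tRNAs. Concretely:

* stem positions share a slot by (stem half, within-stem pair index), so
  stems of unequal length still align pair-by-pair from the stem ends;
* anticodon bases align position-by-position (the triplet is taken as the
  central three bases of the anticodon loop, since annotations carry element
  boundaries only);
* loop and variable-region positions align **end-anchored**: counting in
  from each loop end toward the middle, ties to the 5' side. Loops of
  different length therefore share their end-proximal slots, and a longer
  loop owns extra central slots.

The end-anchored loop rule is a design choice: only the stems and the
anticodon have a physically forced correspondence, and loop positions
adjacent to stems are the most geometrically constrained, so structural
analogy is preserved where it is most credible. The discriminator base is
modelled as a single unpaired element; post-transcriptionally added
residues are outside the encoded gene and are not modelled.

The **position score** of a slot is the mean, over every tRNA position
mapping to the slot, of that position's VHC summary — itself the mean of the
VHC scores of the position's 4 possible alleles (3 substitutions + the
deletion). Averaging over all 4 alleles, rather than a single named allele,
is forced by the fact that the analogous position in another tRNA has no
canonical "same" allele. Both means are unweighted.

## The secondary-structure score

Unpaired positions score 0. For a stem position at within-stem index $i$ in
a stem of $L$ pairs,

$$ \mathrm{SS} = w(i)\,\bigl[\mathrm{class}(\text{new pair}) -
   \mathrm{class}(\text{old pair})\bigr], \qquad
   w(i) = \tfrac14 + \tfrac34\,\frac{(i - \frac{L-1}{2})^2}{(\frac{L-1}{2})^2}. $$

$w$ is 1 at both stem ends and 0.25 at the centre: mispairing at a stem end
frays the helix from its terminus and disrupts the adjacent loop or the
acceptor end, while a central mismatch is buffered by flanking pairs. The
steric classes order pairs by disruption — Watson–Crick 0, G·U wobble 1,
pyrimidine–pyrimidine 2, other mismatch (A·C type) 3, purine–purine 4 — and
a single-base deletion inside a stem takes the maximal class, since it
shifts the pairing register. The difference form makes the score
antisymmetric: a substitution that *improves* pairing (wobble to
Watson–Crick) scores negative, so common compensatory polymorphisms can
drive the total below zero. Stems of a single pair are rejected as
degenerate ($w$ is undefined).

These constants (stratum weights, steric classes, the 0.25 floor) are
concrete choices: the published description of the method fixes only the
orderings (ends above centre, unobserved above observed, confirmed and
heteroplasmic above unconfirmed and homoplasmic, pairing improvements below
zero). All of them live in one constants block at the top of `R/scoring.R`
for retuning.

## Take-one-out evaluation

To measure how the system would treat a variant *naively*, each labelled
reference variant is re-scored with its own evidence deleted: it drops to
the novel branch, and the position score of its slot is recomputed without
its contribution. The benign count distribution is held at its full-data
value during deletion — it is a property of the population database as a
whole, where removing a single variant's counts is negligible, and treating
it as an upstream input keeps the take-one-out operation exactly linear in
the deleted entry. That linearity is what `loo_rescore()` exploits: the
deletion is applied as an exact algebraic adjustment of cached slot means,
verified in the tests against a literal delete-and-rescore oracle to
machine precision.

The sensitivity/specificity sweep calls a variant pathogenic when its score
is **greater than or equal to** the threshold (closed on the pathogenic
side, so the crossover is well defined under ties), and the crossover is
the threshold minimising |sensitivity − specificity|, ties resolved toward
the lower threshold — in a screening context the cheaper error is the false
positive. Reported percentiles are computed against the distribution of
*all* possible variant scores and clamped to 1–99; the four ACMG-style
categories follow the quartiles (Q1 likely benign … Q4 likely pathogenic).

## Tuning the scaling factors

The six factors are tuned by classic differential evolution
(DE/rand/1/bin, F = 0.7, CR = 0.9, greedy selection), minimising

$$ 2 - \bigl[(\mathrm{sens} + \mathrm{spec}) -
   |\mathrm{sens} - \mathrm{spec}|\bigr] = 2 - 2\min(\mathrm{sens},
   \mathrm{spec}) $$

evaluated at the crossover of the take-one-out sweep. The objective rewards
only the worse of the two rates, so the optimum is balanced by
construction. F and CR are textbook defaults — the method itself is the
named choice here, not its hyperparameters — and are isolated in
`de_control()`. Bounds default to (0, 20) for the five positive factors and
(−5, 20) for `var_hx_scal`, whose sign flips the benign-rewarding branch.
DE is stochastic: different seeds reach different near-optimal factor
vectors with similar objective, so `tune_scaling_factors_multi()` runs
several seeds and keeps the lowest objective (ties to the first seed).
Default population 15 and 30 generations converge comfortably on the
benchmark below; the evaluation is cheap because the objective is evaluated
through the cached linear take-one-out design, not by re-traversing the
score table.

## The synthetic benchmark

No public snapshot of the curated variant databases or the species panel
can be redistributed here, so the package ships a generator
(`fixture_spec()`, `simulate_dataset()`) that emulates their statistical
shape:

* **Genome.** 22 cloverleaf tRNA genes (acceptor 7 bp, D 4 bp, anticodon
  and T 5 bp stems; loops 7–9 nt; anticodon loop 7 nt) alternating between
  heavy and light strand with short random spacers — a compact ~1.6 kb
  concatenation, not a full 16.5 kb mitogenome, which is sufficient for
  every operation. Stems are Watson–Crick paired apart from an expected one
  seeded G·U wobble per gene.
* **Conservation.** A 30-species panel; stems and anticodon draw the
  reference base at ~95%, loops at ~60%, the remainder spread over other
  bases and gaps.
* **Evidence and labels.** 38 pathogenic variants (1–3 reports each,
  heteroplasmic with probability 0.7, confirmed with probability 0.5, few
  or no population observations) and 651 benign variants (no reports,
  geometric observation counts with success probability 0.3, mimicking the
  long-tailed allele-frequency skew of population databases with a single
  parameter) against a nominal panel of 40,000 sequences.
* **Planted signal.** With probability `effect_strength` (default 0.9) a
  pathogenic variant is placed at a conserved stem-end or anticodon
  position and a benign variant at a weakly conserved loop position;
  otherwise placement is uniform. The preference is symmetric by design so
  that `effect_strength = 0` yields a genuine null benchmark — both classes
  positionally uniform, alt alleles uniform for both — on which the
  take-one-out crossover sits at chance (≈0.5). If only the pathogenic
  placement were modulated, residual benign structure would leak class
  signal into the "null".

On the default planted benchmark, tuned factors reach balanced
take-one-out sensitivity and specificity in the mid-0.9s; the tests assert
≥ 0.85 with |sens − spec| ≤ 0.1 at a fixed seed, and chance ± 0.1 on the
null. What this shows is that the pipeline recovers a signal of exactly the
kind the score is built to detect. What it does **not** show is real-world
accuracy: real conservation columns are phylogenetically correlated, real
report curation is noisy and biased toward famous variants, real benign
variants are not independent draws, and tRNA-specific idiosyncrasies (the
missing D-arm of tRNA-Ser(AGY), modified bases) are not emulated.

## Numerical and degenerate-input choices

* Scores and adjustments are plain double arithmetic; the summation
  identity `total = var_hx_cons_scal*vhc + Pos_scal*pos + SS_scal*ss` holds
  exactly (bit-for-bit) because the total is computed as that expression.
* All randomness flows from explicit integer seeds (`fixture_spec(seed=)`,
  `de_control(seed=)`); the generator derives per-table seeds by fixed
  small offsets, and identical seeds reproduce byte-identical files.
* A conservation table missing a position is completed with a flagged
  all-gap column (`cons = 1` for every alternate) rather than an error;
  variants absent from the evidence table are canonically novel.
* Degenerate sweeps (all scores identical) are flagged rather than
  rejected; single-pair stems and single-class label sets are errors.
* Problem sizes in the test suite: the full benchmark (22 genes, 6,000+
  scored variants, 689 labelled) exercises tuning and the end-to-end
  contracts; oracle-equivalence checks run on 100 two-gene fixtures.

## Known limitations

* Heteroplasmy of the *query* sample is deliberately not modelled; the
  score is a prior to be weighed against patient heteroplasmy and family
  data.
* The six factors are tuned against curated labels, so database errors
  propagate (a mislabelled reference variant shifts the optimum); the
  take-one-out protocol removes self-evidence but not label error.
* Positions whose pathogenicity is not mediated by conservation, structural
  analogy or stem sterics — e.g. variants acting through aminoacylation
  identity elements in loops — are systematically under-scored.
* The percentile presentation compresses the tails: scores beyond the 99th
  percentile are indistinguishable by rank.
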