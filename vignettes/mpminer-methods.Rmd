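---
title: "Mining and modeling melting-point data with mpminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and modeling melting-point data with mpminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpminer)
```

## The problem

Melting point (MP) is one of the few physicochemical properties reported
for nearly every newly synthesized solid, usually as a one-line
declaration buried in the characterization sentence of an experimental
section ("white needles, m.p. 184–186 °C"). Harvested at scale, such
declarations support quantitative structure–property (QSPR) models of MP
— and through the general solubility equation, of aqueous solubility.
`mpminer` implements the full chain: a grammar-based parser for MP
declarations, association of declarations with annotated chemical
entities, curation into one record per molecule, estimation of the
experimental reproducibility of the data, sparse-descriptor consensus
kernel regression with outlier filtering, a classifier for compounds
that decompose rather than melt, and hypergeometric enrichment of
structural features. Chemical named-entity recognition is deliberately
an *input* (pre-annotated spans), not part of the package.

## The declaration grammar

A declaration is matched as

```
FromLiterature? MeltingPoint Qualifier? (Value | Range | MeasurementError) OutcomeQualifier?
```

with `m.p.`, `mp`, `mpt` and `melting point` prefixes; `>`, `<`, `≥`,
`≤`, `~`, `about`, `approximately`, `approx.` and `ca.` qualifiers;
numerals, decimals and spelled-out cardinals (supported up to 999 with
tens/hundreds composition — enough for any plausible temperature without
solving open-ended language understanding); `-`, `–`, `—` and `to` as
range separators; Celsius and Fahrenheit units; and `decomp.`/`subl.`
style outcome qualifiers. Everything is normalized to a Celsius
interval: measurement errors `v ± e` become `[v − e, v + e]`, Fahrenheit
is converted by `(F − 32)·5/9`, single values become degenerate
intervals, and the verbatim source text is retained. A missing unit
defaults to Celsius, since unitless ranges are the common form inside a
Celsius-normalized corpus. Spelled-out ranges ("fifty-five to sixty")
are not parsed as ranges; they are vanishingly rare compared with
numeric ranges and the first cardinal still yields a usable value.

Two malformed-range repairs are applied before any flagging, because
they are unambiguous to invert: a decimal comma in a bound
(`82-82,5` → 82–82.5) and a truncated upper bound, which is expanded by
borrowing the missing leading digits from the lower bound
(`159-62` → 159–162, `160-2` → 160–162) provided the result is not
inverted. Everything else is left as written and flagged instead:
values above 500 °C, ranges wider than 50 °C, inverted ranges, and — a
fourth rule added here after meeting misprints like "−383 °C" — values
below absolute zero. Flagged records are never silently dropped; the
flag travels with the record so curation can count what it excludes.

## Association

Documents arrive as ordered heading/paragraph blocks with pre-annotated
entity spans. Headings partition the blocks into experimental sections
(leading headingless paragraphs form one anonymous section). A mention
is bound **explicitly** when it sits inside a bracketed group opening
within `window` characters (default 80, configurable — the source
evidence only says "close proximity") after a structure-bearing entity
in the same sentence; otherwise a mention in the final paragraph of a
section binds **implicitly** to the section's target compound, taken as
the last structure-bearing entity of the heading or, failing that, the
first structure-bearing entity of the section — the synthesized product
is normally named in the heading and again in the closing
characterization sentence. Explicit binding always wins, ambiguous
explicit candidates bind to the nearest preceding entity with a
warning, and unbound mentions are reported with a reason rather than
discarded. Records serialize to SDF with provenance fields
(`PATENT_ID`, `PARAGRAPH_NUM`), so any value can be traced back to its
paragraph.

## Curation

Records flagged suspicious are excluded, as are mixtures (SMILES with
more than one connected component — no salt stripping is attempted,
mirroring the exclusion-not-desalting policy of the source pipeline)
and structures that fail to parse. The molecule key is the canonical
SMILES (Open Babel). Within a molecule, measurements differing by at
most ΔT = 1 °C are full duplicates; merging is transitive
(single-linkage over the midpoints), since "duplicate" chains should
collapse to one value, and the first-seen record of each cluster is
kept. The surviving distinct values are genuine repeated measurements.
One representative record is selected per molecule: the one whose
midpoint is nearest the median of the distinct values, with an even
count resolved by the mean of the two central values and exact ties
broken toward the lower temperature, then the earlier document id —
arbitrary but deterministic. ΔT is compared between interval midpoints.
The drug-like subset keeps midpoints in the closed interval
[50, 250] °C.

## Experimental accuracy

If each measurement has standard deviation σ, the difference of two
independent measurements has variance 2σ², so σ is estimated from all
pairwise absolute differences of repeated measurements as
`sqrt(mean(ΔT²)/2)`. This /√2 convention matters: it is stated
prominently because the headline numbers depend on it. Because
duplicate elimination removes pairs with ΔT ≤ 1 °C, the first two bins
of the integer ΔT histogram (bin *b* covers [*b*, *b*+1), contributing
at its center) are artificially depleted; the correction sets bins 0
and 1 each to the mean of the counts in bins 2 and 3 — the closest
literal reading of "the same number of counts as observed for
ΔT = [2, 3]" — and recomputes σ. The temperature-binned accuracy curve
sorts duplicate pairs by pair mean, forms adaptive equal-count bins of
at least 50 pairs, computes a per-bin σ, and can be rescaled by one
global factor so the count-weighted mean matches a target; pairs with
sub-zero means are excluded by default since they are dominated by
processing errors in mined data.

## Descriptors and modeling

QNPR descriptors are counts of contiguous SMILES substrings of one to
three characters, kept when they occur in at least five molecules; the
frequency threshold counts molecules containing the substring, not
total occurrences (the looser of the two readings, configurable).
Splitting is literal — `Cl` is two characters — and canonical SMILES
are fixed upstream so descriptors are reproducible. The matrix is held
sparse; its sparseness statistic is zero entries per non-zero entry.
Unsupervised filtering drops descriptors with two or fewer non-zero
values, then groups descriptors with pairwise R² > 0.95, keeping the
first of each group by column order (greedy, deterministic; no graph
clustering is needed for a target-blind step). The target property is
never consulted, so no selection bias is introduced.

Regression uses ε-SVR with an RBF kernel (libsvm via `e1071`).
Predictors are standardized internally but the response stays in °C,
so ε and C keep their physical meaning; the default triple
(C = 256, ε = 16 °C, γ = 1/p) is the regime found optimal in
large-scale MP modeling, with γ following the libsvm convention.
Validation is fivefold cross-validation with a uniform random fold
permutation (no stratification) under a mandatory seed; interval
targets are collapsed to midpoints upstream, and qualifier-bearing
(">", "<"), sublimation- and decomposition-labeled records are best
excluded from MP regression before training. A grid search over
(C, γ, ε) triples on a configurable fraction of rows breaks ties
toward the smallest C, then γ, then ε. With a wide ε tube libsvm can
return a support-vector-free model; the fit then falls back to
predicting the training mean rather than failing.

Consensus models combine members by simple average, by accuracy
weighting with w = 1/RMSE, or by a linear stack (MLRA) trained on the
members' out-of-fold predictions. The weighted form normalizes by Σw —
a weighted mean, which provably reduces to the simple average for
equal member accuracies, matching the observed behavior of accuracy
weighting; the root-sum-square normalization `√Σw²` that appears in
some write-ups does not have this property and is available behind
`normalization = "rms"` for comparison. The distance-to-model
(CONSENSUS-STD) is the standard deviation of member predictions.

Outlier filtering assumes residuals are N(0, σ) with σ = model RMSE.
For a two-sided tail probability *p* the threshold is z·σ with
2(1 − Φ(z)) = *p*; N·p flags are expected by chance, and the ratio of
observed to expected flags is the signal-to-noise ratio (SNR). The
two-sided convention is forced by the reference arithmetic (22.9
expected at p = 10⁻⁴ for N = 229,000; |z| = 2 giving p just under
0.05). An SNR near 1 means flagged rows are statistically ordinary and
removing them would only shrink the training set.

The decomposition classifier uses stratified bagging: each of 64 bags
resamples the minority class with replacement to its own size and
samples the majority (also with replacement) down to the same count, so
every bag holds exactly twice the minority size with equal class
counts. Out-of-bag votes give each row a prediction from bags that
never trained on it; accuracy is reported as balanced accuracy. Base
learners are pluggable `fit`/`prob` pairs; the default mixes an RBF-SVM
and a decision tree, echoing heterogeneous-ensemble practice.

## The synthetic generators

The corpus generator emits patent-shaped documents — a heading naming
the product, synthesis prose with a structureless precursor entity, and
a characterization tail carrying the declaration either bracketed after
the product entity (explicit) or at the section end (implicit) — with a
ground-truth table constructed jointly with the text. Value kinds cycle
deterministically so all grammar productions appear; qualifiers,
literature markers, outcomes, Fahrenheit units (5%) and spelled-out
values (10%) are sampled at configured rates. Five error classes can be
injected, each inverted exactly by the repair/flag machinery when the
pipeline is correct: decimal commas and truncated ranges (repairable),
inverted ranges, missing decimal points and ten-fold misprints
(flagged). Default injection rates are 2% per class, a realistic error
density for semi-structured text.

The QSPR generator draws molecules from an enumerable family of about
5,100 terminal-group + alkyl-chain + (hetero)aromatic-scaffold
combinations, canonicalized and de-duplicated. The latent MP is linear
in composition counts (rings, nitrogens, oxygens, halogens, acid/amide
groups, chain length) plus a mild ring×nitrogen interaction — visible
to substring descriptors, yet non-linear enough that kernel learners
beat a linear stack — shifted so the family median is 155 °C, the
median of mined patent data. Observations add N(0, σ) noise with
σ = 35 °C, the estimated reproducibility of mined MP measurements;
5.5% of molecules decompose, their median shifted +55 °C (to 210 °C);
duplicated molecules are re-observed with fresh noise; gross outliers
(2% of observations) are offset by 5σ. What the generator does *not*
emulate: realistic patent prose, polymorphism, systematic
threshold-reporting peaks (e.g. values heaped at 250 °C), or chemistry
outside the enumerated family — so green tests certify the machinery,
not performance on real mined text.

## Problem sizes and numerical choices

The test suite runs the parser round trip on 1,000 sections, σ
recovery on 10⁴ simulated pairs, outlier filtering and refit on 5,000
molecules, bagging on 2,000 rows with 64 bags, and consensus on 800
molecules with three members — sizes at which the targeted statistical
properties (5% σ recovery, ≥80% outlier recovery with SNR above 2,
chance-level balanced accuracy within ±0.05) hold with margin while a
full check stays comfortably within an interactive session.
Tolerances on exact arithmetic are 10⁻¹²; Monte-Carlo assertions use
3-standard-error bands. Degenerate inputs fail loudly: empty
difference vectors, all-zero descriptor matrices, empty classes and
non-positive σ are errors, while an empty ε-SVR support set and
missing histogram bins degrade gracefully (mean fallback, skipped
correction with warning).

## Known limitations

* The parser targets English experimental prose with the standard
  declaration forms; OCR noise beyond the stated repair rules is out of
  scope.
* Explicit association requires bracket syntax; prose appositions
  ("benzamide, m.p. 101 °C") bind only through the implicit route.
* The hypergeometric enrichment treats features as independent tests;
  BH q-values are attached (the reference tool reports raw p only), but
  correlated features remain correlated.
* GSE predictions inherit the full error of the supplied logP; no logP
  model is bundled.
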