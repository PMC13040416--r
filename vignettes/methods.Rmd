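---
title: "Methods: screening candidate rHuEPO biomarkers against exercise and altitude confounding"
author: "epoScreen"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epoScreen)
```

# Overview

`epoScreen` asks one question of a candidate doping-biomarker panel: which
of these genes move *only* under rHuEPO administration, and not under the
physiological stimuli — exercise and altitude hypoxia — that activate the
same erythropoietic axis? The pipeline answers it in five stages:
nomenclature harmonisation, an effect-size exercise screen, replication of
per-study altitude differential-expression cut-offs, a two-step
set-overlap that partitions the panel, and over-representation analysis of
the surviving confounder-free genes. This vignette documents the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

# The exercise screen

## Effect sizes from summary statistics

Exercise databases of reprocessed RNA-seq typically expose only per-group
summaries: mean and SD of normalised expression per condition, and an
omnibus rank-test p-value. Group sizes are not published. The screen
therefore uses the standardized mean difference with an **equal-weight
pooled SD**,

$$d = \frac{m_1 - m_2}{\sqrt{(s_1^2 + s_2^2)/2}},$$

rather than an $n$-weighted pooling, which would require the unavailable
group sizes. `effectSizes()` computes one $d$ per gene per non-control
modality, always from the summary statistics (never from attached raw
values), so results are identical whether or not per-sample data are
present.

Degenerate cases are resolved explicitly: if both SDs are zero and the
means are equal, $d = 0$ (a true null); if both SDs are zero and the
means differ, $d$ is undefined (NaN) with the sign of the mean difference
recorded. An undefined $d$ counts as a threshold hit only when
`ScreenConfig(undefinedIsHit = TRUE)` — the default is conservative.

## The screening rule

`classifyGene()` assigns one of four statuses from the omnibus p:
`significant` (p below `alpha`), `nan_p` (p is NaN), `not_significant`,
or `missing` (the gene is absent from the expression resource). The four
statuses always partition the panel. A gene is *responsive* when

* the p gate is open — `significant` or `nan_p` (with
  `gateOnP = TRUE`, the default), or unconditionally with
  `gateOnP = FALSE`; and
* at least one modality reaches `|d| >= dThreshold`.

Defaults: `alpha = 0.05`, `dThreshold = 0.5` (a moderate effect,
the conventional boundary for biologically meaningful shifts),
`controlLabel = "inactivity"`. Two deliberate subtleties:

* **Strict alpha.** The gate uses `p < alpha`; the boundary
  `p == alpha` is measure-zero in practice, but `alphaInclusive = TRUE`
  switches to `<=` for exact replication of analyses that used the
  inclusive form.
* **NaN as a pass-through.** A NaN omnibus p arises when some group has
  zero within-group variance, so the rank test's tie-correction
  denominator vanishes. Such genes cannot be tested but can still carry
  large effects; gating them *in* (rather than discarding them) is a
  design choice that keeps constant-in-one-group genes assessable by
  effect size.

## The rank test

`kruskalWallis()` delegates to the standard tie-corrected Kruskal–Wallis
statistic with the chi-squared approximation. When every observation is
identical the statistic and p are NaN — precisely the degenerate state
the screening rule expects. The chi-squared approximation deviates from
the exact permutation null at very small group sizes (at $n = 3 + 3$ by
up to ~0.05 in p); the test suite quantifies this against an exhaustive
enumeration oracle.

## Reproducing published two-decimal effect sizes

The package ships a summary-statistics fixture of the candidate panel and
the corresponding published two-decimal effect-size table. Recomputing
$d$ from summaries that are themselves printed at two decimals propagates
the input rounding into the result: to first order, means rounded within
$\pm 0.005$ shift $d$ by $0.01/s_p$, and SD rounding adds
$|d|\,0.005\,(s_1+s_2)/(2 s_p^2)$. Where the pooled SD is small (~0.2 on
this scale) the reproduction can move by several hundredths even though
both computations are exact. The unit tests therefore assert each cell of
the published table within this per-cell propagation bound (plus the
$\pm 0.005$ rounding of the printed value itself); a handful of cells
genuinely differ by more than a bare $\pm 0.005$ for this reason, which
the acceptance suite reports honestly rather than masking. One published
effect-size row (CD3D) has no matching summary row in the source tables
(CD3G appears instead); the package treats this as a source-data
inconsistency and does not special-case it.

# Gene-symbol harmonisation

Harmonisation is **offline and table-driven**: the resolution that a live
nomenclature service would provide is consumed as snapshot tables, making
runs reproducible. Matching is case-insensitive through an uppercase key
while the original spelling is preserved in the audit log; `LOC` + digits
flags a provisional placeholder.

The resolution order is total, so results never depend on input order:

1. exact approved-symbol match;
2. synonym match, tie-broken by protein-coding biotype, then non-empty
   description, then the lexicographically smallest approved symbol —
   `ambiguous` is flagged whenever more than one candidate entered the
   tie-break;
3. a second pass of unresolved entries (typically LOC placeholders)
   against a secondary snapshot; a hit re-queries the primary table for
   metadata, and the primary's biotype wins if the two snapshots disagree;
4. anything still unresolved is reported `unmapped` — never an error.

Inputs resolving to the same approved symbol collapse into one panel
member with the union of their provenance; the audit log keeps one row
per input, so `|inputs| == |audit rows|` always holds, and harmonising an
already-harmonised panel is the identity.

# Altitude DEG filters

Each study's published cut-offs are encoded as a `ThresholdConfig` with
the printed operator's inclusivity respected *exactly*: `FC >= 1.2` and
`FDR <= 5%` are inclusive; `q < 0.01` and `log2FC > 0.5` are strict.
Linear and log2 effect bounds are interchangeable (a linear bound is
stored as its log2); when a row supplies only a linear fold change the
conversion snaps 1-ulp floating noise at 12 significant digits so that a
bound stated on either scale treats equivalent rows identically.

Filters are **two-sided by default** (`|log2FC|`), since DEG lists
conventionally include down-regulation even when the published bound is
printed one-sidedly; `twoSided = FALSE` restores the literal one-sided
reading. One study dialect publishes no p criterion, so its config
applies only the effect bound. A row missing a required adjusted p fails
rather than erroring. Contrast labels (altitude intervals, exposure days)
are carried through to a per-contrast breakdown; the day-level sets of
the multi-day study are retained separately and unioned into the study
set, and the per-study sets are aggregated into the altitude union with a
TRUE/FALSE presence matrix.

# Two-step overlap

Step one aggregates confounder sets (the altitude union); step two
decomposes candidate/altitude/exercise membership into the seven
exclusive Venn regions. Overlap is symbol-level; direction of regulation
travels only as provenance metadata. Attribution of the
candidate-altitude overlap partitions it by study sharing pattern
(unique-to-one plus every higher-order intersection, zero counts
included), which both documents the origin of confounding and provides a
partition invariant the tests verify exhaustively.

# Over-representation analysis

Per term: $k$ input genes in the term, $n$ mapped input genes, $K$
universe genes in the term, $N$ universe genes, upper-tail
$p = P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ evaluated
through the log-space survival function, Benjamini–Hochberg adjustment,
fold enrichment $(k/n)/(K/N)$ and rich factor $k/K$. Terms are restricted
to their universe members; input genes outside the universe are dropped
with a warning; an input that maps to nothing is an error. Results sort
by `(pvalue, ID)` — the ID tiebreak makes ranking deterministic.

Choices worth knowing:

* **Universe.** `buildUniverse("measured", ...)` restricts the
  background to the genes actually detectable in the source experiment —
  the honest testable space that avoids inflating significance —
  while `"genome"` uses a full annotation table, the conventional
  fallback when only DEG lists exist. Both sizes are configuration, not
  constants.
* **Biotype exclusion.** Pseudogene (and other) inputs can be excluded
  before testing via a symbol/biotype table; the shipped 50-gene
  confounder-free panel fixture maps 45 genes once its five
  pseudogene/LOC entries are excluded.
* **q-values.** The default q column equals the BH-adjusted p. A
  Storey-style estimate is available behind `qMethod = "storey"` with a
  single fixed $\lambda = 0.5$ — a deliberate simplification; no smoothed
  $\lambda$ grid is fitted.
* **z-scores.** `withZ = TRUE` adds the normal-approximation score
  $(k - nK/N)/\sqrt{\mathrm{Var}}$. It is descriptive, non-canonical,
  and not part of any test decision.
* **Term-size filters** default to off.

# The synthetic-data generators

The generators exist so every stage is testable end-to-end with known
ground truth and no downloads. `SimConfig` fixes the study conditions:

* six conditions — acute aerobic/anaerobic, long-term aerobic/resistance,
  other modalities, and the sedentary control `inactivity`;
* 30 samples per condition by default. The source database does not
  publish per-modality group sizes, so this is exposed as configuration;
  30 per group is a realistic mid-size cohort at which a planted
  $d = 1.2$ is recovered with >95% sensitivity;
* group-wise Gaussian noise on the normalised-expression scale (baseline
  level U(2, 10), per-gene SD U(0.5, 1.5)), with planted effects shifting
  a condition's mean by $d$ SDs relative to control;
* zero-variance genes: one non-control group frozen at a constant and the
  omnibus p set NaN — the mechanism mirrors the observed failure mode
  while still permitting nonzero effect sizes on NaN-p genes, as real
  NaN-p genes show;
* per-dialect planted DEG fractions (default 5%), with planted rows
  passing their dialect's cut-offs by construction and every other row
  violating at least one criterion;
* alias corruption (defaults: 15% synonyms, 10% case/whitespace damage,
  5% LOC placeholders resolvable only through the secondary snapshot);
* annotation sets of 50 random terms of 10–50 genes, with planted terms
  drawing 80% of their members from a designated input set.

Each generator draws from its own RNG stream derived from the master seed
by a fixed offset, so outputs are byte-reproducible and adding one
generator never perturbs another. Altitude-interval contrast labels use
ASCII hyphens (`200-3800M`, `200-5100M`, `3800-5100M`).

**What the generators do not emulate:** raw reads or microarray
intensities, library-size or batch structure, gene–gene correlation,
heavy-tailed or zero-inflated counts, and the internal count models of
the upstream database. Passing recovery tests therefore demonstrate that
the *pipeline logic* is correct under its own statistical assumptions —
not that those assumptions hold for any particular real dataset.

# Problem sizes and test design

The test suite runs entirely on generated or shipped-text data. Sizes
were chosen as the smallest that make the statistical assertions sharp:
200 replicate seeds for effect-recovery and null-calibration Monte-Carlo
(binomial standard errors below 0.5%), 1,000 random set-triples against
the exhaustive Venn oracle, 1,000 random rows plus explicit boundary rows
per DEG dialect against an independent row-scan, the full hypergeometric
grid to $N = 20$ against combinatorial enumeration, and a 20-seed, 110
genes-per-seed sensitivity run for the screen. Published GO-term
statistics and raw-data DEG counts depend on external annotation releases
and raw files and are out of scope by design; the property suites above
stand in for them.

# Known limitations

* The equal-weight pooled SD is an assumption forced by unpublished group
  sizes; with very unbalanced real groups an $n$-weighted $d$ would
  differ.
* The screen treats the omnibus p as a single per-gene quantity; no
  per-modality or longitudinal testing is attempted.
* Harmonisation quality is bounded by the supplied snapshots; the
  package never queries live services.
* Overlap is symbol-level: platform or isoform-level disagreements
  collapse to their symbols.
* ORA ignores annotation DAG structure and term redundancy; no
  semantic collapsing is performed.
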