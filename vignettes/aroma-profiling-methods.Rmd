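---
title: "Methods: Kovats identification, semi-quantification and aroma networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Kovats identification, semi-quantification and aroma networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(aromaprofiler)
library(dplyr)
```

## The problem

Fortified Madeira-style wines owe their sensory identity to trace volatile
organic compounds (VOCs), most at µg/L level. A headspace-SPME/GC–qMS
profile of such a wine yields a peak table: retention times, areas, and
(optionally) a spectral-library candidate with a NIST resemblance score.
Turning that table into statements like "(Z)-whiskylactone plausibly drives
the toast note of old wines" requires four chained inferences, each of which
this package implements as an explicit, testable function:

1. **Identification** — convert retention times to Kovats retention indices
   (KI) against an n-alkane ladder and accept a compound only when spectral
   and retention evidence agree ([`identify_peaks()`]).
2. **Semi-quantification** — scale peak areas by a spiked internal standard
   ([`semi_quantify()`]).
3. **Impact-odorant screening** — compare concentrations to odor thresholds
   (OT) via odor activity values, OAV = c/OT ([`screen_impact_odorants()`]).
4. **Aroma networks** — relate compounds, aroma notes, grape varieties and
   wine ages through a bipartite graph and its shared-compound projections
   ([`build_bipartite()`], [`project_varieties()`]).

The packaged reference library transcribes an 82-compound Madeira wine VOC
inventory spanning ten chemical families (21 esters, 13 higher alcohols, 10
terpenic compounds, 9 acids, 7 norisoprenoids, 7 furanic compounds, 6
lactones, 4 acetals, 4 volatile phenols, 1 sulphur compound), with each
compound's calculated and literature KI, identification evidence, odor
threshold (determined in 10–12% v/v ethanol), odor descriptors, and the
flagged subset of descriptors that constitute Madeira aroma notes.

## Kovats indices and the identification rule

For temperature-programmed GC the van den Dool–Kratz convention defines, for
a peak eluting between alkanes C$_n$ and C$_{n+1}$,

$$\mathrm{KI} = 100\,n + 100\,\frac{t_R - t_{R,n}}{t_{R,n+1} - t_{R,n}},$$

a piecewise-linear, strictly increasing map from retention time to index,
equal to $100 n$ at each anchor. `compute_ki()` implements exactly this (and
its inverse `rt_from_ki()`); the test suite checks it against an independent
bracket-search oracle on a thousand random ladder/retention-time pairs.

A peak is **accepted** iff

* when a spectral candidate with a resemblance score exists, the resemblance
  is at least 80% (the `min_resemblance_pct` default; a candidate at 79%
  with a perfect KI is still rejected), and
* when the candidate has a literature KI, the agreement satisfies both
  $|\mathrm{KI_{calc}} - \mathrm{KI_{lit}}| \le 35$ index units and a 5%
  relative bound (`abs_tol`, `rel_tol_pct`).

Peaks with no spectral candidate may still identify on retention index
alone, but are flagged as lower-tier (`RI`) evidence, mirroring the
distinction between `MS, RI` and `MS, RI, Std` identifications in the
library. The 35-unit default is treated as an upper bound on acceptable
deviation, not as a value the library must attain: over the packaged
records that carry a literature KI the observed deviations run from 0
(linalool, 1537 vs 1537) to 28 (geraniol, 1981 vs 2009), at most 1.6%
relative:

```{r}
glance(ki_deviation_report(read_voc_library()))
```

**Tie-breaking** is fixed and tested because the underlying convention does
not specify it: when several peaks pass for one compound, the smallest
$|\Delta \mathrm{KI}|$ wins, then the largest area, then elution order; each
library compound is assigned to at most one peak.

**Extrapolation** beyond the ladder ends is off by default (an out-of-span
retention time is an error naming the span) and available as an explicit
flag, since an extrapolated index silently degrades to a guess.

## Semi-quantification and replicate dispersion

Concentration relative to the internal standard (4-methyl-2-pentanol,
spiked at 250 µg/L) is

$$c_\mathrm{VOC} = \frac{A_\mathrm{VOC}}{A_\mathrm{IS}} \times c_\mathrm{IS},$$

linear through the origin in area. This is deliberately a
*semi*-quantification — no calibration curves, response factors or
matrix-effect correction — which suffices for threshold screening and
family-level trend statements, and is all the chained analyses consume.
Replicate dispersion is summarized as %RSD = 100·sd/mean per compound using
the sample (n−1) standard deviation; compounds with zero replicate mean are
flagged undefined rather than reported as 0% or infinity. Family aggregates
use the **mean** (not median) concentration per compound across a cohort's
samples, then sum over the family's members; whether such figures are means
or sums over samples is genuinely open, and the mean was chosen so totals
are comparable between cohorts of different size. An old-versus-young trend
is called `increase`/`decrease` only beyond a ±5% band (`flat_tol_pct`),
so floating-point-scale wobble never becomes a trend.

## Odor activity screening

OAV = c/OT, and a compound is a *potential impact odorant* of a sample when
its concentration **strictly exceeds** its threshold (OAV > 1): "higher
than" is read literally, so a concentration exactly at threshold is not
impact, and the boundary is tested. Compounds without a known threshold
(e.g. ethyl pyruvate) get `NA` OAVs — never 0 or ∞ — and can enter impact
tables only via the explicit `include_unknown_ot` switch, since such
compounds are sometimes discussed as odorants on other evidence. The
thresholds travel with the library and were determined in 10–12% v/v
ethanol; Madeira wines run 18–19% v/v, and no matrix correction is applied —
a known limitation: OAVs here rank candidates rather than certify
perceptibility.

The note-by-note impact table intersects, for each aroma note of a sensory
cohort, the compounds carrying that note with the compounds impact-flagged
in that cohort's samples. Because panel evidence can be merged across
varieties in more than one way, both a merged (one row per note) and a
per-variety view are exposed rather than hard-coding one aggregation.

## Aroma networks

The bipartite graph links each compound to its flagged aroma notes; its
note-level projection connects two notes by the number of compounds they
share, and the variety-level projection represents each grape variety by
the union of the compound neighborhoods of its sensory notes for one age
class, connecting varieties by shared-compound counts. Projection weights
are computed by explicit pairwise set intersection (and are cross-checked in
the tests against both a brute-force oracle and igraph's bipartite
projection); weight-0 pairs are omitted so disconnected nodes stay visible
as isolates. Composite panel notes — "dried fruits" — expand to member
descriptors (almond, coconut, nutty, peanut, walnut) before any
neighborhood computation, via a configurable grouping map. Panel notes with
no compound link (mushroom, tea, cocoa, ripe fruit) legitimately contribute
nothing rather than erroring: the panel vocabulary is broader than the
compound-descriptor vocabulary.

Two counts in this area are reported as computed diagnostics rather than
asserted constants: the packaged library yields 14 flagged note tokens
(after synonym normalization), and note inventories of 15 are reachable
under alternative tokenizations (e.g. keeping a composite note and its
members distinct), so the note count is configuration-dependent by design.
Descriptor normalization itself (lower-casing, whitespace/hyphen collapse,
and a packaged synonym map: toasty→toast, flower→floral, fruity→fruit,
woody→wood, spicy→spice) is applied wherever free-text descriptors enter.

One upstream inconsistency is preserved deliberately: the library's
terpenic inventory contains β-pinene (flagged citrus), while downstream
impact discussions sometimes name α-pinene among citrus odorants; the
library follows its own compound inventory and the discrepancy is noted
here instead of being silently "fixed".

```{r}
bp <- build_bipartite(read_voc_library())
length(shared_vocs(bp, "citrus"))   # nine compounds share the citrus note
sens <- read_sensory_profiles()
glance(project_varieties(bp, sens, "old"))
glance(project_varieties(bp, sens, "young"))
```

The old-wine projection is a complete 5-clique with a higher mean shared-VOC
weight than the young projection — the aging process homogenizes the aroma
vocabulary across varieties, which is exactly what the network formalizes.

## The synthetic study generator

No per-sample concentration data are published for the underlying study, so
the generator *emulates* the study conditions with known ground truth; its
outputs are synthetic by construction and never presented as measured
values. Choices, in order of consequence:

* **Design**: 22 wines, five varieties, ages 3–20 y (blended 3/5/10/15,
  vintage 17–20), wine type tied to variety (Malvasia sweet, Bual medium
  sweet, Sercial dry, Verdelho medium dry, Tinta Negra in all four types),
  every variety in both age cohorts; three replicates per wine by default,
  matching triplicate analysis. Sugar sits at each type's band midpoint and
  ethanol at 18.5% v/v.
* **Ladder**: the published per-compound (KI, retention time) pairs are not
  jointly consistent with any single piecewise-linear ladder (adjacent
  compounds imply locally contradictory slopes), so the synthetic ladder
  interpolates a monotone fit of that cloud at KI = 100·n and compounds are
  placed at the *ladder-inverse* of their published calculated KI — making
  identification exactly invertible, with retention times that stay close
  to the published ones (linalool: 23.18 min vs 22.88 published). The
  ladder spans C8–C28, a deliberate superset of the instrument's C8–C20
  calibration series, because library KIs reach 2620; this is documented
  rather than hidden because a real C8–C20 ladder cannot index a third of
  the library without extrapolation.
* **Concentrations**: base level 2×OT when a threshold is known — so aging
  multipliers push compounds across the threshold in both directions and
  the screen is exercised on both sides — else a family-typical µg/L scale.
  Old-wine multipliers: varietal (terpenic, norisoprenoid ×0.5) and
  fermentative (ester, higher alcohol ×0.7) families decline; furanic and
  lactone (×2.0), volatile phenol (×1.8) and acetal (×1.3) families rise;
  acids drift up slightly (×1.1). Ethyl pyruvate is held at 3.54 µg/L in
  Verdelho versus 1.49 µg/L elsewhere, reproducing the reported variety
  contrast for the ethereal note.
* **Noise**: multiplicative Gaussian with CV 5% by default (areas are
  positive and dispersion is reported as CV-like %RSD); negative draws
  truncate at zero area with a warning. Decoy peaks, when requested, carry
  random candidates with resemblance drawn below 80%, so the resemblance
  rule must reject every one.
* **Seeding**: each sample draws from its own stream derived from the study
  seed and the sample id, so any single sample can be regenerated without
  generating the rest; a fixed seed reproduces the whole study exactly.

What passing tests on these data do and do not show: exact noiseless
round-trips and seeded-noise RSD recovery validate the *pipeline algebra* —
identification inverts generation, quantification inverts the area formula,
the screen equals the brute-force threshold filter. They do not validate
peak picking, co-elution handling, spectral matching, or matrix effects,
none of which the generator simulates (it works at peak-table level by
design).

## Problem sizes and numerical choices

The test suite and the acceptance script run the full 22-wine design at one
replicate for exactness checks and three replicates for dispersion checks —
1,804–5,412 peaks end to end — with the KI oracle comparison at 1,000
random ladder/retention-time pairs; these sizes make every property
exhaustive over the 82-compound library while keeping a full run in tens of
seconds. Degenerate inputs are errors, not guesses: an empty library file,
a missing internal-standard peak, a single replicate for an RSD, a
retention time outside the ladder, an unknown compound id or note token all
fail with messages naming the offender. Boundary conventions are half-open
sugar bands (a shared boundary value belongs to the sweeter class, since
the published band edges reuse the same numbers in adjacent classes),
resemblance ≥ 80 acceptance, and strict OAV > 1 impact.

## Limitations

* Semi-quantification is IS-relative; concentrations are comparable within
  the study, not absolute.
* OTs are matrix-mismatched (10–12% vs 18–19% ethanol); OAV ranks, it does
  not certify.
* The aroma-note inventory depends on descriptor tokenization; counts over
  it are reported, not asserted.
* The generator emulates trends and noise, not chromatographic physics.
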