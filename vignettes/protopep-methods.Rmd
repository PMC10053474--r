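---
title: "Methods: protocode fusion, fragment interaction scoring, and the synthetic screen model"
author: "protopep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protocode fusion, fragment interaction scoring, and the synthetic screen model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protopep)
```

# The protocode model

## Codon assignments

A *protocode* assigns amino acids to 3-mer codons over one complementary
base pair — (A,U) or (G,C) — giving eight possible codons per code. Four
protocodes are modelled: dominant and recessive codes for each base
family, with the dominant and recessive code of a family competing for
the same eight codons (Phe and Leu both start at UUU; Pro and Ser both
start at CCC). Members may be placeholders (X1, X1\*, X2): amino acids
assumed to have disappeared, carrying a `deleted` flag so the stop codons
their disappearance leaves behind are computable.

The assignments ship as a versioned plain-text configuration
(`inst/extdata/protocodes.yaml`); the code never invents assignments, it
only validates and transforms them. Validity requires: every codon uses
only the protocode's two bases; no codon is assigned twice within one
protocode (members may recur across protocodes — Arg sits in both GC
codes); amino-acid symbols are canonical one-letter codes or `X<n>`
placeholders; and the declared complement pairs are reverse complements.

Complement pairs are stored at *codon* granularity — quadruples
(aa₁, codon₁, aa₂, codon₂) — rather than as amino-acid pairs. This is a
deliberate design choice: members holding several codons pair with
different partners per codon (Gly's GGG is the reverse complement of
Pro's CCC, but Gly's GGC pairs with Ala's GCC), so an amino-acid-level
pairing cannot express the constraint.

## Combinatorial fusion

`applyFusion()` merges the protocodes into the 64-codon space using
Watson–Crick transition mutations (A↔G, U↔C):

* **Dominant** codes keep every original codon and add its
  *third-position* transition image.
* **Recessive** codes lose their originals to the dominant competitor
  and occupy free codons: for each original codon, both its
  *first-position* and its *first-and-third-position* transition images,
  provided the target is not claimed by any dominant fused set nor by
  another recessive amino acid. Unresolvable codons are reported per
  amino acid in the `conflicts` slot, never dropped silently.

Because transitions commute with complementation, the first-and-third
images of two complementary originals are again reverse complements, so
taking both images preserves the recessive code's internal pairing; this
is asserted, and a violation is reported as a conflict. With the shipped
configuration both candidate images are collision-free and both are
needed to reproduce the SGC sets, so the potential tie between a
single-position and a double-position mutation competing for one free
codon never arises; the conflict detector still guards the general case.

`validateAgainstSgc()` compares every fused codon with the SGC (taken
from `Biostrings::GENETIC_CODE`, T→U). Three annotated non-match states
are passes, because the model itself predicts them:

* `stop_emergent` — a deleted placeholder's codon that is an SGC stop
  (X1 → UAA, UAG; X2 → UGA);
* `late_entry` — AUG and UGG, which the SGC assigns to Met and Trp; the
  model has these amino acids entering *after* fusion (each ends up with
  a single codon), so fusion legitimately reaches their codons from Ile's
  AUA and X2's CGG;
* `reassigned` — a deleted placeholder's codons taken over by a
  traveling amino acid (Leu at UUA/UUG after X1\*).

Everything else is a `mismatch` and fails the amino acid. With the
bundled configuration the fused sets partition all 64 codons exactly and
all 22 (protocode, amino acid) entries pass.

# Library design and array layout

`enumerateLibrary()` generates the full combinatorial peptide set
`|alphabet|^length` in deterministic lexicographic order, with a safety
cap (default 10⁷). The study designs are 7-mers over {G,P,A,R} and
{S,T,C,R} (16,384 each, 32,768 combined) and 6-mers over {K,F,N,I,Y} and
{E,L,D,V,Q,H} (15,625 + 46,656 = 62,281). The synthesized AU library held
only 23,403 peptides; how those were selected is not recorded, so
`subsetLibrary()` provides a seeded uniform subsample as an explicit
stand-in, not a claim about the original selection.

`layoutArray()` places every peptide `copies` times (defaults 3 for AU,
2 for GC) at seeded pseudo-random positions on the smallest near-square
grid (the physical pitch, 60 µm, is carried as metadata only). Random
placement mirrors the real chips' strategy for decoupling binding signal
from local incubation artifacts. Sequences are stored N→C; the
N-terminal acetyl group and C-terminal beta-alanine linker are design
metadata, not sequence characters, which keeps fragment enumeration on
residue letters only.

# Screen datasets and summaries

`readPhotometricTable()` accepts a plain TSV dialect and a
GenePix-results-like dialect (ATF preamble, per-wavelength
`F<wl> Median` / `B<wl> Median` columns). Negative intensities and
duplicate (spot, channel) records fail loudly with row numbers.
`buildScreenDataset()` joins intensities to the manifest; unmatched
intensity records are errors unless a tolerance fraction admits them,
and manifest spots without signals are listed, not imputed. The raw
channel label → RNA channel map is explicit user configuration because
dye/wavelength-to-incubation assignments are chip metadata the tables do
not carry. Background subtraction exists but is off by default — the
screening protocol this models did not subtract background.

Two analysis levels are exposed everywhere: `spot` (every replicate spot
is one signal — the default, since the fragment score's signal sets are
defined over signals from peptides, without a stated pooling step) and
`peptide` (replicates aggregated, default median, robust to single-spot
artifacts). Summary statistics use the sample (n−1) standard deviation
throughout; with small fragment supports the estimator choice is
material, and the unbiased-variance convention is used consistently in
`channelSummary()` and the fragment scores.

# Fragment interaction scoring

For fragment *m* with signal set *I_m*, the interaction score is

$$R_m = \frac{\operatorname{mean}(I_m)}{\operatorname{sd}(I_m)}.$$

*I_m* collects the signals of all peptides containing *m* as a
contiguous substring, with **set semantics**: a peptide counts once no
matter how often *m* recurs in it (an occurrence-weighted mode exists
but is non-default). Enumeration supports k ≥ 1; ranking tables start at
3-mers by convention.

Numerical gates: the score is undefined for singleton or constant signal
sets, so fragments with support < `minSupport` (default 3) or zero
spread are excluded from the ranking and reported separately — never
scored as infinite. Ties in R are broken deterministically: longer
fragment first, then lexicographic.

Note that R is a *homogeneity-weighted* ranking, the inverse coefficient
of variation of the signal set: a fragment whose peptides respond
uniformly outranks one with the same mean but a broader spread. It is a
descriptive ranking statistic, not a calibrated test statistic; no
multiple-testing machinery is attached, by design.

`buildSignatureTable()` arranges scored fragments into cumulative
columns (lengths 3…n, then 3…n+1, …), each cut at `topN` (default 25).
`displacementAnalysis()` reports, per column transition, which top
fragments stay, drop out, or enter; `compositionTrend()` tracks the mean
count of chosen residues in the top fragments per column.

# The synthetic screen generator

## Model

Spot intensities are positive and right-skewed, so the generator is
multiplicative with lognormal noise. For spot *s* with peptide *p* in
channel *c*:

$$I(s) = b_c \cdot \ell(\text{lib}(p), c) \cdot \prod_e
  f_e^{\,n_e(p)} \cdot e^{\beta \cdot \phi(p)} \cdot
  e^{\varepsilon_s},\qquad \varepsilon_s \sim N(0, \sigma^2)$$

with channel baselines $b_c$, per-library multipliers $\ell$, planted
motif effects $f_e > 0$ raised to the (overlapping) occurrence count
$n_e(p)$ — optionally capped at a saturation count, reduced to an
indicator for per-presence effects, or anchored at a fixed position —
and an optional linear property term $\beta\,\phi(p)$ on the log scale.
With $\sigma = 0$ the output is the exact closed form; given a seed the
simulation is fully reproducible, and the noise matrix is drawn once so
channels share spot ordering.

Per-occurrence effects are the default because they make longer planted
runs bind more — the dynamics that lets longer fragments displace
shorter signatures — with the saturation cap reproducing the flattening
of polyproline binding beyond 5 occurrences.

## Preset parameters

`presetPaperlike()` bundles the study conditions as order-of-magnitude
emulations (explicitly not fits to measured data):

| preset | design | baselines | planted effects | library effects |
|---|---|---|---|---|
| AU | 62,281 6-mers subsampled to 23,403; 3 copies | A12 = 1500, U12 = 60 (ratio 25) | F ×1.25, Y ×1.2 per occurrence in A12 | dominant ×1.3 in A12 |
| GC | 2 × 16,384 7-mers; 2 copies | C12 = 3000, G12 = 1000 (ratio 3) | P ×2 per occurrence, saturation 5, in C12; optionally A-at-position-4 ×3 | dominant ×2.5 in C12, ×1.2 in G12 |

σ defaults to 0.3 (log scale): the measured dispersion of the strongest
screen channel (sd/mean ≈ 0.42) motivates a heavy-ish multiplicative
noise default. The baseline ratios encode the reported channel
hierarchies (adenine ≫ uracil; cytosine ~3× guanine), and the library
multipliers keep dominant above recessive so their intensity ranges
separate.

The alanine-at-position-4 bonus (×3, per presence at the anchor) exists
so a polyproline substitution scan has a planted optimum, PPPAPPP. Its
magnitude is a power choice made at design time: with σ = 0.3 and
median-of-2 aggregation, a ×3 bonus clears the lognormal noise floor of
the 21 competing variants with high probability, while a ×1.5 bonus
would be a coin flip. The bonus is a flag (`positionBonus`) because it
serves the scan analysis specifically: as a library-wide positional
effect it injects variance shared by all fragments' signal sets, which
compresses the R ranking and blurs motif recovery; motif-recovery
analyses therefore run the preset without it, scan analyses with it.
The substitution scan itself is simulated on its own mini-array
(`scanScreenConfig()`), matching the real protocol in which scan
variants are synthesized as a separate small chip, screened under the
same generative model.

## What the generator does and does not emulate

It emulates: replicated randomized layouts, channel baseline
hierarchies, dominant/recessive separation, motif-driven multiplicative
binding with saturation, property-driven trends, and lognormal spot
noise. It does not emulate: spatial artifacts (gradients, bleed,
scratches — the randomized layout exists precisely to decouple these),
dye chemistry, washing effects, spot morphology, background
fluorescence structure, or censoring/saturation of the scanner. Passing
recovery tests on synthetic screens therefore demonstrates that the
analysis recovers planted structure under its own statistical
assumptions — it does not validate those assumptions on real chips.

# Problem sizes and determinism

The test suite runs the full-scale GC design (65,536 spots) for the
acceptance-style checks and smaller designs (toy libraries of 4–4096
peptides; a 5,000-peptide subsample for the noise-normality check)
elsewhere, keeping the default suite around half a minute. The
oracle-equivalence check compares the scorer against a naive
double-loop recomputation on a 250-peptide simulated screen (473 scored
fragments) to 10⁻⁹; rescaling all intensities by 7.3 moves no score by
more than ~10⁻¹⁵ relative. Planted-motif recovery (PPP in the top 5 of
the 3-mer column) and scan recovery (argmax PPPAPPP) are evaluated over
20 seeded replicates each in `scripts/acceptance.R`. Every random step —
layout, subsampling, noise — goes through one user-supplied seed, and
repeated runs are byte-identical.

# Known limitations

* The protocode configuration is a transcription of a published
  partition; alternative assignments can be explored by editing the YAML
  but the shipped validation expectations target the bundled table.
* The recessive "take what's left" resolution is per-codon and local; a
  globally optimized re-assignment order is not needed for the shipped
  configuration and is not implemented.
* Property scales are pluggable but the defaults (side-chain charge at
  pH 7.4, Kyte–Doolittle hydrophobicity, Pace–Scholtz helix propensity,
  average residue masses + acetyl) are one reasonable convention among
  several; sum molecular weight in particular is convention-dependent.
* R_m has no sampling-error calibration: fragments with small supports
  have noisy scores, and the support gate is a blunt guard, not an
  inferential correction.
* The published unique-fragment counts per length are not reproducible
  from substring enumeration over the stated alphabets and are not
  asserted anywhere in this package.
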