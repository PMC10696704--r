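---
title: "Methods: DNA-SIP gradient analysis, DIC assimilation rates, and KO enrichment"
author: "ventSIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-SIP gradient analysis, DIC assimilation rates, and KO enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventSIP)
```

# Scope

ventSIP implements the downstream, quantitative half of a DNA
stable-isotope probing (SIP) metagenomics experiment on
chemolithoautotroph communities — the kind of experiment in which
hydrothermal fluid is incubated with ¹³C-bicarbonate (and ¹⁵N-ammonium),
DNA is fractionated on a CsCl buoyant-density gradient, and active
carbon-fixing taxa and their functional genes are identified from the heavy
fractions. The package starts where sequence processing ends: its inputs
are per-fraction density/abundance tables, per-bottle isotope measurements,
per-gene read counts, and per-library KO abundances. Read QC, assembly,
gene prediction, annotation, binning and taxonomy are upstream tool steps
and are out of scope.

Every stage has a seeded synthetic generator with planted truth, so the
whole chain is testable without sequencing or isotope-ratio mass
spectrometry (IRMS) data.

# Gradient analysis

A `GradientProfile` is one fractionation curve: strictly increasing
buoyant densities (g mL⁻¹) with 16S rRNA gene copies mL⁻¹ per fraction.

* **Normalization** is min–max ("scaled between 0 and 1"): the affine map
  sending the minimum to 0 and the maximum to 1. This is chosen over
  divide-by-maximum because only the affine map realizes both endpoints;
  it is idempotent and order-preserving. A profile with all copies equal
  cannot be scaled and is an error.
* **Peak density** is the density of the maximum-copies fraction, ties
  broken toward the heavier density (labeled DNA moves heavier, so the
  heavier candidate is the conservative choice for SIP).
* **Window classification** assigns each fraction to the light (L), heavy
  (H) or ultra-heavy (UH) window by half-open intervals `[lower, upper)`;
  a density exactly on a shared boundary belongs to the heavier window,
  and the heaviest window's upper bound is inclusive. The defaults —
  L = [1.690, 1.712), H = [1.715, 1.735), UH = [1.735, 1.760] g mL⁻¹ —
  are explicit configuration: window boundaries are in practice chosen per
  study by inspecting the gradient curves, so they are parameters here,
  not claims.
* **Fraction selection** finds, within one window, the contiguous run of
  `k` fractions (default `min(3, available)`, mirroring the practice of
  pooling 1–3 continuous fractions with the most 16S copies) maximizing
  summed copies; ties again go heavier. The implementation is checked
  against exhaustive enumeration of all contiguous runs in the test suite.
* **Cross-feeding control**: DNA labeled with both ¹³C and ¹⁵N bands
  heavier than DNA labeled with ¹³C alone. If the ¹³C+¹⁵N peak is strictly
  heavier than the ¹³C peak, the community is dominated by autotrophs
  assimilating both inorganic substrates and heterotrophic cross-feeding
  of labeled carbon is negligible; otherwise (including identical peaks,
  i.e. no ¹⁵N shift) cross-feeding is suspected. Single-peakedness is
  tested after 3-point median smoothing (non-decreasing then
  non-increasing); violations warn rather than fail, because multi-modal
  curves make a single peak comparison unreliable but not meaningless.

# The labeling call

The qualitative SIP reading — an active taxon keeps a heavy-fraction
relative abundance higher than or similar to its light-fraction abundance,
an inactive one declines sharply — is quantified by the ratio
`hlRatio = H/L`:

| verdict | rule (defaults) |
|---|---|
| labeled | `hlRatio ≥ 0.8` |
| unlabeled | `hlRatio ≤ 0.5` (a twofold or steeper decline) |
| ambiguous | between |
| insufficient | both L and H below 0.001 |

"Similar" is quantified as at most a 1.25-fold decline (0.8) and
"declines significantly" as at least twofold (0.5) — the twofold
convention matching the KO classifier below. Both thresholds are explicit
configuration and are reported with the calls. The UH fraction is reported
as corroborating evidence (`uhlRatio`) but does not enter the verdict,
which is defined on heavy vs light. No statistical test is attached to a
single-replicate ratio. Table-level calls exclude taxa below 0.5 %
relative abundance in every fraction, the usual inclusion filter for
community heat maps.

Because fraction abundances are compositional (each fraction's column sums
to 1), a community in which *every* taxon declines equally from L to H is
indistinguishable from one in which every taxon is enriched: closure
rescales all H/L ratios by a common factor. The synthetic generator
(below) and the recovery guarantee are therefore stated for mixtures.

# Isotope arithmetic and DIC assimilation rates

The rate engine is three exact formulas plus a detection-limit rule:

1. `R = (δ¹³C/1000 + 1) × R_VPDB` with `R_VPDB = 0.0112372` (the ¹³C/¹²C
   ratio of the VPDB standard); δ ≤ −1000 ‰ is non-physical and an error.
2. `n = R/(R + 1)`, the ¹³C atom fraction, strictly increasing in R and
   in [0, 1).
3. `rate = (POC_t·n_t − POC₀·n₀)/t × (Ca + Cs)/Cs` — the labeled-carbon
   accumulation in particulate organic carbon per day, corrected by the
   substrate dilution factor `(Ca + Cs)/Cs` because only the added pool
   `Cs` carries the tracer while the organism draws on the whole DIC pool
   `Ca + Cs`.

All computation is at full floating precision; rounding happens only in
the report layer.

**Detection limit.** IRMS delta values carry an analytical precision of
0.1 ‰. A |δ_t − δ₀| smaller than that precision is not a measurement: the
result is flagged BDL (below detection limit) and the rate that a
precision-sized shift *would* imply is reported as the detection limit.
This makes the BDL flag reproducible instead of a lab-book judgement. A
negative computed rate within one detection limit of zero is noise and
clamps to BDL; a more negative rate indicates inconsistent inputs and is
an error. Replicate averaging uses the mean and the sample standard
deviation (n−1) over non-BDL replicates; a condition whose replicates are
all BDL has no datum (ND). Printed dispersion conventions vary between
studies, so only means are treated as reproducible report targets.

**Forward model.** `simulateTracer()` inverts the chain: from a true rate,
the initial POC pool and its δ¹³C, it fixes carbon for `t` days at the
atom fraction of the substrate-diluted DIC pool (the added bicarbonate is
taken as pure ¹³C), retains all fixed carbon in POC
(`POC_t = POC₀ + rate·t` — the simplest mass-conserving closure, stated
as an assumption), converts back to δ¹³C and adds Gaussian noise (sd
0.1 ‰, the analytical precision) to both delta values. Defaults follow
the incubation design the package targets: 3 mM (3000 µmol L⁻¹) added
NaH¹³CO₃, 24 h incubation, ambient DIC 2000 µmol L⁻¹. With zero noise the
estimator recovers the true rate to machine precision; the acceptance
suite checks median relative error < 5 % at 0.1 ‰ noise over 1000
simulated incubations spanning the measured rate range
(0.01–2.5 µmol C L⁻¹ day⁻¹).

# Gene and MAG abundance

The length-normalized relative abundance of gene *k* with `r_k` mapped
reads and length `L_k` is

`G_k = (r_k/L_k) / Σ_i (r_i/L_i)`.

Length units cancel; lengths are stored in nucleotides. `Σ G_k = 1`,
zero-read genes get 0, and the result is invariant to rescaling all read
counts. Mapping itself (and read/ORF length filters) is upstream; counts
are taken as given. Taxon aggregation sums `G_k` at a requested rank, with
an option to exclude genes unclassified at that rank (mirroring the
exclusion of kingdom-level unclassified reads from statistical analysis)
and to renormalize the remainder. MAG relative abundance is the proportion
of uniquely mapped, correctly paired reads out of the library total.

# The KO core/enriched/diluted classifier

Each KEGG ortholog is observed in three metagenomic libraries at a
per-million relative abundance `(a₁, a₂, a₃)`. With fold threshold
`f = 2`:

* **core** — abundances differ by less than f-fold across the three
  libraries: `max < f·min`, all three positive;
* **enriched in library i** — `a_i ≥ f·max(others)`;
* **diluted in library i** — `f·a_i ≤ min(others)`;
* **unclassified** — none of the rules fires.

Design choices that the three informal rules leave open:

* *Boundaries.* Core is strict (`< f`-fold), enriched/diluted are
  inclusive (`≥ f`), so a KO exactly twofold higher is enriched, not core.
* *Coverage.* The three rules do not cover all triples (e.g.
  `(1, 1.5, 2.5)` is neither core, enriched nor diluted), hence the
  explicit `unclassified` category — exclusivity and exhaustiveness are
  then provable and tested.
* *Precedence.* Both enriched and diluted can fire on the same triple
  (e.g. `(1, 3, 9)`); enriched wins, as the category of interest.
* *Zeros.* All comparisons are in multiplication form, never division, so
  zero abundances are exact: a KO present in exactly one library is
  enriched there; one absent from exactly one library is diluted there.
  An all-zero triple is an error.

The classifier is scale-invariant (per-KO common factors cancel) and
library-permutation equivariant; both are property-tested on 10,000
random triples. Ternary coordinates are the barycentric normalization
`a_i/Σa`, and category summaries report per-category KO counts and
per-library abundance totals, which partition the KO set and conserve
each library's total. `filterHighAbundance()` keeps KOs whose maximum
abundance strictly exceeds a floor (default 1000 per million), the filter
used when picking individually interpretable enriched genes.

The published KO counts of the original three-temperature comparison
(thousands of KOs from deposited metagenomes) require the raw sequence
data and are not desk-reproducible; the package's claims about the
classifier are therefore property-based (planted recovery, invariances),
not count reproduction.

# Synthetic data: what it emulates and what it does not

* `simulateGradient()` — Gaussian bands on the density axis. Band center
  `1.660 + 0.098·GC` g mL⁻¹ and shifts +0.036 (full ¹³C) and +0.016
  (full ¹⁵N) g mL⁻¹ are standard SIP physical values and are configurable;
  noise is lognormal multiplicative (qPCR-like). It does not model partial
  labeling, gradient formation physics, or fraction-volume variation; the
  number and spacing of fractions are free parameters, since neither is a
  settled constant of the assay.
* `simulateTracer()` — exact inverse of the rate equations plus Gaussian
  delta noise (IRMS-like), as described above.
* `simulateKOTable()` — planted classes: core KOs equal across libraries,
  enriched/diluted KOs raised/lowered `fold`-fold in one library, lognormal
  base abundances and entrywise lognormal noise. Abundances are emitted on
  a per-million *scale* (expected library total 10⁶) without forcing each
  column to sum to exactly 10⁶: per-library renormalization rescales
  cross-library ratios whenever library totals differ, and on a small
  planted table (e.g. only enriched KOs) it would cancel the planted fold
  entirely. The classifier correspondingly takes abundances as given;
  `perMillion()` is provided for normalizing complete real tables. The
  planted fold must exceed the fold threshold, otherwise classes are
  unrecoverable by construction.
* `simulateFractionTaxa()` — labeled taxa rise fourfold from L to H/UH,
  unlabeled taxa decay fourfold per step, per-taxon weights times
  lognormal noise, columns closed to sum to 1. Because of compositional
  closure the planted states are provably recoverable at zero noise for
  mixtures up to an unlabeled:labeled weight ratio of
  `(uplift − 2·decline)/decline` (= 14 under the defaults); an
  all-unlabeled community is inherently unidentifiable (all ratios close
  to 1 and every taxon is called labeled), which is a limit of
  compositional SIP data, not of the caller.

Passing tests on these generators show that the inference chain is correct
*given* its model assumptions (single Gaussian bands, full labeling,
multiplicative qPCR noise, additive IRMS noise, closed compositions); they
do not validate those assumptions against real gradients, where partial
labeling, GC heterogeneity within taxa and fractionation artifacts blur
every boundary involved.

# Numerical choices and problem sizes

All generators are deterministic under a fixed seed (`withr::with_seed`,
so the user's RNG state is untouched). Internal arithmetic is double
precision throughout; the tested identities hold to 1e-12 (delta
round-trip), 1e-9 (rate round-trip) and 1e-12 (normalization sums). The
test and acceptance runs use 1000 random gradient profiles (≤ 30
fractions) for the selection oracle, 1000 simulated incubations for rate
recovery, 10,000 random triples for classifier invariances, and
360–1000-KO planted tables — sizes at which the Monte-Carlo estimates are
stable to well under the asserted margins while the full suite runs in
well under a minute.

# Known limitations

* Labeling calls are single-replicate ratio heuristics with explicit
  thresholds; they carry no significance statement.
* The detection-limit rule derives from delta precision only; POC
  measurement error is not propagated.
* The KO classifier compares exactly three libraries; other designs need
  pairwise or generalized rules.
* Window boundaries, labeling thresholds and the fold constant are
  configuration, and conclusions can be sensitive to them; the provenance
  sidecar written with every output records the configuration hash so
  results are traceable to their settings.
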