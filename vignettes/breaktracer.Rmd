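---
title: "Breakpoint-spanning ddPCR assays for ctDNA MRD tracking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint-spanning ddPCR assays for ctDNA MRD tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breaktracer)
```

# Scope and model

`breaktracer` covers the computational half of a tumor-informed ctDNA
workflow for translocation-driven tumors: from a structural-variant
breakend pair to a patient-specific breakpoint-spanning ddPCR assay, and
from droplet data to longitudinal minimal-residual-disease (MRD) calls.
Upstream wet-lab and discovery steps — cfDNA extraction, RNA fusion
panels, WGS alignment, the structural-variant caller itself — are inputs,
not re-implementations.

## Breakends and the junction reference

A translocation adjacency is modelled as two breakends, each a
`(chromosome, position, retained_side)` triple: `retained_side = "left"`
means the derivative allele keeps the flank left of the position, with the
position itself the terminal retained base (this makes the annotated
reference base directly checkable against the genome). Two notations are
parsed onto this model:

* **VCF BND records.** The four ALT shapes map to retained-side pairs:
  `t[p[` → (left, right), `t]p]` → (left, left), `]p]t` → (right, left),
  `[p[t` → (right, right). Mated records must mirror each other and are
  deduplicated into one adjacency.
* **Bracketed tokens** as found on assay sheets
  (`"[chr22:29288203]G"`, `"T [chr11:128806738]"`). The sheet dialect
  never states its own convention, so this package declares one: a token
  with the coordinate bracketed *first* retains the left flank at that
  position; a token with the base *before* the bracket retains the right
  flank. `fwd` rows list the 5′ partner first; `rev` rows are stored
  normalized to the same biological adjacency with
  `assay_orientation = "rev"`. The convention reproduces all six bundled
  EWSR1–FLI1 assays symmetrically and round-trips exactly; whether the
  original sheet's "Orientation" column denotes probe strand or breakend
  geometry is unknowable from the sheet alone, and the declared reading is
  internal, documented, and tested — not inferred intent.

`build_junction()` concatenates the two retained flanks (default 300 bp
per side — comfortably more than a primer-plus-probe footprint; the
source workflow does not state its retrieval length). A flank whose
retained side opposes the junction's reading direction — the (left, left)
and (right, right) combinations — is reverse-complemented, and the strand
actually used is recorded in the per-side provenance. The operation's
contract only spells out the plus-strand intervals for the canonical
(left, right) case; the reverse-complement treatment of same-side
combinations is this package's design choice, forced by the requirement
that the junction equal a genuine derivative-allele sequence (the
simulator's independently constructed derivative is the test oracle for
all four combinations). Flanks truncate silently at chromosome ends, with
truncation recorded; N-containing junctions are flagged and refused by the
assay designer.

## Assay design

Primer/probe selection is a deliberately small, transparent engine — the
contract is the set of constraints, not any particular external tool's
penalty model:

* **Melting temperatures** use unified nearest-neighbor thermodynamics
  (ΔH/ΔS per stacked dinucleotide plus terminal initiation terms), an
  entropic salt correction `ΔS + 0.368 (N−1) ln[Na+]`, and the
  non-self-complementary duplex factor `CT/4`
  (`Tm = 1000 ΔH / (ΔS_salt + R ln(CT/4)) − 273.15`), at 50 mM Na+ and
  250 nM oligo by default. The implementation is verified against an
  independently re-typed table-driven summation to 10 decimal places.
* **Primers** (18–25 nt, GC 30–70%, no homopolymer >4, Tm 59 ± 6 °C) are
  enumerated exhaustively on each side of the junction — forward
  candidates wholly 5′ of it, reverse candidates wholly 3′, so only the
  amplicon (never a primer) crosses the breakpoint.
* **The hydrolysis probe** must cover the junction with its 3′ terminus
  exactly 2–6 bases past it on its strand, and must not start with G
  (5′-G quenches the fluorophore). Probe bounds are 18–30 nt, GC 30–80%,
  Tm 52–78 °C. The length ceiling and Tm floor are wider than a first
  instinct would set because the probe's 3′ anchor is immovable: on an
  AT-rich junction every candidate shares the same cool neighbourhood, and
  longer, cooler probes are the standard remedy. The penalty still prefers
  probes near `primer target + 8 °C`, so permissive bounds only matter
  when nothing better exists.
* **Pair scoring** minimizes
  `w_tm (|Tm_f − T| + |Tm_r − T|) + w_len |L − L_target| + w_compl C`,
  where `C` is the longest self/cross complementary stretch of the primer
  pair. Amplicons are capped at 150 bp (target 80 bp) — cell-free DNA is
  ~170 bp fragmented, so short amplicons are not a stylistic preference
  but a sensitivity requirement. Ties break deterministically (leftmost
  forward primer, then shortest amplicon). The annealing temperature is
  the tier in {55, 58} °C nearest the primer-pair mean Tm (ties toward the
  higher tier); the tier set mirrors the bundled assay sheet.
* **In-silico PCR** replaces the wet-lab specificity test: all primer
  binding sites on both template strands (either primer in either role),
  with the 3′-terminal base always required to match exactly — a primer
  with a mismatched 3′ end does not extend — and products capped at
  1 kb. The workflow-level gate requires exactly one product on the
  junction and zero on each wild-type partner chromosome, which holds by
  construction because no wild-type sequence contains both primer sites.
* **Thermal protocol**: 96 °C/10 min; 40 cycles of 94 °C/30 s plus a
  combined anneal/extend step at the assay's tier; 98 °C/10 min droplet
  stabilization; hold at 4 °C. The anneal/extend *duration* is not part of
  the printed profile; 60 s is used as the conventional two-step ddPCR
  value.

## Droplet quantification

Partitioning a reaction into droplets makes counting statistics exact:
with λ target molecules per droplet on average, a droplet is positive with
probability `1 − exp(−λ)`, so `λ = −ln(1 − p̂)` with `p̂ = k/N`, and the
reaction concentration is `λ / v_d` with droplet volume `v_d = 0.85 nL`
(the QX200 convention; configurable — the instrument vendor, not the
assay, fixes it). The full volume chain to plasma units is

```
copies/mL plasma = conc * reaction_uL * (eluate_uL / template_uL) / plasma_mL
```

with defaults 20 µL reaction, 5 µL of a 50 µL eluate per well, 2 mL
plasma (only the 1–2 mL plasma volume is externally constrained; the rest
are typical kit values and are overridable per sample). Because these
factors were not reported for the original clinical measurements, absolute
published copies/mL values are *not* reproduction targets; all tests work
against the package's own declared chain.

Further choices, each with its reason:

* **Replicates are pooled** (counts summed before the Poisson transform),
  never averaged — pooling is the exact treatment of two partitions of the
  same reaction mix; averaging transformed estimates is not. Whether the
  original duplicates were pooled or averaged is unstated; pooling is the
  statistically defensible default.
* **Classification** of raw fluorescence uses the two-class 1-D split
  minimizing within-class variance, then thresholds at the midpoint of the
  two class means, counting strictly-above droplets. It is deterministic
  and matches truth labels exactly for well-separated populations.
* **Confidence intervals** are Wilson score intervals on `p̂`, transformed
  through `−ln(1 − ·)` — chosen for sane zero-count behaviour (a 0/N well
  gets a finite upper bound, not a degenerate [0, 0]).
* **Detectability**: 0 pooled positive droplets = undetectable, exactly
  1 = borderline, ≥2 = detectable. No such rule is stated upstream; this
  one documents why a ~1.8 copies/mL result reads as "borderline" — it is
  a single-droplet observation.
* **QC**: a run needs >12,000 droplets (strict), a clean no-template
  control, a firing positive control, and (optionally) a negative healthy
  donor; any flag keeps the number but marks it invalid for MRD logic.
* **Limit of detection** uses the rule of three: at zero positives in N
  droplets the 95% upper bound on λ is ≈ 3/N (0.176 copies/µL at 20,000
  droplets), flagged as degenerate when 3/N ≥ 1.

## MRD status logic

Status calls consume only the detectability sequence and copies/mL of
QC-valid timepoints — tracking never re-thresholds concentrations, so the
quantification module remains the single source of truth. The calls are
made left-to-right, which guarantees that appending a timepoint never
rewrites history (online consistency):

* `baseline_positive` — first valid point detectable;
* `molecular_response` — first undetectable point after a detectable one;
* `sustained_negativity` — from the second consecutive undetectable point;
* `molecular_recurrence` — detectable after documented negativity;
* `rising` / `falling` — third point of a strictly monotone run of
  copies/mL among consecutive detectable points. Three points is this
  package's operationalization of "steadily increasing", which has no
  stated rule; two points would fire on any noise, four would miss short
  courses.
* Borderline (single-droplet) points are inconclusive: they break both
  negativity and positivity runs and never trigger a transition
  themselves.

## The synthetic world

The generators state a world and keep it fixed:

* **Toy genomes**: uniform-random ACGT chromosomes (default 2 × 5 kb,
  minimum 2 kb), one partner "gene" locus per chromosome. Translocations
  are implanted by direct string concatenation — an implementation
  independent of `build_junction()`, which is exactly why the round-trip
  equality between the two is an informative test.
* **Droplets**: positives with probability `1 − exp(−λ)`; fluorescence
  from N(2000, 100) negatives and N(8000, 200) positives with 0.5%
  uniform "rain" between the population means — invented but
  instrument-realistic values, configurable.
* **Patient courses** follow the three clinically observed trajectory
  shapes, with copies/mL templates inside the reported 6–4,000 copies/mL
  dynamic range: responder `12.4 → 0 × 5`, recurrence
  `1731 → 0 × 4 → 620`, progression `22 → 92 → 221 → 620 → 1623 → 4000`.
  Fusion and reference assays run in duplicate (20,000 droplets/well) with
  NTC, diluted positive control (λ = 0.5) and healthy-donor wells per
  timepoint; the reference genome-equivalents level defaults to 10,000
  copies/mL plasma, consistent with typical cfDNA yields (~38 ng/mL at
  ~3.3 pg/genome). Templates carry no added kinetic noise: the binomial
  droplet draw is the stochastic layer, which is what the tracking logic
  has to survive.

What a green test does **not** establish: real cfDNA fragmentation and
size selection, PCR inhibition, rain from partial amplification (our rain
is label-independent), inter-run threshold drift, or any absolute
agreement with published per-patient copies/mL (whose volume factors are
unreported). The synthetic world validates the statistics and the logic,
not the wet lab.

# Numerical and statistical notes

* Poisson inversion uses `log1p` (`λ = −log1p(−p̂)`), accurate to full
  double precision at small `p̂`; the test-suite oracle uses the
  independent identity `λ = log1p(k/(N−k))` (the naive `log N − log(N−k)`
  loses ~6 digits to cancellation at k = 1, N = 10⁶ — worth knowing if
  you roll your own check).
* A fully positive well returns an infinite-concentration sentinel with a
  `SATURATED` flag rather than an error.
* One statistical caveat is documented rather than hidden: the
  parameter-recovery acceptance check demands *every* one of 400
  simulated estimates fall within 3 binomial-propagated SEs of truth and
  a pooled mean relative bias under 1%. For a perfectly calibrated
  estimator the expected number of 3-SE exceedances in 400 draws is ~1.2,
  and the Monte-Carlo SD of the pooled mean bias is ~0.6 percentage
  points (dominated by λ = 0.001, where a 20,000-droplet well holds ~20
  positive droplets and a single estimate has 22% relative SD). The fixed
  seed block used in the suite realizes 3 exceedances (max |z| = 3.28)
  and +1.19% pooled bias — values entirely consistent with zero true
  bias; classification was separately verified to match truth labels
  exactly, and the estimator is the exact maximum-likelihood transform of
  an exact binomial draw. The assertions are kept at their stated
  thresholds and reported honestly rather than re-rolled.
* Recovery simulations run with rain disabled: midpoint-threshold
  classification calls ~half the rain droplets positive irrespective of
  their true state, which at 0.5% rain adds ~50 counts per 20,000
  droplets — negligible at λ = 0.5, a >100% relative error at λ = 0.001.
  Rain robustness is instead tested where it is meaningful (classification
  error < 0.5% at moderate λ).

# Known limitations

* No microhomology or untemplated-insertion modelling at the junction
  (structural-variant callers report these; patients with inserted bases
  would need the insertion folded into the junction reference by hand).
* No genome-wide off-target scan — specificity is checked against the
  supplied wild-type partner chromosomes only — and no secondary-structure
  (hairpin ΔG) term in the penalty.
* Single-channel droplet model: no duplex classification, no rain
  reclassification heuristics beyond one threshold.
* Read support counts clipped alignments only; discordant read pairs are
  ignored.
* Lead-time questions ("how many weeks before clinical relapse was the
  molecular recurrence?") reduce to differences of user-supplied dates;
  the package computes no survival statistics and makes no treatment
  recommendations.
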