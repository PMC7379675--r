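---
title: "Scoring DNA double-strand breaks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DNA double-strand breaks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbkit)
```

## The model

A DNA molecule is represented atomically: every nucleic-acid residue carries
a strand label (1 or 2) and a 0-based base-pair index along the duplex, and
its sugar-phosphate atoms (P, OP1/OP2, O5', C5', C4', O4', C3', O3', C2',
C1') form the *scorable* backbone group. Geometries come from PDB files
(`parsePdb()`, via bio3d) or from the ideal B-DNA generator
(`buildBdnaFixture()`). All lengths are nanometres internally; PDB Ångströms
are divided by 10 on read.

Irradiation is modelled in three stages:

1. **Source.** Electron energies are drawn from a binned spectrum
   (`SpectrumHistogram`): multinomial bin choice, uniform within the bin.
   `synthLinacSpectrum()` builds an exponentially falling histogram over
   (0, 6] MeV rescaled so that exactly 52% of electrons lie below 1 MeV —
   the two features of a 6 MV LINAC secondary-electron spectrum we treat as
   load-bearing. No figure-level bin contents are claimed, deliberately: the
   generator matches stated summary constraints only.

2. **Transport (parametric stand-in).** Each primary traverses the bounding
   box on a straight chord and leaves interaction sites as a Poisson process
   with linear density LET(E)/meanDeposit, each site's energy drawn from a
   truncated exponential. This preserves the statistical structure the
   scoring layer consumes — spatially clustered, discrete, stochastic
   deposits whose intensity falls with electron energy — while making no
   claim of agreement with condensed-history or track-structure codes. All
   fidelity claims about this stage are confined to its own property tests
   (chord-length statistics, Poisson means, determinism).

3. **Scoring.** Every in-volume deposit is attributed to its nearest atom
   overall; its energy accrues to a nucleotide's backbone tally iff that
   atom is a scorable backbone atom within the capture radius. SSBs are
   called where a tally reaches the energy threshold ET; opposite-strand
   SSBs within the base-pair threshold BPT are paired into DSBs by a greedy
   sweep that provably attains the maximum bipartite matching for this
   window structure. The per-molecule endpoint is binary: `broken` iff at
   least one DSB, because a strand-separation readout cannot distinguish one
   DSB from several.

Absorbed dose is energy deposited in the scoring volume divided by its mass.
The number of primaries needed for a target dose is calibrated linearly from
a pilot exposure (`calibratePrimaries()`): dose from independent primaries
is additive, so a pilot of 3×10⁵ primaries measured at 25 Gy scales to
2.4×10⁶ primaries at 200 Gy.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `etEv` | eV | 19 | centre of the 18–20 eV band that best reproduces dosimeter measurements; 17.5 and 10 eV are common literature alternatives; 8.22 eV (a legacy default) saturates P(DSB) |
| `bptBp` | bp | 10 | the near-universal literature window for opposite-strand break clustering |
| `captureRadiusNm` | nm | 0.35 | covalent-bond scale for deposit-to-atom attribution; a tunable of the assignment rule, not a literature constant |
| `meanDepositEv`, bounds | eV | 40 in [5, 500] | plausible ionization-event scale for low-energy electrons in water; illustrative |
| stopping table | MeV, keV/µm | shipped CSV | piecewise log-linear; editable; illustrative |
| pairing cutoff | nm | 1.2 | generous upper bound on Watson-Crick representative-atom separation |
| replicates | — | 1000 | replicate-count convention for SEM ≈ 1–2 percentage points; reduce for desk-scale runs |

Threshold comparisons are **inclusive** (≥ ET, ≤ BPT), matching the "within
10 bp" phrasing conventional in this literature. Energy is accumulated per
nucleotide across all events before thresholding; a per-deposit alternative
(`reduce = "max"`) is exposed for sensitivity analysis.

## What the fixture generator emulates — and what it does not

`buildBdnaFixture()` places four backbone pseudo-atoms (P, C4', O3', C1')
plus the Watson-Crick hydrogen-bond nitrogen (N1/N3) per nucleotide on two
antiparallel helices with canonical B-form rise (0.34 nm) and twist (36°).
It reproduces what the scoring algorithm actually consumes: strand
topology, base-pair indexing, backbone-atom positions at the right radii,
and complementary pairing. It does **not** emulate nucleosomal wrapping,
histone proteins, solvent, thermal disorder, or full atomic detail — so
tests passing on fixtures validate the scoring machinery and its orderings,
not the absolute P(DSB) of any real chromatin geometry. Real structures
(e.g. the tetranucleosome entry 1ZBB) are supported through `parsePdb()`,
with protein atoms retained as inert nearest-atom absorbers by default: a
deposit nearest to a histone atom scores no strand damage but still counts
toward dose. That default is a modelling choice (the alternative —
dropping them with `includeNonNucleic = FALSE` — slightly increases backbone
capture).

Strand pairing uses the Watson-Crick nitrogen (N1 purine / N3 pyrimidine)
as the representative atom where present, falling back to C1'. Across a
true pair these nitrogens sit ~0.28 nm apart — far below any
neighbouring-nucleotide distance — which makes nearest-distance matching
unambiguous where raw C1'–C1' distances can prefer a cross-strand
minor-groove neighbour.

## Numerical choices

- **Chord sampling.** Chords are isotropic-flux (µ-random): an isotropic
  direction plus a uniform offset on the perpendicular disk of the bounding
  sphere (radius = half the box diagonal × 1.01), rejecting chords that
  miss the box. µ-randomness is what "irradiated isotropically" means for a
  convex target and is the regime in which the Cauchy mean-chord-length
  formula 4V/S holds — which the test suite uses as an analytic oracle.
- **Truncated-exponential deposits.** The rate is solved numerically
  (`uniroot`, tolerance 1e-14) so the *truncated* mean equals
  `meanDepositEv` exactly; sampling is by inverse CDF. Achievable means lie
  in (min, (min+max)/2); anything else errors.
- **Tie-breaks.** Nearest-atom ties resolve to the lowest (chain, residue
  number, atom name); pairing ties to the lowest residue number. Both make
  scoring order-independent and bit-reproducible.
- **Degenerate inputs.** A primary may deposit nothing (valid empty event
  list); zero events yield zero SSBs, zero DSBs, `broken = FALSE`; a pilot
  with zero dose refuses to calibrate; fits require ≥ 3 distinct doses;
  SEM requires ≥ 2 replicates.
- **Determinism.** High-level operations take integer seeds and use R's
  global RNG; replicate i uses seed `baseSeed + i`, the pilot uses
  `baseSeed`. A configuration plus base seed reproduces every output byte
  for byte. Threshold scans generate events once per (dose, replicate) and
  re-score per (ET, BPT), so monotone orderings in ET and BPT are exact.

## Dose scale for desk-size geometries

Dose is a macroscopic average; at nanometre scale it is dominated by rare,
large single-electron deposition events. One chord through a 20-bp fixture
(mass ≈ 2.3×10⁻²³ kg) deposits the equivalent of thousands of gray, so at
25–200 Gy the expected number of traversals of such a volume is far below
one, and an all-traversals source cannot represent it with integer primary
counts. Replicate studies in the tests, examples and acceptance script
therefore use dose grids of order 10⁵–10⁶ Gy on the 20-bp fixture — chosen
so calibrated primary counts stay well above one — and problem sizes of
20–50 bp, 30–400 replicates, and ~10³–10⁴ primaries per exposure. These are
the package's stated problem-size choices; the statistical machinery
(calibration linearity, SEM, monotone thresholds, quadratic fitting) is
scale-free.

## Known limitations

- The transport stage is parametric: absolute P(DSB) values depend on true
  low-energy electron physics and are not reproduced; monotone orderings
  (P(DSB) non-increasing in ET, non-decreasing in BPT, non-decreasing in
  dose; low-threshold saturation) are the supported claims.
- Only direct energy deposition is scored. Indirect (radical-mediated)
  damage is out of scope, as is any repair or complex-damage taxonomy
  (DSB+, clustered lesions).
- The "52% below 1 MeV" spectrum constraint is interpreted as a fraction of
  *electrons*, not of energy carried — the phrasing in the source material
  is ambiguous; users can supply their own binned spectrum file for any
  other weighting.
- No mmCIF support; chains beyond the first two nucleic chains fold onto
  strands 1/2 alternately, which suits duplexes but not multi-duplex
  assemblies with unusual chain order.

## A small end-to-end run

```{r example, eval = FALSE}
g <- buildBdnaFixture(20)
spec <- synthLinacSpectrum()
phys <- defaultPhysicsParams()
pts <- runDoseSeries(g, spec, phys, damageParams(etEv = 19, bptBp = 10),
                     doses = c(1e5, 2e5, 4e5, 6e5, 8e5),
                     nReplicates = 100, baseSeed = 1, pilotPrimaries = 1500)
pts
fitDoseResponse(pts)

scan <- scanThresholds(g, spec, phys,
                       etValues = c(10, 17.5, 19, 22.5),
                       bptValues = c(6, 10, 14),
                       doses = c(4e5, 8e5), nReplicates = 100, baseSeed = 1)
scan
```
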