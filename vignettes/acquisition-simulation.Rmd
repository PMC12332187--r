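---
title: "An in-silico instrument for targeted immunopeptidomics acquisition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An in-silico instrument for targeted immunopeptidomics acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipasim)
```

## The problem this package models

Clinical antigen discovery must find a handful of low-abundance tumor
target peptides (neoantigens, tumor-associated antigens) inside an HLA
immunopeptidome of tens of thousands of peptides, from one limited sample,
in one LC-MS/MS run. Conventional TopN data-dependent acquisition (DDA)
maximizes *global depth* but is stochastic and insensitive to rare
targets; brute-force inclusion-list targeting (ilDDA) spends long
high-sensitivity scans on every analyte that is isobaric with a scheduled
target and collapses global depth. The acquisition scheme simulated here
inserts a cheap *scouting* MS2 scan (sMS2) and a real-time-search filter
(RTSf) between the inclusion-list match and the expensive
*high-sensitivity* scan (hMS2): only precursors whose scout spectrum looks
like the intended target get the long scan. The package implements this
whole loop — ground-truth simulation, scheduling, the three acquisition
methods, offline identification, and the evaluation metrics — so the
target-sensitivity versus global-depth trade-off can be exercised and
tested without an instrument.

## The acquisition model

Time is divided into fixed 3-second cycles on a grid over the LC gradient.
Each cycle has three priority levels:

1. **MS1** (110 ms): observes all eluting precursor features.
2. **Targeted branch** (ilDDA and the RTS-filtered method only): MS1
   features matching an active inclusion entry (charge match, ±10 ppm,
   retention time inside the scheduled window) are queued by descending
   intensity. The RTS-filtered method acquires an sMS2 (30 ms), evaluates
   the filter, and acquires an hMS2 (150 ms — five times the scout) iff
   the filter passes; ilDDA acquires the hMS2 directly. This branch is
   deliberately exempt from dynamic exclusion and from the minimum MS1
   intensity gate, so a target can be interrogated again every cycle.
3. **Discovery branch**: TopN discovery MS2 scans (dMS2, 40 ms, wide
   3.2 Th isolation windows) fill the remaining budget, subject to dynamic
   exclusion (20 s, ±10 ppm) and the intensity gate.

A scan is acquired only if its duration fits the remaining cycle budget,
and a single precursor can be sampled at most 3 times per cycle under the
RTS-filtered method (sMS2 + hMS2 + dMS2), 2 under ilDDA, 1 under DDA.
Cycles advance by the full cycle time even when underused; the per-cycle
accounting (`cycle_budget_report()`) always sums to the cycle time.

Decisions the scheme itself leaves open were resolved as follows: the
targeted queue is ordered by MS1 intensity (ties by m/z) since no ordering
is prescribed; real-time search consumes no simulated time (on the
instrument it overlaps the next scan's ion fill; its 40 ms cap is carried
as metadata); when a filter pass occurs but the hMS2 no longer fits the
cycle budget, the hMS2 is skipped and the event flagged
(`hms2_skipped`); ilDDA's inclusion match requires a charge match, like
the RTS-filtered branch, for comparability; and a precursor already
scanned by the targeted branch remains eligible for discovery in the same
cycle, which is what makes the 3-scan cap reachable.

## Scoring

The vendor's real-time search is closed source; the reconstruction
follows the published fast cross-correlation convention: unit bins of
1.0005079 Da indexed by `round(mz / width)`, square-rooted intensities
with the maximum kept on bin collisions, regional normalization of 10
equal segments to a maximum of 50, and background subtraction over ±75
bins (divisor 151) — which makes the plain dot product with the
theoretical spectrum equal to the offset-corrected cross-correlation, a
property the test suite checks against a direct offset-correlation oracle
to 1e-9. The theoretical spectrum places 50 at each singly-charged b/y
fragment bin and 25 at the flanks; the dot product is divided by 10^4.
These heights and the divisor are calibration constants chosen so that
the published filter threshold (Xcorr ≥ 0.4, with dCn ≥ 0 and |ΔPPM| ≤ 5
for charges 1–3) sits in a realistic operating range: noise-free
self-matches score ≈ 1.5–2.5, isobaric non-targets mostly below 0.4.
A single-candidate search is assigned dCn = 1 (permissive — a lone
confident hit must not be rejected for lack of a runner-up).

The offline engine ranks candidates by hyperscore,
`ln(n_b! · n_y! · max(ΣI_b,1) · max(ΣI_y,1))` with factorials capped at
64, and reports cross-correlation and a normalized spectral contrast
angle, `1 − (2/π)·arccos(cosθ)` over square-rooted intensities at the
theoretical fragment positions, as auxiliary scores. The spectral angle
uses a flat theoretical intensity vector, so its absolute values are not
comparable to angle metrics computed against predicted intensities; only
its ordering is used. Fragment matching uses a closed ±20 ppm interval
with nearest-peak assignment (lower m/z wins exact ties). Cross-correlation
and the spectral angle are invariant under global intensity scaling of the
spectrum; the hyperscore, by construction, is not — its *ranking* is.

## The synthetic ground truth

`generate_peptidome()` draws unique random sequences with lengths peaked
at 9 over 8–14 (mean ≈ 9.5, as in HLA-I elutions), log-normal abundances
(meanlog log(1e5), sdlog 1.5 — about four orders of magnitude of dynamic
range), Gaussian elution peaks with uniform apexes, and length-dependent
charge priors (≤9-mers: 0.2/0.7/0.1 for 1+/2+/3+; longer: 0.1/0.65/0.25).
Each peptide's MS1 intensity is partitioned *deterministically* across
charges by its priors — a design choice that yields multi-charge
precursors (required by the quantification rules) and makes determinism
trivial. MS1 m/z carries 1.5 ppm Gaussian measurement noise and fragment
m/z 4 ppm; without measurement noise the ppm filters would be vacuous.

MS2 spectra are ion-statistical: the ions collected are
`min(AGC target, flux_in_window × max injection time)` with flux
proportional to MS1 intensity; every precursor inside the isolation
window contributes (chimeric co-isolation); each peptide's fragment
intensity profile is drawn once from a Dirichlet (concentration 0.8 per
fragment) keyed by `(profile_seed, sequence)` and reused, so repeated
scans of the same precursor are correlated as in reality; per-fragment
counts get Poisson shot noise; ~30 uniform chemical-noise peaks are
appended. This is why hMS2 scans (higher AGC target and injection time)
yield systematically better spectra for low-abundance precursors — the
mechanism behind the scheme's sensitivity gain — which a seeded test
verifies as a median cross-correlation ordering over 200 draws.

Dilution series multiply spike abundances by the ratio while the
background stays bit-identical across mixtures; ratio 0 is the spike-free
negative control.

**Isobaric interferents.** The realism of the scout filter hinges on
non-target analytes that match a scheduled precursor mass. The generator
builds, for each target sequence, one exact isobar via mass-exact
composition rewrites (N ↔ GG and Q ↔ AG, identities to ~1e-6 Da) followed
by residue shuffling, eluting inside the target's scheduled window.
One isobar per *sequence* (not per charge-state entry) is used because an
isobar shares the target's entire charge envelope. Candidate isobars
sharing more than ~30% of fragment m/z with the target are rejected when
possible (bounded retries keep the least-overlapping candidate): plain
anagrams share so many partial residue sums that they — and their
reversed decoys — behave like the target at the fragment level, which is
not how unrelated real-world isobars behave.

## Scheduling and retention time

Targets are expanded over methionine-oxidation variants (up to 3 per
peptide) and charges 1–3; each (form, charge) gets a ±15 min closed
window around the predicted RT, clamped to the 125-min gradient; modified
forms inherit the unmodified peptide's RT (a sequence-level surrogate
cannot distinguish oxidation). RT prediction is pluggable: externally
predicted or measured RTs enter through the `rt_min` column; the built-in
surrogate is a least-squares fit of RT on the Kyte–Doolittle hydropathy
sum and length over ≥10 calibration pairs. Because the generator's
ground-truth RTs are uniform by design (hence uncorrelated with
hydropathy), the benchmark feeds measured RT plus Gaussian error through
the bypass; the error sd of 13 min (scaled with the gradient) makes the
±15 min window capture ≈75% of targets, the operating point of a
practical scheduled method.

## Identification and FDR

The offline engine searches each MS2 scan against a peptide database
(all modification variants × charges, reversed-sequence decoys with
palindrome collisions dropped): candidates within ±10 ppm of the isolated
m/z at matching charge, plus — in chimeric mode — candidates matching any
MS1 feature of the cycle that lies inside the isolation window. The best
target and best decoy are kept per co-isolation group; a PSM whose
precursor deviates from the isolation center by more than 10 ppm is
flagged `co_isolated`. FDR uses the conservative `(D + 1)/T` estimator
with monotone q-values at the 1% level; peptide-level results take the
best PSM per stripped sequence and re-apply the same procedure. Depth and
target counts in the benchmark are peptide-level (the convention for
unique-stripped-sequence reporting); PSM-level acceptance drives the TID
classification, quantification and the mass-difference analysis. A consequence worth knowing: nothing can
be accepted at 1% until at least 100 targets outrank the top decoy, so
very small searches return empty — intended behavior of the estimator,
not a bug.

A *target identification* (TID) is recorded when an RTS **hit** event's
best candidate peptide is also an accepted PSM on that event's own sMS2
and/or hMS2 scan. Restricting TIDs to hit events (rather than all events)
makes the funnel ordering TIDs ≤ hits ≤ events structural; empirically
the non-hit scout spectra essentially never produce accepted PSMs of
their target anyway.

The same-charge co-isolated mass-difference analysis reproduces a
chemistry fact: because the fractional parts of the 20 residue masses
span < 0.1 Da, mass differences between co-isolated peptides concentrate
near integer multiples of 1 Da; the benchmark checks that ≥80% of
same-charge residuals fall within 0.15 Da.

## Desk-scale study conditions

`benchmark_config()` encodes the conditions the package's end-to-end
checks run under. Generator and engine defaults keep the full-scale
settings (125-min gradient, ±15 min windows, 3-s cycles, the filter
thresholds, ratios 1/16…1/1024 plus negative control). The benchmark
itself is scaled to a desktop: 1600 background peptides and 60 targets on
a 4-min gradient, elution σ of 0.1 min, with the scheduling window, the
RT error, and the elution margin scaled proportionally to the gradient
(15/125, 13/125, 5/125). The density is chosen so that discovery demand
*saturates* the cycle budget, as real immunopeptidomes do — that
saturation is precisely what creates the depth trade-off between methods;
an unsaturated simulation would show targeted scanning as free. Under
these conditions the expected orderings emerge: DDA depth ≥ RTS-filtered
depth ≥ ilDDA depth, RTS-filtered target sensitivity ≥ DDA, chimeric
search ≥ non-chimeric on the same log, and zero target identifications in
the negative control.

What passing these tests does **not** show: real spectra have isotope
envelopes, neutral losses, co-eluting modified forms, chromatographic
drift between replicates, and search spaces of 10^4–10^5 sequences; the
simulator has none of these (replicate variation enters only through
seeds). Absolute depths, rates and score distributions are therefore not
comparable to published instrument runs — directions and orderings are
the claims under test, not magnitudes.

## Determinism

Every stochastic step derives its seed from a master seed and an entity
identifier via a polynomial string hash (`hash_seed()`), and all
random-number use is wrapped so the caller's RNG state is untouched. Two
runs with the same (sample, configuration, seed) are bit-identical end to
end, which the suite asserts on scans, peaks, events and accepted PSMs.

## A minimal session

```{r example, eval = FALSE}
model <- signal_model(gradient_min = 2)
bg <- generate_peptidome(200, seed = 1, gradient_min = 2, rt_margin = 0.2,
                         rt_sigma = 0.1)
sp <- generate_peptidome(20, seed = 2, gradient_min = 2, rt_margin = 0.2,
                         rt_sigma = 0.1, source = "spike", target_fraction = 1)
targets <- predict_rt(data.frame(sequence = sp$sequence, rt_min = sp$rt_apex),
                      gradient_min = 2)
sil <- schedule_targets(targets, halfwidth_min = 0.25, gradient_min = 2)
mix <- make_dilution_series(bg, sp, 1 / 64)[[1]]
log <- run_acquisition(mix, sil, method_config("NeoDiscMS"), model, seed = 7)
db <- build_search_db(c(bg$sequence, sp$sequence))
accepted <- fdr_filter(search_scanlog(log, db), 0.01)
tids <- classify_tids(log, accepted, sp$sequence)
rts_funnel(log, tids)
```
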