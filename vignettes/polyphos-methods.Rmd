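---
title: "Two-tier detection of (poly)phosphate additives: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-tier detection of (poly)phosphate additives: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyphos)
```

## The analytical problem

Condensed phosphates are chains or rings of orthophosphate units joined by
phosphoanhydride bonds. As food additives they fall into three regulatory
classes — pyrophosphates (E450), triphosphates (E451) and polyphosphates
(E452) — with different permitted uses. Undeclared treatment of fresh
products is a fraud and a safety problem, and is analytically hard to
prove: the higher polymers hydrolyse in phosphatase-rich matrices, leaving
mostly orthophosphate, which is also abundant naturally (tens to ~1300
µg/g in untreated tissue); and no reference standards exist above
triphosphate, so the long chains cannot be individually quantified at all.

`polyphos` models the two-channel strategy a control laboratory uses on
high-performance ion-exchange chromatography: a fast qualitative screen on
the suppressed-conductivity channel, and confirmation plus quantification
on a high-resolution Orbitrap coupled to the same separation.

## The anion database

Each target is a free (poly)phosphoric acid observed as its singly
deprotonated anion. `phosphate_species()` stores, per species, the
elemental composition, the expected retention time on the anion-exchange
gradient, the precursor m/z as printed in the instrument method *and* as
computed from monoisotopic masses, and the DIA confirmation fragments.
Computed masses are authoritative for matching; printed values are kept
for provenance. Two printed fragments conflict with assignable ions: a
pyrophosphate confirmation ion printed 78.9561 where the PO₃⁻ ion computes
to 78.9591 (the same table prints 78.9591 for tetraphosphate), and a
triphosphate confirmation ion printed 176.9685 where loss of HPO₃ from the
precursor gives 176.9359, the pyrophosphate anion. In both cases matching
uses the computed value and the printed one is retained, the second
flagged unverified. Isotope labels are first-class composition symbols
(`15N`), so the nitrate internal standard (H¹⁵NO₃, m/z 62.9854) needs no
special casing.

P₂O₅ equivalents — the unit regulation uses for phosphate totals — are
computed on the free-acid basis: each of the nP phosphorus atoms
contributes half a P₂O₅ formula mass, so 100 µg of H₃PO₄ is 72.43 µg P₂O₅.
The sodium-salt masses would be wrong here because the chromatographic
analytes are the anions of the acids.

## Peak detection

The baseline estimator is a rolling median (default window 1 min) followed
by a centred moving average over half that window. A rolling *minimum* —
the other common choice — is biased low by roughly 2.5 noise SD under
white noise, which would leave peak-free regions with a positive median
after subtraction; the median has no such bias and is equally insensitive
to peaks occupying a minority of the window. Because even a median bulges
under a broad peak, detection runs a second pass: the raw signal is
linearly interpolated across the detected peak spans (padded by a quarter
width) and the baseline is re-estimated on that peak-free version. On a
noise-free Gaussian of amplitude A and width σ this recovers the
closed-form area Aσ√(2π) to better than 1%.

Candidate apexes are local maxima of a lightly smoothed
baseline-subtracted signal, gated twice: on height (0.8 × min S/N × robust
noise scale, the 0.8 allowing for smoothing attenuation) and on
topographic prominence (≥ 3 smoothed-noise SD and ≥ 30% of the apex),
which rejects noise ripples riding on real peaks. Peak bounds descend from
the apex to 1% of its height or to the valley towards the neighbouring
peak, whichever comes first — overlapping peaks are valley-split.
Integration is trapezoidal between the bounds.

The noise scale is 1.4826 × the median absolute deviation of the
baseline-subtracted signal, re-estimated for the reported S/N from regions
at least three peak-SD away from every apex; a noise scale at
floating-point level reports the `Inf` sentinel. The apex height is read
at the smoothed maximum rather than as a local raw maximum, which would
bias low peaks upward by the expected maximum of the neighbouring noise;
sparse extracted-ion chromatograms occasionally put the smoothed apex on a
jitter dropout scan, and only in that case (raw < 70% of smoothed) does
the height fall back to the three-sample neighbourhood maximum.

## Screening on the conductometric channel

Screening is qualitative by construction: the 200 µg/g cut-off is a
property of the spiked run the reference is built from, not a
concentration computed from the sample. `build_rrt_reference()` detects
peaks in the spiked run, anchors on the first detected peak —
orthophosphate is both the earliest-eluting anion and the dominant natural
peak in these matrices — and stores the relative retention times of
pyro-, tri- and trimetaphosphate plus up to ten SHMP envelope peaks.
`screen_scd()` repeats the anchoring on the sample trace, so the decision
is invariant under uniform stretching of the time axis. A species matches
when its RRT deviates at most 2.5% (relative) with S/N ≥ 3. The SHMP
envelope is called when at least three *consecutive* envelope RRTs match:
the envelope rule needs a minimum to resist single spurious peaks, and
three consecutive matches is the smallest run that cannot be produced by
one accidental coincidence; the 2.5% rule is applied per peak, not jointly
to the envelope. Duplicate injections, when supplied, must both be
positive.

Validation statistics follow the screening-method conventions: the
false-positive rule requires fewer than 5% of fortified samples below the
blanks' mean + 3 SD, and instrumental linearity is an ordinary
least-squares fit over the 10–100 µg/mL (P₂O₅) working range.

## HRMS confirmation

`extract_xic()` sums centroids within ±5 ppm of the target per scan; 5 ppm
is chosen for a 70,000-resolution full scan with ~2 ppm calibration
scatter, and captures > 95% of the true intensity under 2 ppm jitter.
Confirmation requires (a) a precursor XIC peak within `rt_tol` (default
0.5 min, configurable; the HRMS channel has no published tolerance) of the
expected retention time, and (b) at least one listed fragment, extracted
from DIA scans whose 1 Th isolation window covers the precursor, with an
apex within `rt_tol`/2 of the precursor apex. The co-elution requirement
exists because DIA links precursor and fragment only through the isolation
window; without it any background ion at the fragment mass would
"confirm". Candidate precursor peaks are tried tallest-first and the first
that a fragment co-elutes with is kept, which also makes confirmation
monotone in the tolerances. The reported mass error is the
intensity-weighted mean ppm offset of the precursor centroids across the
peak. Fragment intensity ratios are not scored — without reference
spectra at the fixed collision energy only presence is defensible — and
isotope-pattern scoring is deliberately out of scope.

In-source interconversion (thermal transformation in the heated ESI
source) makes some anions appear at other species' retention times; the
pyrophosphate ion, for instance, can show peaks at the ortho- and
triphosphate retention times. Confirmation only ever uses the peak at the
species' own retention time — chromatographic separation is what makes
quantification immune to the effect — and `resolve_interconversion()`
documents cross-RT signal in the record notes, labelling an unconfirmed
species whose ion elutes only at a longer chain's retention time as that
chain's in-source fragment. The annotation pass uses S/N ≥ 5 so notes
reflect substantial signal rather than background.

The six long-chain anions (tetra-, tetrameta-, penta-, pentameta-, hexa-,
hexametaphosphate) have no standards; their confirmed subset, in elution
order, is the E452 *fingerprint* (`fingerprint_longchain()`).

## Quantification

Calibration is ordinary least squares; the LOD/LOQ formulas (3.3·SD/b,
10·SD/b) take SD as the standard error of the intercept and b as the slope
of the *low-concentration* curve, implemented as the lowest three levels
of a series since the levels are not otherwise enumerated. Back-calculation
passes through the extraction scheme — 2 g of homogenate brought to 40 mL,
diluted 1:10 before injection, i.e. µg/g = µg/mL × 200 by default — and
censoring is applied on the back-calculated sample scale: below LOD
reports `<LOD`, between LOD and LOQ `<LOQ`, no signal ND. Asking to
quantify a long-chain species is an error, not a number: they are
fingerprint-only. Recovery is the before/after-extraction response ratio
in percent; precision is the within-day CV (averaged over days) and the CV
of the day means. The internal standard is carried in the database but
response normalisation is off by default, as an optional ratio — how the
standard is used for normalisation is not specified by the method, so the
package does not guess.

Weighted or robust regression and matrix-effect correction are
deliberately not implemented.

## The verdict

`classify_sample()` applies a cascade per sample: (1) any confirmed
long-chain species ⇒ `polyphosphate_E452`; (2) otherwise any of pyro-,
tri- or trimetaphosphate quantified at ≥ 1 µg/g, or a positive
conductometric screen ⇒ `short_chain_additive`; (3) otherwise any species
present below quantifiable or below-threshold levels ⇒ `trace_endogenous`
— near-trace amounts alone never assert treatment, because endogenous
(poly)phosphates from bacterial and eukaryotic metabolism occur at trace
level in untreated tissue; (4) otherwise `no_evidence`. Rule (3)
deliberately includes amounts quantified *below* the 1 µg/g threshold:
sub-µg/g short-chain levels are narrated as endogenous in the survey data
and should not read as "no evidence".

Orthophosphate is flagged separately (`ortho_elevated`) above a
matrix-specific ceiling — 2000 µg/g for meat and fish, 1500 µg/g for dairy
by default. The ceilings are configurable because no numeric rule exists,
only examples: natural levels in the bundled survey run 33–1299 µg/g while
hydrolysis-affected samples run 2715–12554 µg/g, so the defaults sit in
the wide gap between the two populations. The flag is evidence, not a
verdict: excess orthophosphate is consistent with hydrolysed additives but
never identifies which additive was used. When the HRMS fingerprint and
the screening channel disagree (fingerprint-positive, screen-negative —
real cases exist where a single long-chain species survives while the
conductometric channel sees nothing), the verdict stays fingerprint-driven
and the evidence string records the disagreement.

The bundled survey table (`undeclared_survey()`) encodes the 43
undeclared samples of the application study; with default thresholds it
yields 7 screening positives and 8 E452 verdicts.

## The synthetic-data generator

`synthetic_spec()` fixes the study conditions: Gaussian peaks of σ = 0.08
min (consistent with baseline-resolved peaks 1–2 min apart on this
gradient) at the database retention times; natural orthophosphate defaults
per matrix (meat 850, fish 950, dairy 550, blank 400 µg/g — central values
of the untreated survey rows); an optional matrix interferent at 6.95 min,
emulating the peak seen in some blank matrices and deliberately separated
from every target RRT; additive white noise (SD 1 signal unit),
1% proportional noise and optional drift; and 2 ppm centroid jitter.

Conductometric response is proportional to the P₂O₅-equivalent amount with
sensitivity 0.0625 height units per µg/g P₂O₅, which places a 200 µg/g
single-species spike near S/N 10 — the screening cut-off is then exercised
with a realistic margin rather than passed trivially. The SHMP envelope is
ten peaks on a documented 14–27.5 min grid with geometrically decaying
heights (ratio 0.85); the envelope's first-peak gain is 1.5 relative to a
single species so that the tenth peak still clears S/N 3 at the 200 µg/g
cut-off, reflecting that the commercial standard's response concentrates
in its leading peaks. The true envelope retention times and intensity
pattern are only ever shown graphically in method descriptions, so these
grid values are explicitly artificial.

HRMS scan sets interleave one full scan and one 1 Th DIA window per
database precursor per 0.05-min cycle. Signal centroids follow the
Gaussian elution profile with ppm jitter; every monitored m/z also carries
a log-normal chemical background (median 50 intensity units, sdlog 0.3) —
log-normal because high-resolution extracted windows show dense,
light-tailed chemical noise rather than heavy-tailed spikes. DIA fragments
appear at 30% of the precursor intensity by default. An `interconversion`
fraction re-emits the pyrophosphate ion at the ortho- and triphosphate
retention times to exercise the annotation pass. An SHMP spike distributes
its amount over the six long-chain species with the same 0.85 decay.

What the generator does **not** emulate: real suppressed-conductivity
response curves (it is linear by construction), hydrolysis kinetics during
storage, co-eluting matrix anions other than the single interferent,
retention-time drift between runs, and detector saturation. Passing tests
therefore demonstrate the correctness of the decision logic and the
estimators under the stated noise model, not method performance on real
extracts — instrument-bound figures (the published per-matrix LOD/LOQ,
recovery and CV tables) are not reproducible without the instrument and
are replaced by parameter-recovery suites.

## Numerical choices and problem sizes

Detection tolerances: RRT ±2.5% (relative, per peak, accepting exactly
2.5% despite floating point); HRMS retention ±0.5 min with fragment
co-elution ±0.25 min; XIC extraction ±5 ppm; screening S/N ≥ 3. Censoring
order ND < LOD < LOQ, rendered with the survey tables' symbols. Minimum
peak width is 0.05 min on the densely sampled conductometric channel and
0.1 min (three scan cycles) on XICs. Degenerate inputs fail loudly:
empty compositions, hydrogen-free deprotonation, non-monotone time axes,
missing orthophosphate anchors, two-level calibrations and zero-mean
precision groups are all errors, not NA propagation.

Simulation-backed checks in the test suite and the acceptance script use
50-seed batches for peak-detection recall/FDR and screening rates, 200
repetitions for calibration linearity, and a handful of full FS+DIA scan
sets for the fingerprint — sizes at which the binomial noise on every
checked proportion is far below its margin while a full run stays in the
tens of seconds.

## Known limitations

Profile-mode spectra are rejected, not centroided. Chromatogram alignment
across runs is out of scope; the RRT mechanism absorbs uniform gradient
scaling but not non-linear drift. The SHMP envelope reference must come
from a spiked run (or the generator's documented defaults) because its
true retention pattern is not tabulated. Isotope-pattern confirmation and
fragment-ratio scoring are not implemented. The verdict thresholds
(1 µg/g short-chain, matrix orthophosphate ceilings) are calibrated to the
bundled survey's narrated outcomes and should be revisited for matrices
outside meat/fish/dairy.
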