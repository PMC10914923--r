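---
title: "Quantifying targeted RNA editing from Sanger chromatograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying targeted RNA editing from Sanger chromatograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangeredit)
```

## The measurement

Targeted RNA-editing assays of the TRIBE/HyperTRIBE family fuse an
RNA-binding protein to a deaminase domain: an ADAR catalytic domain converts
adenosines in bound transcripts to inosine, which reverse transcription and
sequencing read as guanosine, so binding leaves A→G marks; APOBEC fusions
leave C→U marks read as C→T. When the question concerns one reporter or one
endogenous transcript, transcriptome-wide sequencing is unnecessary: the
region of interest is RT-PCR amplified and Sanger sequenced, and the editing
level at each substrate position is read off the chromatogram.

At a candidate adenosine the trace shows an A peak and, if the position is
partially edited, a G peak at the same position. `sangeredit` integrates the
four dye channels over each called base's peak and computes the relative
editing

$$ e \;=\; \frac{\mathrm{area}(G)}{\mathrm{area}(A) + \mathrm{area}(G)} $$

(equivalently $T/(C+T)$ in C→T mode). Because amplification, sequencing
chemistry and dye crosstalk produce a nonzero apparent editing level even in
unedited RNA, every experiment carries negative-control replicates (e.g. a
Luciferase construct lacking the RBP fusion). The control mean at each
position is subtracted from each sample replicate's value, giving corrected
per-replicate values whose mean $\bar c$ and sample standard deviation $s_c$
(computed with the $n-1$ denominator across biological replicates) drive two
criteria, both of which must hold for a site to be called significant:

1. $\bar c - 3\,s_c > 0$ — the corrected editing level must sit more than
   three standard deviations above zero (strict inequality);
2. $\bar r \ge 2\,\bar b$ — the uncorrected sample mean $\bar r$ must be at
   least twice the control mean $\bar b$; when the control mean is
   numerically zero (below $10^{-9}$) this reduces to $\bar r > 0$.

The conjunction is deliberately stringent: criterion 1 guards against
replicate scatter, criterion 2 against positions whose background is itself
high. No multiple-testing correction is applied on top — the 3×SD rule is
the stated guard — but the per-run site count is reported so users can apply
an FDR procedure externally if desired.

### Reading of the criteria

The phrase "its standard deviation" in criterion 1 is interpreted as the
sample SD of the corrected values across biological replicates, which equals
the SD of the raw values because the subtracted control mean is a
per-position constant. Criterion 2's singular "value" is interpreted as the
replicate mean; a stricter per-replicate variant (every sample replicate at
least twice the control mean) is available behind
`strict_criterion2 = TRUE`, default off. Background correction subtracts
the control *mean* from each sample replicate rather than pairing
replicates, because sample and control infiltrations are independent.
Corrected values may be negative and are not clipped, so standard
deviations remain honest. The default `min_replicates = 3` mirrors the
common 3–4 biological-replicate design.

## Peak quantification

Trace viewers do not document their area algorithms, so `sangeredit` uses a
deterministic, parameter-free scheme: the window of call $i$ spans the
midpoints to its neighbouring called peaks (first and last windows extended
symmetrically), and each channel's area is the trapezoidal integral of the
linearly interpolated trace over that window at native sampling. Windows
tile the read, so with `baseline = "none"` per-channel areas sum exactly to
the whole-span integral (conservation, tested to 1e-9 relative). The
default `baseline = "window_min"` subtracts the window's per-channel
minimum before integrating, suppressing constant channel offsets; areas are
clipped at zero. Equivalence to any particular commercial viewer is not
claimed — the calibration analysis below is the evidence that the scheme's
ratios respond linearly to template composition.

## Mapping calls to the reference

Basecalls are aligned to the reference amplicon globally
(Needleman–Wunsch, via Biostrings) with match +2, mismatch −2, gap open −5
and extend −1. Partially edited positions are basecalled as IUPAC
two-base codes (e.g. R for A/G); the substitution matrix scores an
ambiguity letter as a match whenever its base set contains the reference
base, so heavily edited reads still map. Alignments below a 70% identity
floor (configurable) fail loudly rather than silently misassigning areas.
Reference positions covered by no aligned call are reported as *not
evaluable*, never as 0% editing: absence of signal is not absence of
editing. Coordinates in all user-facing tables are 1-based on the supplied
reference; domain-specific numbering (e.g. relative to the first intronic
position) is obtained by supplying a correspondingly trimmed reference.
Reads sequenced with a reverse primer are handled by
`orientation = "reverse"`, which reverse-complements traces and calls
before quantification.

## Companion assays

**Calibration.** Mixing edited and unedited templates at known ratios and
measuring the peak-area fraction at the mutated position tests the
linearity of the whole readout. `fit_calibration()` summarises a series by
ordinary least squares of measured on expected fraction; on simulated mixes
over $f \in \{0, 0.05, 0.1, 0.25, 0.5, 0.75, 1\}$ the package recovers a
slope within [0.9, 1.1] with $r^2 \ge 0.98$ at 2% channel noise, the
desk-scale analogue of a plasmid-mix validation.

**CAPS.** An engineered restriction site that appears only upon editing
converts the editing level at one position into a cleaved fraction of the
amplicon. `caps_cleaved_fraction()` computes
`cleaved / (cleaved + uncleaved)` from Bioanalyzer-style band tables on
molar quantities (mass inputs are divided by fragment length); only the
larger matched cleavage fragment is counted, since one cut yields two
fragments from the same molecule. Groups of lanes are compared with an
unpaired two-tailed t-test; the Welch unequal-variance form is the default
(the safer choice when only "unpaired t-test" is specified), switchable to
the pooled form. Degenerate zero-variance inputs are handled in closed form
(t = 0, p = 1 for identical groups; |t| = ∞, p = 0 for a pure shift).

## The synthetic-data generator

`simulate_chromatogram()` builds one Gaussian peak per reference base at
uniform spacing (defaults: spacing 12 samples, peak SD 3, amplitude 1000).
At an edited position with true fraction $f$ the substrate channel carries
$(1-f)$ of the peak and the product channel $f$, with a shared per-position
amplitude factor (CV 0.1) because both signals derive from the same
molecule population. Symmetric crosstalk (default 1% into each other
channel) and additive Gaussian noise (SD 10, i.e. 1% of amplitude) are
added and signals are clipped at zero, as sequencer baselines are.
Basecalls take the maximum-area channel, or a two-base IUPAC code when the
minor channel exceeds 25% of the major — the convention that exercises the
ambiguity-aware aligner. Every replicate's seed derives deterministically
from a master seed, so experiments are bit-reproducible.

What the generator emulates: mixed-template peak superposition, channel
crosstalk background, replicate-to-replicate amplitude variation, baseline
clipping. What it does not: PCR amplification bias, RT errors, dye blobs,
mobility shifts (a jitter parameter exists but defaults to 0 to keep
closed-form expectations exact), or sequence-dependent peak shapes.
Passing recovery tests on synthetic data therefore demonstrates
correctness of the quantification pipeline, not the absence of real-world
chemistry artefacts.

`synthetic_reference()` interleaves one candidate site per five bases
(motif `CATCT` for A→G) so that (i) the bases flanking each candidate
contribute nothing to its substrate/product channels, keeping per-site
expectations clean, and (ii) a read in which *every* candidate is fully
edited still aligns at 80% identity — a situation real amplicons, with a
handful of edited sites, never approach.

### Expected small biases

Two generator features place a floor under the raw editing background:
crosstalk moves ≈1% of the substrate peak into the product channel, and
clipped noise rectifies to a small positive area (≈ $\sigma/\sqrt{2\pi}$
per sample) in every channel. Together they bias the raw ratio by
≈ +0.016 at $f=0$, shrinking towards 0 and changing sign as $f$ grows.
Control subtraction removes this additive background almost exactly — the
corrected mean at $f=0$ is centred on zero — but the corrected value
inherits a multiplicative shrinkage of ≈ $(1-4\cdot\text{crosstalk})$,
about −3% at $f=1$. Recovery of the true fraction is therefore assessed on
the raw measured ratio (the direct analogue of a plasmid-mix calibration),
which stays within ±0.02 of truth across the whole grid at generator
defaults, while significance calling uses the corrected values as defined
above.

## Operating characteristics

`estimate_operating_characteristics()` runs complete simulated experiments
(default 4 sample vs 4 control replicates) across a grid of true fractions
and reports the per-site significant-call rate with binomial standard
errors. Under generator defaults the criteria are conservative and
powerful: the false-positive rate at $f=0$ is ≈ 0.1% over 1000 null
sites (200 sites × 5 runs), while sites with $f \ge 0.25$ — indeed already
$f \ge 0.05$ — are called at ≈ 100%. The theoretical null rate of
criterion 1 alone at $n=4$ is $P(T_3 > 6) \approx 0.5\%$; the conjunction
with criterion 2 pushes the joint rate well below that. Problem sizes in
the shipped tests (24–200 sites, 2–5 runs) were chosen to give Monte-Carlo
standard errors comfortably below the margins being tested.

## Numerical choices and degenerate inputs

* Editing ratios with zero substrate+product area are missing (`NA`), not
  zero; `min_total_area` raises this signal floor if desired.
* Criterion 1 uses a strict inequality; criterion 2 uses ≥. Ties in the
  run summary's maximum are broken by the smaller position.
* Results TSVs store numerics at 6 significant digits and round-trip.
* Delimiter sniffing accepts comma/tab/semicolon with decimal points only;
  worksheet imports are remapped by column name, not by hardcoded layout,
  and precomputed-ratio worksheets bypass peak integration.
* Peak-location ties are rejected at chromatogram construction (strictly
  increasing locations), so integration windows are always well defined.

## Limitations

This package quantifies amplicon Sanger readouts only — it is not a
transcriptome-wide editing caller, performs no basecalling, no mixed-base
re-calling, and no trace preprocessing beyond baseline subtraction. The
criteria's behaviour at replicate counts far above 4, or under correlated
replicate noise, should be explored with the operating-characteristics
harness before relying on the defaults.
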