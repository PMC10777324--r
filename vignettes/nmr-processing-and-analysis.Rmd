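---
title: "Processing and analyzing 1D NMR spectra with nmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing and analyzing 1D NMR spectra with nmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrkit)
```

# Scope and model

`nmrkit` is a headless toolkit for one-dimensional solution NMR: it reads
raw data (JCAMP-DX and Bruker directories), processes it through a
recorded, re-executable filter chain, analyzes the result (peak picking,
integration, automatic multiplet analysis), handles molfile structures for
assignment and answer checking, and serializes everything into a single
JSON workspace.  A first-order spin-system simulator provides ground-truth
inputs, both for the test suite and for instructors fabricating teaching
exercises.

The signal model throughout is the damped complex exponential: a resonance
at chemical shift $\delta$ (ppm) contributes
$a\,e^{2\pi i \nu t}\,e^{-t/T_2}$ to the FID, with
$\nu = (\delta - \delta_{\mathrm{carrier}})\,f_0$ for an observe frequency
$f_0$ in MHz, giving a Lorentzian line of full width at half maximum
$1/(\pi T_2)$ after Fourier transformation.  Scalar coupling to $n$
equivalent protons splits a signal into $n+1$ lines with binomial
intensities — the first-order approximation.  The one deliberately
second-order piece is `simulate_ab()`, the closed-form two-spin AB system
(four lines at $\pm(C \pm J)/2$ about the center, $C=\sqrt{\Delta\nu^2 +
J^2}$, with the characteristic roof effect $1 \mp J/C$); it exists as an
exact oracle that the first-order engine cannot reproduce, and to exercise
the analyzer's fallback paths.

# The processing chain

Every operation between the raw FID and the displayed spectrum is recorded
as a named `filter_record()` with its parameters.  `apply_chain()`
re-executes a chain from the raw FID deterministically, so *editing* a
recorded parameter and re-running is exactly equivalent to having
processed with the edited value from the start.  This is the package's
reversibility contract, and it is tested bitwise.

Numerical choices, each of which the field treats as standard but which
are worth stating:

* **First-point halving.**  The first FID sample is multiplied by 0.5
  before the transform.  A one-sided DFT of a decaying exponential
  otherwise leaves a constant offset of half the first sample across the
  whole spectrum; halving removes it exactly.
* **Zero-filling default.**  Twice the next power of two above the current
  length (`default_zero_fill()`), e.g. 700 points are filled to 2048.
  This interpolates the digital grid without inventing resolution.
* **Axis convention.**  The ppm axis is stored strictly descending, and
  interval arguments are normalized so either order works.
* **Group delay.**  Digitally filtered Bruker data start with a group
  delay of `GRPDLY` points.  The reader records it; `fourier_transform()`
  compensates it as the equivalent frequency-proportional phase ramp (360
  degrees times the group delay across the spectral width), never by
  silently shifting samples.
* **Angles.**  Degrees everywhere, matching spectrometer software; the
  first-order phase parameter is the total phase change across the
  spectral width, zero at the pivot.

## Automatic phase correction

`auto_phase()` has to recover $(\phi_0, \phi_1)$ to a few degrees in the
presence of noise.  Two estimators are combined:

1. A **cluster-phase regression**.  Peaks in the magnitude spectrum are
   grouped into clusters (one per multiplet).  For each cluster the
   complex spectrum is summed over a window symmetric about the cluster's
   magnitude centroid with magnitude weights; by symmetry the dispersive
   component integrates to zero, so the argument of the sum is the local
   dephasing angle.  A weighted linear fit of these angles against
   position gives $(\phi_0, \phi_1)$ directly; it is refined on the
   wrapped angle residual.  Two details matter: the window must be
   centered on the *centroid* (an asymmetric window leaks dispersion into
   the angle), and point-wise peak phases are useless because the phase of
   a Lorentzian rotates by tens of degrees within half a digital bin of
   the line center.
2. A **grid search** on $\phi_0$ in 2-degree steps followed by
   Nelder–Mead refinement of both angles, minimizing a negative-area plus
   derivative-entropy objective evaluated over the signal regions only
   (magnitude above three times the noise, dilated).  Restricting to
   signal regions is essential: over the full spectrum the negative-area
   statistic is dominated by baseline noise and becomes insensitive at
   the few-degree scale.

The regression solution is preferred whenever its absorption objective is
not substantially worse; the grid branch covers pathological inputs with
no usable peak clusters.

## Baseline correction

The default is the classic iterative polynomial fit (degree 3, ten
passes): after each fit, points whose residual exceeds the mean plus two
standard deviations — the peaks — are dropped from the next fit.
`method = "airpls"` provides adaptive iteratively reweighted penalized
least squares on a sparse Whittaker smoother for baselines a cubic cannot
follow.  The estimated baseline is kept on the spectrum object for
inspection.

# Signal analysis

## Noise, peaks, ranges

The noise estimator pools the quietest decile of 32-point windows of the
real part and takes 1.4826 times their median absolute deviation.
Selecting quiet windows makes the estimate immune to even very tall
peaks, but biases it low by a factor of 0.794 (calibrated on Gaussian
noise, essentially independent of spectrum length); the estimate is
rescaled by 1.26 to undo this.

Peak picking takes local maxima of the real part above `min_snr` times
the noise, refines positions by three-point parabolic interpolation and
measures widths from interpolated half-height crossings.  Maxima that sit
within three linewidths of a much taller peak are suppressed by default:
at realistic signal-to-noise, noise riding on a strong line's flank
always produces such spurious "shoulder" maxima.

`detect_ranges()` seeds regions from runs of at least three consecutive
supra-threshold points (single-point noise spikes never qualify; real
lines, several digital bins wide, always do), grows them until the trace
stays below one noise std for five consecutive points, and merges regions
closer than 20 Hz — above the largest common proton coupling — so a
multiplet whose trace dips into the noise between lines remains one
range.

## Multiplet analysis

The classifier works on the picked stick pattern (positions in Hz,
intensities), with spacing tolerance `max(0.2 Hz, 1 digital bin)` and
25 % relative intensity tolerance:

1. simple binomial multiplets `d` through `sept` (equal spacings, Pascal
   ratios);
2. symmetric four-line patterns with equal intensities: read as **two
   overlapping equal-J doublets** when the middle gap is smaller than the
   outer gaps, as a **dd** otherwise.  The two interpretations are
   formally indistinguishable from line positions and intensities alone —
   a dd with couplings $(J_1, J_2)$ and two equal doublets of coupling
   $J_2$ whose centers differ by $J_1$ produce identical sticks — so this
   gap rule is a documented convention.  It reads every dd with
   $J_1 > 2 J_2$ correctly and resolves genuinely overlapping doublet
   pairs; a true dd with $J_1 < 2 J_2$ is reported as two doublets.
3. nested extraction, largest coupling first: the pattern is folded in
   half (pairing line $i$ with line $i + n/2$), and the collapsed
   sub-pattern is classified recursively, yielding `dd`, `dt`, `ddd`, …;
4. a two-signal split at the widest internal gaps when both parts
   classify on their own and both carry at least 10 % of the intensity;
5. if nothing fits and a stick below 10 % of the tallest is present, the
   weakest stick is dropped and classification retried (no first-order
   line of the supported alphabet is that weak, so such sticks are
   artifacts);
6. a sum-of-Lorentzians deconvolution (up to 12 lines, positions bounded
   to the range, widths bounded below by one digital bin) followed by
   re-classification of the fitted components;
7. otherwise multiplicity `"m"` centered on the intensity-weighted
   centroid.

Ties between `t` and `dd` with $J_1 \approx J_2$ go to the simpler `t`.

## Quantitation

Trapezoidal integration (`integrate_region()`) interpolates the interval
endpoints, which makes it exactly additive over adjacent intervals.  For
*relative* quantitation at moderate signal-to-noise, however, wide-window
trapezoids integrate a lot of baseline noise; `fit_lorentzians()` fits
the line model and reports analytic areas ($h \cdot w \cdot \pi/2$),
which is the preferred route and what the acceptance checks use for the
2 % integral-ratio comparisons.  Signal-to-noise follows the spectrometer
convention throughout: `noise_sigma_for_snr()` targets
$S/N = \text{peak height} / (2 \times \text{rms noise})$ in the
unapodized spectrum.

# Structures, topicity and answer checking

`parse_molfile()` reads V2000 connection tables (V3000 is rejected
explicitly) and fills implicit hydrogens by the standard valence model
(C 4, N 3, O 2, halogens 1, S 2/4/6 minimal fit, charge-adjusted).

`canonical_key()` produces a renumbering-invariant text key via
individualization–refinement canonical labeling.  By design the encoding
carries per-atom heavy-bond-order sums and the *unordered* connectivity
rather than per-bond orders, so the two Kekulé drawings of a substituted
aromatic ring compare equal without any aromaticity perception.  The
price is a small loss of constitutional discrimination between bond-order
isomers that agree in all atom order sums and adjacency — acceptable for
answer checking, and documented.  Tetrahedral parity, when requested, is
transported through the relabeling with the permutation sign of each
stereocenter's neighbor list (implicit hydrogen counted as the
highest-numbered neighbor, the molfile convention).

Hydrogen equivalence (`equivalent_hydrogens()`) starts from
Weisfeiler–Lehman refinement, verified exactly by enumerating all
canonical labelings (the set of minimal labelings closes under the
automorphism group, so orbits fall out directly) for molecules up to 64
heavy atoms; beyond that the refinement partition is returned flagged
approximate.  Diastereotopic CH₂ protons are detected by the substitution
test: set a formal parity at the prochiral carbon both ways (with one
hydrogen made explicit as a marker), compare stereo-aware canonical keys,
and check the enantiomer case by flipping every parity.  Identical keys
mean homotopic/equivalent; keys that differ only up to a global mirror
mean enantiotopic (reported equivalent); otherwise the pair is
diastereotopic — which only happens in the presence of a configured
stereocenter, as chemistry requires.  No CIP rules are implemented, and
double-bond E/Z topicity is not considered; these are known limitations.

`check_answer()` compares constitution first (`wrong_constitution`), then
parity (`wrong_stereo` only when stereo checking is requested).

# Projects and exercises

A project serializes to one JSON document ("nmrkit project v1"): numeric
arrays are base64-encoded little-endian IEEE 754 doubles with a declared
dtype, so floats round trip bit-exactly and saving a loaded project
reproduces the file byte for byte.  Unknown top-level keys survive a
load/save cycle.  Stored raw FIDs plus stored filter chains re-execute to
the stored spectra exactly, which is the second half of the reversibility
contract.

`build_toc()` turns a folder hierarchy — any folder holding at least one
JCAMP-DX file and exactly one molfile is an exercise; parents become
categories — into a deterministic `toc.json` plus per-exercise
`exercise.json` (id, spectra, shown molecular formula; never the
solution).  `export_student_bundle()` writes a project with the spectra
and the formula but not the structure; the instructor variant embeds the
solution.  `grade_exercise()` returns only a verdict code and a
formula-match flag.

# The simulator as study-condition generator

All quantitative claims in the tests are made under conditions the
simulator defines, chosen once as typical of a modern 400 MHz proton
spectrometer:

* $T_2$ of 1–1.5 s (0.21–0.32 Hz lines), spectral widths of 1–4 kHz,
  acquisition of 4096–16384 complex points.  For the multiplet grid the
  acquisition is 16384 points over 2400 Hz (6.8 s, about 4.5 relaxation
  times): shorter records leave truncation sidelobes of several percent
  beside each line, which are indistinguishable from real minor lines at
  the tolerances being tested.
* Multiplet classification is exercised over {s, d, t, q, dd} × J ∈
  {2, 4, 7, 10, 12, 16} Hz at S/N 50, with the dd's second coupling set
  to $J/3$ so that every gap stays above three linewidths.
* Phase recovery is benchmarked on a comb of five well-separated singlets
  at S/N 100; sparse spectra whose weak multiplets carry most of the
  first-order phase information recover proportionally less precisely.
* Noise is complex circular Gaussian in the time domain with a mandatory
  seed, so every simulated dataset is bit-reproducible.

What passing these tests does *not* show about real data: lineshapes here
are ideal Lorentzians with flat baselines and no solvent signal, shimming
artifacts, $B_0$ drift, or radiation damping; coupling patterns are first
order, so strongly coupled (AB-type) regions of real spectra will land in
the `"m"` fallback or be read as their first-order lookalikes; and the
digital-filter group delay model is the idealized phase ramp.

# Known limitations

* 1D only; no 2D processing or display concerns anywhere in the API.
* First-order simulation only (the AB oracle excepted, by construction).
* The dd / two-doublet ambiguity resolution is a convention, stated
  above.
* Canonical keys ignore per-bond orders by design (see above) and carry
  tetrahedral parity only — no CIP, no E/Z.
* JCAMP-DX coverage is the common instrument-export denominator: AFFN and
  SQZ/DIF/DUP `(X++(Y..Y))` tables and NTUPLES FIDs; PEAK TABLE files are
  rejected with an explicit error.  The workspace JSON schema is this
  package's own documented format; no attempt is made to bit-match any
  third-party workspace file.

# A worked pass through the pipeline

```{r example, eval = FALSE}
sys <- spin_system(list(
  list(delta_ppm = 3.6, n_protons = 2,
       couplings = list(list(j_hz = 7, n_partners = 3))),
  list(delta_ppm = 1.2, n_protons = 3,
       couplings = list(list(j_hz = 7, n_partners = 2)))), t2_s = 1)
cfg <- sim_config(sfo1_mhz = 400, sw_hz = 2000, td = 8192, seed = 7)
cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, 100)

fid <- simulate_fid(sys, cfg)
spec <- fourier_transform(zero_fill(apodize_exponential(fid, 0.3)))
ph <- auto_phase(spec)
spec <- phase_correct(spec, ph$ph0_deg, ph$ph1_deg, ph$pivot_ppm)
spec <- baseline_correct(spec)

ranges <- detect_ranges(spec, min_snr = 3)
ranges <- set_relative_integrals(ranges, ref = 2, n_protons = 3)
to_publication_string(spec, ranges)
```
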