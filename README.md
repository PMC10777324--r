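# nmrkit

A headless R toolkit for one-dimensional NMR spectroscopy, built for
scripted processing pipelines and for teaching: import raw data, process
it through a reversible filter chain, analyze the signals, check
structures, and package everything into shareable workspaces and quiz
exercises.

**For whom.** Chemists and instructors who want the full 1D workflow —
Fourier transformation, phase and baseline correction, peak picking,
integration, multiplet analysis, assignment bookkeeping — available from
scripts rather than a GUI, with every step recorded and reproducible, and
with a simulator that generates ground-truth spectra for exercises and
tests.

**What it does.**

* **I/O** — JCAMP-DX reading and writing (AFFN and SQZ/DIF/DUP compressed
  `(X++(Y..Y))` tables, NTUPLES blocks for complex FIDs, compound LINK
  files) and Bruker raw directories (`acqus` + binary `fid`, int32 or
  float64, both byte orders, `2^NC` scaling, group delay recorded and
  compensated as a phase ramp).
* **Processing** — each step is a named, parameterized *filter*:
  exponential/Gaussian apodization, zero-filling, FT (first point halved,
  carrier-centered descending ppm axis), manual and automatic phase
  correction, polynomial or airPLS baseline correction, re-referencing.
  Chains re-execute from the raw FID bit-deterministically: editing one
  recorded parameter and re-running equals processing with the edited
  value from scratch.
* **Analysis** — robust noise estimation, peak picking with sub-bin
  interpolation, exactly additive trapezoidal integration, Lorentzian
  line fitting for quantitation, and automatic multiplet analysis:
  first-order patterns (s, d, t, q, quint, sext, sept and nested
  combinations such as dd and dt) with coupling extraction largest-J
  first, resolution of overlapping resonances by deconvolution and a
  documented tie-break for the four-line dd / two-doublet ambiguity, and
  publication-string export
  (`¹H NMR (400 MHz, CDCl₃) δ 7.26 (d, J = 7.0 Hz, 2H).`).
* **Structures** — V2000 molfile parsing, Hill formulas,
  renumbering-invariant canonical keys (Kekulé-form insensitive),
  hydrogen topicity with graph-automorphism orbits and diastereotopic
  CH₂ detection via the substitution test, and answer grading
  (`correct` / `wrong_constitution` / `wrong_stereo`).
* **Workspaces & teaching** — single-file JSON projects with lossless
  base64 float arrays (save → load → save is byte-identical), content-
  sniffing import, exercise-set building from a folder hierarchy
  (spectra + one solution molfile per leaf), solution-redacted student
  bundles, and grading.
* **Simulation** — first-order spin systems with seeded complex Gaussian
  noise, a closed-form AB two-spin oracle, and exercise-fixture
  generation.

The core lineshape model: a resonance contributes
`a·exp(2πiνt)·exp(−t/T₂)` to the FID and becomes a Lorentzian of FWHM
`1/(πT₂)` Hz; coupling to n equivalent protons splits a signal into n+1
binomial lines. See the vignette
(`vignettes/nmr-processing-and-analysis.Rmd`) for the algorithms and the
numerical conventions.

## A worked example

Simulate an ethyl pattern (CH₂ quartet / CH₃ triplet, J = 7 Hz) at 400 MHz,
process it, and analyze it:

```r
library(nmrkit)

sys <- spin_system(list(
  list(delta_ppm = 3.6, n_protons = 2,
       couplings = list(list(j_hz = 7, n_partners = 3))),
  list(delta_ppm = 1.2, n_protons = 3,
       couplings = list(list(j_hz = 7, n_partners = 2)))), t2_s = 1)
cfg <- sim_config(sfo1_mhz = 400, sw_hz = 2000, td = 8192, seed = 7)
cfg$noise_sigma <- noise_sigma_for_snr(sys, cfg, 100)

fid  <- simulate_fid(sys, cfg)
spec <- fourier_transform(zero_fill(apodize_exponential(fid, 0.3)))
ph   <- auto_phase(spec)
cat(sprintf("auto_phase: ph0 = %.2f deg, ph1 = %.2f deg\n",
            ph$ph0_deg, ph$ph1_deg))
spec <- baseline_correct(phase_correct(spec, ph$ph0_deg, ph$ph1_deg,
                                       ph$pivot_ppm))

ranges <- detect_ranges(spec, min_snr = 5)
for (r in ranges)
  cat(sprintf("range %.3f..%.3f ppm  integral %.2f  signals: %s\n",
      r$from_ppm, r$to_ppm, r$absolute_integral,
      paste(sapply(r$signals, function(s)
        sprintf("%.2f ppm %s J=%s", s$delta_ppm, s$multiplicity,
                paste(round(s$j_hz, 1), collapse = "/"))), collapse = "; ")))
ranges <- set_relative_integrals(ranges, ref = 2, n_protons = 3)
cat(to_publication_string(spec, ranges), "\n")
```

This prints:

```
auto_phase: ph0 = 0.34 deg, ph1 = -1.12 deg
range 3.633..3.569 ppm  integral 4.89  signals: 3.60 ppm q J=7
range 1.231..1.167 ppm  integral 7.31  signals: 1.20 ppm t J=7
¹H NMR (400 MHz, simulated) δ 3.60 (q, J = 7.0 Hz, 2H), 1.20 (t, J = 7.0 Hz, 3H).
```

The simulated spectrum was already in phase, so `auto_phase()` returns
corrections near zero; the two detected ranges integrate 2:3 as built,
and the quartet/triplet are classified with J recovered at 7.0 Hz.

A thin command-line front end is installed as `nmrkit` (see
`?nmrkit_cli`): `nmrkit convert`, `nmrkit process`, `nmrkit ranges`,
`nmrkit grade`, `nmrkit exercise build`, `nmrkit simulate`.

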