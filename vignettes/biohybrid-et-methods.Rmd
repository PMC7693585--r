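---
title: "Models and methods: ultrafast electron transfer in photosensitizer-PpcA biohybrids"
author: "hemeET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeET)
```

# Scope

hemeET analyses photo-induced charge transfer between a covalently linked
Ru(II)(bpy)~3~ photosensitizer and the hemes of the triheme cytochrome PpcA:
transient-absorbance (TA) spectral corrections and kinetic fitting, Marcus
driving-force analysis, donor-acceptor distance statistics from labeled
coordinate trajectories, and Guinier/Nernst characterization fitters. A
synthetic-data generator with known ground truth stands in for raw
spectroscopic and simulation data, which are not publicly available for this
system; every empirical statement in this vignette is one the package's test
suite or acceptance script computes.

# The kinetic model

## Two-state sequential scheme

The preferred reading of the TA kinetics is the sequential chain
Ru\* $\xrightarrow{k_{CS}}$ [Ru$^{3+}$/heme$^-$] $\xrightarrow{k_{CR}}$
ground, with charge separation faster than recombination. The
charge-separated population is

$$B(t) = \frac{k_{CS}}{k_{CR}-k_{CS}}\left(e^{-k_{CS}t}-e^{-k_{CR}t}\right),
\qquad t \ge 0,$$

zero before time zero, and the measured heme-reduction trace is
$A\,B(t)$ convolved with a Gaussian instrument response. The convolution is
analytic: for a causal exponential,
$(g \otimes e^{-kt})(t) = \tfrac12 e^{k(\sigma^2 k/2 - u)}
\mathrm{erfc}\!\left(\frac{\sigma^2 k - u}{\sigma\sqrt2}\right)$ with
$u = t - t_0$. The equal-rate limit $k_{CS} = k_{CR} = k$ is handled by its
closed form $k\,t\,e^{-kt}$ (maximum at $t = 1/k$), not by numerical
perturbation.

Numerical stability: for large positive arguments the product
$e^{a}\,\mathrm{erfc}(b)$ is evaluated as
$e^{-u^2/2\sigma^2}\,\mathrm{erfcx}(b)$ (the identity $a - b^2 =
-u^2/2\sigma^2$), and erfcx itself switches to its asymptotic series beyond
$b = 20$, where a literal $e^{b^2}\mathrm{erfc}(b)$ overflows. This keeps the
model finite over nanosecond-scale delay grids ($|u|/\sigma \sim 10^6$).

## The swap degeneracy and the assignment rule

For all rate pairs, $k_{CR}\,B(t;k_{CS},k_{CR}) = k_{CS}\,B(t;k_{CR},k_{CS})$:
swapped constants give shape-identical signals up to an amplitude factor, so
a rise-and-decay trace alone cannot identify which constant is CS. The
package's convention is that `fitBiexponential(..., scheme = "two_state")`
reports the *faster* fitted constant as $\tau_{CS}$ — matching the physical
argument that the multi-state alternative (recombination faster than
separation) would imply recombination on a sub-instrument-response, even
femtosecond, timescale for the ultrafast constructs. Every fit carries a
`degenerate` flag, and `compareSchemes()` reports an explicit
identifiability verdict: on a clean two-state trace both schemes fit equally
well ("indistinguishable"), while a trace with a long-lived plateau
(heme-to-heme branch $k_{HH} > 0$, total reduced-heme population plateauing
at $k_{HH}/(k_{HH}+k_{CR})$) discriminates them by residual sum of squares.
When both schemes fit essentially perfectly (RSS below $10^{-9}$ of the
weighted signal power — numerically exact data), the verdict is
"indistinguishable" regardless of the meaningless RSS ratio.

## Fitting choices

Weighted Levenberg-Marquardt (minpack.lm) on log-scale time constants
(positivity by construction), with free amplitude and time zero:

* **weights** $1/\sigma^2$; when the trace has no uncertainty, $\sigma$ is
  the SD of the pre-pulse points (delay $\le$ $-1$ ps);
* **multi-start**: 8 log-spaced initializations spanning the post-pulse
  delay range, jittered with a fixed internal seed so fits are
  deterministic;
* **fit window** from $t_0 - 2\,\mathrm{IRF\ FWHM}$; the window is fixed
  before optimization and $t_0$ is bounded to a small neighbourhood
  ($\pm\max(10\,\mathrm{FWHM}, 10^{-3}\,t_{max})$) — a window that moved
  with the free $t_0$ would let the optimizer discard points;
* **guard**: traces whose peak is below $5\times$ the median uncertainty are
  rejected ("no detectable kinetic signal") rather than fitted;
* **errors** are 1$\sigma$ from the linearized covariance, delta-method
  transformed to the $\tau$ scale.

# The synthetic TA generator

`simulateTADataset()` builds
$\Delta A(t,\lambda) = A_{heme} S_{heme}(\lambda) B(t') +
A_{Ru} S_{Ru}(\lambda) P_{Ru^*}(t') + A_{ES} S_{ES}(\lambda) e^{-t'/\tau_{ES}}
+ \mathrm{solvent}(t',\lambda) + \mathrm{noise}$, with $t' = t -
t_0(\lambda)$. Parameter choices, each configurable:

| parameter | default | rationale |
|---|---|---|
| heme band | Gaussian, 553 nm, $\sigma$ = 3 nm | sharp reduced-heme alpha band; effectively zero at the 541 nm reference |
| Ru\*/Ru(III) band | Gaussian, 650 nm, $\sigma$ = 40 nm | much broader excited-state feature |
| heme excited-state band | Gaussian, 548 nm, $\sigma$ = 8 nm, $\tau$ = 1 ps | overlaps the 541-553 nm region so that the reference subtraction is genuinely exercised |
| IRF FWHM | 0.17 ps | cross-correlation of two 120 fs pulses |
| chirp | quadratic in $(\lambda - 625)$ nm, ~0.3 ps sweep over 500-750 nm | typical continuum-probe sweep; no magnitude is published for this setup |
| solvent artifact | Gaussian + first derivative at $t_0(\lambda)$, zero outside 3 FWHM | cross-phase modulation confined to pulse overlap |
| noise | i.i.d. Gaussian, 0.02 mOD (2% of the heme band) | matches the stated recovery protocol; no correlated baseline drift |
| grids | 500-750 nm in 2 nm steps; $-5$ to $+3000$ ps, linear then log-spaced | probe range and delay span are the package's choice, not published facts |

Pre-pulse rows (delay $\le -1$ ps) contain only noise by construction, which
the `prepulseCheck()` z-test verifies on every generated dataset.

What the generator does **not** emulate: correlated (1/f) baseline drift,
pump scatter, anisotropy/polarization effects, shot-to-shot statistics, and
wavelength-dependent noise. Passing recovery tests therefore demonstrate the
correctness of the correction-and-fit chain under idealized noise, not
robustness to every instrumental pathology of real data.

# Spectral corrections

**Chirp estimation** (`estimateChirp`) locates, per wavelength column with
peak signal above $8\times$ the pre-pulse noise, the half-rise delay of
$|\Delta A|$ and least-squares fits a polynomial (degree $\le 2$) of
$t_0(\lambda)$. Columns inside the sharp heme band (545-560 nm) are
excluded: that band rises with the charge-separation kinetics rather than
the instrument response, so its half-rise is systematically late; outside
it, the rise is IRF-limited and the half-rise sits at $t_0$ to within a few
fs. With the coherent solvent artifact present, artifact-dominated columns
bias the onset early by a fraction of the IRF width; the residual sweep
error (~0.1 ps worst case) is absorbed by the free $t_0$ of the kinetic fit
and leaves the recovered time constants within their tolerance. Flat data
raise an explicit "no onset detectable" error, never silent zeros.

**Dechirp** re-interpolates each column onto the common grid shifted by
$-t_0(\lambda)$ (linear interpolation); edge points needing extrapolation
are held at the boundary value and counted in the provenance string. Linear
interpolation resolves the IRF rise only if the delay step is well below the
IRF width — on a 0.05 ps grid the double-interpolation error reaches ~2% of
the band amplitude near time zero, on a 0.01 ps grid it is negligible; the
package's tests use the finer grid for identity checks and the default
mixed linear/log grid for recovery, where the error is irrelevant to the
fitted constants.

**Reference subtraction** (`subtractReference`) removes the heme
excited-state component using a generated wild-type-like measurement (no
charge separation, same artifact structure, independent noise). The scale is
least-squares fitted over a wavelength window that always excludes 545-560
nm (protecting the heme-reduction band); the recovery protocols state the
window 500-540 nm, the blue flank where the broad Ru excited-state band —
present in the labeled sample but not the reference — is negligible, so it
cannot inflate the scale. Reference noise attenuates the fitted scale
slightly (errors-in-variables); at 2% noise the effect on the recovered
time constants is below 1%.

**Trace extraction** interpolates $\Delta A$ at 553 and 541 nm linearly
between neighbouring grid wavelengths (grids need not contain the exact
wavelengths); the difference nulls spectrally flat components exactly.

# Marcus analysis

$k = A\exp(-(\Delta G+\lambda)^2/4\lambda k_BT)$ with $\lambda = 0.85$ eV
and $T = 298.15$ K ($k_BT = 0.025693$ eV) throughout. The electronic
prefactor is a free scale: every quantity of interest is a rate ratio, so no
coupling model is implemented. Sign convention: positive shifts move
$\Delta G$ uphill (toward slow-down at or past the apex).

At the apex, a 40 mV shift changes the rate by the factor
$\exp(-0.04^2/4\lambda k_BT) = 0.98185$ — under 2%. The shift for a
1000-fold slow-down from the apex is
$\sqrt{4\lambda k_BT\ln 1000} = 0.777$ eV; a published rounding of "about
600 mV" for the same fold is consistent instead with a driving force
displaced ~0.2 eV uphill of the apex, where the closed-form quadratic root
gives 0.602 eV. The package exposes $\Delta G$ explicitly and the test suite
documents both readings rather than guessing which the original analysis
used.

# Trajectory geometry

## Generator

`simulateTrajectory()` draws a per-frame target minimal distance from a
mixture of Gaussians (modes, weights, jitter; hard-sphere floor 2.0 Å) and
realizes it *exactly* by rigid translation of the photosensitizer group
along the interface axis: template geometries place the closest aromatic
atom of each group on that axis with all other atoms strictly behind it, so
the geometric minimum equals the sampled target to machine precision, and a
random rigid rotation of the photosensitizer about the axis adds
conformational variety without changing the minimum. The first
`equilibrationFrames` frames sit at a displaced distance, emulating
conformations present only at equilibration. Templates carry deliberate
non-aromatic decorations (Fe, Ru, methyl carbons) so the aromatic-selection
logic is exercised; frame spacing (default 10 ps) is metadata only — no
actual dynamics, autocorrelation, or force-field physics is simulated, so
tests of the analysis stack are exact but say nothing about sampling error
in real MD.

## Analysis

"Aromatic atoms" are heme macrocycle C/N and bipyridine ring C/N;
substituents, thioether carbons, Fe and Ru are excluded (encoded in the
group map; the PDB convention is chain H/R plus name prefixes, documented in
`readTrajectory`). Distances are histogrammed on 0.2 Å bins aligned at 0.0,
frequencies in percent of counted frames; modes are local maxima with a
prominence (height above the higher flanking valley) of at least 2
percentage points — low enough to resolve equal-weight subpopulations
separated by ~1 Å at 0.1 Å jitter, high enough to ignore single-bin noise on
10^4-frame histograms. A mode that falls on a bin edge (6.6 Å does) is
reported as the center of whichever adjacent bin wins, i.e. within half a
bin of truth. Equilibration exclusion defaults to the generator-recorded
frame count when present, else the first 10% of frames, and is always
configurable and reported. The van der Waals contact cutoff defaults to
4.0 Å (typical aromatic-carbon contact; the concept, not the number, is
fixed by the physics).

`minDaDistance` provides a brute-force $O(nm)$ reference and an exact
spatial-hash acceleration (cell size set to a cheap upper bound on the
minimum, so the true nearest neighbour is always inside the searched cells);
the test suite asserts bit-identical results. `perAtomMap` localizes which
bipyridine atoms maintain contact and exposes conformational jumps as steps
along the frame axis.

# Characterization fitters

**Guinier** (`guinierFit`): weighted linear fit of $\ln I$ vs $q^2$, window
chosen iteratively under the standard rule $q_{max}R_g \le 1.3$ (the source
analysis does not state its window). Slope $\ge 0$ and window collapse are
explicit errors. The low-q upturn flag (mean standardized residual of the
lowest decile above $3$) implements the elongation diagnostic used to argue
that protruding photosensitizers make a construct less globular.

**Nernst** (`nernstFit`): equal-weight sum of $n$ one-electron terms at
298.15 K ($RT/F = 25.693$ mV) — equal heme extinction assumed; mediator and
electrode details are experimental and not modeled. Individual heme labels
are not identifiable, so per-heme midpoints are reported sorted ascending;
the *apparent* midpoint (fitted fraction = 0.5, by root bracketing) is the
robust observable, and shifting all hemes by $\delta$ shifts it by exactly
$\delta$ in the noiseless limit (tested to $10^{-6}$ mV).

# Reproducibility and problem sizes

All randomness is seed-pinned: generator configs carry a seed, the fit's
multi-start jitter uses a fixed internal seed, and `runPipeline()` writes a
manifest with seeds and MD5 sums that reruns reproduce hash-for-hash. The
recovery protocols use problem sizes chosen to bound the Monte-Carlo error
of a median well below the tolerances they are checked against: 20 seeds for
kinetic recovery at 2% noise (median $\tau_{CS}$ within ±15%), 50 seeds for
mode recovery on 10^4-frame histograms and for the ±2 mV titration-shift
check, 25 seeds per $R_g$ for the 2% Guinier bound, and 30,000-frame
trajectories for the single-trajectory mode reports.

# Known limitations

* The chirp estimator assumes a prompt (IRF-limited) rise outside the heme
  band; systems whose entire probe window rises with slow kinetics would
  need the estimator's window restricted to a coherent-artifact region.
* The reference-subtraction model assumes the contaminant spectrum is
  identical between sample and reference up to one global scale.
* The bi-exponential fit assumes a single kinetically homogeneous
  population; distributed kinetics (a distribution of donor-acceptor
  geometries) would bias both constants.
* Trajectory analysis treats frames as independent; no statistical
  correction for MD autocorrelation is attempted.
* The multi-state scheme implements one proximal-to-distal branch; longer
  heme-to-heme relays would need the chain extended.
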