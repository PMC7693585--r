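# hemeET

Ultrafast photoinduced electron transfer (ET) analysis for
photosensitizer–multiheme cytochrome biohybrids.

## The problem

Covalently linking a Ru(II)(bpy)<sub>3</sub> photosensitizer to engineered
cysteines of PpcA — a 71-residue triheme *c*-type cytochrome from *Geobacter
sulfurreducens* — creates a biohybrid in which a 460 nm pump pulse can inject
an electron from the photo-excited Ru into the heme chain within picoseconds.
Whether that injection is ultrafast (picoseconds) or slow (tens of
nanoseconds) depends on the attachment site: constructs whose photosensitizer
sits sterically locked against a heme show charge separation as fast as
2.3 ps, while mobile, protruding photosensitizers are roughly a thousand
times slower.

Quantifying this requires a chain of computational steps that this package
implements as tested, reusable functions for anyone analysing pump–probe
transient-absorbance (TA) data of such constructs:

* **TA spectral corrections** — probe chirp (wavelength-dependent time zero),
  coherent solvent artifact, and subtraction of heme excited-state dynamics
  via a scaled reference measurement;
* **kinetic trace extraction** — the heme-reduction observable
  ΔΔA(t) = ΔA(553 nm) − ΔA(541 nm);
* **sequential kinetic-scheme fitting** — IRF-convolved two-state
  (CS → CR) and multi-state (CR faster than CS, optional heme-to-heme
  branch) schemes, with the rate-swap degeneracy made explicit;
* **Marcus-theory driving-force analysis** — how midpoint-potential
  perturbations translate into ET-rate fold-changes;
* **MD-trajectory geometry** — minimal donor–acceptor aromatic-atom
  distance distributions (0.2 Å bins), per-atom shortest-distance maps, and
  van der Waals contact fractions from labeled multi-model PDB/XYZ
  trajectories;
* **characterization QC** — Guinier fits of small-angle scattering profiles
  and multi-heme Nernst titration fits.

Because no raw spectroscopic or simulation data are publicly deposited for
this system, the package ships a first-class **synthetic-data generator**
whose ground truth makes every downstream stage testable: TA matrices with
known kinetics, chirp and artifacts; trajectories whose per-frame minimal
distances follow a known mixture of Gaussians realized exactly in geometry;
ideal Guinier profiles; and multi-heme Nernst titration curves.

## The models

**Two-state sequential scheme.** After excitation, Ru\* transfers an electron
to the nearest heme with rate k<sub>CS</sub>; the charge-separated state
recombines with rate k<sub>CR</sub>. The reduced-heme population is

B(t) = k<sub>CS</sub>/(k<sub>CR</sub> − k<sub>CS</sub>) ·
(e<sup>−k<sub>CS</sub>t</sup> − e<sup>−k<sub>CR</sub>t</sup>),

convolved analytically with a Gaussian IRF (default FWHM 0.17 ps, the
cross-correlation of two 120 fs pulses). Because
k<sub>CR</sub>·B(t; k<sub>CS</sub>, k<sub>CR</sub>) =
k<sub>CS</sub>·B(t; k<sub>CR</sub>, k<sub>CS</sub>), the shape alone cannot
say which constant is which; `fitBiexponential()` reports the faster constant
as τ<sub>CS</sub> (the preferred two-state reading) and flags the degeneracy,
and `compareSchemes()` makes the two-state/multi-state ambiguity explicit.

**Marcus analysis.** Nonadiabatic ET rate
k ∝ exp(−(ΔG + λ)²/4λk<sub>B</sub>T) with λ = 0.85 eV. At the apex
(ΔG = −λ) a 40 mV potential shift changes the rate by under 2%, while a
1000-fold slow-down needs ~0.78 eV from the apex (~0.60 eV if ΔG sits 0.2 eV
off-apex) — the energetic argument that distance/coupling, not driving
force, controls the thousand-fold rate span.

**Distance statistics.** The predictor of sub-nanosecond ET is the minimal
distance between aromatic atoms of the photosensitizer (bipyridine rings)
and of the heme macrocycles, binned at 0.2 Å over the trajectory.

## Worked example

Simulate a K52C-like dataset (τ<sub>CS</sub> = 2.3 ps, τ<sub>CR</sub> =
5.9 ps, 2% noise, chirp + solvent + heme excited-state artifacts), run the
correction chain, and fit the two-state scheme:

```r
library(hemeET)

cfg <- taGeneratorConfig(tauCS = 2.3, tauCR = 5.9, seed = 5L)
ds  <- simulateTADataset(cfg)
ref <- simulateReferenceDataset(cfg)      # heme excited state only

est <- estimateChirp(ds)                  # t0(lambda) from signal onsets
ds  <- dechirp(ds, est$coeffs)
ref <- dechirp(ref, est$coeffs)
ds  <- subtractReference(ds, ref, scale = "fit", fitWindow = c(500, 540))

fit <- fitBiexponential(extractTrace(ds), "two_state", irfFWHM = 0.17)
fit
#> KineticFit [two_state]: tauCS = 2.36 +/- 0.29 ps, tauCR = 5.64 +/- 0.63 ps
#>   amplitude = 0.974 mOD, t0 = 0.027 ps, RSS = 141.6 (n = 87)
#>   note: rate-swap degeneracy — assignment follows the two-state convention
```

A single noisy dataset recovers the generator constants to ~3%; the
acceptance protocol below uses the median over 20 seeds. The Marcus and
trajectory stages:

```r
mp <- marcusParams("apex", lambda = 0.85)
foldChangeForShift(0.04, mp)    # 0.9818506  — a 40 mV shift: < 2% effect
shiftForFoldChange(1000, mp)    # 0.7768046  eV for a 1000-fold slow-down

tr <- simulateTrajectory(trajectoryGeneratorConfig(
  nFrames = 30000L, modeDistances = 6.6, jitterSigma = 0.15, seed = 7L))
distanceDistribution(tr)
#> DistanceDistribution: 30000 frames, 37 bins of 0.2 A
#>   modes (A): 6.7
```

The mode bin center 6.7 Å recovers the 6.6 Å ground truth to within one
0.2 Å bin (6.6 Å falls exactly on a bin edge). `runPipeline()` ties all
stages together from a JSON config and writes a seed-pinned, hash-stamped
manifest; rerunning the same config reproduces every output bit-for-bit.

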