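---
title: "Models and methods behind tnckit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnckit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnckit)
```

tnckit is a desk-scale analysis chain for multi-scale studies of cardiac
troponin C (cTnC) variants such as the hypertrophic-cardiomyopathy mutation
C84Y. It covers four layers of the problem: contractile mechanics of
permeabilized cardiac muscle preparations (force–pCa and tension
redevelopment), conformational-ensemble analytics of the cTnC N-domain,
local mutational frustration of residue contacts, and the solution
observables (NMR, CD, SAXS) used to characterize the protein in vitro.
Every analysis stage has a matching seeded synthetic-data generator, so the
whole chain is testable without any external data. This vignette records
the models, the tunable parameters that matter, and the design decisions
taken where the methodology was genuinely open.

## The three-state contraction model

Contractile data are interpreted through a minimal linear scheme over the
states of a thin-filament regulatory unit and its cross-bridges:

$$ B \overset{k_{ON}\,\alpha(\mathrm{pCa})}{\underset{k_{OFF}}{\rightleftharpoons}} C
   \overset{f}{\underset{g}{\rightleftharpoons}} M $$

* **B** — blocked (Ca$^{2+}$-free regulatory unit, no cross-bridge),
* **C** — permissive but detached,
* **M** — attached, force-generating.

All four rate constants ($k_{ON}$, $k_{OFF}$, $f$, $g$) are in s$^{-1}$.
Ca$^{2+}$ enters only the $B \to C$ transition through a Hill occupancy of
the regulatory site II,
$\alpha(\mathrm{pCa}) = 1/(1 + 10^{\,n_{act}(\mathrm{pCa} - \mathrm{pCa}_{50,act})})$,
and isometric force is proportional to the occupancy of $M$, normalized to
its value at saturating Ca$^{2+}$ (pCa 4.0). This is the smallest scheme
consistent with the four named rate constants and with the standard
interpretation of the force–kTR relation (regulatory-unit dynamics at low
force, cross-bridge turnover at high force). Cooperative coupling between
neighboring regulatory units and sarcomere-length dependence are
deliberately out of scope.

The steady state is solved analytically from the chain balance
($B/C = k_{OFF}/(k_{ON}\alpha)$, $M/C = f/g$); a long-time ODE integration
(`deSolve`) serves as the independent oracle in the test suite, and the two
agree to $10^{-8}$ on randomized parameter sets.

### kTR

The release–restretch maneuver is modeled as instantaneous cross-bridge
detachment with unchanged regulatory state: the system restarts from
$M = 0$ with $B$ and $C$ renormalized from their steady-state ratio.
`ktr()` reports either

* `eigen` — the smallest-magnitude nonzero eigenvalue of the generator
  (the slow relaxation mode), or
* `simulate` — an explicit integration with a mono-exponential fit over
  the 5–95% force-rise window (the window avoids lag contamination).

The two agree within 5% whenever the two relaxation modes are separated by
at least a factor of three; the simulated variant is the physically
faithful one when regulatory and cross-bridge timescales mix. The
classical two-state limit $k_{TR} \to f + g$ at saturating Ca$^{2+}$
requires not only fast regulation but a mostly-on regulatory equilibrium
($k_{ON}\alpha \gg k_{OFF}$); otherwise the limit is
$f\,p_C + g$ with $p_C = k_{ON}\alpha/(k_{ON}\alpha + k_{OFF}) < 1$. Tests
exercise the limit at $k_{ON}/k_{OFF} = 100$.

A caveat worth recording: in this non-cooperative scheme the post-slack
regulatory distribution equals the (renormalized) steady-state one, so
slowing the regulatory off-rate cannot elevate the low-force end of the
force–kTR relation — there is no "still-on" regulatory-unit excess for
cross-bridges to reattach into. That elevation is a prediction of
cooperative regulatory-unit models in which strong cross-bridges feed back
on unit activation; reproducing it would require exactly the cooperativity
this package excludes. The genotype-level pattern that is reproduced and
tested is the more curvilinear force–kTR relation (lowered low-force end,
preserved maxima) of a variant with faster attachment and slower
detachment.

### Fitting

`fit_hill()` supports 2-, 3- and 4-parameter Hill regressions
($F_{min} = 0, F_{max} = 1$ fixed; $F_{max}$ free; both free) via
multi-start Levenberg–Marquardt (`minpack.lm`), with standard errors from
the local linearization. `fit_three_state()` jointly fits the force–pCa
and kTR–pCa curves over $(f, g, k_{OFF})$ with $k_{ON}$ held fixed (its
default value is an argument, never hard-coded), residuals normalized by
each curve's data SD so the two observables contribute comparably, rates
log-parameterized for positivity, and eight seeded starts with best-RSS
selection for reproducibility. On noiseless synthetic data the fit
recovers the generating rates to better than 0.1%; at 3% multiplicative
noise with 6 replicates the median relative error is well under 15%.

`perturbation_envelope()` rescales all four rates jointly by
$1 \pm 1\%/3\%$ and retraces the force–kTR locus; joint scaling leaves the
steady state untouched and scales kTR linearly (rate-equation
homogeneity), which the tests assert exactly.

## Ensemble geometry

Conformational ensembles travel as multi-model PDB (one frame == one
MODEL; residue numbers are author numbering, cTnC 1–161, never
renumbered). Parsing and writing are delegated to `bio3d`.

**AB interhelical angle.** Helix A is residues 14–25, helix B residues
38–47 (Cα only). The helix axis is built from the bisector construction:
at each interior Cα the bisector of the two chain bonds points radially at
the local helix axis, and the cross product of consecutive bisectors is
parallel to the axis — exactly so for an ideal helix. The axis is the
first principal direction (SVD) of these local estimates, oriented N→C. A
principal direction of the raw Cα cloud was considered and rejected: for
10–12-residue helices the non-integer number of helical turns biases that
axis by several degrees, which is larger than the effects of interest. The
angle is the arccosine of the oriented-axis dot product, reported in
[0°, 180°] so parallel and antiparallel packings are distinguished.

**Open-state fraction.** Strictly `angle < 110°`, with a seeded bootstrap
CI over models and optional per-replicate fractions (both pooled and
per-replicate summaries are available, since either convention is
defensible).

**RMSF.** Models are least-squares superposed (Kabsch, via
`bio3d::fit.xyz`) onto model 1 using backbone atoms of residues 1–100,
then per-residue Cα fluctuations are computed. The two-point closed form
and rigid-rotation invariance are asserted in tests.

**Contact maps.** Two definitions: any heavy-atom pair within 7 Å with
sequence separation ≥ 6 ("atom–atom" is read as heavy atoms, hydrogens
excluded — configurable in spirit by the mode argument); and Cα within
5 Å with separation ≥ 3 to exclude trivial chain neighbours (the 5 Å Cα
convention is used for frustration maps). Both are verified against an
$O(N^2)$ brute-force oracle on randomized toy structures.

**PCA and free-energy landscapes.** Cα PCA of the core region (residues
4–85 by default) after superposition, eigen-decomposition of the
coordinate covariance, centered projections. The 1D landscape is
$\Delta G = -k_BT \ln(P/P_{max})$ over 50 bins by default, reported in kT
(temperature only annotates; no unit conversion is baked in), with empty
bins masked as `NA` rather than given zero energy — pseudo-counts would
fabricate barriers.

## Local mutational frustration

For each contact $(i, j)$ the native pair energy is compared with decoys
in which both residue identities are independently resampled from the
chain's own composition:

$$ F_{ij} = \frac{\langle E_{decoy}\rangle - E_{native}}{\mathrm{SD}(E_{decoy})} $$

Positive $F$ means the native pair is more favorable than typical decoys
(minimally frustrated); classification uses the conventional cuts
$F \ge 0.78$ (minimal) and $F \le -1$ (high), both configurable. As a
z-score, $F$ is invariant under affine rescaling of the potential, and the
Monte-Carlo estimate converges to exhaustive enumeration on small
alphabets — both are asserted numerically. Default 1000 decoys per
contact, bit-reproducible under a fixed seed.

This index is deliberately a simplified stand-in for the full
AWSEM-based frustratometer, which adds distance- and density-dependent
energy terms; it reproduces qualitative frustration patterns (e.g. a
minimally frustrated hydrophobic core versus a frustrated surface) at desk
scale, not the numerical indices of the webserver. The default potential
is a hydrophobicity-transfer matrix, $E(a,b) = -(h_a + h_b)/4$ on
Kyte–Doolittle hydropathies: it carries the dominant signal of
knowledge-based contact potentials (hydrophobic pairing is favorable) and
any 20×20 symmetric `stat_potential()` can be swapped in.
`compare_states()` tabulates per-contact class transitions across labeled
conformational states (closed / primed / open).

## NMR observables

* **CSP** — $\sqrt{(\Delta\delta_H)^2 + 0.1(\Delta\delta_N)^2}$ in ppm;
  residues missing from either peak list are reported, never imputed.
  Outlier flagging is strictly `> mean + k·SD` with the population
  (divide-by-$n$) SD, computed over a stated residue subset.
* **Temperature coefficients** — OLS slope of the amide $^1$H shift
  (converted to ppb) against temperature in °C; constant shifts get slope
  0 with $R^2$ reported as 0 and a flag.
* **Relaxation rates** — per-residue nonlinear fit of
  $I(t) = I_0 e^{-Rt}$ seeded by log-linear regression; flat decays are
  resolved analytically. R2/R1 profiling computes per-domain means and
  SDs with the N/C split at the D/E linker (default boundary residue 90).
* **CPMG** — $R_{2,eff} = (1/T)\ln(I_0/I_{CPMG})$. The literal formula
  with a leading minus sign yields negative rates for attenuated signal;
  the package uses the physically positive convention and offers
  `as_printed = TRUE` for the literal sign. Exchange-regime
  classification follows the two-frequency rule: *fast* when the 50 and
  1000 Hz values are nearly identical (within
  $\varepsilon = \max(2\,\mathrm{s}^{-1}, 10\%$ of the cohort mean$)$) yet
  elevated > 1 SD above the cohort average; *intermediate* when the
  dispersion decays by more than $\varepsilon$ and the 50 Hz value is
  similarly elevated.
* **Titration Kd** — global fit of the 1:1 quadratic bound-fraction
  isotherm with one shared $K_d$ and per-residue saturation CSP (profiled
  linearly), matching a single reported affinity per peptide; warns when
  the titration never approaches saturation.

## CD and SAXS descriptors

Mean residue ellipticity is
$[\theta]_{MRE} = \theta \cdot 0.1\,(MW/n)/(l \cdot c)$; the denominator
groups path length and concentration, the only dimensionally consistent
reading of the conventional formula. Thermal unfolding is fit as a linear
baseline plus one or two Boltzmann sigmoids
$A_i/(1 + e^{(T_{m,i} - T)/k_i})$ (van 't Hoff $\Delta H$ parameterization
is intentionally omitted since only $T_m$ is interpreted), multi-start
over a $T_m$ grid. Model selection between 1 and 2 transitions uses BIC:
the extra transition costs three parameters, and an AIC penalty of 2 per
parameter would admit a spurious second transition on pure noise roughly
11% of the time ($P(\chi^2_3 > 6)$), while the $\log n$ BIC penalty keeps
the false-preference rate negligible at thermogram-sized $n$ (~350
points); both scores are reported on the fit object.

Kratky transforms are exact elementwise $s^2 I(s)$; the dimensionless
variant $( sR_g, (sR_g)^2 I/I_0 )$ peaks at $(\sqrt3, 3/e)$ for a compact
globule, which doubles as a self-check of the Guinier helper
($\ln I$ vs $s^2$ regression with the window $sR_g \le 1.3$ enforced
iteratively).

## Synthetic data: what it emulates, and what it does not

Every generator records its ground-truth parameters in the output and is a
pure function of (spec, seed); the parameter-recovery suite requires every
estimator to invert its generator to ≤ 0.1% on noiseless input. The
default study conditions are:

* **Force–pCa** — genotype parameter maps pCa50 = 5.56 (WT) and 5.72
  (C84Y) with a common Hill coefficient of 2.5 (murine preparations
  typically fall between 2 and 3, and the genotypes did not differ in
  cooperativity), $F_{min} = 0$, $F_{max} = 1$, additive Gaussian noise of
  SD 0.04 on normalized force (S.E.M.-scale for n = 5–6 preparations), 6
  replicates, on a 14-point pCa 7.0–4.0 grid densified around the
  midpoint.
* **3-state mechanics** — model-exact force and kTR curves with
  multiplicative Gaussian noise (default 3%).
* **Two-helix ensembles** — ideal α-helical Cα traces (rise 1.5 Å/residue,
  radius 2.3 Å, 100°/residue — textbook values) labeled with the helix
  A/B residue numbers, with the generating angle of each model drawn from
  a prescribed (possibly bimodal) mixture and stored as ground truth.
* **Titrations** — the 1:1 isotherm at the conventional ligand series
  (0, 15, 40, 70, 120, 150, 200 μM); the displacement is split
  $\Delta\delta_H = \sqrt{0.7}\,d$, $\Delta\delta_N = \sqrt{3}\,d$ so the
  CSP combination recovers the total exactly (a generator convention — no
  per-nucleus split is ever reported for real data).
* **Relaxation/CPMG** — mono-exponential decays on the standard R1/R2
  delay lists; dispersion from the fast-exchange (Luz–Meiboom) closed
  form $R_{2,eff} = R_2^0 + R_{ex}(1 - (4\nu/k_{ex})\tanh(k_{ex}/4\nu))$,
  which suffices to exercise the qualitative two-frequency classifier
  (Carver–Richards fitting is out of scope).
* **Melts and SAXS** — sigmoid-plus-baseline thermograms on the 20–90 °C,
  0.2 °C grid; SAXS as a Guinier-globule/Debye-chain mixture, whose
  folded and unfolded limits give bell-shaped and plateau Kratky curves
  respectively.

These generators reproduce the statistical structure the analyses assume —
not the physics of real data. Passing recovery tests demonstrates that the
estimators are correct and well-conditioned under the stated noise models;
it says nothing about force-field accuracy, spin physics beyond the closed
forms, scattering systematics, or biological variability between
preparations.

## Numerical choices and problem sizes

Optimizers are bounded/log-parameterized Levenberg–Marquardt with fixed
multi-start seeds throughout; ties in multi-start selection resolve to the
first-best RSS. Degenerate inputs are contracts, not surprises: zero decoy
variance, empty Guinier windows, non-decaying intensities, all-zero rate
matrices and inconsistent multi-model atom rosters all raise informative
errors (tested). The test suite runs at deliberately desk-scale problem
sizes — e.g. 100 random parameter sets for the steady-state oracle, 2000
models for bimodal-angle recovery, 12 noisy seeds for three-state recovery
and 100 seeds for melt model selection — chosen so the whole suite
completes in about a minute while keeping Monte-Carlo assertions inside
3-sigma bands of their analytic expectations.

## Known limitations

* The three-state scheme is non-cooperative; force–kTR phenomena that
  require regulatory-unit coupling (see the kTR caveat above) are outside
  its reach, as are sarcomere-length effects and mechanistic
  sinusoidal-stiffness modeling.
* The frustration index is contact-potential based; it does not reproduce
  AWSEM frustratometer values, electrostatics, or single-residue and
  configurational variants.
* NMR analysis stops at observables: no spectral processing, peak
  picking, assignment, Carver–Richards global fits, or model-free
  analysis (rotational correlation times are not estimated).
* SAXS handling covers Kratky/Guinier descriptors only — no $P(r)$
  inversion or ensemble modeling; CD handling stops at $T_m$ fitting, with
  no secondary-structure deconvolution.
* Coordinate I/O is single-chain-oriented multi-model PDB; mmCIF and
  binary trajectory formats are not supported.
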