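---
title: "Vessel-length-based FFR simulation: model, assumptions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-length-based FFR simulation: model, assumptions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octffr)
```

## The problem

Fractional flow reserve (FFR) — the ratio of pressure distal to a coronary
stenosis to aortic pressure under maximal (hyperemic) vasodilation — is the
reference index for deciding whether a lesion is hemodynamically
significant (FFR ≤ 0.8). Computing FFR from intravascular imaging requires
two things: an accurate lumen geometry of the imaged segment (which OCT
pullbacks provide at sub-millimetre pitch), and outlet boundary conditions
describing everything downstream of that segment — arterioles, capillaries,
veins — which no intravascular image can see.

`octffr` implements a vessel-length route to those boundary conditions.
The key observation is physiological: a longer epicardial vessel subtends
more myocardium, induces more resting flow, and therefore presents less
flow resistance. Territory-level resistances can thus be calibrated from
summed vessel lengths measured on an ordinary angiogram, with no
ventricular muscle-mass imaging. The imaged segment itself is resolved
spatially and coupled to a lumped circuit of the microcirculation.

## Flow split and resistance calibration

With `l_LAD`, `l_LCX` and the two RCA sub-lengths (RV- and LV-feeding)
measured above a 1 mm diameter cutoff, resting flow divides as

```
Q_LAD : Q_LCX : Q_RCA = l_LAD : l_LCX : l_RCA,eff
```

where the RV-feeding RCA length is down-weighted by `alpha`, the LV-to-RV
muscle volume ratio (default 3.46, the composite clinical value; the
observed inter-subject band is about ±30%, i.e. 2.42–4.5). Two forms of
the effective RCA length are provided behind `rca_length_variant`:

* `additive` (default): `l_rv / alpha + l_lv`. This is the form whose
  single-territory limits are physiologic (no RV vessels → `l_lv`), and it
  produces territory splits on the ~30/30/40 scale seen clinically.
* `as_printed`: the harmonic combination `1 / (alpha/l_rv + 1/l_lv)`,
  retained for fidelity with the original formulation. For typical lengths
  it yields effective RCA lengths an order of magnitude too small (and it
  degenerates when either sub-length is zero, which the package reports as
  an error rather than returning the misleading limit).

Total resting coronary flow is taken as 4% of cardiac output
(`hr × stroke_volume`), the perfusion pressure as the cuff-estimated mean
aortic pressure (`DBP + (SBP − DBP)/3`) minus a fixed 5 mmHg right-atrial
pressure, giving each territory resistance as `ΔP / (fraction × Q_cor)`.

## The resistance amplification factor

The imaged segment usually sits distal to side branches. Under the
radius–flow scaling law `Q = m·r^k` (k = 2 by default, reflecting
cross-sectional-area-proportional flow; 2–3 admissible) and flow
conservation at the bifurcations, the fraction of parent flow reaching the
segment is

```
AMP_R = 1 − Σ_i (r_di / r_p)^k,        0 < AMP_R ≤ 1
```

and the total resistance distal to the segment outlet is `R_p / AMP_R`.
The proportionality constant `m` cancels. A configuration whose daughter
term reaches 1 would starve the segment entirely and is rejected as
non-physical.

## The distal network

`R_ROI` is distributed over three series RC compartments — arterioles
(`coa`), capillaries (`coc`), veins (`cov`) — in proportions 0.32/0.52/0.16
with compliances 0.01/0.02/0.05 mL/mmHg. These proportions and compliances
are conventional coronary lumped-model values, exposed in configuration;
they are not measurable from the imaging inputs. The arteriolar and
capillary compliances are referenced to the intramyocardial pressure
`P_imp = γ·P_LV` (γ = 0.75), modelling systolic compression of intramural
vessels; the venous compliance is referenced to ground. A collateral
resistor (default 5 × `R_ROI`) from the aorta switches in when the
arteriolar node falls below 30 mmHg, mimicking recruitment of collateral
supply in severe lesions.

One wiring choice deserves emphasis because the three resistor labels are
one position offset from the nodes they connect: the segment outlet feeds
node `coa` directly, `r_coc` connects `coa → coc`, `r_cov` connects
`coc → cov`, and the terminal venous-to-atrium resistor is `r_coa`. This
keeps the series chain exactly equal to `R_ROI`, which is what the
resting-flow calibration demands — any other closure would silently break
the 4%-of-cardiac-output rule. The closed-form steady state
`p_coa = p_ra + q·R_ROI` is tested against this wiring.

Hyperemia multiplies the three compartment resistances by 0.25 (adenosine
steady-state), leaving compliances, γ and the collateral resistance
unchanged. Resistances are constant within a simulation: time-varying
arterial resistance is minimized at hyperemia and is not modelled.

## The imaged segment: a quasi-1D solver

The segment solver is deliberately reduced-order: a cross-section-averaged
quasi-steady model in which the pressure drop obeys

```
Δp = a_v·q + a_t·q·|q|
a_v = ∫ 128 μ / (π D(s)^4) ds          (Poiseuille, trapezoidal)
a_t = k_t·ρ/2·(1/A_min − 1/A_ref)^2    (post-stenotic separation loss)
```

with `k_t = 1.52`, a standard empirical expansion-loss constant, and
`A_ref` the proximal reference area. Viscosity comes from the Einstein
dilute-suspension model `μ = μ_plasma (1 + 2.5 HCT)` (plasma 1.2 mPa·s,
density 1060 kg/m³). Flow is assumed laminar; the solver warns when the
throat Reynolds number exceeds 2000. Axial pressure is reconstructed by
distributing the viscous drop along the local Poiseuille integrand and
placing the separation drop at the minimal-area frame — the spatial
attribution inside the throat is a convention of this package, chosen so
the boundary values are exact and the profile is monotone for forward
flow.

This solver preserves every coupling-relevant quantity (outlet flow,
distal pressure) and is analytically verifiable: the uniform-tube limit is
tested against the Poiseuille closed form and the whole coupled pipeline
against a two-resistor divider. The coupling and network layers are
solver-agnostic by contract — anything mapping
(geometry, p_in, p_out) → (q, p(s)) can be slotted in, including a full 3D
Navier–Stokes model. Fluid inertia inside the segment is neglected at each
time step (quasi-steady); unsteadiness enters through the network
capacitors and the time-varying boundary pressures.

## Driving waveforms

The inputs are clinical scalars, not pressure traces, so waveform shapes
are constructed: aortic pressure rises from DBP to SBP as `sin²` over a
systolic fraction of 0.35 of the cycle and stays at DBP in diastole (the
`sin²` envelope meets DBP continuously at end-systole); LV pressure is
`SBP·sin²` in systole with an 8 mmHg diastolic baseline. All shape
parameters are configurable; none of them is identifiable from the input
data, and FFR — a ratio of cycle means — is insensitive to the details at
the level the package targets.

## Coupling and time integration

Each time step solves a fixed point at the interface: the segment is
solved with aortic pressure at the inlet and the arteriolar node pressure
at the outlet; the network is advanced one backward-Euler step with the
resulting outlet flow; the exchanged pressure is updated until successive
iterates agree to 1e-6 mmHg. The update is one under-relaxed step (factor
0.5) followed by secant iterations on the interface residual. Plain
under-relaxation is not sufficient here: the interface gain is roughly
`R_distal/a_v`, which exceeds 200 in the stiff capacitance-free limit used
by the verification tests, and a fixed relaxation factor diverges there.
The secant update is exact for the affine maps that arise between
collateral-switch states and typically converges in 2–4 iterations.

Backward Euler was chosen because the network is stiff (compliances down
to 1e-12 mL/mmHg appear in the algebraic-limit tests); the implicit step
is unconditionally stable and recovers the instantaneous resistor solution
as C → 0. The step is `period/1000`. The collateral switch state is
resolved consistently within the step (solve, check, re-solve once).

Cycles are marched from a uniform initial state at mean aortic pressure
until the cycle-to-cycle change of FFR is below 1e-4 (at most 20 cycles;
the shipped cases converge in 5–9). FFR is defined as the ratio of
cycle-mean distal pressure to cycle-mean aortic pressure under hyperemia —
the clinical Pd/Pa convention; an instantaneous diastolic convention would
be an alternative, and the choice is stated rather than inferred. Charge
conservation is monitored: at periodic convergence the net per-cycle flux
through each capacitor is under 1% of the mean cycle flow (0.01–0.2% on
the shipped cases).

## The synthetic pullback generator

No patient OCT data ship with the package; geometry comes from a
generator that emulates what a segmented pullback looks like: frames at
fixed sub-millimetre pitch, circular-to-elliptic contours (aspect ratio
≥ 1), localized Gaussian area stenoses parameterized by centre, FWHM and
fractional area reduction, a 5% area floor to keep the solver well-posed,
and seeded smooth low-order-Fourier radial noise capped at 2% of the local
radius. The centreline is straight: curvature information is genuinely
absent from pullback imaging, so the generator does not pretend to have
it. Frames may be stored in either acquisition order (pullbacks run
distal→proximal); profiles are normalized proximal→distal from 0.

What passing tests on this geometry do show: the calibration arithmetic,
the loss-coefficient reduction, the coupling fixed point, stenosis-severity
monotonicity, and conservation properties. What they cannot show:
agreement with invasively measured FFR on real lesions — eccentric,
calcified, curved, serially stenosed vessels are outside the generator's
vocabulary, and serial stenoses in one territory are explicitly out of
scope for the network construction.

## Shipped study conditions

Three synthetic cases (`shipped_cases()`) span the clinical range: a mild
(30% area reduction) LAD lesion, a moderate (60%) LCX lesion, and a severe
(90%) RCA lesion, all under the reference-cohort median hemodynamics
(SBP 140, DBP 81 mmHg, HR 67 bpm, stroke volume 65 mL, hematocrit 40.2%).
They produce FFR ≈ 0.99, 0.96 and 0.69. Simulations use 1000 steps per
cycle; a severity sweep or α-sensitivity battery over these cases runs in
a few minutes on one core. The α-sensitivity property (max |ΔFFR| over the
±30% α band) is bounded at 0.02 on this battery — a deliberately wider
bound than what patient-specific studies report (±0.006), because the
synthetic RCA case concentrates its territory sensitivity in a way the
desk-scale battery cannot average away.

## Numerical choices and degenerate inputs

* Polygonal contours carry an intrinsic area deficit (~0.16% for 64
  vertices); analytic comparisons use either exact profiles or tolerances
  ≥ 0.5%.
* Zero-length and all-zero trees, daughter radii at or above the parent,
  non-positive areas, constant vectors in correlations, and both-zero RCA
  territories all raise classed errors (`octffr_invalid_input`,
  `octffr_non_physical_branching`, ...) rather than propagating NaN.
* A branch with zero flow fraction is reported as an infinite-resistance
  error, never silently capped.
* Contour CSVs are written with 17 significant digits so profiles
  round-trip bit-for-bit.
* The diagnostic cutoff counts FFR exactly 0.8 as positive (the clinical
  ≤ convention); a strict `<` mode is available.

## Limitations

Straight centreline; fixed walls; single focal stenosis per segment;
epicardial losses proximal to the imaged segment neglected (aortic
pressure is applied directly at the inlet); compartment splits,
compliances and collateral parameters are literature-conventional rather
than patient-identifiable; waveform shapes are constructed. These mirror
the method's own stated limitations and the package documents rather than
hides them.
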