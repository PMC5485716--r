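# octffr

Desk-scale simulation of coronary **fractional flow reserve (FFR)** from
OCT-pullback-like lumen geometry, with outlet boundary conditions
calibrated from **angiographic vessel lengths** instead of ventricular
muscle mass.

FFR — the ratio of pressure distal to a stenosis to aortic pressure under
maximal hyperemia, with ≤ 0.8 the clinical significance threshold — is
normally computed from imaging by coupling a flow solver of the imaged
segment to a lumped-parameter model (LPM) of the downstream
microcirculation. The LPM resistances are the hard part: muscle-mass
methods need CT, which OCT workflows don't have. `octffr` implements the
vessel-length alternative end to end:

1. **Flow split from lengths.** Resting flow divides among LAD, LCX and
   RCA in proportion to subtended vessel length
   (`Q_LAD : Q_LCX : Q_RCA = l_LAD : l_LCX : l_RCA,eff`), the RV-feeding
   RCA length down-weighted by the LV/RV volume ratio α (default 3.46).
   With total coronary flow 4% of cardiac output and a 5 mmHg right-atrial
   pressure, territory resistances follow as `ΔP / (f·Q_cor)`.
2. **Resistance amplification.** Side branches between the ostium and the
   imaged segment take their share of flow under the scaling law
   `Q = m·r^k` (k = 2), so the total resistance distal to the segment is
   `R_p / AMP_R` with `AMP_R = 1 − Σ (r_di/r_p)^k ∈ (0, 1]`.
3. **Quasi-1D segment solver.** The lumen profile reduces to
   `Δp = a_v q + a_t q|q|` (Poiseuille integral + separation loss,
   K_t = 1.52), with Einstein viscosity from hematocrit.
4. **Distal network.** Three series RC compartments (arterioles,
   capillaries, veins) with intramyocardial compression `P_imp = 0.75·P_LV`
   on the arterial compartments, a pressure-triggered collateral switch,
   and hyperemia as resistance scaling to 25% of resting.
5. **Iterative coupling.** Per-step fixed-point exchange of outlet flow
   and pressure (secant-accelerated), marched to a periodic FFR.
6. **Agreement statistics.** Bland–Altman, Pearson/Spearman, R², and
   diagnostic confusion at the 0.8 cutoff for measured-vs-simulated
   batteries.

No patient data are required or included: a seeded synthetic pullback
generator produces OCT-like contour stacks with parameterized stenoses.

## Worked example

```r
library(octffr)

lengths <- branch_lengths(110, 100, 70, 100)  # l_LAD, l_LCX, RCA RV/LV parts, mm
hemo    <- patient_hemo()                     # cohort medians: 140/81 mmHg, 67 bpm, ...

(split <- flow_fractions(lengths))
#> Territory flow split (alpha = 3.46, additive variant)
#>   LAD  33.3%   LCX  30.3%   RCA  36.4%

(resist <- branch_resistances(split, hemo))
#> Resting branch resistances (mmHg·s/mL): LAD 98.9, LCX 108.8, RCA 90.5
#>   delta_p = 95.7 mmHg, q_cor = 2.903 mL/s

# one diagonal (r = 1.0 mm) leaves the LAD (r_p = 1.75 mm) before the segment
rroi <- roi_total_resistance(resist$r_lad, amp_factor(branching_spec(1.75, 1.0)))
rroi$amp_r; rroi$r_roi
#> 0.6734694      146.8829

# full pipeline on a shipped synthetic case (severe RCA stenosis)
res <- simulate_ffr(shipped_cases()[3])
res
#> FFR = 0.688 (converged after 9 cycles)
#>   cycle-mean flow 1.55 mL/s, mean Pa 91.3 mmHg, capacitor charge imbalance 0.0067%
```

Reading: 33/30/36% of resting coronary flow goes to LAD/LCX/RCA for these
lengths; the LAD territory presents ~99 mmHg·s/mL at rest; the diagonal
branch amplifies the distal resistance of the imaged segment by 1/0.673;
and the severe (90% area reduction) RCA case yields a hyperemic FFR of
0.69 — hemodynamically significant — with the periodic solution conserving
capacitor charge to 0.007% of mean flow.

A thin CLI wraps the same functions:

```sh
exec/octffr synth    --config case.yaml --out contours.csv
exec/octffr simulate --config inst/extdata/cases/case_severe_rca.yaml --out result.json
exec/octffr validate --pairs pairs.csv --cutoff 0.8 --out report.json
```

## Documentation

The methods vignette (`vignettes/octffr-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults, the
synthetic-geometry generator and what it does and does not emulate, the
numerical scheme (implicit stepping, secant-accelerated interface
coupling), and known limitations.
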