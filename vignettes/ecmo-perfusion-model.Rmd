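---
title: "Methods: a reduced-order model of perfusion level in peripheral VA-ECMO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order model of perfusion level in peripheral VA-ECMO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Peripheral veno-arterial ECMO drains venous blood, oxygenates it, and
returns it through a femoral cannula. The return stream is steady and runs
*retrograde* up the descending aorta, against the pulsatile antegrade
stream the heart still ejects. Three consequences matter clinically: the
distribution of flow between upper body and lower body, the loss of
pulsatility in peripheral waveforms, and the position of the watershed
where the two streams meet — which decides whether poorly oxygenated blood
ejected by failing lungs perfuses the carotid territory. `ecmoflow`
quantifies all three across assist levels with a model small enough to be
verified line by line against closed forms.

## Model class and assumptions

The arterial tree is solved as a **linear transmission-line network in the
frequency domain**, not by 3D CFD. Assumptions, in decreasing order of
consequence:

1. *Linearity.* Convective acceleration is dropped; each harmonic of the
   cardiac cycle is solved independently and superposed. This removes
   jets, vortices and turbulence — precisely the 3D features near the
   cannula tip. The package therefore claims *trend-level* fidelity for
   spatial quantities (watershed motion, regional shear), not pointwise
   values.
2. *Axisymmetric Womersley profiles.* Per harmonic, the velocity profile
   in a segment is fully developed oscillatory pipe flow; the wall
   friction factor is `F₁₀ = 2J₁(Λ)/(Λ J₀(Λ))` with `Λ = i^{3/2} α`,
   `α = R√(ωρ/μ)`.
3. *Thin uniform compliance.* Wall distensibility enters only through a
   pulse wave speed `c` per segment (`C′ = A/(ρc²)`); no tapering, no
   viscoelasticity.
4. *Static outlets.* All five outlets are held at a constant 70 mmHg, so
   outlet pressure carries no harmonics and the flow split is set entirely
   by the vessel impedances. Real peripheral beds add terminal resistance
   and compliance; their absence exaggerates the share of flow taken by
   low-resistance paths (see *Limitations*).
5. *Newtonian blood*, ρ = 1050 kg/m³, μ = 0.0035 kg/(m·s).

The steady (cycle-mean) part is the α → 0 limit: a Poiseuille resistance
network `R = 128 μ L / (π D⁴)` solved by nodal analysis with Kirchhoff
conservation at every junction.

## Parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| cycle period | 0.8 | s | reference cardiac period of the study design |
| total perfusion | 5 | L/min | physiological requirement; held fixed across assist levels |
| outlet pressure | 70 | mmHg | reference outlet condition, all outlets |
| diameters | 28 / 7 / 7 / 7 / 11.3 / 10.3 | mm | reference geometry (aorta inlet, three arch branches, descending aorta at diaphragm, left femoral); right femoral reuses the left femoral calibre since only the left is specified |
| segment lengths | 80 / 50 / 50 / 50 / 400 / 250 / 200 / 50 | mm | representative adult values; the source geometry specifies no lengths, so these are package defaults, fully configurable |
| wave speed | 6 | m/s | mid-range adult aortic pulse wave velocity, uniform; configurable per segment |
| systolic fraction | 0.35 | – | typical ejection duration at 75 bpm |
| samples / cycle | 800 | – | 1 ms resolution; all series share this grid |
| harmonics | 20 | – | see *Numerical choices* |
| station spacing | 5 | mm | resolution of WSS and watershed localisation |

## The synthetic source generator

The package generates its own boundary data; there are no external inputs.
The cardiac source is a **half-sine systolic ejection** with zero diastolic
flow, peak solved analytically as `mean · π/(2·systolic fraction)`; the
ECMO source is constant. For a target blood assist index the composer
splits the fixed 5 L/min total by bracketed root-finding on the ECMO level.

What this emulates: the amplitude/mean structure of a ventricular outflow
waveform and the steadiness of a centrifugal pump, which is what the HI,
BAI and watershed analyses actually consume. What it does not emulate:
dicrotic-notch detail, regurgitant valve flow, heart-rate and contractility
changes with unloading (in reality the heart does not keep a fixed waveform
shape as the pump takes over), pump pulsation modes, or respiratory
modulation. A green trend test therefore establishes that the *model class*
reproduces the expected physics under the stated stylised sources — not
that any individual patient waveform would.

Two readings of the blood assist index are implemented because they
genuinely differ for a zero-diastolic cardiac shape: the instantaneous
integrand `F_E/(F_E+F_C)` equals 1 throughout diastole whenever any pump
flow is present, so the instantaneous index cannot fall below the
diastolic fraction of the cycle (≈ 0.65 at the default systolic fraction);
targets such as 40 % are unreachable in that reading. The **mean-flow
ratio is therefore the default mode**, covers all of [0, 1], and is what
the sweep levels refer to; the instantaneous value is always reported
alongside. The composer refuses infeasible instantaneous targets with the
achievable range in the message rather than silently switching modes.

## Numerical choices

* **Complex Bessel ratio.** `J₁/J₀` at `arg z = 3π/4` is evaluated by a
  modified Lentz continued fraction from the three-term recurrence (J_n is
  the minimal solution, so the fraction converges for all z); the naive
  power series cancels catastrophically beyond |z| ≈ 10, and the suite
  cross-checks the fraction against an independent series oracle at α = 5.
* **Harmonic truncation.** 20 harmonics of the 1.25 Hz fundamental
  (25 Hz bandwidth). The half-sine corner gives the source a spectral tail
  above the cut; the retained-band solution changes by < 0.2 % RMS at the
  outlets when doubling to 40 harmonics (asserted in the suite at < 1 %).
  Junction mass closure is checked against the **band-limited projection**
  of each source — the inflow the truncated model actually imposes, which
  the nodal solve conserves to machine precision; the raw-vs-band-limited
  source discrepancy is recorded separately on every solution
  (`source_bandlimit_error_fraction`, ≈ 10 % of mean at the sharpest
  corner) so the truncation is visible rather than hidden inside a closure
  "residual".
* **Cycle integrals.** All periodic integrals (BAI, OSI, means) use the
  wrapped trapezoid on the endpoint-excluded uniform grid, which for a
  periodic signal equals the plain sample mean — piecewise-constant test
  cases are integrated exactly.
* **Degenerate inputs.** HI and OSI of an identically zero series are
  defined as 0 (a sweep endpoint otherwise produces 0/0); the BAI
  integrand is defined as 0 where both flows vanish, which keeps the
  index of a pump-off run exactly 0.
* **Watershed localisation.** The interface is the most proximal
  antegrade→retrograde transition of signed sectional flow along the
  cardiac-to-cannula path, linearly interpolated between stations; further
  crossings are counted in an attribute. Flows below 10⁻⁹ of the profile
  maximum are treated as stagnant. Two boundary clamps keep the cycle mean
  well defined at the sweep extremes: a trunk already retrograde at the
  root reports the proximal end (`fully_retrograde`), and a fully
  antegrade trunk while the cannula source is actively injecting reports
  the distal end (`at_cannula` — the cardiac stream has pushed the
  watershed onto the cannula orifice). Without the distal clamp, peak
  systole at low assist levels drops out of the average and biases the
  low-BAI mean proximally, inverting the trend for a bookkeeping reason
  rather than a physical one. A steady cardiac-only run still reports
  *no* interface (zero existence fraction).

## Design decisions that were genuinely open

* **Arc-length coordinate through the access limb.** The watershed
  coordinate runs root → ascending aorta → descending aorta → right
  femoral access segment (0 at the root, 680 mm at the cannula node by
  default), because the two streams meet along that path; an aorta-only
  coordinate censors low-assist systole (see above).
* **ECMO as a point flow source.** Cannula size and insertion depth are
  unspecified in the reference design; cannula hydraulics are out of
  scope. The distal right femoral limb is retained with its own outlet so
  the lower-limb split has both femoral arteries.
* **Region mapping for reporting.** "Aortic arch" = trunk stations within
  40 mm of the arch branch node; "femoral artery" = stations within one
  femoral diameter of the iliac bifurcation. A 1D model has no inner/outer
  wall distinction, so regional WSS is a section average — a declared
  fidelity limit when comparing against wall-resolved maps.
* **Flow-split trend signs are reported, not asserted.** In 3D, the
  cannula jet carries momentum that helps lower-limb perfusion compete;
  in a transmission line the nearby femoral outlets win on impedance, so
  `r_up` *falls* with BAI here. The sweep computes the Pearson r of both
  splits against BAI and warns when the sign disagrees with the expected
  clinical direction instead of failing.
* **No p-values.** Trend correlations are computed over 4 assist levels;
  a p-value at n = 4 is not interpretable, so r is reported alone.

## Limitations

Absolute flow splits are dominated by the fixed-pressure outlets (no
peripheral resistance), so `r_up`/`r_down` magnitudes are not
physiological even though conservation and the index definitions are
exact. WSS magnitudes are section-averaged Womersley values — useful for
cross-level comparison, low against wall-resolved 3D values near bends and
bifurcations. Everything downstream of the velocity field (oxygen
transport, hemolysis, endothelial response) is out of scope. The sweep
reports levels {0, 40, 60, 80} % by design; other levels are accepted
anywhere a level list is taken.

Nothing in this vignette states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.
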