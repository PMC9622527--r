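---
title: "Methods: conduit and reservoir function from 4D flow velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conduit and reservoir function from 4D flow velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

A large artery serves two mechanical roles. As a *conduit* it transports
the stroke volume with as little pressure loss as possible; as a
*reservoir* (Windkessel) it stores part of the systolic volume
elastically and releases it in diastole, damping pulsatility. This
package quantifies both roles from a single non-invasive acquisition: a
time-resolved 3D velocity field (4D flow PC-MRI) plus a static lumen
segmentation at peak systole.

## Conduit: the work-energy pressure balance

For a vascular segment bounded by an entry and an exit plane, the
mechanical-energy balance of the Navier-Stokes equations relates the
total pressure difference along the segment to three energy terms,

$$\Delta P_{tot} = \frac{1}{Q}\left(\frac{\partial K_e}{\partial t}
  + A_e + V_e\right),$$

with $K_e = \tfrac{\rho}{2}\int |v|^2\,dV$ the kinetic energy in the
segment, $A_e = \tfrac{\rho}{2}\oint |v|^2 (v\cdot n)\,dA$ the net
kinetic-energy flux through the two planes, $V_e = \int 2\mu\,
(\varepsilon\!:\!\varepsilon)\,dV$ the laminar viscous dissipation rate
($\varepsilon$ the strain-rate tensor), and $Q$ the flow rate. Each term
divided by $Q$ is a pressure component: the *kinetic* component
$\Delta P_{kin}$ (temporal acceleration, driven by ventricular
contraction; its cycle mean is near zero because acceleration and
deceleration cancel), the *advective* component $\Delta P_{adv}$ (the
signature of calibre change — tapering or residual narrowing), and the
viscous term (frictional loss, always dissipative). The sign convention
is entry-minus-exit: positive values mean the entry plane is at higher
pressure. Conduit function is judged on $\Delta P_{adv}$ and the $V_e$
rate at peak systole, when both are largest.

At a single cross-section the *simplified advective* (SAW) pressure
$$\Delta P_{SAW} = \frac{\rho}{2 Q}\int |v|^2 (v\cdot n)\,dA$$
is the pressure needed to accelerate the observed full velocity profile
from rest. It refines the simplified Bernoulli estimate (which uses one
peak velocity) and neglects the proximal inlet velocity: for plug flow
it reduces to $\rho v^2/2$, for a parabolic profile with mean speed
$\bar v$ it equals $\rho \bar v^2$. Evaluated at every 1-mm centreline
station it maps *where* along the vessel the flow momentum is created.

## Reservoir: pulse wave velocity and the Moens-Korteweg modulus

The stiffer the wall, the faster a flow/pressure waveform travels. PWV
is estimated foot-to-foot: the flow waveform is extracted at every 1-mm
station, upsampled in time, the foot of the systolic upstroke located by
intersecting tangents, and the wave speed obtained in a 20-mm moving
window as the inverse slope of foot time against arc length. The
Moens-Korteweg relation converts the local PWV, lumen diameter $D$ and
wall thickness $h$ to an elastic modulus
$$E = \rho\, c^2 \frac{D}{h},$$
reported in kPa. Because $E$ depends on $D/h$, BSA-indexed diameter and
thickness can be supplied interchangeably with raw values.

## Anatomy

The centreline is tracked between two seed landmarks as the shortest
path through the lumen weighted towards the interior distance-transform
ridge, recentred on cross-section centroids, Gaussian-smoothed along arc
length, and resampled at 1-mm stations. Curvature at a station is the
inverse circumradius of three consecutive points; diameter is the
effective diameter $2\sqrt{A/\pi}$ of the perpendicular lumen
cross-section; wall thickness is the per-side half-difference of
epi- and endo-vascular diameters (the convention adopted here for
"difference between diameters"; observer replicates are averaged). The
aorta is divided at five landmarks into AA, TA, DA1 and DA2, and all
lengths (and, for consistency of reporting units, curvature) are indexed
by body surface area.

# Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| blood density $\rho$ | 1060 | kg/m^3 | WERP, SAW, Moens-Korteweg |
| dynamic viscosity $\mu$ | 0.004 | Pa.s | viscous dissipation |
| `q_min_frac` | 0.1 | – | frames with $|Q|$ below this fraction of the cycle peak are flagged NaN (the $1/Q$ quotient is meaningless near zero flow) |
| PWV window | 20 | mm | moving-average span for foot-time regression; at 1-mm stations this averages ~20 foot-time pairs |
| temporal upsampling | 20 | x | cubic-spline refinement before foot detection; per-millimetre transit (~0.25 ms at 4 m/s) is far below the 30-ms frame spacing |
| centreline smoothing $\sigma$ | 4 | mm | see numerical choices |
| normality $\alpha$ | 0.05 | – | Shapiro-Wilk gate for test selection |

Blood properties are conventional whole-blood values; neither is
measurable from the data, and both are config-overridable. The choices
of foot definition (intersecting tangents, the standard in the PWV
literature and robust to baseline drift) and window span are exposed in
the configuration; a threshold-crossing foot would change absolute foot
times but not transit-time differences.

# The synthetic phantoms

The generators emulate the study conditions of a paediatric 4D-flow
acquisition — ~1-mm grids (0.5 mm where convergence headroom is needed),
24 frames over a ~700-ms cycle (~30-ms temporal resolution) — and carry
analytic truth evaluated independently of the grid:

* **Poiseuille**: parabolic steady flow; truth from the Hagen-Poiseuille
  law ($\Delta P = 8\mu L Q/\pi R^4$, $V_e = Q\,\Delta P$).
* **Womersley**: prescribed oscillatory flow with the complex
  Bessel-function profile; truth includes the Womersley number and the
  analytic pressure-gradient amplitude and phase.
* **Tapered plug**: Bernoulli advective pressure
  $\rho(v_{out}^2 - v_{in}^2)/2$, with an analytic radial velocity
  component keeping the field divergence-free.
* **Propagating wave**: plug flow $Q(s,t) = Q_0 f(t - s/c)$ with an
  S-shaped (raised-cosine) upstroke — aortic flow acceleration peaks
  mid-upstroke, which is also the geometry the intersecting-tangents
  foot method is built for — optional piecewise-constant $c(s)$ and
  seeded Gaussian velocity noise at a stated SNR against peak speed.
* **Torus**: mask-only curvature/diameter truth ($\kappa = 1/R_t$).

The noise model is i.i.d. Gaussian per velocity component — a
deliberate simplification of PC-MRI noise with no velocity aliasing,
no venc scaling, no spatial correlation from k-space undersampling, and
a rigid non-moving wall. Passing phantom tests therefore establishes
that the *estimators* are correct and convergent on ideal fields of
study-scale resolution; it does not establish robustness to
reconstruction artefacts, segmentation error or wall motion in patient
data.

# Numerical choices

* **Velocity gradients** (viscous term): second-order central
  differences inside the lumen, first-order one-sided differences at the
  wall. Ghost-value schemes (zero or mirrored exterior velocity) were
  rejected after convergence testing against the Poiseuille dissipation
  oracle: on a voxelised staircase boundary they create spurious
  tangential gradients and converge non-monotonically, while the
  one-sided interior scheme converges monotonically (-5.8 percent at
  1-mm, -1.4 percent at 0.5-mm voxels).
* **Centreline smoothing**: $\sigma = 4$ mm Gaussian kernel, evaluated
  on a dense (1/8-station) parameter grid before uniform arc-length
  resampling. Three-point curvature at 1-mm spacing measures a sagitta
  of $\sim\!1/(8R)$ mm — micrometres for aortic radii — so stations must
  lie on a smooth curve: coarser evaluation leaves chord kinks that
  dominate the estimate, and $\sigma = 2$ mm leaves ~7 percent staircase
  bias at 1-mm voxels. $\sigma = 4$ mm is still far below aortic bend
  radii (tens of mm).
* **Cross-section area**: fractional sum of the trilinearly interpolated
  lumen indicator over the in-plane connected component containing the
  centreline point (branches cut by the same plane are excluded by the
  connectivity rule). A binary 0.5-level pixel count is biased by up to
  half a pixel ring (+4 percent diameter on lattice-aligned discs); the
  fractional sum places the boundary at the indicator mid-crossing.
* **Flow rate for the WERP quotient**: mean of the inlet and outlet
  plane fluxes; the residual inlet/outlet difference is reported as a
  flow-conservation QC metric, never silently corrected.
* **Temporal derivative**: central differences over frames, one-sided at
  the ends of a non-periodic series, periodic wrap when the cycle is
  flagged periodic (prospective triggering may truncate late diastole,
  so periodicity is an explicit flag, not an assumption).
* **Peak timing**: three-point parabolic interpolation around the
  discrete maximum (frame spacing ~30 ms is coarse relative to
  between-group timing differences of tens of ms); zero crossings by
  linear interpolation after the peak, with an explicit absent flag
  when no crossing exists.
* **Degenerate inputs**: flat waveforms, empty masks, disconnected
  seeds, non-positive BSA and epi <= endo diameters raise errors naming
  the offending input; near-zero-flow frames and retrograde PWV windows
  are flagged invalid (NaN) rather than raised, because they are
  expected in normal data.
* **Determinism**: all noise is seeded; rerunning a pipeline
  configuration reproduces outputs byte-identically, and every output
  file carries the configuration hash and package version.

# Design choices where the method was open

* **Wall thickness** is reported per side, $(D_{epi}-D_{endo})/2$; the
  alternative full-difference convention would double the values and
  halve $E$. The choice is flagged in the function documentation.
* **Curvature is BSA-indexed** exactly like lengths, matching the
  reporting convention of per-segment tables (units m^-1/m^2), even
  though dimensional custom differs.
* **Segment planes** default to the landmark stations themselves (no
  inset); the WERP control volume between them excludes branch lumens by
  the connected-component rule seeded from the mid-segment centreline
  point.
* **Peak systole** defaults to the frame maximising in-mask kinetic
  energy (virtual angiography) or inlet flow for profile work, and is
  config-overridable.
* **Two-sided tests, no multiplicity correction**, and the t-test is
  used only when *both* groups pass the Shapiro-Wilk gate at
  $\alpha = 0.05$; otherwise the exact (small-sample) Mann-Whitney
  U-test.

# Problem sizes used in validation

The bundled validation runs use tubes of 6-8 mm radius and 80-120 mm
length at 0.5-1-mm voxels (1.3 x 10^5 lumen voxels at the finest), 24
frames per 700-ms cycle, 100 noise seeds for the Monte-Carlo PWV study
and 1000 seeds for the Shapiro-Wilk calibration — sizes chosen so the
whole suite validates every estimator on a desktop machine in minutes
while staying at the resolution scale of the emulated acquisition.

# Known limitations

* Axis-aligned grids only (no oblique NIfTI affines); world geometry is
  spacing + origin.
* Finite resolution biases the viscous rate low (the wall shear layer is
  under-resolved); the mesh-refinement test quantifies the effect on the
  Poiseuille oracle, and the same bias is expected — unquantified — on
  patient-scale data.
* The Moens-Korteweg relation assumes a thin-walled elastic tube with
  inviscid fluid; in a compliant, tapering, branching aorta the derived
  $E$ is an effective, not a constitutive, modulus.
* PWV windows spanning regions of genuinely different wall stiffness
  average the transition (one window of blur, as the two-region phantom
  shows).
* The statistics layer implements the published protocol (gate + two
  tests); it is not a general inference framework.
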