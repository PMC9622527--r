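# aortaflow

Non-invasive assessment of the **conduit** and **reservoir** function of
large arteries from 4D flow (time-resolved, three-directional
phase-contrast MRI) velocity fields and a lumen segmentation, written for
researchers in quantitative cardiovascular imaging. The package targets
the setting where both functions must be mapped *along* a vessel — e.g. a
surgically reconstructed aorta — rather than summarised by a single
number.

## What it computes

**Conduit function** (resistance to bulk transport), from the work-energy
relative pressure (WERP) balance over a vascular segment:

    dP_tot = (1/Q) * ( dKe/dt + Ae + Ve )

where `Q` is the flow rate through the segment, `dKe/dt` the rate of
change of kinetic energy in the segment (temporal acceleration), `Ae` the
net advective kinetic-energy flux through the entry and exit planes
(spatial acceleration from calibre change), and `Ve` the laminar viscous
dissipation rate `int 2 mu (eps:eps) dV`. Each term divided by `Q` is a
pressure component (`dP_kin`, `dP_adv`, viscous term); positive values
mean higher pressure at the entry than the exit plane. The simplified
advective formulation (SAW) gives the advective pressure at a single
cross-section from the full velocity profile,
`dP_SAW = rho / (2 Q) * int |v|^2 (v.n) dA`, a profile-aware correction
of the simplified Bernoulli estimate.

**Reservoir function** (elastic buffering), from flow waveforms evaluated
at every millimetre of the vessel centreline: foot-to-foot transit times
(intersecting-tangents foot detection on temporally upsampled waveforms)
give the pulse wave velocity `PWV` in a 20-mm moving window, and the
Moens-Korteweg relation converts it to a wall elastic modulus

    E = rho * PWV^2 * D / h        (D lumen diameter, h wall thickness)

**Anatomy**: centreline extraction from the lumen mask (distance-ridge
tracking, cross-section centroid recentring, Gaussian smoothing, 1-mm
stations), three-point curvature, cross-sectional diameter, wall
thickness from endo/epi diameters, four-segment subdivision (AA, TA,
DA1, DA2) from five anatomical landmarks, and body-surface-area indexing.

**Validation phantoms**: Poiseuille, Womersley (complex Bessel-function
profile), tapered plug, propagating flow wave and torus generators, each
carrying closed-form ground truth (pressure drop, dissipation rate, wave
speed, curvature) computed independently of the voxel grid.

**Cohort statistics**: mean +/- SD summaries, a Shapiro-Wilk normality
gate selecting Student's t-test or the Mann-Whitney U-test, and
percentage / fold-change derived statistics.

## Worked example

Validate the WERP estimator against the Hagen-Poiseuille law on a
synthetic tube (R = 8 mm, L = 80 mm, Q = 70 ml/s, 0.5-mm voxels), for
which the analytic pressure drop is `8 mu L Q / (pi R^4)` = 13.93 Pa =
0.104 mmHg and the dissipation rate `Q * dP` = 0.975 mJ/s:

```r
library(aortaflow)
p  <- poiseuille_phantom(R = 8, L = 80, Q = 70, voxel = 0.5)
cl <- extract_centreline(p$mask, p$truth$axis_start, p$truth$axis_end)
cv <- segment_control_volume(p$mask,
        cross_section_at(p$mask, cl, 2),
        cross_section_at(p$mask, cl, max(cl$arc_length) - 2), cl)
tr <- segment_pressure_traces(p$field, cv)
L  <- cv$outlet$station - cv$inlet$station
c(dp_tot_mmhg = tr$dp_tot_mmhg[1] * 80 / L,
  ve_mj_s     = tr$ve_rate_mj_s[1] * 80 / L)
#> dp_tot_mmhg     ve_mj_s
#>   0.1010884   0.9431514
```

Both land within a few percent of the closed forms (the small deficit is
the voxelised wall). A pulse-wave phantom validates the reservoir side:

```r
ph <- propagating_wave_phantom(c = 4, L = 120, R = 6, Q0 = 60,
                               period = 700, frames = 24, voxel = 1)
cl <- extract_centreline(ph$mask, c(0, 0, 0), c(0, 0, 120))
ws <- waveform_series(ph$field, ph$mask, cl)
mean(pwv_estimate(ws, window = 20)$pwv, na.rm = TRUE)
#> [1] 3.999635
```

The full per-subject chain (angiography, centreline, segments, WERP
traces, SAW profile, PWV / E profile, QC report) runs from a YAML
configuration via `run_pipeline()`, or from the shell through the thin
CLI at `inst/cli/aortaflow.R` (subcommands `phantom` and `run`).

## Limitations

Grids are assumed axis-aligned (spacing from the NIfTI header, origin and
frame times from a JSON sidecar); velocity anti-aliasing and eddy-current
correction are assumed done upstream; turbulent dissipation is out of
scope. See the methods vignette (`vignettes/aortaflow-methods.Rmd`) for
the model assumptions, numerical choices and what phantom validation does
and does not establish about patient data.
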