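---
title: "Estimating the subsurface temperature peak from surface thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the subsurface temperature peak from surface thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodepth)
```

## The problem

Hyperthermic laser treatments of subcutaneous tissue (laser lipolysis,
radiofrequency and related procedures) heat a target volume below the skin
while the surface is actively cooled. The combination shifts the temperature
peak a few millimetres below the surface, exactly where no camera can see it.
Knowing that peak — its temperature `T_max` and depth `z_max` — is what
separates a therapeutic dose from a burn, yet inserting thermocouples defeats
the purpose of a non-invasive treatment.

`thermodepth` implements a non-contact estimator that uses only what an
infrared camera can record: the evolution of the *surface* temperature
`T_surf(t)` during the **inactive period**, when laser and cooling are
switched off and the tissue relaxes freely. A subsurface peak announces
itself unmistakably in that signal — heat diffuses back to the cooled
surface, so `T_surf(t)` *rises* during the first tens of seconds of
relaxation, at a rate and with a shape controlled by how hot and how deep the
peak is.

Directly inverting the heat equation for the initial condition is severely
ill-posed: noise of a few hundredths of a degree is amplified without bound.
The package instead regularizes by restriction to a parametric family:

1. generate a large set of physically plausible candidate depth temperature
   profiles `T(z)` from a closed-form family,
2. forward-simulate the surface relaxation of every candidate with a 1D
   heat-diffusion model, collecting a database of (profile, trace) pairs,
3. match the measured trace against the database over a time window
   `[0, t_m]` and report the profile behind the best-fitting trace.

## The candidate profile family

Candidates are generated from

$$T(z) = (T_{\mathrm{surf}} - 1) + (z + 1)^{B / (C (z+1) + A)} - D\,(z+1),$$

with depth $z$ in millimetres. The power term equals 1 at the surface, rises
to a single maximum below it and decays back towards 1, which is exactly the
shape that surface cooling plus volumetric heating leaves behind; $D$
(°C/mm) tilts the deep tail to represent a bulk temperature gradient, and
$T_{\mathrm{surf}}$ anchors the surface value, $T(0) = T_{\mathrm{surf}} - D$.

Two structural facts make this family convenient to work with:

* the depth of the power-term maximum depends only on $A/C$, through
  $u(\ln u - 1) = A/C$ with $u = z + 1$, not on $B$;
* the peak amplitude is strictly increasing in $B$.

`solve_profile_params()` exploits this weak coupling: alternating
one-dimensional root solves for $A$ (targeting a peak depth) and $B$
(targeting an amplitude) converge in a few sweeps. `design_grid()` uses it
to build databases that tile the (peak depth, peak amplitude) plane on a
*uniform* ladder. A raw Cartesian grid in $(A, B, C, D)$ — also available
via `parameter_grid()` — covers that plane extremely unevenly: over a modest
range of $C$ the amplitude $\exp(B \ln u /(Cu+A))$ spans several orders of
magnitude, so most raw-grid entries are either physically absurd or
redundant, while what actually limits inversion accuracy is the spacing of
peak depths and amplitudes represented in the database.

## The forward model

During relaxation there are no sources, so the field obeys pure 1D
conduction, $\rho c_p \, \partial T/\partial t = k\, \partial^2 T/\partial z^2$,
with the air–tissue boundary losing heat by natural convection and thermal
radiation:

$$-k \frac{\partial T}{\partial z}\Big|_{z=0} =
  h_{NC}\,(T_{\mathrm{air}} - T_{\mathrm{surf}}) +
  \sigma \varepsilon\,(T_{\mathrm{env}}^4 - T_{\mathrm{surf}}^4).$$

The quartic terms are evaluated on the Kelvin scale (the balance is
dimensionally meaningful only on an absolute scale); every interface of the
package speaks °C. Evaporation is not modelled as a separate flux — for a
dry surface well below 60 °C its contribution is small and is conventionally
folded into $h_{NC}$.

Defaults describe subcutaneous fat: $\rho = 860$ kg/m³, $c_p = 2870$
J/(kg K), $k = 0.23$ W/(m K) (configurable over the plausible 0.17–0.32
range), $\varepsilon = 0.98$, $h_{NC} = 13$ W/(m² K) (common values run
10–15), air and surroundings at 25 °C. The domain is a 34 mm slab; the
bottom boundary is a fixed 25 °C (water-bath condition), with an insulated
option used by the conservation oracles. For in-vivo style scenarios
`layered_simulate()` stacks media with different properties (harmonic-mean
face conductivities enforce flux continuity at interfaces) and the deep
boundary can be fixed at body temperature, 36 °C.

### Discretization

Node-centred finite volumes (surface and bottom nodes own half cells) with
`dz = 0.1` mm; time stepping is Crank–Nicolson with `dt = 0.05` s, with the
radiative flux lagged one Picard iterate and re-iterated until the surface
node moves by less than 1e-6 °C (at most 10 sweeps). Crank–Nicolson was
chosen over backward Euler after measuring that first-order time truncation
at this step size exceeded the package's own refinement tolerance (halving
`dz` and `dt` must change a 120 s trace by less than 0.01 °C sup-norm;
backward Euler left 0.012 °C, Crank–Nicolson leaves 0.006 °C). An explicit
FTCS scheme is retained purely as a cross-check; it enforces
$dt \le dz^2 \rho c_p / (2k)$.

The solver is validated in the test suite against closed forms: the
equilibrium fixed point, conservation of the spatial mean under adiabatic
boundaries (to 1e-6 relative), the semi-infinite convective-cooling `erfc`
solution (within 0.05 °C over 120 s; measured 0.002 °C), free-space Gaussian
spreading (within 0.02 °C), implicit/explicit agreement (within 0.02 °C),
and the discrete maximum principle on randomized initial fields.

## The database and the matching step

`build_database()` evaluates every candidate on the solver grid and stores
its 120 s trace sampled at 1 Hz (the thermal camera rate is configurable; 1
Hz is a choice, not a measured property). Databases persist as a JSON
manifest plus CSV payloads at 17 significant digits — loading is exact — and
carry an md5 fingerprint over the canonical serialization of their inputs,
recomputed and checked on load.

`match_trace()` first discards candidates whose trace starts more than
`anchor_tolerance` away from the measured `trace(0)`, then linearly
interpolates the surviving database traces onto the measured time stamps
inside `[0, t_m]` and minimizes the RMS deviation. Ties are broken toward
the smaller peak depth, then database order. Design choices worth spelling
out:

* **Metric.** Uniformly weighted RMSE. It is the simplest metric consistent
  with least-squares matching; the winning residual is recorded in the
  result for auditability.
* **No inter-entry interpolation.** The estimate is always a stored member;
  grid density, not interpolation, controls resolution. This keeps the
  estimator auditable (every answer is a concrete simulated candidate).
* **Anchor tolerance 0.3 °C.** The residual surface has a flat diagonal
  valley: a candidate whose initial surface temperature is ~0.5 °C off can
  imitate the measured trace by placing its peak ~2 mm deeper. With the
  0.25 °C anchor ladder, 0.3 °C still always admits the correct anchor cell
  (quantization 0.125 °C plus noise on one sample) while excluding the
  distant impostors; we measured the depth-error spread dropping by roughly
  half relative to a 0.5 °C tolerance.
* **Interpolation direction.** Database traces are interpolated onto the
  measured stamps — the measurement is ground truth; simulation grids are
  under our control.

### Default database sizing

The default grid (`default_grid_spec()`) was sized with a resolution
experiment: a 25,000-entry fine ladder (0.2 mm × 0.2 °C) was built once and
coarser ladders emulated by subsetting, measuring ensemble recovery accuracy
per resolution. Accuracy degrades smoothly with ladder spacing; 0.45 mm ×
0.6 °C keeps the ensemble depth-error spread comfortably inside the package's
acceptance bounds at about 5,000 entries and a ~2 minute build on one CPU.
The core ladder covers peak depths 0.5–8.2 mm and amplitudes 2–18.2 °C —
the regime a 120 s surface observation can actually resolve; the thermal
diffusion length $\sqrt{4 \alpha t}$ in fat is ≈ 6.7 mm at 120 s — extended
by a coarse coverage ladder to 15 mm and 25 °C and by monotone surface-peak
entries (`z_max = 0`). Anchors span 28–30 °C every 0.25 °C by default; for a
single measured trace, `anchor_bracket(trace)` centres the ladder on the
observed initial temperature instead.

## The synthetic-data generator

No tissue recordings ship with the package, so `scenario_suite()` emulates
the validation measurements: truth profiles are drawn from the same closed
form with *continuous* parameters (hence never on the finite database grid),
forward-simulated, and observed at 1 Hz with i.i.d. Gaussian sensor noise of
σ = 0.1 °C — the NETD scale of an uncooled microbolometer camera; the real
camera's noise was not characterized, and the pixel averaging applied to real
frames has no synthetic counterpart, so σ absorbs both.

The ensemble reproduces the structure of the measured set:

* peak amplitudes span 3.5–17.5 °C, split at 10 °C into class A (low
  cooling settings) and class B (strong cooling);
* peak depth co-varies with the class, A ~ U(1.5, 4) mm, B ~ U(3, 7) mm,
  because the cooling setting drives amplitude and depth together (stronger
  cooling pushes a hotter peak deeper);
* profile width C ~ U(0.4, 0.7) and bulk slope D up to
  min(0.12, 0.008 × amplitude) °C/mm — the bound reflects a feasibility
  constraint of the family: a deep, low-amplitude bump cannot out-slope a
  large bulk gradient, so unbounded D draws would request profiles that do
  not exist;
* the initial surface temperature is drawn in 28–30 °C over the 25 °C
  room/bath condition.

What passing the synthetic recovery study does **not** show: robustness to
lateral (2D/3D) diffusion, to tissue heterogeneity and uncertain thermal
properties, to model error in $h_{NC}$, or to truth profiles outside the
generating family. It isolates exactly the error sources the inversion
itself introduces — grid quantization, window truncation and sensor noise.

## The recovery study

`peak_recovery_study()` is the end-to-end experiment: build the default
database, draw 30 seeded off-grid truths, simulate and degrade their traces,
match at windows of 30/60/90/120 s, and tabulate the signed estimators
`dT_max` and `dz_max` (estimated minus true). With the defaults (problem
sizes: ~4,900 database entries, 30 scenarios, 121-sample traces) a full run
takes about two minutes; `scripts/acceptance.R` reruns it from scratch and
writes the ensemble error statistics as JSON.

Typical behaviour, all recomputed by the tests and the acceptance script:
mean absolute errors at the full 120 s window of ≈ 0.14 °C and ≈ 0.14 mm
with ensemble spreads ≈ 0.18 °C and ≈ 0.17 mm; median errors non-increasing
in `t_m`; class-A scenarios already inside 0.5 °C / 0.5 mm at `t_m` = 30 s
while class B needs the longer windows — short relaxation recordings suffice
exactly when the cooling was mild.

## Numerical details and degenerate inputs

* Profiles must start at z = 0 with strictly increasing depth; traces must
  start at t = 0 with uniform stamps (jittered stamps are resampled with a
  warning by `read_trace()`).
* Peak extraction refines the grid argmax with a 3-point parabola when the
  argmax is interior; ties break toward the smallest depth (the
  conservative, hotter-near-surface reading). A constant profile therefore
  reports its peak at the surface.
* `generate_profile()` rejects parameter sets whose exponent denominator
  $C(z+1)+A$ vanishes on the grid, and any non-finite evaluation.
* Initial profiles are transferred to the solver grid by linear
  interpolation with a flat tail beyond their last node.
* All randomness flows from explicit integer seeds; identical seeds give
  bitwise-identical suites, traces and results.

## Limitations

The model is strictly 1D and homogeneous (the layered solver relaxes only
the homogeneity); blood perfusion is absent, so in-vivo use of the layered
model is an approximation; the estimator can only return members of the
candidate family, so structurally different true profiles (e.g. double
peaks) are projected onto it; and accuracy beyond ~8 mm depth degrades
intrinsically — the surface simply carries little information about that
region within 120 s.
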