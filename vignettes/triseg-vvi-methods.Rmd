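---
title: "Biventricular mechanics and ventricular interdependence with trisegvvi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biventricular mechanics and ventricular interdependence with trisegvvi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`trisegvvi` simulates the mechanics and hemodynamics of the two cardiac
ventricles as a coupled system, for studying ventricular–ventricular
interaction (VVI): how dysfunction of one ventricle alters the function of
the other through the shared septum, the pericardium, and the closed
circulatory loop.  This vignette is the package's account of the model, its
assumptions, the parameters that matter, and the numerical and design
choices behind the implementation.

## The heart model

The ventricles are represented by the three-segment (TriSeg) idealization:
the LV free wall (LW), the interventricular septum (SW), and the RV free
wall (RW) are thick-walled spherical caps joined at a common circular
junction of radius $y_m$.  Each wall $i$ has an axial midwall displacement
$x_{m,i}$ (the x axis runs from LV to RV; $x_{m,LW} < 0 < x_{m,RW}$, and a
positive septal curvature means the septum bows into the RV).  The midwall
— the surface halfway through the wall thickness — carries all kinematics:

$$A_m = \pi\,(x_m^2 + y_m^2), \qquad
  C_m = \frac{2 x_m}{x_m^2 + y_m^2}, \qquad
  V_m = \frac{\pi}{6} x_m (x_m^2 + 3 y_m^2).$$

Myofiber strain follows the small-curvature expansion with
$z = 3 C_m V_w / (2 A_m)$:

$$\varepsilon_f = \tfrac12 \ln (A_m/A_{m,\mathrm{ref}})
  - \tfrac{1}{12} z^2 - 0.019\, z^4, \qquad
  L_s = L_\mathrm{ref} e^{\varepsilon_f},$$

and the representative midwall tension and its junction components are

$$T_m = \frac{\sigma V_w}{2 A_m}\Big(1 + \frac{z^2}{3} + \frac{z^4}{5}\Big),
\qquad T_x = T_m \sin\alpha,\; T_y = T_m \cos\alpha,\;
\sin\alpha = \frac{2 x_m y_m}{x_m^2 + y_m^2}.$$

At every instant the four unknowns $(x_{m,LW}, x_{m,SW}, x_{m,RW}, y_m)$
satisfy four equilibrium conditions: $\sum_i T_{x,i} = 0$,
$\sum_i T_{y,i} = 0$, and consistency of the two cavity volumes with the
midwall cap volumes (the midwall bisects each wall volume).  Chamber
pressures follow from the axial balance over the free-wall caps,
$P_{LV} = -2 T_{x,LW}/y_m$ and $P_{RV} = +2 T_{x,RW}/y_m$ (kPa converted to
mmHg by 1 mmHg = 0.133322 kPa), plus the pericardial pressure.

Note on the membrane law: because $\sigma$ is a *fiber* stress distributed
isotropically in the wall plane, a thin closed sphere built from this
machinery obeys $P = \sigma_f h / r$, i.e. the textbook Laplace relation
$P = 2\bar\sigma h/r$ with the isotropic-equivalent stress
$\bar\sigma = \sigma_f/2$.  The test suite checks this equivalence to 5%.
Any constant factor here is absorbed by the calibration below and cannot
affect simulated hemodynamics.

### Sarcomere laws

Total wall stress is $\sigma_i = k_{pas,i}\,\sigma_{pas} +
k_{act,i}\,\sigma_{act}$ with

$$\sigma_{pas} = (\nu_L (L_s - L_{c,0}))^\gamma, \qquad
  \sigma_{act} = \nu_L (L_c - L_{c,0})\,\frac{L_s - L_c}{L_{se,iso}}\,Y(t),
  \qquad
  \dot L_c = \Big(\frac{L_s - L_c}{L_{se,iso}} - 1\Big) v_{max}.$$

Defaults (lengths in micrometres): $L_\mathrm{ref} = 2$, $L_{c,0} = 1.51$,
$L_{se,iso} = 0.04$, $v_{max} = 3.5\ \mu m/s$.  $\nu_L = 1\ \mu m^{-1}$ is a
pure unit conversion; the stress scale lives entirely in $k_{pas}/k_{act}$,
so this choice is calibration-neutral.  Below slack ($L_s < L_{c,0}$) the
passive law is clamped to zero — tension cannot be negative.  The
activation $Y(t)$ is a phenomenological driving function: a half-cosine
rise over $T_S = k_{TS} T$ and fall over $T_R = k_{TR} T$
($k_{TS} = k_{TR} = 0.2$, $T = 60/HR$ s), zero elsewhere, with a common
beat onset for all three walls (no inter-wall activation delay).  $Y$
enters only the active stress, not the $L_c$ dynamics.

### Pericardium

$$P_{peri} = \exp\!\big(s\,(V_h/V_{h,0} - 1)\big) - 1 \quad \text{(mmHg)},$$

with $V_h = V_{LV} + V_{RV}$, $s = 10$, and $V_{h,0}$ set 25% above the
total end-diastolic chamber volume.  This form is zero at the reference
volume, bounded below by $-1$ mmHg (small negative values below $V_{h,0}$
are retained), and engages steeply outside the normal working range.  The
alternative reading $\exp(s V_h/V_{h,0}) - 1$ would give $\sim 2\times
10^4$ mmHg at the reference volume and is rejected as unphysical.  Atria
are not modeled as chambers (their volumes are folded into the venous
compartments), so they do not contribute to $V_h$.

## The circulation

Six compartments in a closed loop — LV, systemic arteries (SA), systemic
veins (SV), RV, pulmonary arteries (PA), pulmonary veins (PV) — with
ideal-diode valves (forward flow $\max(\Delta P, 0)/R$).  The mitral and
tricuspid resistances are $5\times10^{-4}$ mmHg s/mL; ejection passes
through diodes in series with the arterial viscoelastic components
$R_{t,SA} = 0.08$ and $R_{t,PA} = 0.02$ mmHg s/mL.  Reported arterial
pressures include the viscoelastic term $R_t\,\dot V$; venous compartments
are purely elastic.

Parameter derivation from the subject block: compartment volumes are fixed
fractions of total blood volume (LV 3%, SA 20%, SV 54%, RV 3%, PA 5%,
PV 15%); unstressed volumes are fractions of the compartment volume (SA
70%, SV 90%, PA 40%, PV 90% healthy); compliances are maximal stressed
volume over maximal pressure (e.g. $C_{SA} = 300/120 = 2.5$ mL/mmHg); and
$R_{sys} = (\bar P_{SA} - \bar P_{SV})/CO$,
$R_{pul} = (\bar P_{PA} - \bar P_{PV})/CO$ with $CO = SV \times HR$ from
the subject stroke volume (75 mL for the normative adult, giving
$R_{sys} \approx 1.213$ mmHg s/mL).

Two deliberate choices:

* **Disease unstressed-volume switch.**  Dysfunction simulations raise the
  stressed:unstressed ratio (SA 60%, SV 80%, PA 35%, PV 75% unstressed),
  emulating the venoconstrictive volume redistribution of heart failure.
  Compliances keep their healthy-column values: recomputing them from the
  disease stressed fraction would almost exactly cancel the redistribution
  at nominal volumes, defeating its purpose.  The switch therefore changes
  only where blood sits, not vessel wall properties.
* **Fixed unstressed volumes under loading.**  Volume loading scales the
  circulating volume while unstressed volumes stay at their
  parameterization values, so the added volume is entirely stressed and
  raises pressures — this is what makes compensation by volume loading
  work, and why the healthy compensated baseline sits slightly *below* the
  nominal 5 L.

The ventricular "fractions" only seed initial conditions; ventricular
pressures come exclusively from the TriSeg walls.

## Calibration

Calibration turns one set of routine measurements (arterial pressures,
ventricular ESP/EDP/ESV/EDV, total blood volume, heart rate) into a
subject-specific model in three steps.

**Geometry.**  The LV (LW + SW) is a thick sphere enclosing $EDV_{LV}$
with thickness 8 mm; wall volume and midwall area split 2/3 : 1/3 between
free wall and septum.  The RW comes from its own sphere around $EDV_{RV}$
with thickness 4 mm.  Because reference areas are anchored at the EDVs,
sarcomeres sit near $L_\mathrm{ref} = 2\ \mu m$ at end-diastole.

**Passive steepness $\gamma$.**  The Klotz single-beat method turns one
(EDP, EDV) pair into a full empirical EDPVR: $V_0 = EDV\,(0.6 - 0.006\,
EDP)$, $V_{30} = V_0 + (EDV - V_0)/(EDP/A_n)^{1/B_n}$ with $A_n = 27.78$
mmHg, $B_n = 2.76$, and the power law $P = \alpha V^\beta$ through
(EDV, EDP) and $(V_{30}, 30)$.  The model's ex vivo EDPVRs (static
inflation of both chambers, zero activation, no pericardium) are fitted to
the LV and RV Klotz curves jointly — the RV is assumed to share the LV's
material behavior — by least squares over a 40-point grid spanning 0.5–1.3
times EDV, with $k_{pas}$ re-anchored at every candidate $\gamma$ so that
only the *shape* drives the fit.  Parameter recovery on model-generated
reference curves is exact to better than three significant figures.

**Scaling factors.**  Per wall, $k_{pas,i} = EDP_i/(\Gamma_{i,d}\,
\sigma_{pas,i,d})$ at the end-diastolic configuration and $k_{act,i} =
ESP_i/(\Gamma_{i,s}\,\sigma_{act,i,s})$ at the end-systolic configuration
(built from the ESVs by the same spherical construction) with 60%
activation.  $\Gamma_i$ is computed numerically as the chamber pressure
produced by unit fiber stress in wall $i$ at the frozen configuration; the
septum is calibrated against its transmural pressures ($EDP_{LV} -
EDP_{RV}$, $ESP_{LV} - ESP_{RV}$).  Two refinements over a single-pass
evaluation:

* $\sigma_{pas,d}$ is evaluated at the *configuration's* end-diastolic
  sarcomere length rather than at a literal 2.0 $\mu m$.  The two agree to
  about 1% in length, but $\gamma \approx 7$ amplifies that to tens of
  percent in stress; using the configuration length makes the calibrated
  heart reproduce its own (EDV, EDP) anchor exactly and the calibration
  idempotent.  At end-systole $L_c$ takes its isometric quasi-steady value
  $L_s - L_{se,iso}$, so $\sigma_{act,s} = (L_s - L_{se,iso} - L_{c,0})\,Y$.
* Configuration and factors are iterated to a fixed point (the equilibrium
  geometry depends weakly on the relative wall stiffnesses); this
  converges in a handful of iterations.

```{r calibration}
library(trisegvvi)
subject <- subject_data()          # normative healthy 70-kg adult
cal <- calibrate_heart(subject)    # gamma fit + k_pas/k_act
cal
```

## Experiments

**Dysfunction.**  Acute systolic dysfunction scales $k_{act}$ of the
targeted walls to 60% (moderate) or 40% (severe); acute diastolic
dysfunction scales $k_{pas}$ by 7 or 15.  For LV dysfunction the septum is
part of the LV (LW and SW scaled jointly); RV dysfunction scales the RW
only.  Scaling is acute: the reference geometry is not re-derived (no
remodeling).  All dysfunction runs activate the disease unstressed-volume
column.

**Simulation protocol.**  The nine-state system (six compartment volumes,
three contractile lengths) is integrated with `deSolve::lsoda` at relative
tolerance $10^{-6}$ and absolute tolerance $10^{-8}$ mL, 20 beats of
transient washout plus 2 recorded beats at 500 samples per beat.  Each
right-hand-side evaluation performs the quasi-static wall solve: a damped
Newton iteration (relative tolerance $10^{-9}$, warm-started from the
previous evaluation).  If the warm-started 4-unknown Newton fails — which
can happen near valve-switching states at extreme stiffness — the solver
falls back to a reduced 2-unknown formulation in $(V_{m,SW}, y_m)$ in
which the volume constraints are enforced exactly by inverting the
monotone cap-volume cubic, then to perturbed geometric restarts, and
finally to a stress-continuation homotopy that ramps $k_{pas}/k_{act}$ up
from a soft configuration.  Closed-loop volume is conserved to machine
precision by construction; beat-to-beat periodicity after the transient is
$\sim 10^{-6}$ for the healthy protocol and $\sim 10^{-3}$ for the most
severely dilating dysfunction cases (the 20+2 protocol is retained there
rather than extending the transient).

**Compensation.**  The compensated baseline is the circulating volume at
which the cycle-mean systemic arterial pressure over the final beat equals
95 mmHg within 0.5 mmHg, found by bisection on total blood volume over
0.8–3.5 times the nominal value.  The lower bound sits below 100% because
the healthy baseline itself compensates slightly below nominal volume; the
350% upper bound is returned with a `compensated = FALSE` flag when the
target is unreachable (severe dysfunction).

```{r compensation}
circ <- derive_circulation_parameters(subject)
comp <- find_compensated_tbv(cal$heart, circ)
cardiac_metrics(comp$sim)
septal_curvature_timecourse(comp$sim)
```

**Metrics.**  From the final recorded beat: EDV/ESV as the volume
extremes, EDP/ESP as pressures at those instants, $SV = EDV - ESV$,
$EF = 100\,SV/EDV$, $CO = SV \times HR$, and cardiac power output as the
pressure–volume loop area times beat frequency
(1 mmHg mL = $1.33322\times10^{-4}$ J).  Septal curvature time courses are
phase-annotated from the valve flows; the isovolumic-relaxation plateau is
the mean curvature between aortic closure and mitral opening.

**Loading sweeps and loci.**  `volume_loading_sweep()` runs the model to
periodicity across circulating-volume fractions and assembles ESPVR,
EDPVR, and Frank–Starling loci from the per-beat end-systolic and
end-diastolic points.  Two operational definitions used by the test suite
deserve note, both consequences of the pericardial constraint at high
loading:

* The Frank–Starling relation (SV vs EDP) is monotone on the *ascending
  limb* only: once the pericardium pins the end-diastolic volume
  (around 1.4 times nominal volume for the healthy heart), SV falls on a
  descending limb while EDP keeps rising.
* "Apparent stiffening" of the LV under severe RV dysfunction is
  quantified as the slope of the rising-EDV branch of the LV
  end-diastolic locus over loading fractions 0.9–1.3.  Beyond that range
  every case's locus becomes near-vertical or backward-bending
  (pericardium-dominated), making slope comparisons degenerate.  On the
  rising branch the healthy slope is well below the severe RV systolic
  and diastolic dysfunction slopes even though LV wall properties are
  untouched — the interaction-mediated stiffening of interest.

**Heart-size (Klotz collapse) experiment.**  Reproducing the EDPVR
normalization across EDVs of 62.5–250 mL scales the wall thicknesses with
the linear dimension, $h \propto EDV^{1/3}$, preserving geometric
similarity (larger hearts have thicker walls).  Under similarity the
normalized curves collapse exactly; with thickness held fixed at all
sizes, a 62.5 mL chamber with an 8 mm wall is far from similar to a
250 mL one and the curves do not collapse.

## What the normative generator does and does not emulate

The default subject is a synthetic normative healthy adult (120/80 mmHg,
EDV 125 mL both ventricles, SV 75 mL, 5 L blood, HR 60), with LV ESP
derived as 1.05 times systolic pressure and RV EDP as a quarter of LV EDP.
Simulations inherit every idealization of that construction: spherical
walls with uniform properties, a single lumped compliance per vascular
bed, no atria, no valve regurgitation or stenosis, no baroreflex or
autonomic control (compensatory volume loading is the surrogate for
neurohumoral compensation), no pulse-wave propagation, and acute
dysfunction without remodeling.  Passing tests therefore demonstrate
internal consistency and faithful mechanics of this idealized system —
not agreement with any individual patient.  Heart-rate dependence is
exposed (`hr` argument everywhere) but all reference results are at
60 bpm.

One internal tension of the parameterization is worth knowing: at periodic
steady state the cardiac output is pinned by
$CO = (\bar P_{SA} - \bar P_{SV})/R_{sys}$, with $\bar P_{SV}$ held near
the RV filling pressure by the small tricuspid resistance.  With
$R_{sys}$ derived from the normative stroke volume (75 mL) and the
compensation target of 95 mmHg, the compensated flow is necessarily
around 4.7 L/min.  Reference tabulations that pair a 95 mmHg mean with a
4.1 L/min output imply a systemic resistance about 13% higher than this
recipe yields; quantities that scale with absolute flow (SV, LV power,
filling pressures at compensation) inherit that offset, while
flow-normalized quantities (ejection fractions, RV power, curvature,
$\gamma$) do not.

## Known limitations

* The quasi-static wall solve assumes mechanical equilibrium at every
  instant; wall inertia and viscoelasticity are absent.
* The passive law is a single power law; at extreme overstretch
  ($L_s \gtrsim 2.6\ \mu m$) real myocardium deviates.
* Severe dysfunction at high loading operates the pericardium far outside
  its calibrated range; results there are qualitative.
* The ex vivo inflation protocol inflates both chambers jointly at the
  EDV ratio; isolated single-chamber inflation would differ slightly
  through septal coupling.
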