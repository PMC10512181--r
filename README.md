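# trisegvvi

Mechanistic simulation of **ventricular–ventricular interaction**: a
three-segment (TriSeg) biventricular heart coupled to a six-compartment
closed-loop circulation, with subject-specific calibration and an
experiment suite for acute systolic/diastolic dysfunction of either
ventricle under compensatory volume loading.

The package is aimed at cardiovascular physiologists and modelers who want
to ask *system-level* questions — how does a failing right ventricle impair
left-ventricular filling? when does volume loading restore arterial
pressure, and at what cost in filling pressure and ventricular power? —
without finite-element cost.

## The model in brief

The LV free wall, septum, and RV free wall are thick-walled spherical caps
joined at a common junction circle; at every instant the displacements
solve a tension balance (ΣT_x = 0, ΣT_y = 0 plus the two cavity-volume
constraints), from which chamber pressures follow (P_LV = −2T_x,LW/y_m,
P_RV = +2T_x,RW/y_m, plus pericardial pressure
P_peri = exp(s(V_h/V_h0 − 1)) − 1).  Wall stress is
σ = k_pas (L_s − L_c0)^γ + k_act (L_c − L_c0)((L_s − L_c)/L_se,iso) Y(t)
with a half-cosine activation Y(t).  The circulation closes the loop
through systemic/pulmonary arterial and venous compliances, resistances
derived from normative pressures and cardiac output, and ideal-diode
valves.

Calibration needs only routine measurements (arterial pressures,
ventricular ESP/EDP/ESV/EDV, blood volume, heart rate): wall geometry from
the EDVs, the passive steepness γ by least-squares fit of the model's
ex vivo EDPVRs to Klotz single-beat curves, and per-wall stress scaling
factors k_pas/k_act from the end-diastolic/end-systolic pressures.  See the
methods vignette (`vignettes/triseg-vvi-methods.Rmd`) for the full account.

## Worked example

```r
library(trisegvvi)

subject <- subject_data()          # normative healthy 70-kg adult
cal <- calibrate_heart(subject)    # geometry + Klotz gamma fit + k_pas/k_act
cal
#> TriSeg calibration report
#>   gamma = 7.170 (Klotz fit)
#>   k_pas: LW 341.1, SW 542.4, RW 131.8
#>   k_act: LW 525.7, SW 736.2, RW 216
#>   Klotz fit SSE 1.577 mmHg^2 over 40 points x 2 ventricles

circ <- derive_circulation_parameters(subject)
comp <- find_compensated_tbv(cal$heart, circ)   # volume-load to mean 95 mmHg
comp$sim
#> TriSeg closed-loop simulation: HR 60 bpm, TBV 4488 mL, 20+2 beats
#>   volume conservation 4.7e-15 (relative), periodicity 4.9e-07
#>  ventricle       SV       EF       CO       CPO      ESP       EDP      ESV      EDV
#>         LV 78.17834 62.25461 4.690701 1.3092202 106.1091 4.3950131 47.40007 125.5784
#>         RV 78.17851 62.28048 4.690711 0.2378693  19.4697 0.4427178 47.34801 125.5265
```

Reading the output: γ ≈ 7.2 is the passive length–tension steepness that
makes the model's passive inflation curves overlay the empirical Klotz
EDPVRs of both ventricles.  The compensated healthy baseline settles at
4.49 L circulating volume; both ventricles eject the same stroke volume
(series circulation), the LV at ~62% ejection fraction and ~1.3 W of
pressure–volume power, the RV at ~0.24 W.  Dysfunction experiments start
from this calibrated heart, e.g.

```r
weak_lv <- apply_dysfunction(cal$heart,
                             dysfunction_spec("LV", "systolic", "severe"))
circ_d <- derive_circulation_parameters(subject, disease = TRUE)
find_compensated_tbv(weak_lv, circ_d)
```

and `run_study()` orchestrates the full healthy + 4-dysfunction × 2-severity
panel.  A thin command-line front end with `calibrate` / `simulate` /
`sweep` / `study` subcommands lives at `inst/scripts/trisegvvi`.

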