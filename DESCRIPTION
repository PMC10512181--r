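Package: trisegvvi
Title: TriSeg Biventricular Mechanics with a Closed-Loop Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic simulation of ventricular-ventricular interaction.
    Implements a three-segment (TriSeg) biventricular heart model in which the
    left ventricular free wall, septum, and right ventricular free wall are
    thick-walled spherical caps coupled by a tension balance at a shared
    junction, embedded in a six-compartment closed-loop lumped-parameter
    circulation with diode valves and a pericardial constraint.  Provides
    subject-specific parameterization from routine hemodynamic measurements,
    calibration of passive stiffness against Klotz single-beat end-diastolic
    pressure-volume relationships, and an experiment suite for acute systolic
    and diastolic dysfunction of either ventricle under compensatory volume
    loading, reporting stroke volume, ejection fraction, cardiac power output,
    ESPVR/EDPVR loci, Frank-Starling curves, and septal curvature dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
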