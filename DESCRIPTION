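Package: mir22sim
Title: Multiscale PK-PD Simulation of Nanoparticle-Delivered miRNA-22 Therapy in Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic tumor-compartment pharmacokinetic-pharmacodynamic
    (PK-PD) model of nanoparticle-delivered miRNA-22 therapy for
    triple-negative breast cancer, alone or combined with doxorubicin and
    anti-PD-L1 immunotherapy (atezolizumab). Provides the 17-state ordinary
    differential equation model with empirical tumor perfusion, vascular
    surface area, size-dependent nanoparticle clearance and hindered-pore
    permeability sub-models; stiff integration of dosing schedules with
    bolus events; allometric mouse-to-human translation; nonlinear
    least-squares calibration against longitudinal tumor-volume data;
    virtual-patient populations by Latin hypercube sampling with
    RECIST-analog response classification; local and global parameter
    sensitivity analysis of percent tumor growth inhibition; and
    Chou-Talalay median-effect analysis of drug synergy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
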