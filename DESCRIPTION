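Package: cavbtools
Title: Electrophysiology and Strain Dyssynchrony Analysis for the Chronic AV-Block Dog Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse cardiac electrophysiology and echocardiographic
    strain recordings from chronic atrioventricular-block (CAVB) dog
    experiments. Extracts per-beat fiducials from surface ECG, right
    ventricular monophasic action potential (MAP) and left ventricular
    unipolar electrogram (EGM) channels; computes rate-corrected intervals
    (Van de Water QTc), activation times, activation-recovery intervals
    (ARI), MAP duration at 80% repolarization, short-term variability of
    repolarization (STV), interventricular dispersion (dMAPD, dAT) and the
    intraventricular AT-ARI regression slope; detects and scores Torsade de
    Pointes episodes (n+1 rule, defibrillation-weighted arrhythmia score,
    inducibility); and quantifies radial-strain dyssynchrony (peak strain,
    onset, time-to-peak and their free-wall minus septum deltas). Includes a
    seeded synthetic-recording generator with full ground truth for
    validation, and a virtual-experiment pipeline emulating the sinus-rhythm,
    idioventricular, RV-apex-paced and biventricular-paced study arms with a
    dofetilide challenge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
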