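Package: eatfmri
Title: Simulation and Analysis Pipeline for the Error Awareness Task fMRI Paradigm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for event-related fMRI studies of error awareness using the
    Go/No-Go Error Awareness Task (EAT). Generates constrained EAT trial
    sequences, simulates behavioral responses, questionnaire traits and 4D BOLD
    runs with known ground truth, classifies aware and unaware commission
    errors, estimates hemodynamic impulse response functions by FIR
    deconvolution with gamma-variate fitting and percent-area activation,
    performs Monte Carlo cluster-extent group inference on paired t-maps, and
    links cluster activity to psychopathological trait scales via
    cross-validated lasso regression with bootstrap stability selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
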