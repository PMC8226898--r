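Package: focusurf
Title: Focused-Ultrasound Fields in Layered Tissue and Fast Surrogate Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-wave simulation of focused ultrasound from rectangular
    phased arrays in layered tissue: Rayleigh-Sommerfeld source planes, an
    angular-spectrum propagator with power-law attenuation and plane-wave
    transmission across tissue interfaces, acoustic intensity and power
    deposition, and a steady-state Pennes bio-heat solver. Includes a
    parameter-sweep driver that builds tabular datasets of focal-zone maxima
    (pressure, power deposition, temperature) over array element counts and
    focus depths, and a surrogate-modelling layer that trains and compares
    linear regression, regression trees, support vector regression and random
    forests on such datasets using RMSE, R-squared, AIC and BIC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite,
    rpart,
    e1071,
    randomForest,
    parallel
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
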