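Package: stenoscreen
Type: Package
Title: Virtual Patient Haemodynamics and Machine Learning Screening for Arterial Stenosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates virtual patient databases of the aorto-iliac
    bifurcation with a one-dimensional pulse-wave propagation model
    (tube-law closure, three-element Windkessel outflows, Fourier-series
    inlet flow), parameterises stenoses by severity and extent, and
    trains and evaluates binary and multiclass screening classifiers
    (cost-weighted logistic regression, SVM, naive Bayes, random forest;
    one-vs-all, one-vs-one and a custom probabilistic configuration)
    on standardised Fourier waveform features.  Includes combination
    searches over measurement subsets, like-for-like symmetry audits,
    learning curves, severity analysis and ROC/AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
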