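Package: crisprarNoise
Title: Independent Tuning of Gene Expression Mean and Noise with Paired
    CRISPR Activation and Repression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and analyses for tuning gene expression noise with a
    single dCas9 carrying both an activating and a repressing sgRNA
    (CRISPRar) on one bacterial promoter. Implements the two-state
    (telegraph) promoter model with CRISPR-modulated switching rates,
    including same-strand competitive inhibition and opposite-strand
    interference between the two sgRNA modules; estimation of regulation
    strengths from expression fold changes; flow-cytometry-style event
    statistics (gating, mean, noise as squared coefficient of variation,
    control normalization); noise-versus-inverse-mean linear fits and
    region-wise average deviations; empirical-rule classification and
    decision-tree selection of constructs with matched mean or matched
    noise; contour maps of mean and noise over the switching-rate plane;
    an exact Gillespie simulator used as a numerical oracle for the
    analytic moment formulas; and a reproducible synthetic cytometry data
    generator emulating the study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, GeneExpression, Software, FlowCytometry
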