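Package: lnmaudit
Title: Auditing Lesion Network Mapping Against Elementary Connectome Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to implement and audit lesion network mapping (LNM) and its
    symptom-weighted variant (sLNM) in atlas space. The LNM pipeline is
    provided both as the full per-lesion seed-connectivity procedure (one-
    sample t maps across a normative subject set, thresholding, group rules)
    and as its exact compressed linear form, the row-selection product of a
    lesion matrix with a group connectome. The package generates structured
    synthetic connectomes (modular, anticorrelated, gradient and hub
    structure), lesion sets with tunable spatial overlap, and symptom scores;
    extracts the elementary properties of a connectome (degree, principal
    gradients, Newman modules, anticorrelation fraction); implements spin
    permutation, degree-preserving rewiring and other null models; and runs
    diagnostic analyses quantifying how strongly LNM outputs converge onto
    the degree (row-summation) vector and other elementary properties of the
    input matrix, including sensitivity/specificity/conjunction test
    simulations over lesion-overlap sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
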