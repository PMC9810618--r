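Package: neoresponse
Title: Pathological Response and Multi-Omics Dynamics Under Neoadjuvant
    Immunotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of paired pre/post-treatment tumor
    multi-omics in neoadjuvant immunotherapy cohorts: pathological
    response classification (CPR/MPR/PPR+ and Becker tumor regression
    grades) with exact Clopper-Pearson binomial confidence intervals,
    purity-corrected variant-allele-fraction dynamics with mutation-fate
    classification and purity-balanced tumor mutational burden, subclone
    consistency checks, T-cell receptor repertoire metrics (clone
    expansion score, clonotype size classes, Shannon/D50 diversity, V/J
    usage, pairwise overlap), and configurable immune gene-set signature
    scoring. A fully synthetic cohort generator reproduces the
    statistical structure of such studies so the entire pipeline runs and
    is testable without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
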