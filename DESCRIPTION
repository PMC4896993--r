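Package: morphozone
Title: Geometric Morphometrics of Craniofacial Shape Across Hybrid Zones
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying multivariate shape transitions along
    admixture gradients with 3D landmark data. Implements generalized
    Procrustes superimposition with object- and matching-symmetry
    decomposition, centroid size, fluctuating-asymmetry scores, and shape-space
    dimensionality bookkeeping; multivariate shape statistics (two-sample
    Hotelling T2 tests on principal component scores, cross-validated linear
    discriminant analysis, permutation tests for multivariate regression of
    shape on covariates, between-group principal component analysis, Mantel
    tests, and angle tests for the directionality of shape-change vectors); an
    end-to-end hybrid-zone analysis pipeline producing tidy report tables; and
    a synthetic landmark-data generator that emulates a polygenic additive
    architecture of shape differences for testing and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
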