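Package: clinemorph
Title: Contact-Zone Analysis of Parapatric Species: Morphometrics, Clines,
    P-Matrix Comparison and Niche Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid and contact zones between parapatric
    species from individual-level data. Provides TPS landmark input/output and
    generalized Procrustes alignment, linear-discriminant species assignment
    with confidence filtering, estimation and comparison of phenotypic
    covariance (P) matrices via the angle between leading eigenvectors and an
    affine-invariant matrix distance with bootstrap significance,
    individual-based maximum-likelihood sigmoid cline fitting with
    profile-likelihood confidence intervals, a sliding-window P-matrix scan
    along a transect, variant filtering and hybrid-index based F1 detection
    from genotype matrices, environmental niche overlap (Schoener's D,
    Warren's I) with randomization similarity tests, and a synthetic
    contact-zone simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
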