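Package: isovct
Title: Variance-Component Score Tests for Isoform-Level Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint testing of all isoforms of a gene for differential
    expression from RNA-seq counts via a variance-component score test in a
    negative binomial (or Poisson) generalized linear mixed model.  The score
    statistic treats per-isoform disease effects as random; its null
    distribution is obtained either theoretically, from the efficient
    information after profiling out the per-isoform baselines, or empirically,
    by permuting group labels.  Includes a simulator for the generative model
    (per-isoform log-baselines and effects drawn from normal distributions,
    counts Poisson or negative binomial), scenario runners for type-I-error
    and power studies, and a dataset-level pipeline with Benjamini-Hochberg
    adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
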