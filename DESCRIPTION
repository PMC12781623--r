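Package: lexisom
Title: Dual Self-Organising-Map Model of the Comprehension-Production
    Vocabulary Gap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates early word learning with two Kohonen self-organising
    maps (auditory and visual) coupled by Hebbian cross-modal associations,
    and studies how processing perturbations (reduced map size, input noise,
    neighbourhood disruption) reshape the comprehension-production vocabulary
    gap, as in Williams syndrome. Provides the artificial-vocabulary stimulus
    generator, the training and lexical testing loop, trajectory metrics
    (area under the curve, quantisation error, categorisation rating), a
    statistical harness (exact binomial sign tests with one-sided
    Clopper-Pearson bounds, Benjamini-Hochberg correction, monotone I-spline
    smoothing), and a synthetic generator of CDI-style vocabulary cohorts for
    typically developing children and cross-syndrome comparison groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    splines,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
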