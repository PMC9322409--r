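Package: corcompat
Title: Significance-Filter Bias and Compatibility Curves for Pearson
    Correlations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo machinery for studying the behaviour of null
    hypothesis significance tests of Pearson correlations: p-value
    variability and statistical power across a grid of true correlations
    and sample sizes, and the conditional (significance-filtered)
    distributions of effect-size estimates that give rise to the winner's
    curse. Also constructs compatibility curves (p-value functions) for an
    observed bivariate sample, either parametrically through the Fisher z
    transformation or non-parametrically by paired bootstrap resampling,
    with compatibility-interval extraction at any level and plain-language
    reporting of estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    patchwork,
    optparse,
    withr
Config/testthat/edition: 3
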