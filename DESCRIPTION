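Package: introblocker
Title: Ancestral Haplotype Group Inference from Windowed Genetic Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions resequenced genomes of predominantly selfing species
    into non-overlapping genomic windows, computes binwise identity-by-state
    distances, assigns each window of each accession to an ancestral
    haplotype group (AHG) by average-linkage hierarchical clustering under a
    variant-density threshold, and threads labels across windows with a
    priority-order referring strategy followed by Bayesian smoothing.
    Includes a two-component Gaussian mixture fit of the log distance
    distribution for threshold derivation and divergence dating, downstream
    population statistics (Shannon diversity selection scan, copy number
    variation enriched blocks, donor contribution and coverage, saturation
    curves, AHG distance matrices), detection and dating of stable
    centromeric AHG blocks, and a tract-based admixture simulator with exact
    truth ancestry for validating inference accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
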