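Package: genomovar
Title: Genome-Based Taxonomy and Pan-Genome Dynamics for Bacterial Species Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for delineating genomovars within bacterial species
    complexes from whole-genome sequence data. Implements fragment-based
    average nucleotide identity (ANI), tetranucleotide usage correlation
    (TETRA), and a digital DNA-DNA hybridization (dDDH) estimate from
    summed local-match identities; homolog-family clustering and
    pan-genome categorization (cloud, shell, softcore, strict core);
    pan/core rarefaction with Heaps-law and exponential-decay curve
    fitting; neighbor-joining trees, Kendall-Colijn topology comparison
    with a random-tree null, and threshold-graph genomovar delineation;
    ancestral gene gain-loss inference under a two-state Markov model
    with a Wagner-parsimony cross-check; and screening for ordered
    multi-gene marker clusters such as the ectoine biosynthesis operon.
    A seeded synthetic species-complex generator provides ground-truth
    datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
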