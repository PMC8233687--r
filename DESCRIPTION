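Package: mutdensity
Title: Per-Gene Mutation Density and Expression-Rate Correlations in
    Experimental Evolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes per-gene observed-mutation counts and
    length-normalized mutation densities from metagenomic time series of
    long-term evolution experiments, and tests their rank association
    with gene-level covariates (mRNA abundance, protein abundance,
    protein-protein interaction degree) using two-sided Spearman tests
    with explicit tie and zero-count handling.  Includes a synthetic
    hypermutator-evolution generator with abundance-coupled purifying
    selection for end-to-end validation, and a configuration-driven
    pipeline that emits machine-readable reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
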