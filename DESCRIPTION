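Package: ogmstr
Title: Sizing Short Tandem Repeat Expansions from Optical Genome Mapping Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures short-tandem-repeat expansion length and somatic
    instability at single-molecule resolution from optical genome mapping
    (OGM) data, exemplified by the CTG18.1 trinucleotide repeat in TCF4.
    Builds in-silico reference label maps from FASTA by motif digestion,
    reads and writes the BNX/CMAP/XMAP label-map formats, selects
    locus-spanning molecules, converts inter-marker distances to
    per-molecule expansion sizes and repeat counts with the close-marker
    averaging correction, and summarises per-sample mosaicism with 200 bp
    histograms. Includes a synthetic molecule generator with tissue-specific
    mosaicism models and label/sizing noise, a simplified dynamic-programming
    label aligner for synthetic data, and the downstream instability
    statistics (Anderson-Darling normality, Spearman correlation with
    bootstrap CI, Mann-Whitney, paired Wilcoxon, and log-linear models with
    mean-centred interactions).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    nortest,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
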