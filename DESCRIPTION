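Package: archipelago
Title: Divergence-Island Genome Scans from Pooled Allele Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects divergence islands (DIs) between one marine and several
    independently derived freshwater populations from pool-seq allele
    frequencies, in the threespine stickleback tradition of genome scans.
    Provides marker-SNP polarization, a seed-and-extend sliding-window
    island scan with cross-population merging and marker-density filtering,
    per-island response/pervasiveness and core/periphery decomposition,
    the pairwise marker-SNP overlap statistic R with its frequency-band
    sharing correction, windowed Dxy and pi, and permutation tests of
    genomic clustering of islands with optional stratification by local
    recombination rate. A synthetic pool-seq generator with known ground
    truth supports end-to-end validation without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
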