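Package: ecothermo
Title: Eco-Thermodynamic Analysis of Methanogenic Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the energetics and ecology of anaerobic
    catabolism in methanogenic ecosystems such as anaerobic digesters.
    Computes standard and in-situ Gibbs free energy changes of catabolic
    reactions from a bundled table of transformed formation energies,
    performs ATP-yield bookkeeping over electron carriers (NADH, reduced
    ferredoxin, ETF, quinol), solves for maximum tolerable hydrogen partial
    pressures and classifies pathways as H2-sensitive or H2-tolerant.
    Provides rule-based metabolic reconstruction from genome annotation
    tables (pathway completeness, electron-carrier re-oxidation, operon
    co-localisation, conductive-pilin and multiheme-cytochrome sequence
    rules), metatranscriptome-based activity calling with RPKM
    normalisation, community-level statistics (Pearson screens, group t
    tests, PCA with confidence ellipses), and a synthetic community
    generator with planted metabolic niches for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Biostrings,
    igraph,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
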