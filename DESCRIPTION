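Package: metadia
Title: Untargeted Data-Independent Acquisition Metaproteomics
Version: 0.1.0
Authors@R:
    person("Metadia", "Developers", email = "metadia@example.org", role = c("aut", "cre"))
Description: Library-free analysis of data-independent acquisition (DIA)
    mass spectrometry data from complex microbial communities. DIA runs are
    deconvolved into DDA-like pseudospectra by two-dimensional ion-trace
    detection and elution-profile correlation, identified against a protein
    database with target-decoy FDR control, assembled into a pseudospectral
    library, quantified across runs by targeted fragment extraction, and
    summarised into peptide-centric taxonomic and functional profiles.
    Includes a ground-truth community and acquisition simulator for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    xml2,
    yaml,
    optparse,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
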