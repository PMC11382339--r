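Package: oligofrag
Title: Fragment-Ion Catalogues, Peak Assignment and 2DMS Simulation for
    Modified Oligonucleotides
Version: 0.1.0
Authors@R:
    person("oligofrag", "maintainers", email = "oligofrag@example.org",
           role = c("aut", "cre"))
Description: Generates exhaustive theoretical fragment-ion catalogues for
    chemically modified oligonucleotides (phosphorothioate backbones,
    LNA/cEt bridged sugars, methylated bases) using the McLuckey a/b/c/d
    and w/x/y/z cleavage nomenclature, including neutral losses, base
    losses from any ion type, internal fragments, adducts and charged base
    loss.  Assigns experimental peak lists to catalogues with ppm
    tolerances, classifies matches into a standard peak taxonomy, and
    reports sequence coverage and fragmentation efficiency.  Counts sulfur
    atoms from resolved fine-structure isotope patterns, and simulates
    two-dimensional FT-ICR MS acquisition with multi-scan accumulation,
    low-rank transient denoising and 2D-FFT processing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
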