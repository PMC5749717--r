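Package: mobius
Title: Golden Gate Simulation and Planning for the Mobius Assembly Cloning Standard
Version: 0.1.0
Authors@R:
    person("Mobius", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: In silico tools for hierarchical Golden Gate cloning with the
    Mobius Assembly standard: Type IIS digestion mechanics (BsaI, AarI),
    one-pot digestion-ligation simulation with overhang-matching product
    enumeration, two-level assembly planning for arbitrary numbers of
    transcriptional units, restriction-site domestication scanning and
    synonymous-codon editing, onboarding primer design, and a deterministic
    synthetic 16-vector toolkit for testing without external sequence
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
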