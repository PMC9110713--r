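Package: agodesign
Title: Design Toolkit for PfAgo Artificial-Restriction-Enzyme Plasmid Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automates the computational design of multi-fragment plasmid
    assemblies that use Pyrococcus furiosus Argonaute (PfAgo) loaded with
    single-stranded DNA guides as a programmable artificial restriction
    enzyme (ARE). Given an ordered set of DNA fragments defining a circular
    plasmid, the package designs 24-bp junction recognition sequences and
    their 16-nt guide pairs under digestion filters (GC content,
    G-quadruplexes, homopolymer runs, off-target k-mer uniqueness), screens
    the resulting 12-nt sticky ends against a ligase mismatch-fidelity model,
    designs tailed PCR primers with nearest-neighbor melting-temperature
    balancing, selects verification restriction digests with well-separated
    band patterns, proves each design scarless by in-silico
    digestion-ligation simulation, and compiles acoustic/tip-based
    liquid-handler picklists for robotic execution. A seeded synthetic-design
    generator makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
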