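Package: jumbophage
Title: Discovery and Ecology of Jumbo Phages in Gut Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying jumbo bacteriophages (genomes > 200 kb) from
    assembled metagenomic contigs and characterising their ecology. Implements a
    keyword/exclusion phage-calling rule with CRISPR spacer corroboration, a
    BUSCO-ratio false-positive filter, lifestyle assignment from lysogeny scores,
    alternative genetic-code detection by coding-density comparison, crAss-like
    phage classification by translated marker homology and fragment-based
    nucleotide identity, CRT-style CRISPR array detection with spacer-protospacer
    matching and interaction-network construction, reciprocal-best-hit orthologue
    fractions with neighbor-joining proteomic trees for family demarcation, and
    SparCC-style compositional correlation networks with bootstrap significance
    over breadth-filtered coverage abundances. Ships a synthetic-community
    generator that plants every signal the pipeline detects, with ground truth,
    so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
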