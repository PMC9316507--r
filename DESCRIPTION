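Package: circaid
Title: Full-Length Circular RNA Annotation, Divergent Primer Design, and
    Circular Feature Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterising full-length circular
    RNAs (circRNAs) from long, junction-spanning reads such as Sanger
    amplicon sequences. Provides gene-model loading and validation,
    seeded simulation of multi-exon loci, circRNAs with truncated exons
    and planted back-splice-junction homology, and rolling-circle reads;
    a back-splice junction annotator that chains exon matches, calls the
    junction with truncation offsets, quantifies junction-overlap
    ambiguity, and applies a junction-evidence confirmation rule;
    outward-facing (divergent) primer design with nested and semi-nested
    second rounds and in-silico PCR on circular templates; and circular
    feature scanners for open reading frames across the junction, miRNA
    seed sites, DRACH m6A consensus sites, and IUPAC RNA-binding-protein
    motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
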