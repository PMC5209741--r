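Package: ITSscreen
Title: Pseudogene and Recombinant Screening for Cloned Nuclear rDNA ITS Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnoses non-concerted evolution in cloned nuclear ribosomal DNA
    internal transcribed spacer (ITS) sequences. Delimits ITS1/5.8S/ITS2 on each
    clone by anchor alignment, screens clones for pseudogene signatures (reduced
    GC content relative to co-sample clones, substitutions in the conserved
    angiosperm 5.8S motifs M1-M3, loss of the ability to form helices B4-B8 of
    the 5.8S secondary structure), detects chimeric clones with a maximum
    chi-squared breakpoint statistic and sliding-window similarity profiles,
    and contrasts nucleotide diversity (k, Pi) between presumed functional and
    pseudogene copies. Includes a fully labelled synthetic rDNA clone generator
    (CpG-deamination GC erosion, motif/helix lesions, deletions, spliced
    chimeras) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
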