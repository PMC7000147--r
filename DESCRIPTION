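Package: tissplice
Title: Tissue-Specific Splice Junctions and Junction-Peptide Databases from
    RNA-Seq Junction Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers tissue-specific splice junctions from STAR SJ.out.tab
    junction tables using empirical percent-spliced-in (PSI) estimates and a
    pairwise dPSI scoring system, builds splice-junction peptide databases
    (66-nt junction windows, three-frame translation, stop-codon and
    junction-position filters, composition-preserving shuffled decoys) for
    proteogenomic searches, and post-processes mass-spectrometry
    identification tables (target-decoy FDR, distributed normalized spectral
    abundance factors, junction-spanning peptide mapping). Also provides
    expression thresholds (TPM, calibration-curve cutoff) and nuclear-envelope
    gene-set enrichment statistics, together with a synthetic-data generator
    that plants tissue-specific junctions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
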