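# Fixture builders shared across test files. Everything is generated in code;
# no data files are read from disk except temp files written by the tests.

# A stop-free contig: "GCT" repeated reads Ala/Leu/Cys in the three frames
# and contains no stop codon in any frame.
stopfree_genome <- function(n_codons = 200, chrom = "chrA") {
  g <- Biostrings::DNAStringSet(paste(rep("GCT", n_codons), collapse = ""))
  names(g) <- chrom
  g
}

make_sj <- function(chrom, intron_start, intron_end, strand = "+",
                    unique_reads = 10, annotated = FALSE, motif = 0L,
                    multi_reads = 0L, max_overhang = 40L) {
  data.frame(chrom = chrom, intron_start = as.integer(intron_start),
             intron_end = as.integer(intron_end), strand = strand,
             motif = as.integer(motif), annotated = annotated,
             unique_reads = as.integer(unique_reads),
             multi_reads = as.integer(multi_reads),
             max_overhang = as.integer(max_overhang),
             stringsAsFactors = FALSE)
}

# A junction_window built directly from its two flanks (transcription order).
make_window <- function(upstream, downstream, strand = "+",
                        key = "chrT:100-200(+)") {
  structure(list(window = paste0(upstream, downstream),
                 junction_offset_nt = nchar(upstream),
                 upstream_flank = upstream, downstream_flank = downstream,
                 strand = strand, clipped = FALSE, key = key),
            class = "junction_window")
}

# Ordered pairwise dPSI records for one junction given per-tissue PSI values.
make_dpsi <- function(psi_by_tissue, chrom = "chr1", intron_start = 100L,
                      intron_end = 300L, strand = "+") {
  tissues <- names(psi_by_tissue)
  rows <- list()
  for (a in tissues) for (b in setdiff(tissues, a)) {
    rows[[paste(a, b)]] <- data.frame(
      chrom = chrom, intron_start = intron_start, intron_end = intron_end,
      strand = strand, annotated = FALSE, cond_a = a, cond_b = b,
      dpsi = psi_by_tissue[[a]] - psi_by_tissue[[b]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact two-sided p of a 2x2 table by hypergeometric enumeration (the
# independent oracle for exact_test_2x2): sum the probabilities of all
# tables with the observed margins whose probability does not exceed the
# observed table's.
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  p <- exp(logp)
  obs <- p[match(a, k)]
  sum(p[p <= obs * (1 + 1e-7)])
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                      "I", "K", "L", "M", "N", "P", "Q",
                                      "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

residue_multiset <- function(x) sort(strsplit(x, "")[[1]])
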