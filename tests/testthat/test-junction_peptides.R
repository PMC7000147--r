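# Junction windows, three-frame translation with stop rules, novel-region
# peptides, validation, redundancy removal, decoys and database assembly.

test_that("extract_window takes 66 nt of exonic context on each side", {
  genome <- stopfree_genome(200)  # 600 nt
  j <- data.frame(chrom = "chrA", intron_start = 151, intron_end = 310)
  w <- extract_window(j, genome, strand = "+")
  expect_equal(nchar(w$window), 132L)
  expect_equal(w$junction_offset_nt, 66L)
  expect_false(w$clipped)
  expect_equal(w$upstream_flank,
               as.character(Biostrings::subseq(genome[[1]], 85, 150)))
  expect_equal(w$downstream_flank,
               as.character(Biostrings::subseq(genome[[1]], 311, 376)))
})

test_that("windows near the contig edge are clipped and flagged", {
  genome <- stopfree_genome(200)
  j <- data.frame(chrom = "chrA", intron_start = 11, intron_end = 310)
  w <- extract_window(j, genome, strand = "+")
  expect_equal(nchar(w$upstream_flank), 10L)
  expect_equal(nchar(w$window), 76L)
  expect_equal(w$junction_offset_nt, 10L)
  expect_true(w$clipped)
  expect_error(extract_window(data.frame(chrom = "chrZ", intron_start = 10,
                                         intron_end = 20), genome),
               "absent")
})

test_that("minus-strand windows are the reverse complement, offset mirrored", {
  set.seed(55)
  genome <- Biostrings::DNAStringSet(
    paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = ""))
  names(genome) <- "chrA"
  j <- data.frame(chrom = "chrA", intron_start = 200, intron_end = 350)
  wp <- extract_window(j, genome, strand = "+")
  wm <- extract_window(j, genome, strand = "-")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_equal(wm$window, rc(wp$window))
  expect_equal(wm$junction_offset_nt,
               nchar(wp$window) - wp$junction_offset_nt)
})

test_that("a stop-free 132-nt window gives 44/43/43-aa frame peptides", {
  w <- make_window(strrep("GCT", 22), strrep("GCT", 22))
  p <- translate_window(w)
  expect_equal(nrow(p), 3)
  expect_equal(nchar(p$sequence), c(44L, 43L, 43L))
  expect_equal(p$junction_offset_aa, c(22L, 21L, 21L))
  expect_false(any(grepl("*", p$sequence, fixed = TRUE)))
})

test_that("a stop codon before the junction removes that frame", {
  up <- paste0(strrep("GCT", 11), "TAA", strrep("GCT", 10))  # TAA @ nt 34-36
  w <- make_window(up, strrep("GCT", 22))
  p <- translate_window(w)
  expect_false(0L %in% p$frame)
  expect_setequal(p$frame, c(1L, 2L))
})

test_that("a stop after the junction truncates the peptide, which is kept", {
  dn <- paste0(strrep("GCT", 3), "TGA", strrep("GCT", 18))  # in-frame @ +9 nt
  w <- make_window(strrep("GCT", 22), dn)
  p <- translate_window(w)
  f0 <- p[p$frame == 0L, ]
  expect_equal(nrow(f0), 1)
  expect_equal(nchar(f0$sequence), 25L)  # 22 before + 3 after the junction
  expect_equal(f0$junction_offset_aa, 22L)
})

test_that("codons containing N translate to X", {
  up <- paste0(strrep("GCT", 21), "GNT")
  w <- make_window(up, strrep("GCT", 22))
  f0 <- translate_window(w)
  f0 <- f0[f0$frame == 0L, ]
  expect_equal(substr(f0$sequence, 22, 22), "X")
})

test_that("unstranded windows are translated on both strands", {
  w <- make_window(strrep("GCT", 22), strrep("GCT", 22), strand = ".")
  p <- translate_window(w)
  expect_equal(nrow(p), 6)
  expect_setequal(unique(p$sense), c("+", "-"))
})

test_that("novel-region translation enforces the 7-aa floor", {
  # 18 stop-free nt: frame 0 gives 6 aa -> dropped (frames 1/2 give 5)
  expect_equal(nrow(translate_novel_region(strrep("GCT", 6))), 0)
  # 21 stop-free nt: frame 0 gives exactly 7 aa -> kept
  p <- translate_novel_region(strrep("GCT", 7))
  expect_equal(nrow(p), 1)
  expect_equal(nchar(p$sequence), 7L)
  expect_equal(p$frame, 0L)
  # a leading stop empties frame 0
  p2 <- translate_novel_region(paste0("TAA", strrep("GCT", 12)))
  expect_false(0L %in% p2$frame)
})

test_that("junction-position validation enforces the 22/22 rule", {
  expect_true(validate_junction_peptide(44, 22))
  expect_false(validate_junction_peptide(44, 0))    # not junction-spanning
  expect_false(validate_junction_peptide(30, 20))   # only 10 aa after
  expect_false(validate_junction_peptide(50, 23))   # starts too far in
  expect_true(validate_junction_peptide(43, 21))
})

test_that("every emitted junction database entry spans its junction", {
  set.seed(91)
  genome <- Biostrings::DNAStringSet(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- paste0("chr", 1:4)
  js <- data.frame(chrom = sample(names(genome), 20, replace = TRUE),
                   intron_start = sample(100:300, 20),
                   stringsAsFactors = FALSE)
  js$intron_end <- js$intron_start + sample(60:200, 20)
  js$strand <- sample(c("+", "-"), 20, replace = TRUE)
  e <- junction_peptide_entries(js, genome)
  expect_true(all(validate_junction_peptide(nchar(e$sequence),
                                            e$junction_offset_aa)))
  expect_true(all(nchar(e$sequence) <= 44))
  expect_true(all(startsWith(e$accession, "jnc|")))
})

test_that("mirrored minus-strand construction yields identical peptides", {
  set.seed(92)
  L <- 600L
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
  genome_fwd <- Biostrings::DNAStringSet(seq)
  names(genome_fwd) <- "chrA"
  genome_rev <- Biostrings::DNAStringSet(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))))
  names(genome_rev) <- "chrA"
  fwd <- junction_peptide_entries(
    data.frame(chrom = "chrA", intron_start = 200, intron_end = 350,
               strand = "+"), genome_fwd)
  rev <- junction_peptide_entries(
    data.frame(chrom = "chrA", intron_start = L - 350 + 1,
               intron_end = L - 200 + 1, strand = "-"), genome_rev)
  expect_setequal(fwd$sequence, rev$sequence)
  expect_equal(sort(fwd$junction_offset_aa), sort(rev$junction_offset_aa))
})

test_that("dedupe_entries collapses exact duplicates and is idempotent", {
  e <- data.frame(accession = c("a", "b", "c"),
                  sequence = c("PEPTIDE", "PEPTIDE", "PEPTIDX"),
                  stringsAsFactors = FALSE)
  d <- dedupe_entries(e)
  expect_equal(d$accession, c("a", "c"))
  expect_identical(dedupe_entries(d), d)
})

test_that("decoys preserve length and residue composition per target", {
  e <- data.frame(accession = c("t1", "t2", "t3"),
                  sequence = c("PEPTIDE", "M", "MKLAAAQRSTVWY"),
                  stringsAsFactors = FALSE)
  d <- make_decoys(e, seed = 7)
  expect_equal(d$accession, paste0("decoy_", e$accession))
  expect_equal(nchar(d$sequence), nchar(e$sequence))
  for (i in seq_len(nrow(e))) {
    expect_identical(residue_multiset(d$sequence[i]),
                     residue_multiset(e$sequence[i]))
  }
  expect_identical(d$sequence[2], "M")
  expect_identical(make_decoys(e, seed = 7), d)   # deterministic
  expect_false(identical(make_decoys(e, seed = 8)$sequence[3],
                         d$sequence[3]))
})

test_that("assemble_database pairs every target with one decoy", {
  set.seed(12)
  ref <- data.frame(accession = paste0("REF", 1:10),
                    sequence = vapply(1:10, function(i) random_aa(40),
                                      character(1)))
  cont <- data.frame(accession = c("KER1", "TRYP"),
                     sequence = c(random_aa(30), random_aa(25)))
  jp <- data.frame(accession = paste0("J", 1:3),
                   sequence = vapply(1:3, function(i) random_aa(44),
                                     character(1)),
                   junction_offset_aa = 22L, kind = "novel-junction",
                   source = paste0("chr1:", 1:3, "00-500(+)"))
  db <- assemble_database(ref, cont, jp, seed = 3)
  expect_equal(db$summary$n_targets, 15)
  expect_equal(db$summary$n_decoys, 15)
  expect_equal(db$summary$n_total, 30)
  expect_equal(db$summary$contaminant, 2L)
  expect_equal(sum(db$entries$category == "decoy"), 15)

  # decoy multiset invariant holds globally
  targets <- db$entries[db$entries$category != "decoy", ]
  decoys <- db$entries[db$entries$category == "decoy", ]
  expect_identical(sort(unlist(strsplit(targets$sequence, ""))),
                   sort(unlist(strsplit(decoys$sequence, ""))))
  expect_error(assemble_database(ref[0, ]), "no target")
})

test_that("redundant sequences collapse before decoy generation", {
  ref <- data.frame(accession = paste0("REF", 1:10),
                    sequence = vapply(1:10, function(i) random_aa(40),
                                      character(1)))
  jp <- data.frame(accession = c("Jdup", "J2", "J3"),
                   sequence = c(ref$sequence[1], random_aa(44),
                                random_aa(44)),
                   junction_offset_aa = 22L, kind = "novel-junction",
                   source = "chr1:100-500(+)")
  db <- assemble_database(ref, junction_peptides = jp, seed = 3)
  expect_equal(db$summary$n_redundant_removed, 1L)
  expect_equal(db$summary$n_targets, 12)
  expect_equal(db$summary$n_decoys, 12)
  # the surviving copy is the first-seen (reference) entry
  expect_false("Jdup" %in% db$entries$accession)
})

test_that("write_database emits a readable FASTA and manifest", {
  ref <- data.frame(accession = "P1", sequence = "MKLPEPTIDEQRST")
  db <- assemble_database(ref, seed = 1)
  fa <- withr::local_tempfile(fileext = ".fa")
  mf <- withr::local_tempfile(fileext = ".tsv")
  man <- write_database(db, fa, mf)
  back <- read_fasta(fa)
  expect_equal(back$id, db$entries$accession)
  expect_equal(back$seq, db$entries$sequence)
  tsv <- utils::read.delim(mf)
  expect_equal(tsv$length, nchar(db$entries$sequence))
})
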