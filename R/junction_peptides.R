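# Construction of the proteogenomic search database: junction windows,
# three-frame translation with stop-codon rules, novel-region peptides,
# redundancy removal, composition-preserving shuffled decoys and the
# junction-position validation of candidate peptides.

#' Extract the nucleotide window around a splice junction
#'
#' The junction's coordinates are extended by `flank` nucleotides in both
#' directions: the window is the `flank` nt immediately 5' of the intron
#' joined to the `flank` nt immediately 3' of it (the spliced exonic
#' context). For genes on the minus strand the window is
#' reverse-complemented so that it reads in transcription order, and the
#' junction offset is mirrored. Flanks are clipped (and flagged) at
#' chromosome ends.
#'
#' @param junction One-row junction data frame or list with `chrom`,
#'   `intron_start`, `intron_end`.
#' @param genome Named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param strand Gene strand: `"+"`, `"-"` or `"."` (unknown; the window is
#'   returned in plus orientation and translated on both strands
#'   downstream).
#' @param flank Flank length in nt (default 66).
#' @return List of class `junction_window`: `window` (character, in
#'   transcription order for stranded genes), `junction_offset_nt`
#'   (= number of window nt 5' of the boundary), `upstream_flank`,
#'   `downstream_flank` (transcription order), `strand`, `clipped`, `key`.
#' @export
extract_window <- function(junction, genome, strand = "+", flank = 66) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chrom <- as.character(junction$chrom)
  if (!chrom %in% names(genome)) {
    stop("chromosome ", chrom, " absent from genome")
  }
  s <- as.integer(junction$intron_start)
  e <- as.integer(junction$intron_end)
  stopifnot(s <= e, flank > 0)
  len <- Biostrings::width(genome[chrom])
  if (s < 1 || e > len) stop("junction outside chromosome bounds")
  up_start <- max(1L, s - as.integer(flank))
  dn_end <- min(len, e + as.integer(flank))
  up <- as.character(Biostrings::subseq(genome[[chrom]], up_start, s - 1L))
  dn <- as.character(Biostrings::subseq(genome[[chrom]], e + 1L, dn_end))
  clipped <- nchar(up) < flank || nchar(dn) < flank
  if (strand == "-") {
    rc <- function(x) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(x)))
    upstream <- rc(dn)
    downstream <- rc(up)
  } else {
    upstream <- up
    downstream <- dn
  }
  structure(list(
    window = paste0(upstream, downstream),
    junction_offset_nt = nchar(upstream),
    upstream_flank = upstream,
    downstream_flank = downstream,
    strand = strand,
    clipped = clipped,
    key = junction_key(chrom, s, e, strand)
  ), class = "junction_window")
}

# Translate one reading frame of a window and apply the stop-codon rules:
# a stop at or before the codon containing the junction boundary kills the
# candidate; a stop after it truncates the peptide there.
.translate_frame <- function(window_nt, offset_nt, frame) {
  usable <- nchar(window_nt) - frame
  n3 <- (usable %/% 3L) * 3L
  if (n3 < 3L) return(NULL)
  nt <- substr(window_nt, frame + 1L, frame + n3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  off_aa <- (offset_nt - frame) %/% 3L
  if (offset_nt - frame <= 0L) return(NULL)  # boundary precedes the frame
  boundary_codon <- ceiling((offset_nt - frame) / 3)
  stops <- which(strsplit(aa, "")[[1]] == "*")
  if (any(stops <= boundary_codon)) return(NULL)
  if (length(stops)) aa <- substr(aa, 1L, min(stops) - 1L)
  if (nchar(aa) == 0L) return(NULL)
  list(sequence = aa, junction_offset_aa = off_aa)
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Three-frame translation of a junction window
#'
#' Translates the window in frames 0, 1 and 2 with the standard genetic code
#' (codons containing N translate to `X`). A candidate is removed when a
#' stop codon occurs at or before the codon containing the junction
#' boundary, and truncated at the first stop after it. For an unclipped
#' stop-free window with 66-nt flanks this yields ~44-aa peptides with the
#' junction 22 residues in. Windows from unstranded junctions (`strand ==
#' "."`) are additionally translated in the three frames of the reverse
#' complement, giving up to six candidates.
#'
#' @param window A `junction_window` from [extract_window()].
#' @param kind Peptide category carried through to the database (default
#'   `"novel-junction"`).
#' @return Data frame `sequence`, `frame`, `sense` (`+`/`-` relative to the
#'   window), `junction_offset_aa`, `source` (junction key), `kind`; zero
#'   rows when no frame survives.
#' @export
translate_window <- function(window, kind = "novel-junction") {
  stopifnot(inherits(window, "junction_window"))
  senses <- if (identical(window$strand, ".")) c("+", "-") else "+"
  rows <- list()
  for (sense in senses) {
    nt <- if (sense == "+") window$window else .revcomp_chr(window$window)
    off <- if (sense == "+") window$junction_offset_nt
           else nchar(window$window) - window$junction_offset_nt
    for (f in 0:2) {
      tr <- .translate_frame(nt, off, f)
      if (is.null(tr)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = tr$sequence, frame = f, sense = sense,
        junction_offset_aa = tr$junction_offset_aa,
        source = window$key, kind = kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(), frame = integer(),
                      sense = character(), junction_offset_aa = integer(),
                      source = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-frame translation of a novel exon or retained intron
#'
#' Each frame is translated with the standard genetic code and truncated at
#' its first stop codon; translations shorter than `min_len` amino acids are
#' discarded. Minus-strand sequences are reverse-complemented first;
#' unstranded input (`strand == "."`) is translated on both strands.
#'
#' @param sequence Nucleotide sequence of the novel region.
#' @param strand `"+"`, `"-"` or `"."`.
#' @param min_len Minimum peptide length to keep (default 7).
#' @return Data frame `sequence`, `frame`, `sense`.
#' @export
translate_novel_region <- function(sequence, strand = "+", min_len = 7) {
  senses <- if (identical(strand, ".")) c("+", "-") else "+"
  nt0 <- if (identical(strand, "-")) .revcomp_chr(sequence) else sequence
  rows <- list()
  for (sense in senses) {
    nt <- if (sense == "+") nt0 else .revcomp_chr(nt0)
    for (f in 0:2) {
      n3 <- ((nchar(nt) - f) %/% 3L) * 3L
      if (n3 < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(nt, f + 1L, f + n3)),
        if.fuzzy.codon = "X"))
      stop_at <- regexpr("*", aa, fixed = TRUE)
      if (stop_at > 0) aa <- substr(aa, 1L, stop_at - 1L)
      if (nchar(aa) < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = aa, frame = f, sense = sense, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(), frame = integer(),
                      sense = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate that a candidate peptide truly spans its junction
#'
#' A junction peptide passes when its sequence crosses the splice boundary
#' with the start at most `max_start` residues before the junction and the
#' end at least `min_end` residues after it (22/22 for 66-nt flanks), and at
#' least one residue on the upstream side.
#'
#' @param length_aa Peptide length in residues (vectorized).
#' @param junction_offset_aa Residues 5' of the boundary (vectorized).
#' @param max_start Maximum allowed offset of the junction from the peptide
#'   start (default 22).
#' @param min_end Minimum residues after the junction (default 22).
#' @return Logical vector.
#' @export
validate_junction_peptide <- function(length_aa, junction_offset_aa,
                                      max_start = 22, min_end = 22) {
  junction_offset_aa >= 1 &
    junction_offset_aa <= max_start &
    (length_aa - junction_offset_aa) >= min_end
}

#' Junction database entries from a junction table and genome
#'
#' Runs [extract_window()] and [translate_window()] over every junction,
#' keeps only candidates passing [validate_junction_peptide()], and formats
#' accessions as
#' `jnc|chrom:start-end(strand)|frame=f|off=aa|kind=kind`.
#'
#' @param junctions Junction data frame (already filtered as desired); its
#'   `strand` column gives the translation direction per junction.
#' @param genome Named [Biostrings::DNAStringSet] or character vector.
#' @param flank Flank length in nt (default 66).
#' @param kind Category label for these entries.
#' @param max_start,min_end Junction-position validation bounds.
#' @return Data frame `accession`, `sequence`, `category` (`"junction"`),
#'   `junction_offset_aa`, `kind`, `source`, `frame`, `sense`, `clipped`.
#' @export
junction_peptide_entries <- function(junctions, genome, flank = 66,
                                     kind = "novel-junction",
                                     max_start = 22, min_end = 22) {
  rows <- list()
  for (i in seq_len(nrow(junctions))) {
    win <- extract_window(junctions[i, ], genome,
                          strand = junctions$strand[i], flank = flank)
    peps <- translate_window(win, kind = kind)
    if (nrow(peps) == 0) next
    ok <- validate_junction_peptide(nchar(peps$sequence),
                                    peps$junction_offset_aa,
                                    max_start, min_end)
    peps <- peps[ok, ]
    if (nrow(peps) == 0) next
    peps$clipped <- win$clipped
    rows[[length(rows) + 1L]] <- peps
  }
  if (!length(rows)) {
    return(data.frame(accession = character(), sequence = character(),
                      category = character(), junction_offset_aa = integer(),
                      kind = character(), source = character(),
                      frame = integer(), sense = character(),
                      clipped = logical(), stringsAsFactors = FALSE))
  }
  peps <- do.call(rbind, rows)
  data.frame(
    accession = sprintf("jnc|%s|frame=%d|off=%d|kind=%s",
                        peps$source, peps$frame, peps$junction_offset_aa,
                        peps$kind),
    sequence = peps$sequence,
    category = "junction",
    junction_offset_aa = peps$junction_offset_aa,
    kind = peps$kind,
    source = peps$source,
    frame = peps$frame,
    sense = peps$sense,
    clipped = peps$clipped,
    stringsAsFactors = FALSE)
}

#' Collapse exactly redundant sequences
#'
#' Exact full-sequence duplicates are collapsed to the first-seen entry
#' (idempotent).
#'
#' @param entries Data frame with a `sequence` column.
#' @return The de-duplicated rows.
#' @export
dedupe_entries <- function(entries) {
  out <- entries[!duplicated(entries$sequence), ]
  rownames(out) <- NULL
  out
}

#' Composition-preserving shuffled decoys
#'
#' One decoy per target entry: a seeded uniform permutation of the target's
#' residues, so decoy length and amino-acid composition equal the target's.
#' Decoy accessions are prefixed `decoy_`.
#'
#' @param entries Data frame with `accession` and `sequence`.
#' @param seed RNG seed (decoy sets are reproducible for a fixed seed).
#' @return Data frame `accession`, `sequence`, `category` (`"decoy"`),
#'   `paired_target`.
#' @export
make_decoys <- function(entries, seed = 1) {
  stopifnot(nrow(entries) > 0)
  set.seed(seed %% .Machine$integer.max)
  shuffled <- vapply(entries$sequence, function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(accession = paste0("decoy_", entries$accession),
             sequence = shuffled,
             category = "decoy",
             paired_target = entries$accession,
             stringsAsFactors = FALSE)
}

#' Assemble the final target-decoy search database
#'
#' Targets are the exact-redundancy-collapsed union of reference proteins,
#' contaminants, junction peptides and novel-region peptides (in that
#' precedence order); decoys are composition-preserving shuffles of every
#' target, so the decoy count equals the full target count (references +
#' contaminants + junction/novel sequences) and the database holds twice the
#' target count in total.
#'
#' @param reference Data frame `accession`, `sequence` of reference
#'   proteins.
#' @param contaminants Optional contaminants data frame (user supplied,
#'   typically keratins and proteases).
#' @param junction_peptides Optional data frame from
#'   [junction_peptide_entries()].
#' @param novel_region Optional data frame `accession`, `sequence` of
#'   novel-exon / intron-retention peptides.
#' @param seed Decoy shuffle seed.
#' @return List with `entries` (targets then decoys; columns `accession`,
#'   `sequence`, `category`, `paired_target`, plus junction metadata columns
#'   where applicable) and `summary` (named counts).
#' @export
assemble_database <- function(reference, contaminants = NULL,
                              junction_peptides = NULL, novel_region = NULL,
                              seed = 1) {
  as_entries <- function(x, category) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    data.frame(accession = x$accession, sequence = x$sequence,
               category = category,
               junction_offset_aa =
                 if ("junction_offset_aa" %in% names(x))
                   x$junction_offset_aa else NA_integer_,
               kind = if ("kind" %in% names(x)) x$kind else NA_character_,
               source = if ("source" %in% names(x)) x$source
                        else NA_character_,
               stringsAsFactors = FALSE)
  }
  targets <- rbind(as_entries(reference, "reference"),
                   as_entries(contaminants, "contaminant"),
                   as_entries(junction_peptides, "junction"),
                   as_entries(novel_region, "novel-region"))
  if (is.null(targets) || nrow(targets) == 0) {
    stop("cannot assemble a database with no target sequences")
  }
  n_before <- nrow(targets)
  targets <- dedupe_entries(targets)
  targets$paired_target <- NA_character_
  decoys <- make_decoys(targets, seed = seed)
  decoys$junction_offset_aa <- NA_integer_
  decoys$kind <- NA_character_
  decoys$source <- NA_character_
  decoys <- decoys[, names(targets)]
  entries <- rbind(targets, decoys)
  rownames(entries) <- NULL
  cat_counts <- table(factor(targets$category,
                             levels = c("reference", "contaminant",
                                        "junction", "novel-region")))
  summary <- c(as.list(cat_counts),
               list(n_redundant_removed = n_before - nrow(targets),
                    n_targets = nrow(targets),
                    n_decoys = nrow(decoys),
                    n_total = nrow(entries)))
  list(entries = entries, summary = summary)
}

#' Write a database to FASTA plus a TSV manifest
#'
#' @param db List from [assemble_database()].
#' @param fasta_path,manifest_path Output paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the manifest data frame (`accession`, `category`,
#'   `length`, `source`).
#' @export
write_database <- function(db, fasta_path = NULL, manifest_path = NULL) {
  entries <- db$entries
  if (!is.null(fasta_path)) {
    write_fasta(data.frame(id = entries$accession, desc = "",
                           seq = entries$sequence), fasta_path)
  }
  manifest <- data.frame(accession = entries$accession,
                         category = entries$category,
                         length = nchar(entries$sequence),
                         source = entries$source,
                         stringsAsFactors = FALSE)
  if (!is.null(manifest_path)) {
    utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(manifest)
}
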