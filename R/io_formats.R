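# Reading/writing of the standard formats the pipeline touches.
# All genomic coordinates held in memory are 1-based inclusive (the SJ.out.tab
# and GTF convention); BED export converts to 0-based half-open explicitly.

#' Build the canonical identity key of a splice junction
#'
#' Junction identity is `(chrom, intron_start, intron_end, strand)`, formatted
#' as `chrom:start-end(strand)`. Coordinates are the 1-based first and last
#' base of the intron.
#'
#' @param chrom Chromosome names.
#' @param intron_start,intron_end 1-based first/last intron base.
#' @param strand `"+"`, `"-"` or `"."` (unknown/unstranded).
#' @return Character vector of keys.
#' @export
junction_key <- function(chrom, intron_start, intron_end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, as.integer(intron_start),
          as.integer(intron_end), strand)
}

.sj_cols <- c("chrom", "intron_start", "intron_end", "strand", "motif",
              "annotated", "unique_reads", "multi_reads", "max_overhang")

.empty_sj <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(), motif = integer(),
             annotated = logical(), unique_reads = integer(),
             multi_reads = integer(), max_overhang = integer(),
             stringsAsFactors = FALSE)
}

#' Read a STAR SJ.out.tab splice-junction table
#'
#' Parses the 9-column tab-separated junction table emitted by the STAR
#' aligner: chromosome, intron start, intron end, strand code (0 undefined,
#' 1 `+`, 2 `-`), splice motif code, annotation flag, uniquely-mapping read
#' count, multi-mapping read count and maximum spliced overhang. Coordinates
#' are kept 1-based inclusive.
#'
#' @param path Path to an SJ.out.tab file.
#' @return A data frame with one row per junction and columns `chrom`,
#'   `intron_start`, `intron_end`, `strand` (`+`/`-`/`.`), `motif`,
#'   `annotated` (logical), `unique_reads`, `multi_reads`, `max_overhang`.
#' @export
read_star_sj <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_sj())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed SJ.out.tab row (fewer than 9 fields) at line ",
         which(nf < 9L)[1L], " of ", path)
  }
  mat <- t(vapply(fields, function(f) f[1:9], character(9)))
  num <- suppressWarnings(apply(mat[, 2:9, drop = FALSE], 2, as.integer))
  num <- matrix(num, nrow = nrow(mat))
  bad <- which(apply(num, 1, anyNA))
  if (length(bad)) {
    stop("malformed SJ.out.tab row (non-numeric field) at line ", bad[1L],
         " of ", path)
  }
  if (any(num[, c(6, 7, 8)] < 0)) {
    stop("negative read/overhang count in ", path)
  }
  strand_code <- num[, 3]
  if (any(!strand_code %in% 0:2)) {
    stop("invalid strand code (must be 0, 1 or 2) at line ",
         which(!strand_code %in% 0:2)[1L], " of ", path)
  }
  data.frame(
    chrom        = mat[, 1],
    intron_start = num[, 1],
    intron_end   = num[, 2],
    strand       = c(".", "+", "-")[strand_code + 1L],
    motif        = num[, 4],
    annotated    = num[, 5] != 0L,
    unique_reads = num[, 6],
    multi_reads  = num[, 7],
    max_overhang = num[, 8],
    stringsAsFactors = FALSE
  )
}

#' Write junctions back to SJ.out.tab layout
#'
#' Inverse of [read_star_sj()]; `write_star_sj` then `read_star_sj` is the
#' identity on the canonical columns.
#'
#' @param sj Junction data frame as returned by [read_star_sj()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_star_sj <- function(sj, path) {
  stopifnot(all(.sj_cols %in% names(sj)))
  out <- data.frame(
    sj$chrom, sj$intron_start, sj$intron_end,
    match(sj$strand, c(".", "+", "-")) - 1L,
    sj$motif, as.integer(sj$annotated),
    sj$unique_reads, sj$multi_reads, sj$max_overhang
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Imports exon records from an Ensembl-dialect GTF and groups them by
#' transcript within gene. Genes named in `ne_genes` are flagged as encoding
#' nuclear-envelope (NE) proteins.
#'
#' @param path Path to a GTF file.
#' @param ne_genes Character vector of NE gene identifiers (e.g. read from a
#'   one-id-per-line text file); may be empty.
#' @return An object of class `gene_models`: a list with
#'   \describe{
#'     \item{genes}{data frame `gene_id`, `chrom`, `strand`, `is_ne`.}
#'     \item{exons}{data frame `gene_id`, `transcript_id`, `chrom`, `strand`,
#'       `start`, `end` (1-based inclusive), sorted within transcript.}
#'   }
#' @export
read_gtf <- function(path, ne_genes = character()) {
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(S4Vectors::mcols(gr))
  is_exon <- meta$type == "exon"
  if (any(is_exon) && (!"transcript_id" %in% names(meta) ||
                       anyNA(meta$transcript_id[is_exon]))) {
    stop("GTF exon record without a transcript_id attribute in ", path)
  }
  gene_ids <- unique(meta$gene_id[!is.na(meta$gene_id)])
  ex <- gr[is_exon]
  if (length(ex)) {
    exm <- as.data.frame(S4Vectors::mcols(ex))
    exons <- data.frame(
      gene_id = exm$gene_id,
      transcript_id = exm$transcript_id,
      chrom = as.character(GenomicRanges::seqnames(ex)),
      strand = as.character(GenomicRanges::strand(ex)),
      start = GenomicRanges::start(ex),
      end = GenomicRanges::end(ex),
      stringsAsFactors = FALSE
    )
    exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
    rownames(exons) <- NULL
  } else {
    exons <- data.frame(gene_id = character(), transcript_id = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  no_exon <- setdiff(gene_ids, unique(exons$gene_id))
  if (length(no_exon)) {
    warning("gene(s) without exon records: ",
            paste(no_exon, collapse = ", "))
  }
  gene_chrom <- c(
    stats::setNames(exons$chrom, exons$gene_id),
    stats::setNames(as.character(GenomicRanges::seqnames(gr)), meta$gene_id)
  )
  gene_strand <- c(
    stats::setNames(exons$strand, exons$gene_id),
    stats::setNames(as.character(GenomicRanges::strand(gr)), meta$gene_id)
  )
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = unname(gene_chrom[gene_ids]),
    strand = unname(gene_strand[gene_ids]),
    is_ne = gene_ids %in% ne_genes,
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Write gene models as GTF
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes, readable by [read_gtf()].
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  ex <- models$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start, end = ex$end),
    strand = ex$strand,
    type = "exon",
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read/write FASTA sequence records
#'
#' Thin wrappers over Biostrings FASTA IO returning a plain data frame.
#' `read_fasta(write_fasta(x))` is the identity up to line wrapping.
#'
#' @param path File path.
#' @return For `read_fasta`, a data frame with columns `id` (first header
#'   token), `desc` (remainder of the header, possibly `""`) and `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (any(set@ranges@width == 0L)) {
    stop("empty sequence record in ", path)
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- unique(id[duplicated(id)])
  if (length(dup)) {
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "))
  }
  data.frame(id = id, desc = desc, seq = as.character(set),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param records Data frame with columns `id`, `seq` and optionally `desc`,
#'   or a named character vector of sequences.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), desc = "", seq = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(records)))
  if (any(nchar(records$seq) == 0L)) stop("refusing to write empty sequence")
  headers <- records$id
  if (!is.null(records$desc)) {
    has_desc <- nzchar(records$desc)
    headers[has_desc] <- paste(records$id[has_desc], records$desc[has_desc])
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Export junctions as BED6
#'
#' Converts the internal 1-based inclusive intron coordinates to BED's
#' 0-based half-open convention: `bed_start = intron_start - 1`,
#' `bed_end = intron_end`. The score column carries the unique read count.
#'
#' @param sj Junction data frame.
#' @return Data frame with BED6 columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
sj_to_bed <- function(sj) {
  data.frame(
    chrom = sj$chrom,
    start = sj$intron_start - 1L,
    end = sj$intron_end,
    name = junction_key(sj$chrom, sj$intron_start, sj$intron_end, sj$strand),
    score = sj$unique_reads,
    strand = sj$strand,
    stringsAsFactors = FALSE
  )
}

#' @rdname sj_to_bed
#' @param path Output path for the BED file (tab-separated, no header).
#' @export
write_bed <- function(sj, path) {
  utils::write.table(sj_to_bed(sj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a nuclear-envelope gene list
#'
#' One gene identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
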