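# Post-processing of MS identification tables: identification filters,
# target-decoy FDR estimation, distributed normalized spectral abundance
# factors (dNSAF) and mapping of identified peptides back onto splice
# junctions.

#' Filter protein identifications on peptide and spectral support
#'
#' A protein is retained when it was detected by at least `min_peptides`
#' distinct peptides or accumulated at least `min_spectra` spectral counts
#' ("and/or", i.e. inclusive OR; 1 peptide with 13 spectra passes).
#'
#' @param ids Identification data frame with columns `n_peptides` and
#'   `spectral_count` (a `peptides` column of `;`-separated sequences may
#'   stand in for `n_peptides`).
#' @param min_peptides Minimum distinct peptide count (default 2).
#' @param min_spectra Minimum spectral count (default 13).
#' @return The retained rows.
#' @export
filter_identifications <- function(ids, min_peptides = 2, min_spectra = 13) {
  if (!"n_peptides" %in% names(ids)) {
    if (!"peptides" %in% names(ids)) {
      stop("need an n_peptides or peptides column")
    }
    ids$n_peptides <- lengths(strsplit(ids$peptides, ";", fixed = TRUE))
  }
  keep <- ids$n_peptides >= min_peptides | ids$spectral_count >= min_spectra
  out <- ids[keep, ]
  rownames(out) <- NULL
  out
}

#' Target-decoy false discovery rates at the protein and spectral levels
#'
#' With composition-preserving shuffled decoys searched alongside targets,
#' `protein_fdr = 100 * n_decoy_proteins / n_target_proteins` and
#' `spectral_fdr = 100 * decoy_spectra / target_spectra`. The denominator is
#' targets only; set `include_decoys_in_denominator = TRUE` for the
#' (targets + decoys) convention.
#'
#' @param ids Identification data frame with `is_decoy` (logical) and
#'   `spectral_count` columns (decoy status may also be encoded by a
#'   `decoy_` accession prefix).
#' @param include_decoys_in_denominator Use targets + decoys as denominator.
#' @return List of class `fdr_report`: `protein_fdr` and `spectral_fdr`
#'   (percentages), `n_target_proteins`, `n_decoy_proteins`,
#'   `n_target_spectra`, `n_decoy_spectra`.
#' @export
estimate_fdr <- function(ids, include_decoys_in_denominator = FALSE) {
  if (!"is_decoy" %in% names(ids)) {
    ids$is_decoy <- startsWith(ids$accession, "decoy_")
  }
  nt <- sum(!ids$is_decoy)
  nd <- sum(ids$is_decoy)
  if (nt == 0) stop("no target identifications: FDR undefined")
  st <- sum(ids$spectral_count[!ids$is_decoy])
  sd <- sum(ids$spectral_count[ids$is_decoy])
  pd <- if (include_decoys_in_denominator) nt + nd else nt
  sden <- if (include_decoys_in_denominator) st + sd else st
  structure(list(
    protein_fdr = 100 * nd / pd,
    spectral_fdr = if (sden > 0) 100 * sd / sden else 0,
    n_target_proteins = nt, n_decoy_proteins = nd,
    n_target_spectra = st, n_decoy_spectra = sd
  ), class = "fdr_report")
}

#' Distributed normalized spectral abundance factors (dNSAF)
#'
#' Spectral counts of peptides shared between proteins are distributed
#' proportionally to the proteins' unique spectral counts:
#' `share_i = sSpC * uSpC_i / sum(uSpC_j)` over the proteins sharing the
#' peptide (split evenly when none has unique support). Then
#' `dSAF_i = (uSpC_i + share_i) / length_i` and `dNSAF_i = dSAF_i /
#' sum(dSAF)`, so the dNSAF values sum to 1.
#'
#' @param proteins Data frame with `accession`, `length` (residues) and
#'   `unique_spc` (unique spectral counts).
#' @param shared Optional data frame of shared peptides with columns
#'   `spectra` and `accessions` (`;`-separated accessions sharing the
#'   peptide).
#' @return Data frame `accession`, `unique_spc`, `shared_spc`, `dsaf`,
#'   `dnsaf`.
#' @export
compute_dnsaf <- function(proteins, shared = NULL) {
  stopifnot(all(c("accession", "length", "unique_spc") %in% names(proteins)))
  if (any(proteins$length <= 0)) stop("protein with non-positive length")
  share <- stats::setNames(numeric(nrow(proteins)), proteins$accession)
  if (!is.null(shared) && nrow(shared) > 0) {
    for (i in seq_len(nrow(shared))) {
      accs <- strsplit(shared$accessions[i], ";", fixed = TRUE)[[1]]
      m <- match(accs, proteins$accession)
      if (anyNA(m)) stop("shared peptide names unknown accession: ",
                         paste(accs[is.na(m)], collapse = ", "))
      u <- proteins$unique_spc[m]
      w <- if (sum(u) > 0) u / sum(u) else rep(1 / length(u), length(u))
      share[m] <- share[m] + shared$spectra[i] * w
    }
  }
  dsaf <- (proteins$unique_spc + share) / proteins$length
  if (sum(dsaf) == 0) stop("all spectral counts are zero")
  data.frame(accession = proteins$accession,
             unique_spc = proteins$unique_spc,
             shared_spc = unname(share),
             dsaf = dsaf,
             dnsaf = dsaf / sum(dsaf),
             stringsAsFactors = FALSE)
}

#' Map identified peptides onto junction database entries
#'
#' A peptide supports a junction when it occurs within a junction entry's
#' sequence overlapping the splice boundary with at least one residue on
#' each side (match start <= junction offset and match end >= offset + 1).
#' Peptides supporting more than one junction are flagged ambiguous;
#' peptides matching no junction entry are listed as unmatched.
#'
#' @param peptides Character vector of identified peptide sequences.
#' @param db_entries Database entry data frame (e.g. `assemble_database()`'s
#'   `entries`) with `accession`, `sequence`, `category`,
#'   `junction_offset_aa`, `source`, `kind`.
#' @return List with `hits` (data frame `peptide`, `accession`, `junction`,
#'   `kind`, `match_start`, `ambiguous`) and `unmatched` (character).
#' @export
find_junction_peptides <- function(peptides, db_entries) {
  jdb <- db_entries[db_entries$category == "junction" &
                      !is.na(db_entries$junction_offset_aa), ]
  peptides <- unique(peptides)
  rows <- list()
  supported <- character()
  for (pep in peptides) {
    plen <- nchar(pep)
    hit_idx <- which(vapply(jdb$sequence, function(s)
      grepl(pep, s, fixed = TRUE), logical(1), USE.NAMES = FALSE))
    for (j in hit_idx) {
      starts <- gregexpr(pep, jdb$sequence[j], fixed = TRUE)[[1]]
      off <- jdb$junction_offset_aa[j]
      spans <- starts[starts <= off & (starts + plen - 1L) >= off + 1L]
      if (!length(spans)) next
      supported <- c(supported, pep)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = pep, accession = jdb$accession[j],
        junction = jdb$source[j], kind = jdb$kind[j],
        match_start = spans[1L], stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(), accession = character(),
               junction = character(), kind = character(),
               match_start = integer(), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    n_junc <- tapply(hits$junction, hits$peptide,
                     function(x) length(unique(x)))
    hits$ambiguous <- unname(n_junc[hits$peptide] > 1)
  } else {
    hits$ambiguous <- logical()
  }
  rownames(hits) <- NULL
  list(hits = hits, unmatched = setdiff(peptides, supported))
}
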