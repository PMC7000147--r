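# Junction filtering and empirical PSI/dPSI quantification. PSI is estimated
# at the junction level (not whole transcripts) by an empirical ratio of read
# counts over the junction and its splice-site competitors, with replicates
# pooled by summing counts.

#' Filter junctions on read support and intron length
#'
#' Retains a junction iff its uniquely-mapping read support is at least
#' `min_reads` (default 6) and its predicted intron is at least `min_intron`
#' nucleotides long (default 60; shorter annotated introns are very rare).
#' Input order is preserved.
#'
#' @param sj Junction data frame ([read_star_sj()] layout).
#' @param min_reads Minimum unique read support (inclusive).
#' @param min_intron Minimum intron length in nt (inclusive).
#' @return The retained rows of `sj`.
#' @export
filter_junctions <- function(sj, min_reads = 6, min_intron = 60) {
  if (min_reads < 0 || min_intron < 0) stop("thresholds must be non-negative")
  if (nrow(sj) == 0) return(sj)
  keep <- sj$unique_reads >= min_reads &
    (sj$intron_end - sj$intron_start + 1L) >= min_intron
  out <- sj[keep, ]
  rownames(out) <- NULL
  out
}

#' Union of junction tables
#'
#' Set union by junction identity key `(chrom, intron_start, intron_end,
#' strand)`; read counts are aggregated by summing across tables and the
#' annotated flag is OR-ed.
#'
#' @param tables List of junction data frames (or a single data frame).
#' @return One junction data frame with aggregated support.
#' @export
union_junctions <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  all <- do.call(rbind, tables)
  if (nrow(all) == 0) return(.empty_sj())
  key <- junction_key(all$chrom, all$intron_start, all$intron_end, all$strand)
  first <- !duplicated(key)
  out <- all[first, ]
  idx <- match(key, key[first])
  out$unique_reads <- as.integer(rowsum(all$unique_reads, idx)[, 1])
  out$multi_reads <- as.integer(rowsum(all$multi_reads, idx)[, 1])
  out$annotated <- as.logical(rowsum(as.integer(all$annotated), idx)[, 1] > 0)
  out$max_overhang <- as.integer(
    vapply(split(all$max_overhang, idx), max, numeric(1)))
  rownames(out) <- NULL
  out
}

# TRUE for rows of x having a matching junction in y. Strand "." on either
# side matches any strand (unstranded libraries cannot assign one).
.match_junctions <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(rep(FALSE, nrow(x)))
  locus_x <- paste(x$chrom, x$intron_start, x$intron_end)
  locus_y <- paste(y$chrom, y$intron_start, y$intron_end)
  hit <- logical(nrow(x))
  idx <- split(seq_len(nrow(y)), locus_y)
  for (i in seq_len(nrow(x))) {
    cand <- idx[[locus_x[i]]]
    if (is.null(cand)) next
    hit[i] <- any(x$strand[i] == "." | y$strand[cand] == "." |
                    y$strand[cand] == x$strand[i])
  }
  hit
}

#' High-confidence novel junctions found in two independent datasets
#'
#' Returns the junctions of `set_a` that (i) are not annotated and (ii) are
#' also present in `set_b`. Matching is by junction key; a `.` strand on
#' either side matches any strand, so stranded and unstranded datasets can be
#' intersected.
#'
#' @param set_a,set_b Junction data frames (e.g. dataset-level unions).
#' @param annotation Data frame of annotated junctions (or `NULL` to use the
#'   `annotated` flag carried by `set_a`).
#' @return The high-confidence novel rows of `set_a`.
#' @export
intersect_novel <- function(set_a, set_b, annotation = NULL) {
  if (nrow(set_a) == 0) return(set_a)
  is_ann <- if (is.null(annotation)) set_a$annotated
            else .match_junctions(set_a, annotation)
  novel <- set_a[!is_ann, ]
  out <- novel[.match_junctions(novel, set_b), ]
  rownames(out) <- NULL
  out
}

#' PSI of a novel cassette exon from inclusion/exclusion junction reads
#'
#' For a manually screened cassette exon, `psi = NEIJ / (2 * CEJ + NEIJ)`,
#' where `NEIJ` is the summed read count over the two novel-exon inclusion
#' junctions and `CEJ` the read count of the canonical exclusion junction.
#' The factor 2 balances the two inclusion junctions of a cassette exon
#' against its single skipping junction, bounding the estimate in [0, 1].
#'
#' @param neij Novel-exon inclusion junction reads (non-negative).
#' @param cej Canonical exclusion junction reads (non-negative).
#' @return PSI in [0, 1].
#' @export
compute_novel_exon_psi <- function(neij, cej) {
  if (any(neij < 0) || any(cej < 0)) stop("read counts must be non-negative")
  if (any(neij + cej == 0)) {
    stop("no supporting reads: PSI undefined when NEIJ + CEJ == 0")
  }
  neij / (2 * cej + neij)
}

#' Empirical PSI of a junction against its splice-site competitors
#'
#' `psi = reads(target) / (reads(target) + sum reads(competitors))`, the
#' competitors being the de-duplicated junctions sharing the target's donor
#' or acceptor site. A zero denominator means the junction is not
#' quantifiable.
#'
#' @param target Read count of the target junction.
#' @param competitors Numeric vector of competitor read counts (may be
#'   empty).
#' @return List with `psi` (NA when unquantifiable), `supporting_reads` (the
#'   denominator) and `quantifiable`.
#' @export
psi_from_counts <- function(target, competitors = numeric()) {
  stopifnot(length(target) == 1, target >= 0, all(competitors >= 0))
  denom <- target + sum(competitors)
  if (denom == 0) {
    return(list(psi = NA_real_, supporting_reads = 0, quantifiable = FALSE))
  }
  list(psi = target / denom, supporting_reads = denom, quantifiable = TRUE)
}

#' Per-condition junction PSI table
#'
#' For each condition, replicate tables are pooled by summing read counts
#' ([union_junctions()]); each junction's PSI is then its pooled read count
#' over the pooled reads of all junctions sharing its donor or acceptor
#' splice site (itself included). Junctions whose denominator is zero are
#' reported as unquantifiable.
#'
#' @param tables_by_condition Named list: condition -> list of replicate
#'   junction data frames (or a single data frame).
#' @return Data frame with columns `chrom`, `intron_start`, `intron_end`,
#'   `strand`, `annotated`, `condition`, `psi`, `supporting_reads`,
#'   `quantifiable`.
#' @export
junction_psi <- function(tables_by_condition) {
  stopifnot(length(names(tables_by_condition)) == length(tables_by_condition))
  res <- lapply(names(tables_by_condition), function(cond) {
    pooled <- union_junctions(tables_by_condition[[cond]])
    if (nrow(pooled) == 0) return(NULL)
    donor <- paste(pooled$chrom, pooled$strand, pooled$intron_start)
    acceptor <- paste(pooled$chrom, pooled$strand, pooled$intron_end)
    donor_sum <- rowsum(pooled$unique_reads, donor)
    acceptor_sum <- rowsum(pooled$unique_reads, acceptor)
    denom <- donor_sum[donor, 1] + acceptor_sum[acceptor, 1] -
      pooled$unique_reads
    data.frame(chrom = pooled$chrom, intron_start = pooled$intron_start,
               intron_end = pooled$intron_end, strand = pooled$strand,
               annotated = pooled$annotated, condition = cond,
               psi = ifelse(denom > 0, pooled$unique_reads / denom, NA_real_),
               supporting_reads = denom,
               quantifiable = denom > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Signed PSI difference between two conditions
#'
#' `dpsi = psi_a - psi_b`: positive values mean higher inclusion in condition
#' A. An event is called differential when `dpsi >= threshold` (inclusive).
#'
#' @param psi_a,psi_b PSI values (vectors recycle).
#' @return For `delta_psi`, the signed difference in [-1, 1].
#' @export
delta_psi <- function(psi_a, psi_b) {
  stopifnot(all(psi_a >= 0 & psi_a <= 1, na.rm = TRUE),
            all(psi_b >= 0 & psi_b <= 1, na.rm = TRUE))
  psi_a - psi_b
}

#' @rdname delta_psi
#' @param dpsi Signed PSI differences.
#' @param threshold Differential-splicing threshold (default 0.2).
#' @return For `call_differential`, a logical vector (NA PSI on either side
#'   gives no call, i.e. NA).
#' @export
call_differential <- function(dpsi, threshold = 0.2) {
  dpsi >= threshold
}

#' All ordered pairwise dPSI records from a PSI table
#'
#' For every ordered pair of conditions (A, B), junctions quantifiable in
#' both contribute a record `dpsi = psi_A - psi_B`. Junctions unquantifiable
#' in either condition of a pair yield no record for that comparison.
#'
#' @param psi Data frame from [junction_psi()].
#' @return Data frame `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `annotated`, `cond_a`, `cond_b`, `dpsi`.
#' @export
dpsi_table <- function(psi) {
  psi <- psi[psi$quantifiable, ]
  conds <- unique(psi$condition)
  key <- junction_key(psi$chrom, psi$intron_start, psi$intron_end, psi$strand)
  out <- list()
  for (a in conds) for (b in setdiff(conds, a)) {
    ia <- which(psi$condition == a)
    ib <- which(psi$condition == b)
    m <- match(key[ia], key[ib])
    ok <- !is.na(m)
    if (!any(ok)) next
    ra <- ia[ok]; rb <- ib[m[ok]]
    out[[paste(a, b)]] <- data.frame(
      chrom = psi$chrom[ra], intron_start = psi$intron_start[ra],
      intron_end = psi$intron_end[ra], strand = psi$strand[ra],
      annotated = psi$annotated[ra] | psi$annotated[rb],
      cond_a = a, cond_b = b,
      dpsi = delta_psi(psi$psi[ra], psi$psi[rb]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
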