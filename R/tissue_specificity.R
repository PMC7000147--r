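# Tissue-specificity scoring: for each tissue, every pairwise dPSI comparison
# against the other tissues is thresholded to a binary inclusion score; the
# per-tissue scores are tallied and a junction is labeled with the tissue
# holding a strict maximum, or NA on ties.

#' Per-tissue binary comparison tables from dPSI records
#'
#' For tissue T, the table holds one entry per (junction, other tissue)
#' comparison, oriented as `dpsi = psi_T - psi_other`: the entry is 1 when
#' `dpsi >= threshold` (inclusion in T) and 0 otherwise. Comparisons missing
#' from `dpsi` (e.g. the junction was unquantifiable in one tissue) are
#' absent, not 0.
#'
#' @param dpsi Data frame from [dpsi_table()] (columns `cond_a`, `cond_b`,
#'   `dpsi` and the junction key columns).
#' @param threshold Differential threshold (default 0.2, inclusive).
#' @return Data frame `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `tissue` (= `cond_a`), `other` (= `cond_b`), `score` (0/1 integer).
#' @export
build_tissue_tables <- function(dpsi, threshold = 0.2) {
  if (threshold < 0) stop("threshold must be non-negative")
  data.frame(
    chrom = dpsi$chrom, intron_start = dpsi$intron_start,
    intron_end = dpsi$intron_end, strand = dpsi$strand,
    tissue = dpsi$cond_a, other = dpsi$cond_b,
    score = as.integer(call_differential(dpsi$dpsi, threshold)),
    stringsAsFactors = FALSE
  )
}

#' Tally per-tissue scores for each junction
#'
#' Sums the binary entries of each tissue's table: `score(junction, T)` is
#' the number of comparisons in which the junction was more included in T
#' (`dpsi >= threshold`). With `n` tissues the maximum attainable score is
#' `n - 1`. `n_scorable` counts the comparisons actually available for the
#' junction in that tissue.
#'
#' @param tables Data frame from [build_tissue_tables()].
#' @return Data frame `chrom`, `intron_start`, `intron_end`, `strand`,
#'   `tissue`, `score`, `n_scorable`.
#' @export
score_junctions <- function(tables) {
  grp <- paste(junction_key(tables$chrom, tables$intron_start,
                            tables$intron_end, tables$strand), tables$tissue)
  first <- !duplicated(grp)
  idx <- match(grp, grp[first])
  out <- tables[first, c("chrom", "intron_start", "intron_end", "strand",
                         "tissue")]
  out$score <- as.integer(rowsum(tables$score, idx)[, 1])
  out$n_scorable <- as.integer(rowsum(rep(1L, nrow(tables)), idx)[, 1])
  rownames(out) <- NULL
  out
}

#' Assign a tissue label from a vector of per-tissue scores
#'
#' The junction is labeled with the tissue holding the unique strict maximum
#' score; when two or more tissues tie at the maximum, or all scores are
#' zero, the junction is called not specific (`NA`).
#'
#' @param scores Named numeric vector, one score per tissue.
#' @return The winning tissue name, or `NA_character_`.
#' @export
assign_label <- function(scores) {
  stopifnot(length(names(scores)) == length(scores))
  if (length(scores) == 0 || max(scores) == 0) return(NA_character_)
  top <- which(scores == max(scores))
  if (length(top) > 1) return(NA_character_)
  names(scores)[top]
}

#' Assign tissue-specificity labels to all junctions
#'
#' Applies [assign_label()] per junction over its per-tissue score tally. A
#' junction needs at least one scorable comparison to be labeled; junctions
#' absent from every comparison never appear here.
#'
#' @param scores Data frame from [score_junctions()].
#' @return Data frame with one row per junction: key columns, `label`
#'   (tissue or NA), `max_score` and `n_tissues_scored`.
#' @export
assign_specificity <- function(scores) {
  key <- junction_key(scores$chrom, scores$intron_start, scores$intron_end,
                      scores$strand)
  parts <- split(seq_len(nrow(scores)), key)
  rows <- lapply(parts, function(i) {
    s <- stats::setNames(scores$score[i], scores$tissue[i])
    data.frame(chrom = scores$chrom[i[1]],
               intron_start = scores$intron_start[i[1]],
               intron_end = scores$intron_end[i[1]],
               strand = scores$strand[i[1]],
               label = assign_label(s),
               max_score = max(s),
               n_tissues_scored = length(s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tally labeled junctions per tissue
#'
#' Counts tissue-specific junctions per tissue plus the not-specific (NA)
#' count; the counts sum to the number of junctions. When `is_ne` flags are
#' supplied the counts are additionally split into NE and non-NE genes.
#'
#' @param labels Data frame from [assign_specificity()] (or any data frame
#'   with a `label` column).
#' @param tissues Tissue names defining the tally rows (defaults to the
#'   labels observed).
#' @param is_ne Optional logical vector, one flag per junction.
#' @return Data frame `tissue` (including `"NA"`), `n` and, with `is_ne`,
#'   `n_ne` / `n_non_ne`.
#' @export
tally_by_tissue <- function(labels, tissues = NULL, is_ne = NULL) {
  lab <- labels$label
  if (is.null(tissues)) tissues <- sort(unique(lab[!is.na(lab)]))
  lvls <- c(tissues, "NA")
  lab_f <- factor(ifelse(is.na(lab), "NA", lab), levels = lvls)
  out <- data.frame(tissue = lvls, n = as.integer(table(lab_f)),
                    stringsAsFactors = FALSE)
  if (!is.null(is_ne)) {
    stopifnot(length(is_ne) == nrow(labels))
    out$n_ne <- as.integer(table(lab_f[is_ne]))
    out$n_non_ne <- as.integer(table(lab_f[!is_ne]))
  }
  out
}

#' Tissue-specificity labels straight from replicate junction tables
#'
#' Convenience pipeline: pool replicates and compute junction PSI per tissue
#' ([junction_psi()]), form all ordered pairwise dPSI records
#' ([dpsi_table()]), threshold them into per-tissue tables, tally scores and
#' assign labels.
#'
#' @param tables_by_tissue Named list: tissue -> list of replicate junction
#'   data frames.
#' @param threshold dPSI threshold (default 0.2).
#' @param min_reads,min_intron Junction filters applied to the pooled tables
#'   (see [filter_junctions()]).
#' @return Data frame from [assign_specificity()], with the per-tissue
#'   scores attached as attribute `"scores"`.
#' @export
label_tissue_junctions <- function(tables_by_tissue, threshold = 0.2,
                                   min_reads = 6, min_intron = 60) {
  pooled <- lapply(tables_by_tissue, function(reps)
    filter_junctions(union_junctions(reps), min_reads, min_intron))
  psi <- junction_psi(pooled)
  dpsi <- dpsi_table(psi)
  scores <- score_junctions(build_tissue_tables(dpsi, threshold))
  labels <- assign_specificity(scores)
  attr(labels, "scores") <- scores
  labels
}
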