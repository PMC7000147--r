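# Expression thresholds (TPM, calibration-curve cutoff, expressed-gene
# unions) and the gene-set enrichment statistics: NE over-representation
# among differentially spliced genes (two-sample Kolmogorov-Smirnov test on
# per-comparison proportions), exon-count comparisons and intrinsic-disorder
# enrichment (Fisher's exact test).

#' Transcripts per million from a count matrix
#'
#' Per sample, `TPM_i = 1e6 * (N_i / L_i) / sum_j (N_j / L_j)`; every column
#' sums to one million, and TPM is invariant to rescaling a sample's counts.
#'
#' @param counts Non-negative genes x samples matrix.
#' @param lengths Gene lengths in nucleotides (positive, one per row).
#' @return Matrix of TPM values with the dimnames of `counts`.
#' @export
count_to_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  stopifnot(length(lengths) == nrow(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Median-of-ratios size factors and the default expression transform
#'
#' `normalize_log2()` divides each sample by its median-of-ratios size
#' factor (computed over genes with non-zero geometric mean) and returns
#' `log2(normalized count + 1)`. This is the default plug-in transform for
#' [calibration_cutoff()]; any monotone per-gene summary can replace it.
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Matrix of transformed values.
#' @export
normalize_log2 <- function(counts) {
  counts <- as.matrix(counts)
  lg <- rowMeans(log(counts))
  use <- is.finite(lg)
  if (!any(use)) {
    sf <- rep(1, ncol(counts))
  } else {
    sf <- apply(counts, 2, function(col)
      exp(stats::median(log(col[use]) - lg[use], na.rm = TRUE)))
    sf[!is.finite(sf) | sf <= 0] <- 1
  }
  log2(sweep(counts, 2, sf, "/") + 1)
}

#' Expressed-gene cutoff from a retained-genes calibration curve
#'
#' Sweeps candidate cutoffs over the range of the transformed per-gene
#' expression values and counts genes retained (value >= cutoff) at each.
#' On bimodal data the curve falls steeply across the unexpressed mode,
#' stays flat over the between-mode gap, and declines again over the
#' expressed mode; the knee is that flat stretch. The cutoff is placed at
#' the midpoint of the first value gap that (i) spans at least `gap_frac`
#' of the value range and (ii) has at least `side_mass` of the genes on
#' each side -- i.e. the first cutoff region where the retained set has
#' fallen from all genes to a stable set of genes. The mass condition makes
#' the cutoff invariant to adding a few genes far above it. When no such
#' gap exists (unimodal or degenerate values) a warning is raised and the
#' minimum is returned, retaining every gene.
#'
#' @param values One transformed expression value per gene (e.g. row means
#'   of [normalize_log2()] output).
#' @param n_grid Grid size for the reported calibration curve (default
#'   200).
#' @param gap_frac Minimum gap width as a fraction of the value range
#'   (default 0.05).
#' @param side_mass Minimum fraction of genes required below and above the
#'   gap (default 0.1).
#' @return The cutoff value, with the swept curve (grid and retained
#'   counts) attached as attribute `"curve"`.
#' @export
calibration_cutoff <- function(values, n_grid = 200, gap_frac = 0.05,
                               side_mass = 0.1) {
  values <- values[is.finite(values)]
  stopifnot(length(values) > 0, n_grid >= 2)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    warning("degenerate calibration curve: all values identical")
    return(structure(lo, curve = data.frame(cutoff = lo,
                                            retained = length(values))))
  }
  grid <- seq(lo, hi, length.out = n_grid)
  retained <- vapply(grid, function(g) sum(values >= g), numeric(1))
  sv <- sort(values)
  n <- length(sv)
  widths <- diff(sv)
  below <- seq_len(n - 1) / n
  ok <- widths >= gap_frac * (hi - lo) & below >= side_mass &
    (1 - below) >= side_mass
  if (!any(ok)) {
    warning("no clear knee in the calibration curve; retaining all genes")
    cutoff <- lo
  } else {
    i <- which(ok)[1L]
    cutoff <- (sv[i] + sv[i + 1L]) / 2
  }
  structure(cutoff, curve = data.frame(cutoff = grid, retained = retained))
}

#' Expressed genes by the calibration cutoff or a TPM floor
#'
#' `expressed_genes()` applies [calibration_cutoff()] to the mean
#' transformed expression per gene; `expressed_by_tpm()` implements the
#' simpler `TPM >= tpm_min` rule (default 1 TPM) on mean TPM per gene.
#'
#' @param counts Genes x samples count matrix (rownames = gene ids).
#' @param transform Function mapping the count matrix to transformed values
#'   (default [normalize_log2()]).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(counts, transform = normalize_log2) {
  tv <- rowMeans(transform(counts))
  cut <- calibration_cutoff(tv)
  rownames(counts)[tv >= as.numeric(cut)]
}

#' @rdname expressed_genes
#' @param lengths Gene lengths for the TPM computation.
#' @param tpm_min TPM floor (default 1).
#' @export
expressed_by_tpm <- function(counts, lengths, tpm_min = 1) {
  tpm <- count_to_tpm(counts, lengths)
  rownames(counts)[rowMeans(tpm) >= tpm_min]
}

#' Union of expressed-gene sets for a two-condition comparison
#'
#' @param a,b Character vectors of expressed gene ids.
#' @return Their union.
#' @export
expressed_union <- function(a, b) union(a, b)

#' NE enrichment among differentially spliced genes across comparisons
#'
#' For each two-condition comparison, computes the proportion of expressed
#' genes encoding NE proteins and the proportion of spliced genes (genes
#' with at least one junction at `dpsi >= 0.2` in that comparison) encoding
#' NE proteins, then contrasts the two proportion collections with a
#' two-sample Kolmogorov-Smirnov test. Proportions are discrete, so tied
#' values make the KS p-value approximate (and conservative); the tie
#' warning is suppressed.
#'
#' @param expressed_sets List (length >= 2) of expressed-gene id vectors,
#'   one per comparison (typically [expressed_union()] of the two
#'   conditions).
#' @param spliced_sets List of spliced-gene id vectors, parallel to
#'   `expressed_sets`.
#' @param ne_genes Character vector of NE gene ids.
#' @return List of class `enrichment_result`: `proportions` (data frame
#'   `comparison`, `prop_expressed_ne`, `prop_spliced_ne`), `statistic` (KS
#'   D), `p_value`, `mean_expressed_ne`, `mean_spliced_ne`.
#' @export
splicing_enrichment <- function(expressed_sets, spliced_sets, ne_genes) {
  stopifnot(length(expressed_sets) == length(spliced_sets))
  if (length(expressed_sets) < 2) {
    stop("need at least 2 comparisons for the KS test")
  }
  pe <- vapply(expressed_sets, function(g) mean(g %in% ne_genes), numeric(1))
  ps <- vapply(spliced_sets, function(g) mean(g %in% ne_genes), numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, pe))
  structure(list(
    proportions = data.frame(comparison = seq_along(pe),
                             prop_expressed_ne = pe, prop_spliced_ne = ps),
    statistic = unname(ks$statistic),
    p_value = ks$p.value,
    mean_expressed_ne = mean(pe),
    mean_spliced_ne = mean(ps)
  ), class = "enrichment_result")
}

#' Maximum exon count per expressed gene, split NE vs non-NE
#'
#' For every expressed gene, the transcript with the most exons defines the
#' gene's exon count. Genes without any transcript are excluded with a
#' message. Restricting to expressed genes matters because NE genes are, by
#' construction of proteomics screens, expressed.
#'
#' @param models A `gene_models` object ([read_gtf()] /
#'   [simulate_gene_models()]).
#' @param expressed Optional character vector of expressed gene ids (NULL =
#'   all genes with transcripts).
#' @return Data frame `gene_id`, `max_exons`, `is_ne`.
#' @export
max_exons_per_gene <- function(models, expressed = NULL) {
  ex <- models$exons
  per_tx <- table(ex$transcript_id)
  tx_gene <- ex$gene_id[match(names(per_tx), ex$transcript_id)]
  max_ex <- tapply(as.integer(per_tx), tx_gene, max)
  genes <- models$genes
  no_tx <- setdiff(genes$gene_id, names(max_ex))
  if (length(no_tx)) {
    message("excluding ", length(no_tx), " gene(s) without transcripts")
  }
  out <- data.frame(gene_id = names(max_ex),
                    max_exons = as.integer(max_ex),
                    stringsAsFactors = FALSE)
  out$is_ne <- genes$is_ne[match(out$gene_id, genes$gene_id)]
  if (!is.null(expressed)) out <- out[out$gene_id %in% expressed, ]
  rownames(out) <- NULL
  out
}

#' Call a protein intrinsically disordered from its residue score track
#'
#' Default rule: at least `min_residues` residues (default 20) with score
#' strictly above `threshold` (default 0.5), counted anywhere in the
#' protein. With `consecutive = TRUE` the rule instead requires a
#' contiguous stretch of at least `min_residues` such residues.
#'
#' @param scores Numeric per-residue scores in [0, 1] (longest annotated
#'   protein per gene, by convention).
#' @param threshold Disorder score threshold (exclusive).
#' @param min_residues Residue count required (inclusive).
#' @param consecutive Require one contiguous stretch instead of a total
#'   count.
#' @return Logical.
#' @export
disorder_call <- function(scores, threshold = 0.5, min_residues = 20,
                          consecutive = FALSE) {
  if (length(scores) == 0) stop("empty disorder score track")
  stopifnot(all(scores >= 0 & scores <= 1))
  high <- scores > threshold
  if (!consecutive) return(sum(high) >= min_residues)
  if (!any(high)) return(FALSE)
  runs <- rle(high)
  max(runs$lengths[runs$values]) >= min_residues
}

#' Two-sided exact test and odds ratio for a 2x2 table
#'
#' Fisher's exact test (two-sided, conditional on margins) plus the sample
#' cross-product odds ratio `(a*d)/(b*c)`.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`.
#' @param conf_int Also compute the conditional-MLE odds ratio and its 95%
#'   confidence interval (skipping it is much faster in tight loops).
#' @return List `p_value`, `odds_ratio` (cross-product) and, with
#'   `conf_int`, `conditional_odds_ratio` (Fisher MLE) and `conf_int` (95%).
#' @export
exact_test_2x2 <- function(a, b, c, d, conf_int = TRUE) {
  tab <- matrix(c(a, c, b, d), nrow = 2)
  ft <- stats::fisher.test(tab, alternative = "two.sided",
                           conf.int = conf_int)
  list(p_value = ft$p.value,
       odds_ratio = (a * d) / (b * c),
       conditional_odds_ratio = if (conf_int) unname(ft$estimate) else NULL,
       conf_int = if (conf_int) ft$conf.int else NULL)
}

#' Disorder enrichment in NE vs non-NE proteins
#'
#' Crosses disorder calls with NE membership into a 2x2 table and tests it
#' with a two-sided Fisher's exact test (alternative: odds ratio != 1).
#'
#' @param calls Logical vector of disorder calls ([disorder_call()]).
#' @param is_ne Logical vector of NE membership, parallel to `calls`.
#' @return List of class `enrichment_result`: `table` (2x2: NE/non-NE x
#'   disordered/not), `p_value`, `odds_ratio`, `conditional_odds_ratio`,
#'   `conf_int`, `prop_ne_disordered`, `prop_other_disordered`.
#' @export
disorder_enrichment <- function(calls, is_ne) {
  stopifnot(length(calls) == length(is_ne))
  a <- sum(is_ne & calls); b <- sum(is_ne & !calls)
  c <- sum(!is_ne & calls); d <- sum(!is_ne & !calls)
  et <- exact_test_2x2(a, b, c, d)
  structure(list(
    table = matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("NE", "non-NE"),
                                   c("disordered", "ordered"))),
    p_value = et$p_value,
    odds_ratio = et$odds_ratio,
    conditional_odds_ratio = et$conditional_odds_ratio,
    conf_int = et$conf_int,
    prop_ne_disordered = if (a + b > 0) a / (a + b) else NaN,
    prop_other_disordered = if (c + d > 0) c / (c + d) else NaN
  ), class = "enrichment_result")
}

#' Percentage of a count over its denominator, at printing precision
#'
#' Small helper for reporting count/percentage pairs like `1461/2963
#' (49\%)`.
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places (default 0, i.e. whole percent).
#' @return `round(100 * num / den, digits)`.
#' @export
as_percentage <- function(num, den, digits = 0) {
  round(100 * num / den, digits)
}
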