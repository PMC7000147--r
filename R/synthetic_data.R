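# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised against planted ground truth without any external download. All
# generators are pure functions of (config, seed): they seed the RNG on entry.

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate a five-tissue body-map design (brain, heart, liver,
#' skeletal muscle, testes) with replicated junction tables from two
#' independently produced datasets, planted tissue-specific cassette-exon
#' events (high inclusion in one tissue, low elsewhere) and low-count noise
#' junctions.
#'
#' @param n_tissues Number of tissues.
#' @param tissues Tissue names (length `n_tissues`).
#' @param n_replicates Replicate junction tables per tissue per dataset.
#' @param n_genes Number of simulated genes (each on its own contig).
#' @param fraction_ne Fraction of genes flagged as nuclear-envelope (NE).
#' @param n_planted Planted tissue-specific cassette events per tissue.
#' @param psi_high Inclusion level (PSI) of a planted junction in its labeled
#'   tissue.
#' @param psi_low Inclusion level everywhere else.
#' @param mean_depth Mean read depth per splicing event and replicate.
#' @param dispersion Negative-binomial (Gamma-Poisson) dispersion of junction
#'   read counts; 0 gives Poisson noise. The default 0.02 corresponds to a
#'   biological coefficient of variation of ~0.14, typical of inbred
#'   laboratory-animal replicates.
#' @param noise_junctions Spurious low-support junctions (1--5 reads) added
#'   per table; about half predict introns shorter than 60 nt.
#' @param exon_rate Poisson rate for extra exons beyond the minimum of 2.
#' @param ne_exon_boost Additive increase of `exon_rate` for NE genes (0 =
#'   identical exon-count distributions).
#' @param n_samples Samples in the simulated count matrix.
#' @param frac_expressed Fraction of genes expressed in the count matrix.
#' @param frac_disordered Fraction of proteins given a disordered region.
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 5,
                       tissues = c("brain", "heart", "liver", "muscle",
                                   "testes"),
                       n_replicates = 3,
                       n_genes = 60,
                       fraction_ne = 0.2,
                       n_planted = 3,
                       psi_high = 0.8,
                       psi_low = 0.05,
                       mean_depth = 100,
                       dispersion = 0.02,
                       noise_junctions = 20,
                       exon_rate = 4,
                       ne_exon_boost = 0,
                       n_samples = 6,
                       frac_expressed = 0.6,
                       frac_disordered = 0.4,
                       seed = 1) {
  if (length(tissues) != n_tissues) stop("length(tissues) must be n_tissues")
  if (!(psi_low >= 0 && psi_low < psi_high && psi_high <= 1)) {
    stop("need 0 <= psi_low < psi_high <= 1")
  }
  if (n_genes < 2) stop("n_genes must be at least 2")
  if (any(c(n_tissues, n_replicates, mean_depth, n_samples) <= 0)) {
    stop("counts and depths must be positive")
  }
  if (dispersion < 0) stop("dispersion must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

# NB(mu, dispersion) counts; Poisson in the dispersion -> 0 limit.
.rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate gene models, their genome and an NE gene list
#'
#' Each gene sits on its own contig with multi-exon structure: exon count
#' `2 + Poisson(exon_rate + ne_exon_boost * is_ne)`, exon lengths 90--210 nt,
#' intron lengths 80--300 nt and 150-nt flanks. Genes with at least four
#' exons get a second transcript skipping one internal exon, so per-gene
#' maximum exon counts are non-trivial.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a named [Biostrings::DNAStringSet]), `models`
#'   (a `gene_models` object as from [read_gtf()]) and `ne_genes` (character).
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed %% .Machine$integer.max)
  n <- config$n_genes
  gene_id <- sprintf("G%04d", seq_len(n))
  chrom <- sprintf("chr%d", seq_len(n))
  is_ne <- rep(FALSE, n)
  is_ne[sample.int(n, round(config$fraction_ne * n))] <- TRUE
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_exons <- 2L + stats::rpois(n, config$exon_rate +
                                 config$ne_exon_boost * is_ne)

  exon_rows <- vector("list", n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    k <- n_exons[i]
    elen <- sample(90:210, k, replace = TRUE)
    ilen <- if (k > 1) sample(80:300, k - 1, replace = TRUE) else integer()
    start <- integer(k); end <- integer(k)
    pos <- 151L
    for (j in seq_len(k)) {
      start[j] <- pos
      end[j] <- pos + elen[j] - 1L
      pos <- end[j] + (if (j < k) ilen[j] else 0L) + 1L
    }
    contig_len <- end[k] + 150L
    seqs[i] <- .random_dna(contig_len)
    tx <- data.frame(gene_id = gene_id[i],
                     transcript_id = paste0(gene_id[i], ".t1"),
                     chrom = chrom[i], strand = strand[i],
                     start = start, end = end, stringsAsFactors = FALSE)
    if (k >= 4L) {
      skip <- sample(2:(k - 1), 1)
      tx2 <- tx[-skip, ]
      tx2$transcript_id <- paste0(gene_id[i], ".t2")
      tx <- rbind(tx, tx2)
    }
    exon_rows[[i]] <- tx
  }
  exons <- do.call(rbind, exon_rows)
  rownames(exons) <- NULL
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chrom
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      is_ne = is_ne, stringsAsFactors = FALSE)
  list(genome = genome,
       models = structure(list(genes = genes, exons = exons),
                          class = "gene_models"),
       ne_genes = gene_id[is_ne])
}

# Junctions between consecutive exons of one transcript (intron coordinates).
.transcript_junctions <- function(tx) {
  k <- nrow(tx)
  if (k < 2) return(NULL)
  data.frame(chrom = tx$chrom[1],
             intron_start = tx$end[-k] + 1L,
             intron_end = tx$start[-1] - 1L,
             strand = tx$strand[1],
             stringsAsFactors = FALSE)
}

#' Simulate per-tissue replicate junction tables with planted truth
#'
#' For each tissue, `n_planted` genes with at least three exons carry a
#' cassette event on their second exon: the two inclusion junctions (novel,
#' unannotated) draw reads from `NB(mean_depth * psi)` and the skipping
#' junction (annotated) from `NB(mean_depth * (1 - psi))`, with
#' `psi = psi_high` in the labeled tissue and `psi_low` elsewhere.
#' Constitutive junctions draw reads at `mean_depth`. The same planted events
#' are written, with independent noise, into two datasets `A` and `B` so that
#' cross-dataset intersection logic is exercisable. Noise junctions with
#' fewer than 6 reads (and often introns < 60 nt) are added to every table.
#'
#' @param sim Output of [simulate_gene_models()].
#' @param config The same [sim_config()].
#' @return List with
#'   \describe{
#'     \item{tables}{`tables[[dataset]][[tissue]][[replicate]]`, each a
#'       junction data frame in [read_star_sj()] layout.}
#'     \item{truth}{data frame of planted inclusion junctions: junction
#'       coordinates, `gene_id`, `tissue`, `role` (`inclusion_upstream` /
#'       `inclusion_downstream`).}
#'     \item{annotation}{data frame of all annotated junctions.}
#'   }
#' @export
simulate_junction_tables <- function(sim, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  exons <- sim$models$exons
  primary <- exons[endsWith(exons$transcript_id, ".t1"), ]
  counts <- table(primary$gene_id)
  eligible <- names(counts)[counts >= 3L]
  need <- config$n_tissues * config$n_planted
  if (length(eligible) < need) {
    stop("not enough genes with >= 3 exons to plant ", need, " events")
  }
  planted_genes <- sample(eligible, need)
  plant <- data.frame(gene_id = planted_genes,
                      tissue = rep(config$tissues, each = config$n_planted),
                      stringsAsFactors = FALSE)

  # Structural junctions per planted gene.
  truth <- NULL
  event <- list()
  for (i in seq_len(nrow(plant))) {
    tx <- primary[primary$gene_id == plant$gene_id[i], ]
    j12 <- data.frame(chrom = tx$chrom[1], intron_start = tx$end[1] + 1L,
                      intron_end = tx$start[2] - 1L, strand = tx$strand[1])
    j23 <- data.frame(chrom = tx$chrom[1], intron_start = tx$end[2] + 1L,
                      intron_end = tx$start[3] - 1L, strand = tx$strand[1])
    j13 <- data.frame(chrom = tx$chrom[1], intron_start = tx$end[1] + 1L,
                      intron_end = tx$start[3] - 1L, strand = tx$strand[1])
    event[[plant$gene_id[i]]] <- list(inc = rbind(j12, j23), exc = j13,
                                      tissue = plant$tissue[i])
    truth <- rbind(truth,
                   cbind(rbind(j12, j23),
                         gene_id = plant$gene_id[i],
                         tissue = plant$tissue[i],
                         role = c("inclusion_upstream",
                                  "inclusion_downstream")))
  }
  rownames(truth) <- NULL

  # Annotated junction universe: constitutive junctions (all transcripts)
  # plus the cassette-skipping junction; minus the planted inclusion introns.
  # Planted genes keep only their primary transcript so that no annotated
  # junction competes for the cassette's splice sites and the planted PSI
  # stays the event's true inclusion level.
  ann_exons <- exons[!(exons$gene_id %in% planted_genes &
                         !endsWith(exons$transcript_id, ".t1")), ]
  ann <- do.call(rbind, lapply(split(ann_exons, ann_exons$transcript_id),
                               .transcript_junctions))
  ann <- rbind(ann, do.call(rbind, lapply(event, `[[`, "exc")))
  key <- junction_key(ann$chrom, ann$intron_start, ann$intron_end, ann$strand)
  truth_key <- junction_key(truth$chrom, truth$intron_start, truth$intron_end,
                            truth$strand)
  ann <- ann[!duplicated(key) & !(key %in% truth_key), ]
  rownames(ann) <- NULL

  depth <- config$mean_depth
  disp <- config$dispersion
  one_table <- function(tissue) {
    rows <- list()
    # constitutive/annotated junctions
    mu_ann <- rep(depth, nrow(ann))
    # skipping junctions of planted events get event-specific mu below;
    # remove their default row first
    exc_key <- vapply(event, function(e)
      junction_key(e$exc$chrom, e$exc$intron_start, e$exc$intron_end,
                   e$exc$strand), character(1))
    ann_key <- junction_key(ann$chrom, ann$intron_start, ann$intron_end,
                            ann$strand)
    base <- ann[!(ann_key %in% exc_key), ]
    rows$ann <- cbind(base,
                      motif = 1L, annotated = TRUE,
                      unique_reads = .rcounts(nrow(base), depth, disp),
                      multi_reads = 0L, max_overhang = 50L)
    for (g in names(event)) {
      e <- event[[g]]
      psi <- if (identical(e$tissue, tissue)) config$psi_high
             else config$psi_low
      inc <- cbind(e$inc, motif = 1L, annotated = FALSE,
                   unique_reads = .rcounts(2L, depth * psi, disp),
                   multi_reads = 0L, max_overhang = 50L)
      exc <- cbind(e$exc, motif = 1L, annotated = TRUE,
                   unique_reads = .rcounts(1L, depth * (1 - psi), disp),
                   multi_reads = 0L, max_overhang = 50L)
      rows[[g]] <- rbind(inc, exc)
    }
    # low-support noise junctions, ~half with sub-60-nt introns
    nn <- config$noise_junctions
    if (nn > 0) {
      gidx <- sample.int(nrow(sim$models$genes), nn, replace = TRUE)
      ns <- sample(300:600, nn, replace = TRUE)
      ilen <- ifelse(stats::runif(nn) < 0.5,
                     sample(20:59, nn, replace = TRUE),
                     sample(60:200, nn, replace = TRUE))
      rows$noise <- data.frame(
        chrom = sim$models$genes$chrom[gidx],
        intron_start = ns, intron_end = ns + ilen - 1L,
        strand = sim$models$genes$strand[gidx],
        motif = 0L, annotated = FALSE,
        unique_reads = sample(1:5, nn, replace = TRUE),
        multi_reads = 0L, max_overhang = 20L,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out <- out[out$unique_reads > 0L, ]
    out <- out[!duplicated(junction_key(out$chrom, out$intron_start,
                                        out$intron_end, out$strand)), ]
    rownames(out) <- NULL
    out
  }

  tables <- list()
  for (ds in c("A", "B")) {
    tables[[ds]] <- lapply(stats::setNames(config$tissues, config$tissues),
                           function(tis) {
                             lapply(seq_len(config$n_replicates),
                                    function(r) one_table(tis))
                           })
  }
  list(tables = tables, truth = truth, annotation = ann)
}

#' Simulate a gene-level count matrix with expressed-gene truth
#'
#' Counts come from a two-component mixture: unexpressed genes draw near-zero
#' Poisson counts (mean 0.2) while expressed genes draw negative-binomial
#' counts around log-normal per-gene means, so any monotone transform of the
#' counts shows a clear knee separating the two modes.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x samples integer matrix), `lengths`
#'   (gene lengths, nt) and `expressed` (logical truth per gene).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 2L) %% .Machine$integer.max)
  n <- config$n_genes
  m <- config$n_samples
  expressed <- rep(FALSE, n)
  expressed[sample.int(n, round(config$frac_expressed * n))] <- TRUE
  mu <- ifelse(expressed, stats::rlnorm(n, log(200), 0.8), 0)
  counts <- matrix(0L, n, m,
                   dimnames = list(sprintf("G%04d", seq_len(n)),
                                   sprintf("S%d", seq_len(m))))
  for (j in seq_len(m)) {
    base <- stats::rpois(n, 0.2)
    expr <- .rcounts(n, mu, max(config$dispersion, 0.05))
    counts[, j] <- ifelse(expressed, expr + base, base)
  }
  list(counts = counts,
       lengths = sample(500:3000, n, replace = TRUE),
       expressed = expressed)
}

#' Simulate per-residue intrinsic-disorder score tracks
#'
#' Proteins flagged as disordered receive a contiguous region of at least 25
#' residues with scores above 0.5; unflagged proteins get at most 10 such
#' residues. Scores are in [0, 1].
#'
#' @param proteins Data frame with columns `accession` and `length`
#'   (residues).
#' @param config A [sim_config()].
#' @return List with `tracks` (named list of numeric score vectors) and
#'   `truth` (data frame `accession`, `disordered`).
#' @export
simulate_disorder_tracks <- function(proteins, config) {
  stopifnot(inherits(config, "sim_config"),
            all(c("accession", "length") %in% names(proteins)))
  set.seed((config$seed + 3L) %% .Machine$integer.max)
  n <- nrow(proteins)
  can_flag <- proteins$length >= 25L
  flagged <- rep(FALSE, n)
  idx <- which(can_flag)
  n_flag <- min(length(idx), round(config$frac_disordered * n))
  flagged[sample(idx, n_flag)] <- TRUE
  tracks <- vector("list", n)
  names(tracks) <- proteins$accession
  for (i in seq_len(n)) {
    len <- proteins$length[i]
    sc <- stats::runif(len, 0.05, 0.45)
    if (flagged[i]) {
      rl <- sample(25:min(len, 60), 1)
      at <- sample.int(len - rl + 1L, 1)
      sc[at:(at + rl - 1L)] <- stats::runif(rl, 0.55, 0.95)
    } else {
      rl <- sample(0:min(10L, len), 1)
      if (rl > 0) {
        at <- sample.int(len - rl + 1L, 1)
        sc[at:(at + rl - 1L)] <- stats::runif(rl, 0.55, 0.95)
      }
    }
    tracks[[i]] <- sc
  }
  list(tracks = tracks,
       truth = data.frame(accession = proteins$accession,
                          disordered = flagged, stringsAsFactors = FALSE))
}
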