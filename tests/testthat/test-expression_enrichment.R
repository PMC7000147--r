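# TPM, calibration-curve cutoff, expressed-gene sets and the enrichment
# statistics.

test_that("TPM follows the length-normalized formula", {
  one <- count_to_tpm(matrix(5, 1, 1), lengths = 1000)
  expect_equal(as.numeric(one), 1e6)

  two <- count_to_tpm(matrix(c(10, 10), 2, 1), lengths = c(1000, 2000))
  expect_equal(as.numeric(two), c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)

  m <- matrix(rpois(40, 50), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  len <- sample(500:2000, 10)
  t1 <- count_to_tpm(m, len)
  expect_equal(unname(colSums(t1)), rep(1e6, 4), tolerance = 1e-6)
  expect_equal(count_to_tpm(2 * m, len), t1, tolerance = 1e-9)

  m[, 2] <- 0
  expect_error(count_to_tpm(m, len), "s2")
})

test_that("the calibration cutoff lands between bimodal modes", {
  set.seed(101)
  vals <- c(stats::rnorm(300, 0, 0.3), stats::rnorm(300, 8, 0.3))
  cut <- calibration_cutoff(vals)
  expect_gt(as.numeric(cut), max(vals[1:300]))
  expect_lt(as.numeric(cut), min(vals[301:600]))
  curve <- attr(cut, "curve")
  expect_equal(nrow(curve), 200)
  expect_true(all(diff(curve$retained) <= 0))
})

test_that("degenerate calibration curves warn and return the minimum", {
  expect_warning(cut <- calibration_cutoff(rep(3, 50)), "degenerate")
  expect_equal(as.numeric(cut), 3)
})

test_that("genes far above the cutoff do not move the expressed set", {
  set.seed(102)
  vals <- c(stats::rnorm(200, 0, 0.3), stats::rnorm(200, 8, 0.3))
  cut1 <- as.numeric(calibration_cutoff(vals))
  vals2 <- c(vals, stats::rnorm(50, 40, 1))
  cut2 <- as.numeric(calibration_cutoff(vals2))
  expect_gt(cut2, max(vals[1:200]))
  expect_lt(cut2, min(vals[201:400]))
  expect_identical(vals >= cut1, vals >= cut2)
})

test_that("expressed-gene selection recovers the planted mixture", {
  cfg <- sim_config(n_genes = 500, frac_expressed = 0.5, seed = 33)
  sc <- simulate_counts(cfg)
  called <- rownames(sc$counts) %in% expressed_genes(sc$counts)
  expect_gte(mean(called == sc$expressed), 0.95)
})

test_that("the TPM floor selects genes with mean TPM at or above it", {
  counts <- matrix(c(1000, 10, 0,
                     1000, 0, 2), nrow = 3,
                   dimnames = list(c("hi", "lo", "off"), c("s1", "s2")))
  lengths <- c(1000, 1000, 1000)
  tpm <- count_to_tpm(counts, lengths)
  expect_setequal(expressed_by_tpm(counts, lengths, tpm_min = 1),
                  rownames(counts)[rowMeans(tpm) >= 1])
  expect_true("hi" %in% expressed_by_tpm(counts, lengths))
  expect_false("hi" %in% expressed_by_tpm(counts, lengths,
                                          tpm_min = 1e6))
})

test_that("expressed_union is a plain set union", {
  expect_setequal(expressed_union(c("a", "b"), c("b", "c")),
                  c("a", "b", "c"))
  expect_setequal(expressed_union(paste0("g", 1:10), paste0("h", 1:5)),
                  c(paste0("g", 1:10), paste0("h", 1:5)))
  expect_setequal(expressed_union(c("a"), c("a")), "a")
})

test_that("identical proportion collections give KS statistic 0, p 1", {
  sets <- lapply(1:5, function(i) paste0("g", 1:20))
  ne <- paste0("g", 1:5)
  r <- splicing_enrichment(sets, sets, ne)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(splicing_enrichment(sets[1], sets[1], ne), "at least 2")
})

test_that("a planted NE-proportion shift is detected across comparisons", {
  set.seed(104)
  universe <- paste0("g", 1:1000)
  ne <- paste0("g", 1:170)
  w <- ifelse(universe %in% ne, 1.806, 1)  # ~ +0.1 NE proportion
  expressed_sets <- lapply(1:20, function(i) sample(universe, 300))
  spliced_sets <- lapply(1:20, function(i)
    sample(universe, 100, prob = w))
  r <- splicing_enrichment(expressed_sets, spliced_sets, ne)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$mean_spliced_ne, r$mean_expressed_ne)
})

test_that("max exon counts take the transcript maximum per gene", {
  exons <- rbind(
    data.frame(gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1",
               strand = "+", start = c(1, 100, 200), end = c(50, 150, 250)),
    data.frame(gene_id = "g1", transcript_id = "g1.t2", chrom = "chr1",
               strand = "+", start = c(1, 100, 200, 300, 400),
               end = c(50, 150, 250, 350, 450)),
    data.frame(gene_id = "g2", transcript_id = "g2.t1", chrom = "chr2",
               strand = "-", start = 1, end = 500))
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr2", "chr3"),
                      strand = c("+", "-", "+"),
                      is_ne = c(TRUE, FALSE, FALSE))
  gm <- structure(list(genes = genes, exons = exons), class = "gene_models")
  expect_message(mx <- max_exons_per_gene(gm), "without transcripts")
  expect_equal(mx$max_exons[mx$gene_id == "g1"], 5L)
  expect_equal(mx$max_exons[mx$gene_id == "g2"], 1L)
  expect_false("g3" %in% mx$gene_id)
  expect_equal(nrow(max_exons_per_gene(gm, expressed = "g1")), 1)
})

test_that("disorder calls use the 20-residue threshold on >0.5 scores", {
  expect_false(disorder_call(c(rep(0.9, 19), rep(0.1, 50))))
  expect_true(disorder_call(c(rep(0.9, 20), rep(0.1, 50))))
  expect_false(disorder_call(rep(0, 30)))
  expect_error(disorder_call(numeric()), "empty")
  # scores exactly at 0.5 do not count (strictly above)
  expect_false(disorder_call(rep(0.5, 40)))

  # consecutive-stretch variant: 20 high residues in two separated runs
  scattered <- c(rep(0.9, 10), rep(0.1, 5), rep(0.9, 10), rep(0.1, 5))
  expect_true(disorder_call(scattered))
  expect_false(disorder_call(scattered, consecutive = TRUE))
  expect_true(disorder_call(c(rep(0.9, 20), rep(0.1, 5)),
                            consecutive = TRUE))
})

test_that("the 2x2 exact test reports the cross-product odds ratio", {
  r <- exact_test_2x2(20, 80, 10, 90)
  expect_equal(r$odds_ratio, 2.25)
  expect_equal(r$p_value, stats::fisher.test(matrix(c(20, 10, 80, 90),
                                                    2))$p.value)
  d <- disorder_enrichment(calls = c(rep(TRUE, 20), rep(FALSE, 80),
                                     rep(TRUE, 10), rep(FALSE, 90)),
                           is_ne = rep(c(TRUE, FALSE), c(100, 100)))
  expect_equal(d$odds_ratio, 2.25)
  expect_equal(d$table["NE", "disordered"], 20)
  expect_equal(d$prop_ne_disordered, 0.2)
})

test_that("exact test agrees with hypergeometric enumeration (spot check)", {
  set.seed(105)
  for (rep in 1:200) {
    r1 <- sample(1:12, 1); r2 <- sample(1:12, 1)
    a <- sample(0:r1, 1); cc <- sample(0:r2, 1)
    expect_equal(exact_test_2x2(a, r1 - a, cc, r2 - cc,
                                conf_int = FALSE)$p_value,
                 enum_fisher_p(a, r1 - a, cc, r2 - cc), tolerance = 1e-10)
  }
})

test_that("under the null the odds-ratio CI covers 1 at nominal rate", {
  set.seed(106)
  n_rep <- 1000
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    is_ne <- rep(c(TRUE, FALSE), c(100, 400))
    calls <- stats::runif(500) < 0.35   # disorder independent of NE
    ci <- disorder_enrichment(calls, is_ne)$conf_int
    covered[i] <- ci[1] <= 1 && 1 <= ci[2]
  }
  expect_gte(mean(covered), 0.93)
})

test_that("count/percentage reporting matches printing precision", {
  expect_equal(as_percentage(1461, 2963), 49)
  expect_equal(as_percentage(20, 80, digits = 1), 25)
})
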