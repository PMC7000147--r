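---
title: "Methods: tissue-specific splice junctions and junction-peptide databases"
author: "tissplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific splice junctions and junction-peptide databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissplice)
```

## The problem

Many nuclear-envelope (NE) proteins are mutated in strikingly
tissue-specific diseases (muscular dystrophies, cardiomyopathies,
lipodystrophies) despite being near-ubiquitously expressed. One candidate
mechanism is tissue-specific alternative splicing: a tissue may express a
splice variant -- possibly unannotated -- that carries unique interaction or
targeting sequences. `tissplice` implements a desk-scale, fully testable
version of the computational workflow used to look for such variants: it

1. reads per-replicate splice-junction tables (STAR `SJ.out.tab` layout),
   filters and pools them, and estimates junction-level inclusion (PSI);
2. scores every junction for tissue specificity over all pairwise tissue
   comparisons and assigns a tissue label or NA;
3. builds a proteogenomic search database of junction-spanning peptides
   (66-nt windows, three-frame translation, stop-codon and
   junction-position filters, composition-preserving decoys) so that mass
   spectrometry can confirm translation of predicted variants;
4. post-processes MS identification tables (identification filters,
   target-decoy FDR, dNSAF abundances, peptide-to-junction mapping);
5. computes the supporting enrichment statistics: expression thresholds,
   NE over-representation among spliced genes, exon-count comparisons and
   intrinsic-disorder enrichment.

Every stage can be exercised against synthetic data with planted ground
truth (section *Synthetic data*), which is how the package's test suite
validates the method.

## Junction-level quantification

Whole-isoform reconstruction from short reads is unreliable, so all
quantification is at the level of individual exon--exon junctions,
identified by `(chrom, intron_start, intron_end, strand)` with 1-based
inclusive intron coordinates. Junctions are filtered on unique-read support
(`>= 6` reads) and predicted intron length (`>= 60` nt); both bounds are
inclusive and exposed as arguments.

**Empirical PSI.** For a junction $j$ with pooled unique-read count $r_j$,

$$\widehat{\mathrm{PSI}}_j \;=\; \frac{r_j}{r_j + \sum_{k \in C(j)} r_k},$$

where $C(j)$ is the de-duplicated set of junctions sharing $j$'s donor or
acceptor splice site. Replicates are pooled by summing counts before the
ratio is taken; the denominator is reported as `supporting_reads` and a
zero denominator marks the junction unquantifiable (no dPSI record is
emitted for it). This is a deliberate stand-in for Bayesian
posterior-expected PSI machinery: it has no prior and no shrinkage, so at
low read depth its estimates are noisier, but it is transparent,
deterministic, and exact in the high-depth limit. Pooling (rather than
averaging per-replicate PSI) weights replicates by their information
content; it is the package's fixed convention.

**Manually screened cassette exons.** For a novel cassette exon supported
by two inclusion junctions (summed count NEIJ) against one canonical
skipping junction (count CEJ),

$$\mathrm{PSI} = \frac{\mathrm{NEIJ}}{2\,\mathrm{CEJ} + \mathrm{NEIJ}}.$$

The factor 2 balances the two inclusion junctions of a cassette exon
against its single exclusion junction and bounds the estimate in $[0, 1]$;
`compute_novel_exon_psi()` refuses the 0/0 case rather than returning 0,
since no signal is not the same as no inclusion.

**dPSI and the differential call.** `dpsi = psi_A - psi_B` (positive =
higher inclusion in A); an event is differential when `dpsi >= 0.2`, with
the threshold inclusive. 0.2 is the conventional threshold for a
biologically meaningful splicing change in the tissue-comparison
literature.

## Tissue-specificity scoring

For each tissue $T$ and each junction, every comparison $T$ vs. other
tissue contributes a binary entry: 1 if $\mathrm{psi}_T -
\mathrm{psi}_{\text{other}} \ge 0.2$, else 0. Per-tissue scores are the
sums of these entries, so with $n$ tissues the ceiling is $n - 1$ (4 for
the five-tissue design). A junction is labeled with the tissue holding a
*strict* maximum score; ties at the maximum and all-zero score vectors give
NA (not specific). Conventions worth making explicit:

* the orientation is always `psi_T - psi_other` inside tissue $T$'s table,
  so inclusion in $T$ is a positive sign, and all $n - 1$ oriented
  comparisons per tissue are used;
* comparisons that cannot be made (a junction unquantifiable in one
  tissue) are *absent*, not zero -- `n_scorable` tracks how many
  comparisons were available so that NA-by-absence is distinguishable from
  NA-by-tie;
* tallies per tissue plus the NA count always sum to the number of
  junctions (`tally_by_tissue()`), optionally split by NE membership.

High-confidence novel junctions are those absent from the annotation and
present in two independently produced datasets (`intersect_novel()`).
Matching is strand-blind when either side carries strand `.`, because
unstranded libraries cannot assign a strand; this is a package choice for
joining stranded to unstranded datasets, not a documented convention of any
upstream tool.

## The junction-peptide database

For each junction the genomic sequence is extended 66 nt on both sides of
the intron and the two exonic flanks are joined (the spliced context). For
minus-strand genes the window is reverse-complemented so it reads in
transcription order; building from a reverse-complemented genome with
flipped strand yields identical peptides (property-tested). Windows at
contig ends are clipped, kept, and flagged -- the junction-position filter
below removes those whose peptides no longer span the boundary
convincingly.

Each window is translated in frames 0--2 with the standard genetic code
(codons containing N give X). A candidate is discarded if a stop codon
occurs at or before the codon containing the junction boundary (the
peptide would end before crossing the junction) and truncated at the first
stop after it. A stop-free 132-nt window therefore yields a 44-residue
frame-0 peptide with the junction 22 residues in, and 43-residue peptides
in frames 1 and 2. Junctions without a usable strand (`.`, unstranded data
with no overlapping gene) are translated in all three frames of both
strands, giving up to six candidates. Novel exons and retained introns are
translated the same way, truncated at the first stop, and kept only at
`>= 7` aa.

Candidates must pass the junction-position check: start at most 22
residues before the boundary and end at least 22 residues after it
(`validate_junction_peptide()`, bounds = flank/3). Exact duplicate
sequences are then collapsed to the first-seen entry, and *after*
de-duplication every target (reference proteins + user-supplied
contaminants + junction and novel-region peptides) receives one decoy: a
seeded uniform permutation of its residues, preserving length and
amino-acid composition exactly. The decoy count therefore equals the full
target count and the database holds twice the target count in total.
Contaminants are user-supplied because the customary keratin/protease sets
are lab-specific.

## MS post-processing

* **Identification filter**: keep proteins with `>= 2` distinct peptides
  *or* `>= 13` spectral counts ("and/or" read as inclusive OR -- an AND
  would exclude the 1-peptide/13-spectra proteins the rule is written to
  admit).
* **FDR**: `100 * decoys / targets` at the protein and spectral levels.
  The denominator is targets-only by default, matching the common
  search-pipeline reporting convention; `include_decoys_in_denominator`
  switches to the (targets + decoys) convention since reported FDRs do not
  always say which was used.
* **dNSAF**: spectral counts of shared peptides are distributed in
  proportion to the sharing proteins' unique spectral counts (split evenly
  when none has unique support), then length-normalized and scaled to sum
  to 1. This is the standard distributed-NSAF convention; the package
  adopts it explicitly because abundance-factor definitions vary between
  pipelines. Parsimony filtering (removing subset proteins) is
  deliberately *not* applied, so junction-supporting entries are never
  hidden by a longer protein.
* **Peptide-to-junction mapping**: an identified peptide supports a
  junction if it occurs in a junction entry's sequence overlapping the
  boundary with at least one residue on each side; peptides supporting
  several junctions are flagged ambiguous, and unmatched peptides are
  listed rather than dropped.

## Expression thresholds and enrichment statistics

**TPM.** $\mathrm{TPM}_i = 10^6 (N_i/L_i) / \sum_j (N_j/L_j)$ per sample;
columns sum to $10^6$ and the measure is invariant to rescaling a sample's
counts. `expressed_by_tpm()` implements the simple `TPM >= 1` rule; note
that a fixed floor of 1 is calibrated to transcriptome-scale gene counts
(tens of thousands of genes) and is not meaningful on small synthetic
transcriptomes, where the calibration cutoff below is the appropriate
tool.

**Calibration cutoff.** Expressed genes are selected by sweeping cutoffs
over a monotone transform of the counts (default: `log2(count/size factor
+ 1)` with median-of-ratios size factors; any transform can be plugged
in). On real data the retained-gene curve falls steeply across the
unexpressed mode, is flat across a gap, then declines over the expressed
genes; the cutoff belongs in the flat stretch. The package places it at
the midpoint of the first value gap spanning at least 5% of the value
range with at least 10% of genes on each side. A naive
largest-single-grid-step rule was rejected: the per-step drop is maximal
where the unexpressed mode is *densest* (e.g. at the all-zero genes), not
where the modes separate, and misclassifies low-count unexpressed genes.
The 10% mass condition makes the cutoff invariant to a handful of
extremely highly expressed genes; when no qualifying gap exists (unimodal
or degenerate data) the function warns and retains all genes, which is
also the correct limit for a fully expressed transcriptome. Per
comparison, the expressed set is the union of the genes expressed in
either condition.

**Splicing enrichment.** For each two-condition comparison the NE
proportion among expressed genes and among spliced genes (genes with at
least one junction at `dpsi >= 0.2`) form two paired collections; a
two-sample Kolmogorov-Smirnov test contrasts them. Proportions are
discrete, so ties make the KS p-value approximate and conservative; the
tie warning is suppressed deliberately. At least two comparisons are
required.

**Exon counts.** Per expressed gene, the transcript with the most exons
defines the gene's exon count; restricting to expressed genes avoids
skewing the comparison, since NE genes (identified by proteomics) are by
construction expressed.

**Intrinsic disorder.** The default call requires at least 20 residues
with score > 0.5 anywhere in the protein (one score per residue of the
longest annotated protein per gene); `consecutive = TRUE` instead requires
a contiguous 20-residue stretch. Both rules circulate in the literature
and they disagree on proteins with scattered high-scoring residues, so
both are provided and neither is silently chosen. Enrichment of disorder
in NE vs non-NE proteins uses a two-sided Fisher's exact test; the
cross-product odds ratio $(ad)/(bc)$ is reported alongside the
conditional-MLE estimate and its 95% CI because the two differ for small
tables.

## Synthetic data

`sim_config()` fixes the study conditions; the generators are pure
functions of (config, seed).

* **Design**: 5 tissues (brain, heart, liver, muscle, testes), 3
  replicates per tissue, and two independently noised datasets `A`/`B`
  carrying the same planted events, mirroring a replicated two-lab body-map
  design and making cross-dataset intersection testable.
* **Gene models**: one contig per gene; exon count `2 + Poisson(4)` (an
  additive NE boost is available to give NE genes more exons), exon
  lengths 90--210 nt, introns 80--300 nt. Genes with `>= 4` exons get a
  second, exon-skipping transcript so per-gene maximum exon counts are
  non-trivial. Planted genes keep only their primary transcript, so no
  annotated junction competes for the cassette's splice sites and the
  planted inclusion level is the event's true PSI.
* **Planted events**: per tissue, 3 cassette events on distinct genes; the
  two inclusion junctions (novel) draw `NB(depth * psi)` reads and the
  skipping junction (annotated) `NB(depth * (1 - psi))`, with `psi = 0.8`
  in the labeled tissue and `0.05` elsewhere -- a strong but realistic
  tissue-specific inclusion profile of the kind reported for
  muscle-specific cassette exons.
* **Noise**: negative-binomial (Gamma-Poisson) counts with dispersion
  0.02, i.e. a biological coefficient of variation of about 0.14, typical
  of replicates from genetically identical laboratory animals; 0 gives
  Poisson noise. Each table also receives 20 spurious junctions with 1--5
  reads, about half predicting introns under 60 nt, to exercise both
  filters.
* **Counts and disorder**: the count matrix is a two-component mixture
  (near-zero Poisson vs log-normal negative-binomial) so the calibration
  curve has a knee; disorder tracks plant a `>= 25`-residue high-scoring
  region in flagged proteins and at most 10 high residues otherwise,
  placing truth safely on either side of the 20-residue rule.

What passing tests on these data do and do not show: the generator
emulates junction-count statistics, not sequencing. There is no read
mapping, no mapping bias, no multi-mapping ambiguity near paralogs, no
coverage-dependent junction discovery, no intron-retention signal from
exonic coverage, and the genome is random sequence rather than a real
assembly. Recovery results therefore validate the *inference logic*
(filtering, pooling, PSI, scoring, labeling, database construction) under
the stated noise model, not end-to-end performance on real RNA-Seq.

## Problem sizes and determinism

The test suite validates the statistical claims at deliberately desk-scale
sizes chosen by the package: tissue-label recovery over 20 seeds (5
tissues x 3 events x 2 junctions each, depth 100, 3 replicates;
sensitivity and precision both `>= 0.95`); PSI accuracy over 200 planted
junction measurements at depth 1000 (`|psi_hat - psi_true| <= 0.05` for
`>= 95%`); exact-test agreement with hypergeometric enumeration for all
2x2 tables with margins up to 30; and KS type-I error / power over 1000
replicates of 20 comparisons. All simulations run from fixed seeds, and
every generator re-seeds from its config, so results are bit-reproducible.

Known limitations: the PSI estimator carries no uncertainty interval, so
low-depth junctions can produce confident-looking dPSI values (the
read-support filter is the only guard); scoring treats comparisons
symmetrically and cannot represent graded specificity across two tissues
(such events land on NA by design); and the junction windows use raw
genomic flanks, which for junctions near other introns may include
intronic sequence that a spliced transcript would not contain -- acceptable
for novel junctions whose exon structure is unknown, but a known source of
non-biological peptides in the database (the decoy-based FDR absorbs
them).
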