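---
title: "Methods: editing-based target calling and poly(A)-site analysis"
author: "tribepas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: editing-based target calling and poly(A)-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribepas)
```

# Scope

`tribepas` implements the bespoke computations of a HyperTRIBE-style target
identification and polyadenylation study in *Arabidopsis*: an RNA-binding
protein (an m6A reader of the ECT/YTHDF family) fused to a hyperactive ADAR
catalytic domain deposits A-to-G editing marks on bound mRNAs; target
transcripts are called by testing per-position editing proportions against
free-ADAR control lines. A companion Smart-seq2 analysis extracts poly(A)
sites (PAS) from oligo-dT-primed reads, clusters them into poly(A)-site
clusters (PACs), and asks whether dominant PACs or dominant PASs shift
between genotypes. Everything runs offline: a synthetic-data module
generates toy genomes and ground-truth-labelled experiments that emulate
the statistical structure the analysis assumes.

Out of scope by design: read alignment, transcript quantification,
negative-binomial differential-expression fitting (consumed as an external
table), GO enrichment, and iCLIP peak calling.

# The differential editing model

At a candidate position, sample $i$ contributes $y_i$ reads of the
alternative base out of $n_i$ informative reads ($n_i = $ reference +
alternative counts; the editing proportion is $G/(A+G)$ in transcript
orientation). We model $y_i$ as beta-binomial with mean $p_i$ and
intra-site correlation $\rho$ shared across samples:

$$ y_i \sim \mathrm{BetaBin}(n_i, p_i, \rho), \qquad
   \mathrm{logit}(p_i) = \mathbf{x}_i^\top \beta , $$

where $\mathbf{x}_i$ holds an intercept, a group indicator (fusion vs.
control, or triple- vs. single-mutant background), and optionally a
z-scored per-sample ADAR-transgene abundance. The beta-binomial absorbs
replicate overdispersion: biological replicates of the same line do not
share one binomial proportion, and ignoring that inflates false positives
severely at realistic $\rho$.

Differential editing is a likelihood-ratio test between nested designs
(with/without the group column), all parameters fitted by direct
likelihood maximisation (Nelder-Mead on $(\beta, \mathrm{logit}\,\rho)$).
**Reference distribution.** With 5 + 5 replicates the usual
$\chi^2_1$ reference is anticonservative: under a null simulation at
proportion 0.01, $\rho = 0.02$, coverage $\sim$ Poisson(100), the raw
$p < 0.05$ fraction was 0.078. We therefore refer $\mathrm{LRT}/\mathrm{df}_1$
to an $F(\mathrm{df}_1,\, n - k)$ distribution, with $k$ the number of
mean parameters of the full model — the same small-sample device used by
quasi-likelihood F tests. The same simulation then yields 0.050–0.055
across null proportions 0.01–0.1, inside the calibration band the test
suite asserts ([0.03, 0.07]).

The effect size is reported as
$\log_2 \mathrm{FC} = \log_2(\hat p_{\text{test}} / \hat p_{\text{ref}})$
on pooled proportions with one pseudocount added to each group's
alternative and reference totals, so zero-count groups stay finite.

## Calling pipeline and thresholds

1. **Pileup** (`pileup_counts`): strand-aware base counts over annotated
   genes via `Rsamtools::pileup`, reported in transcript orientation
   (minus-strand genes: T→C on the reference strand becomes A→G).
   Positions under genes on both strands are dropped as unorientable;
   positions below `min_coverage` (default 10) in every fusion sample are
   dropped. `min_base_quality` defaults to 20.
2. **Candidates** (`detect_candidate_positions`): every position with at
   least one mismatching read in at least one fusion sample — no
   significance pre-filter, so the multiple-testing correction sees the
   full candidate set.
3. **Test + BH**: the beta-binomial LRT per candidate;
   Benjamini–Hochberg across all tested candidates.
4. **Filters** (`classify_and_filter_sites`): keep transcript-orientation
   A→G only; drop user-masked variants; drop heuristic SNPs — pooled
   control alternative proportion ≥ 0.35, or ≥ 0.8 in every sample of
   every group (the homozygous pattern). Both thresholds are exposed.
5. **Significance**: control comparison `p_adj < 0.01` and
   `log2fc > 1`; background comparison (`compare_backgrounds`)
   `p_adj < 0.1` and `|log2fc| > 0.25`, additionally requiring the
   position to be significant against the free-ADAR control in at least
   one background. All four thresholds are arguments.
6. **Gene aggregation** (`sites_to_target_genes`): a gene is a target iff
   it contains ≥ 1 significant filtered site; intergenic sites are
   reported, not dropped.

## The ADAR-abundance covariate

Editing scales with transgene dosage, and dosage varies across lines.
`compare_backgrounds` therefore z-scores the per-sample ADAR abundance
within the comparison ("scaled" abundance made unitless) and adds it to
the linear predictor, testing the background effect on top of it. The
synthetic covariate scenario couples each site's proportion linearly to
abundance with **no** true background effect, with a 3-fold dosage
difference between backgrounds (means 6 vs. 18 arbitrary units, 20%
replicate-level CV). Under that confound the covariate-free test reports
90–98% of sites at `p_adj < 0.1` while the covariate-adjusted test
reports ≤ 0.3% — the behaviour the covariate exists to produce. The
dosage figures are a design choice of the generator (nothing in the data
model pins them); they were chosen so the confound dominates
replicate-level dosage noise, and checked across independent seeds.

# Poly(A)-site extraction

- **Tail detection** (`trim_polya_tails`): a read is poly(A)-containing
  if it ends in ≥ 9 3'-terminal A (or begins with ≥ 9 5'-terminal T)
  nucleotides at a mismatch rate ≤ 6%. The tail is the *longest valid
  terminal run*; a run may contain interior mismatches but may not begin
  or end with one (otherwise non-A padding could inflate tails). Ties
  between a 3'A and 5'T reading go to 3'A; 5'T reads are antisense and
  flagged for reverse-complementation. The implementation strips maximal
  terminal A-runs and single mismatch bases alternately (vectorised); the
  test suite holds it to exact agreement with a brute-force enumeration
  of every terminal run length on 10,000 random reads.
- **Read filter** (`filter_trimmed_read`): retained portion longer than
  20 nt and mean Phred quality (arithmetic mean over the retained
  portion) greater than 25, both strict; mates of kept reads are kept.
- **PAS location** (`locate_pas`): the 3'-most aligned base in gene
  orientation; up to 2 soft-clipped/mismatched 3'-terminal bases do not
  shift the call (config-exposed).
- **Internal-priming filter** (`mispriming_read_filter`): a call is an
  oligo-dT mispriming artifact iff the 15-nt window immediately
  downstream (gene orientation) is ≥ 80% purines — inclusive threshold,
  window strictly downstream. Filtered reads are kept in a companion
  track, because the cluster-level filter below needs them. Windows
  truncated below 8 bases by a contig end classify genuine, with a
  warning.

# PAC calling

Per sample, `subtractive_kde` estimates Gaussian kernel densities
(bandwidth 15 nt, unit-mass kernel truncated at 4 sd) of PAS-read 3' ends
(foreground) and of tail-less gene-body read 3' ends (background), on the
nucleotide grid per contig and strand, and subtracts the background
scaled by the foreground/background read-count ratio (scale-free by
default; overridable). `call_clusters` takes maximal runs of positive
subtracted signal, trims each to the span of its supporting reads, and
requires ≥ 2 genuine reads. The bandwidth, minimum reads, and scale stand
in for an upstream pipeline's unpublished defaults and are all exposed.

Cluster-level filters, in order:

1. **False-positive filter** (`cluster_fp_filter`): a cluster is removed
   entirely iff misprime-filtered reads overlapping it outnumber genuine
   reads (strictly).
2. **Replicate consensus** (`replicate_consensus_and_merge`): a cluster
   must overlap (≥ 1 bp) clusters in ≥ 2 of 3 replicates of its genotype
   *and* overlap such a supported cluster in the other genotype; the
   survivors are coalesced with standard merge semantics and per-sample
   support is re-aggregated. Merging is idempotent and merged PACs are
   pairwise disjoint.
3. **Contig exclusion** (`exclude_contigs`): organelle/rDNA-analogue
   contigs (or listed loci) are dropped and counted.

`assign_pacs_to_genes` assigns each merged PAC to the overlapping gene on
the matching strand, extending annotated spans 200 nt 3'-ward (PASs fall
downstream of annotated ends); multi-gene overlaps resolve to the nearer
annotated 3' end.

# Genotype comparisons of poly(A) usage

For genes with more than one PAC, the **dominant PAC** per genotype is
the cluster with the most reads, summed over that genotype's replicates;
a gene is *shifted* iff the dominant identities differ. Exact read-count
ties are excluded (reason `"tie"`) rather than broken — any tie-break
would fabricate a result. The **most common PAS** is the single position
within all of a gene's PACs carrying the most reads; the signed distance
$d$ between genotypes is reported in gene orientation (negative =
upstream) and binned into ±10 / ±100 / ±1000 / >1000 classes that
provably partition the determinable genes, alongside a per-nucleotide
±40 nt histogram. Enrichment of shifts across target sets uses Fisher's
exact test (two-sided, from the hypergeometric distribution; odds ratio
with a Haldane 0.5 correction when a cell is empty).

# Target-set algebra

`build_target_sets` forms, over the expressed-gene universe: the
*permissive* set (HyperTRIBE targets of either reader, or iCLIP
targets), the *stringent* set (HyperTRIBE targets corroborated by
iCLIP), and the *non-target* set (expressed genes outside permissive).
The structural invariants (stringent ⊆ permissive; permissive and
non-target disjoint and jointly covering expressed) are assertable via
`validate_target_sets` and are exercised on randomized universes.
`specificity_classes` derives strictly reader-specific targets,
targets acquired by the other reader only in the triple-mutant
background, and putative targets of the third (knocked-out) reader.
`filter_and_classify_expression` applies the expression filters (mRNA
mode: ≥ 1 TPM in all samples and ≥ 5 TPM total; small-RNA mode: not
< 1 RPM everywhere) and labels genes up/down/unchanged from an external
DE table at FDR < 0.05 and fold change > 1.5 (or < 1/1.5), strictly.

# What the synthetic data emulates — and what it does not

`build_toy_genome` places non-overlapping genes on both strands of two
chromosome analogues plus one organelle and one rDNA analogue, each gene
carrying 1–3 PASs near its 3' end (dominant usage weight 0.7; in 10% of
multi-PAS genes the dominant PAS is swapped in the second genotype — the
injected ground-truth shifts) and, in about half the genes, an
internal-priming decoy whose downstream 15-nt window is ≥ 80% purine by
construction. PAS downstream windows are pyrimidine-biased and PAS/decoy
positions are non-A on the sense strand, so simulated tails separate
cleanly from templated genomic adenosines.

`simulate_editing_counts`/`simulate_editing_experiment` draw per-site
coverage from a Poisson and alternative counts from the beta-binomial
(with SNP positions at proportion ~1 or ~0.5 in *all* groups, including
controls), optionally coupling editing to ADAR dosage;
`simulate_smartseq_experiment` generates tailed, misprimed, and body
reads (multinomial class counts that always conserve the per-gene total)
with Gaussian PAS jitter, shifted-negative-binomial tail lengths floored
at 9 nt, and ≤ 6% interior tail mismatches.

Not emulated: isoform structure and splicing, position-dependent error
profiles, quality-score realism beyond a constant mean, aligner
artifacts (the simulator emits its own alignments — alignment is out of
scope), or genomic base-composition realism. Passing tests therefore
demonstrate correctness of the statistics and bookkeeping under the
stated noise model, not robustness to every artifact of real libraries.
Tail-length and jitter distributions are placeholders exposed in the
generator's arguments; nothing downstream depends on their exact shape.

# Numerical choices and degenerate inputs

- Coordinates are 1-based closed internally (the package is
  GRanges-native); BED output is 0-based half-open via `rtracklayer`,
  site tables are 1-based.
- Mismatch-rate comparisons in tail detection use a small additive
  tolerance so an exact 6% boundary (e.g. 3 of 50) is inclusive under
  floating-point arithmetic; the purine threshold is inclusive by direct
  `>= 0.8`.
- Beta-binomial fits start from the pooled proportion and
  $\rho = 0.05$; a non-finite or boundary fit yields `NA` p-values
  rather than a fabricated result. Sites where one group has zero
  coverage are skipped and reported.
- Kernel densities use a unit-mass truncated kernel on a grid padded by
  the kernel half-width, so each raw density sums exactly to its read
  count and no boundary mass is lost.
- Empty inputs return empty, typed results (empty candidate lists, empty
  tracks, `NA` recall against empty truth) instead of errors, except
  where the contract demands an error (empty genome, empty expressed
  universe, a genotype with fewer than two replicates).

# Problem sizes used by the validation suite

The acceptance-style checks run, per invocation: 10,000 random reads for
the trimming oracle; 2,000 null and 500 true editing sites (5 + 5
replicates, coverage ~ Poisson(100)); 300 covariate-coupled sites; and
one poly(A) experiment of 200 genes × 3 + 3 replicates with ~50–200
tailed reads per gene per sample (~430,000 reads). These sizes keep each
property estimate's Monte-Carlo error well below the asserted margins.

# Known limitations

- The beta-binomial F reference is a calibration device, not an exact
  small-sample distribution; calibration was verified at the study's
  replicate numbers (5v5) and proportions, not asymptotically.
- With ρ = 0.02 and five replicates per group, the pooled editing
  proportion has a sampling sd of ~0.03–0.04 for true proportions above
  0.3 regardless of coverage; point estimates at strongly edited sites
  are correspondingly noisy even when detection is certain.
- Dominant-PAC calls sum reads over replicates within genotype;
  replicate-level voting is not implemented (the aggregation the source
  analyses describe).
- The subtractive-KDE parameters stand in for an upstream tool's
  unpublished defaults; absolute PAC boundaries depend on them, though
  recovery of true PAS positions within ± one bandwidth is insensitive
  across the tested range.
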