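#' Draw ground-truth editing sites (and SNP decoys) on a toy genome
#'
#' Picks positions whose transcript-orientation reference base is `A` inside
#' nuclear genes and assigns each a true editing proportion per group, plus
#' optional homozygous/heterozygous SNP positions whose alternative-allele
#' proportion is the same in every group (including controls) by
#' construction.
#'
#' @param genome a [build_toy_genome()] result.
#' @param n_sites number of true editing sites.
#' @param prop named list of per-group true editing proportions; each entry
#'   is a single value or a range `c(lo, hi)` sampled uniformly per site.
#'   Groups absent from `prop` get proportion 0.
#' @param groups group labels the truth table should carry (defaults to
#'   `names(prop)`).
#' @param rho beta-binomial intra-site correlation across replicates.
#' @param n_snp_hom,n_snp_het numbers of homozygous (proportion 0.995) and
#'   heterozygous (proportion 0.5) SNP positions.
#' @param min_spacing minimum distance between drawn sites (nt), so that
#'   short simulated reads cover at most one site.
#' @param seed integer seed.
#' @return data.frame with `site_id`, `gene_id`, `contig`, `pos`, `strand`,
#'   `ref`, `alt` (both in transcript orientation), `kind`
#'   (`edit`/`snp_hom`/`snp_het`), `rho`, and one `prop_<group>` column per
#'   group.
#' @export
make_editing_truth <- function(genome, n_sites, prop, groups = names(prop),
                               rho = 0.02, n_snp_hom = 0L, n_snp_het = 0L,
                               min_spacing = 160L, seed = 1) {
  stopifnot(inherits(genome, "ToyGenome"), n_sites >= 0,
            !is.null(names(prop)))
  set.seed(seed)
  nuclear <- genome$genes[!genome$genes$contig %in% genome$decoy_contigs, ]

  ## candidate positions: transcript-orientation A inside nuclear genes
  cand <- list()
  for (i in seq_len(nrow(nuclear))) {
    g <- nuclear[i, ]
    chars <- strsplit(substring(genome$contigs[[g$contig]], g$start, g$end),
                      "")[[1]]
    want <- if (g$strand == "+") "A" else "T"  # forward-strand base
    at <- g$start + which(chars == want) - 1L
    if (length(at)) {
      cand[[length(cand) + 1L]] <- data.frame(
        gene_id = g$gene_id, contig = g$contig, pos = at,
        strand = g$strand, stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  cand <- cand[sample(nrow(cand)), ]

  pick_spaced <- function(df, n, used) {
    picked <- integer(0)
    for (r in seq_len(nrow(df))) {
      p <- df$pos[r]; ct <- df$contig[r]
      near <- used$contig == ct & abs(used$pos - p) < min_spacing
      if (!any(near)) {
        picked <- c(picked, r)
        used <- rbind(used, df[r, c("contig", "pos")])
      }
      if (length(picked) == n) break
    }
    list(rows = df[picked, , drop = FALSE], used = used)
  }

  used <- data.frame(contig = character(), pos = integer())
  sel <- pick_spaced(cand, n_sites + n_snp_hom + n_snp_het, used)
  got <- sel$rows
  if (nrow(got) < n_sites + n_snp_hom + n_snp_het) {
    stop("could not place ", n_sites + n_snp_hom + n_snp_het,
         " spaced sites; genome has room for ", nrow(got))
  }
  got$kind <- rep(c("edit", "snp_hom", "snp_het"),
                  c(n_sites, n_snp_hom, n_snp_het))
  got$ref <- "A"
  got$alt <- "G"
  got$rho <- rho
  for (gp in groups) {
    pr <- prop[[gp]]
    got[[paste0("prop_", gp)]] <- if (is.null(pr)) {
      0
    } else if (length(pr) == 2L) {
      runif(nrow(got), pr[1], pr[2])
    } else {
      rep_len(pr, nrow(got))
    }
  }
  got[got$kind == "snp_hom", paste0("prop_", groups)] <- 0.995
  got[got$kind == "snp_het", paste0("prop_", groups)] <- 0.5
  got$site_id <- sprintf("site%04d", seq_len(nrow(got)))
  rownames(got) <- NULL
  got[, c("site_id", "gene_id", "contig", "pos", "strand", "ref", "alt",
          "kind", "rho", paste0("prop_", groups))]
}

## per-sample editing proportion for one truth row, with optional linear
## coupling of editing to ADAR transgene abundance; `mean_abundance` is the
## mean over the whole experiment (not just the samples passed in)
truth_sample_props <- function(truth_row, samples, covariate_coupling,
                               mean_abundance = mean(samples$adar_abundance)) {
  p <- unlist(truth_row[paste0("prop_", samples$group)], use.names = FALSE)
  if (covariate_coupling && truth_row$kind == "edit") {
    p <- p * samples$adar_abundance / mean_abundance
  }
  pmin(pmax(p, 0), 0.995)
}

#' Simulate per-site base counts for an editing experiment
#'
#' The count-level generator behind the editing statistics: for every truth
#' site and sample it draws coverage from a Poisson and the
#' alternative-base count from a beta-binomial with the site's group
#' proportion and intra-site correlation `rho`, then scatters sequencing
#' errors over the remaining bases. With `covariate_coupling = TRUE` a
#' site's proportion scales linearly with the sample's ADAR abundance
#' (relative to the mean across samples), emulating transgene-dosage-driven
#' variation in editing.
#'
#' @param truth a [make_editing_truth()] table.
#' @param sample_sheet a [make_sample_sheet()] table; `group` values must
#'   match the truth's `prop_<group>` columns.
#' @param coverage_mean mean per-site coverage (Poisson).
#' @param error_rate per-base sequencing error rate in `[0, 0.05]`.
#' @param covariate_coupling couple editing proportion to `adar_abundance`.
#' @param seed integer seed.
#' @return A [base_count_matrix()] with the truth table as attribute
#'   `"truth"`.
#' @export
simulate_editing_counts <- function(truth, sample_sheet, coverage_mean = 100,
                                    error_rate = 0.001,
                                    covariate_coupling = FALSE, seed = 1) {
  stopifnot(coverage_mean > 0, error_rate >= 0, error_rate <= 0.05)
  if (any(truth$kind == "edit" & truth$ref != "A")) {
    stop("editing truth sites must have reference base A in transcript ",
         "orientation")
  }
  set.seed(seed)
  ns <- nrow(truth); np <- nrow(sample_sheet)
  counts <- array(0L, c(ns, np, 4L), dimnames = list(NULL, NULL, BASES))
  for (i in seq_len(ns)) {
    n <- rpois(np, coverage_mean)
    p <- truth_sample_props(truth[i, ], sample_sheet, covariate_coupling)
    alt <- rbetabinom(np, n, p, truth$rho[i])
    ## sequencing errors scatter reference reads over all three non-ref
    ## bases (including the alt base)
    rest <- n - alt
    other <- setdiff(BASES, c(truth$ref[i], truth$alt[i]))
    ea <- rbinom(np, rest, error_rate / 3)
    e1 <- rbinom(np, rest - ea, error_rate / 3)
    e2 <- rbinom(np, rest - ea - e1, error_rate / 3)
    counts[i, , truth$alt[i]] <- alt + ea
    counts[i, , other[1]] <- e1
    counts[i, , other[2]] <- e2
    counts[i, , truth$ref[i]] <- rest - ea - e1 - e2
  }
  bcm <- base_count_matrix(truth[, c("contig", "pos", "strand", "ref")],
                           counts, sample_sheet)
  attr(bcm, "truth") <- truth
  bcm
}

#' Simulate an editing experiment as aligned reads (BAM) plus truth table
#'
#' Per-site coverages and alternative-base counts are drawn exactly as in
#' [simulate_editing_counts()]; reads consistent with those counts are then
#' fabricated around each site (random offsets, genomic sequence elsewhere,
#' uniform sequencing errors) and written as coordinate-sorted, indexed BAM
#' per sample. Edits at minus-strand genes appear as T-to-C mismatches on
#' the genomic forward strand, as they would in real unstranded alignments.
#'
#' @inheritParams simulate_editing_counts
#' @param genome a [build_toy_genome()] result.
#' @param out_dir output directory for BAM files and the truth TSV.
#' @param read_length simulated read length (nt).
#' @param background_reads_per_gene extra mismatch-free reads scattered over
#'   each gene body, so pileups also contain non-candidate positions.
#' @return list with `bam` (named vector of BAM paths), `truth`,
#'   `truth_tsv`, and `sample_sheet`.
#' @export
simulate_editing_experiment <- function(genome, truth, sample_sheet, out_dir,
                                        coverage_mean = 30,
                                        error_rate = 0.001,
                                        read_length = 75L,
                                        background_reads_per_gene = 10L,
                                        covariate_coupling = FALSE,
                                        seed = 1) {
  stopifnot(inherits(genome, "ToyGenome"), coverage_mean > 0,
            error_rate >= 0, error_rate <= 0.05)
  if (any(truth$kind == "edit" & truth$ref != "A")) {
    stop("editing truth sites must have reference base A in transcript ",
         "orientation")
  }
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clen <- nchar(genome$contigs)

  ## forward-strand ref/alt base per site
  fwd_ref <- ifelse(truth$strand == "+", truth$ref, comp_base(truth$ref))
  fwd_alt <- ifelse(truth$strand == "+", truth$alt, comp_base(truth$alt))

  bam <- setNames(character(nrow(sample_sheet)), sample_sheet$sample_id)
  for (j in seq_len(nrow(sample_sheet))) {
    smp <- sample_sheet[j, ]
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      n <- rpois(1L, coverage_mean)
      if (n == 0L) next
      p <- truth_sample_props(truth[i, ], smp, covariate_coupling,
                              mean(sample_sheet$adar_abundance))
      alt_n <- rbetabinom(1L, n, p, truth$rho[i])
      offs <- sample.int(read_length, n, replace = TRUE) - 1L
      start <- pmin(pmax(truth$pos[i] - offs, 1L),
                    clen[[truth$contig[i]]] - read_length + 1L)
      seqs <- substring(genome$contigs[[truth$contig[i]]],
                        start, start + read_length - 1L)
      at <- truth$pos[i] - start + 1L
      base <- rep(fwd_ref[i], n)
      if (alt_n > 0) base[seq_len(alt_n)] <- fwd_alt[i]
      substr(seqs, at, at) <- base
      rows[[length(rows) + 1L]] <- data.frame(
        contig = truth$contig[i], start = start, seq = seqs,
        stringsAsFactors = FALSE)
    }
    if (background_reads_per_gene > 0) {
      for (gi in seq_len(nrow(genome$genes))) {
        g <- genome$genes[gi, ]
        m <- background_reads_per_gene
        start <- sample(g$start:max(g$start, g$end - read_length + 1L), m,
                        replace = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = g$contig, start = start,
          seq = substring(genome$contigs[[g$contig]], start,
                          start + read_length - 1L),
          stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, rows)
    ## uniform sequencing errors
    n_err <- rbinom(nrow(reads), read_length, error_rate)
    for (r in which(n_err > 0)) {
      at <- sample.int(read_length, n_err[r])
      for (a in at) {
        substr(reads$seq[r], a, a) <-
          sample(setdiff(BASES, substr(reads$seq[r], a, a)), 1L)
      }
    }
    bam[j] <- write_alignments(reads, clen,
                               file.path(out_dir, smp$sample_id),
                               read_length)
  }
  truth_tsv <- file.path(out_dir, "editing_truth.tsv")
  write.table(truth, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(bam = bam, truth = truth, truth_tsv = truth_tsv,
       sample_sheet = sample_sheet)
}

## write reads (contig, start, seq) as SAM text and convert to sorted,
## indexed BAM via Rsamtools
write_alignments <- function(reads, contig_lengths, dest_prefix,
                             read_length, mapq = 60L, qual_phred = 37L) {
  sam <- paste0(dest_prefix, ".sam")
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  lens <- nchar(reads$seq)
  body <- sprintf("r%06d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                  seq_len(nrow(reads)), reads$contig,
                  as.integer(reads$start), mapq, lens, reads$seq,
                  const_qual(qual_phred, lens))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, dest_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}
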