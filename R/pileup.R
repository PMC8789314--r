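#' Strand-aware base-count pileup over annotated genes
#'
#' Quantifies per-position A/C/G/T counts from aligned RNA-seq libraries,
#' reported in transcript orientation: positions inside minus-strand genes
#' have their observed bases complemented, so a genomic T-to-C mismatch on a
#' minus-strand gene is recorded as A-to-G. Positions overlapped by genes on
#' both strands are dropped (their transcript orientation is ambiguous), as
#' are positions below `min_coverage` in every fusion sample.
#'
#' @param bam_files named character vector of indexed BAM paths, names are
#'   sample ids matching `sample_sheet$sample_id`.
#' @param genome genome sequence: a `ToyGenome`, named character vector of
#'   contigs, or FASTA path (used for the reference base per position).
#' @param annotation gene models: a `ToyGenome`, `GRanges` with `gene_id`,
#'   or data.frame (`gene_id`, `contig`, `start`, `end`, `strand`).
#' @param sample_sheet sample sheet with `sample_id` and `group`.
#' @param fusion_samples sample ids whose coverage supports candidate
#'   positions (the ADAR-fusion libraries). Defaults to every sample whose
#'   group is not `"control"`.
#' @param min_base_quality minimum base quality to count (Phred).
#' @param min_coverage a position is kept only if at least one fusion
#'   sample covers it with at least this many reads.
#' @return A [base_count_matrix()].
#' @export
pileup_counts <- function(bam_files, genome, annotation, sample_sheet,
                          fusion_samples = NULL,
                          min_base_quality = 20L, min_coverage = 10L) {
  genes <- as_genes_df(annotation)
  seqs <- contig_seqs(genome)
  if (is.null(names(bam_files))) names(bam_files) <- sample_sheet$sample_id
  stopifnot(all(sample_sheet$sample_id %in% names(bam_files)))
  if (is.null(fusion_samples)) {
    fusion_samples <-
      sample_sheet$sample_id[sample_sheet$group != "control"]
  }
  gr <- genes_granges(genes)
  which_gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)

  pparam <- Rsamtools::PileupParam(
    max_depth = 250000L, min_base_quality = as.integer(min_base_quality),
    min_nucleotide_depth = 1L, distinguish_strands = FALSE,
    distinguish_nucleotides = TRUE, include_deletions = FALSE,
    include_insertions = FALSE)
  sparam <- Rsamtools::ScanBamParam(which = which_gr)

  per_sample <- lapply(sample_sheet$sample_id, function(sid) {
    bf <- Rsamtools::BamFile(bam_files[[sid]])
    p <- Rsamtools::pileup(bf, scanBamParam = sparam, pileupParam = pparam)
    p[p$nucleotide %in% BASES, c("seqnames", "pos", "nucleotide", "count")]
  })
  names(per_sample) <- sample_sheet$sample_id

  all_pos <- unique(do.call(rbind, lapply(per_sample, function(p)
    data.frame(contig = as.character(p$seqnames), pos = p$pos))))
  if (nrow(all_pos) == 0L) {
    return(base_count_matrix(
      data.frame(contig = character(), pos = integer(), strand = character(),
                 ref = character()),
      array(0L, c(0L, nrow(sample_sheet), 4L),
            dimnames = list(NULL, NULL, BASES)),
      sample_sheet))
  }
  all_pos <- all_pos[order(all_pos$contig, all_pos$pos), ]

  ## transcript strand from the overlapping gene(s); ambiguous positions out
  pos_gr <- GenomicRanges::GRanges(all_pos$contig,
                                   IRanges::IRanges(all_pos$pos, width = 1L))
  on_plus <- GenomicRanges::countOverlaps(
    pos_gr, gr[GenomicRanges::strand(gr) == "+"], ignore.strand = TRUE) > 0
  on_minus <- GenomicRanges::countOverlaps(
    pos_gr, gr[GenomicRanges::strand(gr) == "-"], ignore.strand = TRUE) > 0
  keep <- xor(on_plus, on_minus)
  all_pos <- all_pos[keep, , drop = FALSE]
  strand <- ifelse(on_plus[keep], "+", "-")

  key <- paste(all_pos$contig, all_pos$pos)
  counts <- array(0L, c(nrow(all_pos), nrow(sample_sheet), 4L),
                  dimnames = list(NULL, NULL, BASES))
  for (j in seq_along(per_sample)) {
    p <- per_sample[[j]]
    i <- match(paste(p$seqnames, p$pos), key)
    ok <- !is.na(i)
    counts[cbind(i[ok], j, match(as.character(p$nucleotide[ok]), BASES))] <-
      p$count[ok]
  }
  ## complement observed bases for minus-strand genes
  minus <- strand == "-"
  if (any(minus)) {
    counts[minus, , ] <- counts[minus, , c("T", "G", "C", "A"), drop = FALSE]
  }

  ## reference base in transcript orientation
  fwd_ref <- mapply(function(ct, p) substr(seqs[[ct]], p, p),
                    all_pos$contig, all_pos$pos, USE.NAMES = FALSE)
  if (any(!all_pos$contig %in% names(seqs))) {
    stop("BAM contigs missing from the genome: ",
         paste(setdiff(all_pos$contig, names(seqs)), collapse = ", "))
  }
  ref <- ifelse(minus, comp_base(fwd_ref), fwd_ref)

  ## coverage rule: >= min_coverage in at least one fusion sample
  fus <- match(fusion_samples, sample_sheet$sample_id)
  cov <- apply(counts[, fus, , drop = FALSE], c(1, 2), sum)
  keep2 <- apply(cov >= min_coverage, 1, any)

  base_count_matrix(
    data.frame(contig = all_pos$contig, pos = all_pos$pos, strand = strand,
               ref = ref, stringsAsFactors = FALSE)[keep2, , drop = FALSE],
    counts[keep2, , , drop = FALSE],
    sample_sheet)
}

#' Detect candidate editing positions
#'
#' Every position with at least one non-reference base in at least one
#' fusion sample is passed on for testing; no significance filtering is
#' applied at this stage. Mismatches confined to control samples do not
#' create candidates. For each candidate the alternative base is the
#' non-reference base with the highest total count across fusion samples
#' (ties broken in A,C,G,T order).
#'
#' @param bcm a [base_count_matrix()].
#' @param fusion_samples sample ids of the fusion libraries (default: all
#'   samples whose `group` is not `"control"`).
#' @return `bcm$sites` restricted to candidates, with columns `alt` and the
#'   row index `site_idx` into `bcm`.
#' @export
detect_candidate_positions <- function(bcm, fusion_samples = NULL) {
  if (is.null(fusion_samples)) {
    fusion_samples <- bcm$samples$sample_id[bcm$samples$group != "control"]
  }
  fus <- match(fusion_samples, bcm$samples$sample_id)
  stopifnot(!anyNA(fus))
  n <- nrow(bcm$sites)
  if (n == 0L) return(cbind(bcm$sites, alt = character(0), site_idx = integer(0)))

  mism <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
  for (b in BASES) {
    m <- bcm_base(bcm, b)[, fus, drop = FALSE]
    mism[, b] <- rowSums(m)
  }
  mism[cbind(seq_len(n), match(bcm$sites$ref, BASES))] <- 0L
  has_mism <- rowSums(mism) > 0L
  alt <- BASES[max.col(mism, ties.method = "first")]
  out <- cbind(bcm$sites, alt = alt, site_idx = seq_len(n))[has_mism, ,
                                                            drop = FALSE]
  rownames(out) <- NULL
  out
}
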