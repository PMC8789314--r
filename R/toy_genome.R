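#' Build a toy genome with annotated genes, poly(A) sites, and decoys
#'
#' Constructs a small synthetic genome for exercising the editing and
#' polyadenylation pipelines offline. Nuclear genes are placed without
#' overlap on two chromosome-analogue contigs, on both strands. Each gene
#' carries one to `max_pas` true poly(A) sites (PAS) near its 3' end with
#' per-genotype usage weights; a configurable fraction of multi-PAS genes
#' has its dominant PAS swapped in the second genotype (an injected
#' alternative-polyadenylation shift, recorded as ground truth). A subset of
#' genes carries an internal-priming decoy: a position whose downstream
#' 15-nt window is purine-rich by construction (>= 80% purines in gene
#' orientation), mimicking genomic stretches at which oligo-dT misprimes.
#' One organelle-analogue and one rDNA-analogue contig (each with a gene)
#' are included so contig-exclusion rules have something to exclude.
#'
#' The sense base at every PAS and decoy position is forced to a
#' non-adenosine so that untemplated tails are cleanly separable from
#' templated genomic adenosines, and PAS downstream windows are
#' pyrimidine-biased (purine fraction well below the 0.8 mispriming
#' threshold) so genuine sites are never mistaken for internal priming.
#'
#' Coordinates are 1-based closed internally (the Bioconductor convention);
#' [write_toy_genome()] emits 0-based half-open BED and 1-based GFF3/TSV.
#'
#' @param n_genes number of nuclear genes (>= 1).
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param gene_length_range two integers, uniform range of gene lengths (nt).
#' @param decoy_density probability that a gene carries an internal-priming
#'   decoy (at least one decoy is always placed genome-wide).
#' @param max_pas maximum number of true PASs per gene (drawn uniformly
#'   from `1:max_pas`).
#' @param genotypes character vector of genotype labels; PAS usage weights
#'   are generated per genotype. The first label is the reference genotype.
#' @param shift_fraction fraction of multi-PAS genes whose dominant PAS is
#'   swapped in the non-reference genotypes (ground-truth APA shifts).
#' @param intergenic minimum intergenic gap (nt).
#' @param contig_length optional fixed nuclear contig length; if the genes
#'   cannot be placed without overlap within it, construction fails with a
#'   diagnostic.
#'
#' @return An object of class `ToyGenome`: a list with `contigs` (named
#'   character vector of sequences), `genes` (data.frame: gene_id, contig,
#'   start, end, strand), `pas` (data.frame: gene_id, contig, pos, strand
#'   and one `weight_<genotype>` column per genotype), `decoys` (data.frame
#'   of internal-priming decoy positions), `decoy_contigs` (names of the
#'   organelle/rDNA analogues), `shifted_genes`, and `genotypes`.
#' @examples
#' g <- build_toy_genome(n_genes = 10, seed = 1)
#' nrow(g$genes)
#' @export
build_toy_genome <- function(n_genes = 50, seed = 1,
                             gene_length_range = c(600L, 1200L),
                             decoy_density = 0.5, max_pas = 3L,
                             genotypes = c("wt", "mut"),
                             shift_fraction = 0.1,
                             intergenic = 300L,
                             contig_length = NULL) {
  if (n_genes < 1) stop("`n_genes` must be >= 1: an empty genome is not usable")
  stopifnot(length(genotypes) >= 1, max_pas >= 1,
            decoy_density >= 0, decoy_density <= 1)
  set.seed(seed)

  gene_len <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                     replace = TRUE)
  contig_of <- rep(c("chr1", "chr2"), length.out = n_genes)
  strand_of <- sample(c("+", "-"), n_genes, replace = TRUE)

  ## sequential non-overlapping placement per contig
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    contig = contig_of, start = NA_integer_, end = NA_integer_,
    strand = strand_of, stringsAsFactors = FALSE
  )
  nuclear <- c("chr1", "chr2")
  contig_len <- setNames(integer(length(nuclear)), nuclear)
  for (ct in nuclear) {
    idx <- which(genes$contig == ct)
    at <- intergenic + 1L
    for (i in idx) {
      genes$start[i] <- at
      genes$end[i] <- at + gene_len[i] - 1L
      at <- genes$end[i] + intergenic + sample(0:intergenic, 1L)
    }
    contig_len[ct] <- at + intergenic
    if (!is.null(contig_length)) {
      if (contig_len[ct] > contig_length)
        stop("gene placement exhausted: ", length(idx), " genes need ",
             contig_len[ct], " nt on ", ct, " but `contig_length` is ",
             contig_length)
      contig_len[ct] <- as.integer(contig_length)
    }
  }

  ## decoy contigs: organelle and rDNA analogues, one gene each
  decoy_contigs <- c("mito", "rdna")
  contig_len <- c(contig_len, mito = 2500L, rdna = 2000L)
  extra <- data.frame(
    gene_id = c("mito_g1", "rdna_g1"),
    contig = decoy_contigs,
    start = c(501L, 401L), end = c(1500L, 1400L),
    strand = c("+", "-"), stringsAsFactors = FALSE
  )
  genes <- rbind(genes, extra)

  ## random base sequence per contig (as per-base vectors for patching)
  seqs <- lapply(contig_len, function(n)
    sample(BASES, n, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)))

  ## helper: write a sense-orientation base vector starting at `pos + 1`
  ## downstream of `pos` (gene orientation) into the forward-strand sequence
  patch_downstream <- function(seqv, pos, strand, sense_bases) {
    k <- length(sense_bases)
    if (strand == "+") {
      at <- pos + seq_len(k)
      ok <- at <= length(seqv)
      seqv[at[ok]] <- sense_bases[ok]
    } else {
      at <- pos - seq_len(k)
      ok <- at >= 1L
      seqv[at[ok]] <- comp_base(sense_bases[ok])
    }
    seqv
  }
  patch_at <- function(seqv, pos, strand, sense_base) {
    seqv[pos] <- if (strand == "+") sense_base else comp_base(sense_base)
    seqv
  }

  ## place PASs near each gene's 3' end and decoys in gene bodies
  pas_rows <- list()
  decoy_rows <- list()
  shifted <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start + 1L
    n_pas <- sample(seq_len(max_pas), 1L)
    ## offsets from the 3' end, most-proximal first; kept >= 70 nt inside
    ## the gene so simulated read bodies fit without clamping
    offs <- 70L + cumsum(c(0L, sample(150:300, max(0L, n_pas - 1L),
                                      replace = TRUE)))
    offs <- offs[offs < len - 70L]
    n_pas <- length(offs)
    pos <- if (g$strand == "+") g$end - offs else g$start + offs

    ## usage weights: a clear dominant plus an even split of the rest
    w <- rep((1 - 0.7) / max(1L, n_pas - 1L), n_pas)
    dom <- sample(seq_len(n_pas), 1L)
    if (n_pas == 1L) w <- 1 else w[dom] <- 0.7
    wmat <- matrix(rep(w, length(genotypes)), ncol = length(genotypes))
    colnames(wmat) <- genotypes
    is_shift <- n_pas > 1L && length(genotypes) > 1L &&
      runif(1) < shift_fraction
    if (is_shift) {
      alt <- safe_sample(setdiff(seq_len(n_pas), dom), 1L)
      for (gt in genotypes[-1]) {
        wmat[c(dom, alt), gt] <- wmat[c(alt, dom), gt]
      }
      shifted <- c(shifted, g$gene_id)
    }
    pr <- data.frame(gene_id = g$gene_id, contig = g$contig, pos = pos,
                     strand = g$strand, stringsAsFactors = FALSE)
    for (gt in genotypes) pr[[paste0("weight_", gt)]] <- wmat[, gt]
    pas_rows[[i]] <- pr

    ## patch sense base at PAS (non-A) and a pyrimidine-biased downstream
    ## window (purine fraction <= 8/15, safely below the 0.8 threshold)
    for (p in pos) {
      seqs[[g$contig]] <- patch_at(seqs[[g$contig]], p, g$strand, "C")
      k_pur <- sample(2:7, 1L)
      win <- sample(c(sample(PURINES, k_pur, replace = TRUE),
                      sample(c("C", "T"), 15L - k_pur, replace = TRUE)))
      seqs[[g$contig]] <- patch_downstream(seqs[[g$contig]], p, g$strand, win)
    }

    ## internal-priming decoy: gene-body position with purine-rich
    ## downstream window, kept >= 100 nt away from any PAS
    want_decoy <- runif(1) < decoy_density ||
      (i == 1L && decoy_density > 0)
    if (want_decoy) {
      cand <- 100:(len - 120L)
      cand <- cand[vapply(cand, function(o) all(abs(o - offs) >= 100L), TRUE)]
      if (length(cand)) {
        o <- safe_sample(cand, 1L)
        dpos <- if (g$strand == "+") g$end - o else g$start + o
        seqs[[g$contig]] <- patch_at(seqs[[g$contig]], dpos, g$strand, "C")
        k_pur <- sample(13:15, 1L)
        win <- sample(c(sample(PURINES, k_pur, replace = TRUE,
                               prob = c(0.8, 0.2)),
                        sample(c("C", "T"), 15L - k_pur, replace = TRUE)))
        seqs[[g$contig]] <- patch_downstream(seqs[[g$contig]], dpos,
                                             g$strand, win)
        decoy_rows[[length(decoy_rows) + 1L]] <-
          data.frame(gene_id = g$gene_id, contig = g$contig, pos = dpos,
                     strand = g$strand, stringsAsFactors = FALSE)
      }
    }
  }

  out <- structure(list(
    contigs = vapply(seqs, paste, "", collapse = ""),
    genes = genes,
    pas = do.call(rbind, pas_rows),
    decoys = if (length(decoy_rows)) do.call(rbind, decoy_rows) else
      data.frame(gene_id = character(), contig = character(),
                 pos = integer(), strand = character()),
    decoy_contigs = decoy_contigs,
    genotypes = genotypes,
    shifted_genes = shifted,
    seed = seed
  ), class = "ToyGenome")
  rownames(out$pas) <- NULL
  out
}

#' @export
print.ToyGenome <- function(x, ...) {
  cat("ToyGenome:", length(x$contigs), "contigs (",
      paste0(names(x$contigs), collapse = ", "), "), ",
      nrow(x$genes), "genes, ", nrow(x$pas), "PASs, ",
      nrow(x$decoys), "internal-priming decoys\n")
  invisible(x)
}

#' Write a toy genome to standard annotation formats
#'
#' Emits the genome FASTA, gene models as GFF3 and BED6, and ground-truth
#' TSVs for PAS usage weights and internal-priming decoys. Outputs are
#' deterministic: the same `ToyGenome` always produces byte-identical files.
#'
#' @param genome a [build_toy_genome()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths
#'   (`fasta`, `gff3`, `bed`, `pas`, `decoys`).
#' @export
write_toy_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "ToyGenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gff3 = file.path(dir, "genes.gff3"),
             bed = file.path(dir, "genes.bed"),
             pas = file.path(dir, "true_pas.tsv"),
             decoys = file.path(dir, "decoys.tsv"))

  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, paths["fasta"])

  gr <- genes_granges(genome$genes)
  gr$type <- "gene"
  gr$ID <- genome$genes$gene_id
  rtracklayer::export(gr, paths["gff3"], format = "gff3")

  bed <- gr
  bed$name <- genome$genes$gene_id
  bed$score <- 0L
  rtracklayer::export(bed, paths["bed"], format = "bed")

  write.table(genome$pas, paths["pas"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(genome$decoys, paths["decoys"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Build a sample sheet for simulated experiments
#'
#' @param groups character vector of group labels (e.g. genotype or
#'   fusion/control); one block of replicates is generated per label.
#' @param n_reps replicates per group (scalar or per-group vector); at least
#'   2 per group are required for any statistical comparison.
#' @param adar_mean mean ADAR transgene abundance per group (scalar or named
#'   by group). Per-sample abundances are lognormal around this mean.
#' @param adar_cv coefficient of variation of abundance across replicates.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `group`, `replicate`,
#'   `adar_abundance`.
#' @export
make_sample_sheet <- function(groups, n_reps = 5L, adar_mean = 10,
                              adar_cv = 0.25, seed = 1) {
  set.seed(seed)
  n_reps <- rep_len(n_reps, length(groups))
  if (any(n_reps < 2)) stop("need >= 2 replicates per group")
  if (is.null(names(adar_mean))) {
    adar_mean <- setNames(rep_len(adar_mean, length(groups)), groups)
  }
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[i]
    sdlog <- sqrt(log(1 + adar_cv^2))
    ab <- stats::rlnorm(n_reps[i], log(adar_mean[[g]]) - sdlog^2 / 2, sdlog)
    data.frame(sample_id = sprintf("%s_r%d", g, seq_len(n_reps[i])),
               group = g, replicate = seq_len(n_reps[i]),
               adar_abundance = ab, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
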