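#' Call merged poly(A)-site clusters from an extraction result
#'
#' The full PAC-calling pipeline over all samples of an
#' [extract_polya()] result: per-sample subtractive KDE, cluster calling,
#' the cluster-level mispriming filter, replicate consensus across both
#' genotypes, interval merging, organelle/rDNA contig exclusion, and gene
#' assignment.
#'
#' @param ex an [extract_polya()] result covering all samples.
#' @param genotype_map named character vector, sample id -> genotype.
#' @param genome a `ToyGenome` (used for annotation and its
#'   `decoy_contigs`), or pass `annotation`/`exclude` explicitly.
#' @param annotation gene models (defaults to the genome's).
#' @param exclude contigs to exclude (defaults to the genome's
#'   `decoy_contigs`).
#' @param bandwidth,min_reads see [subtractive_kde()] and
#'   [call_clusters()].
#' @param min_reps replicate-consensus threshold (see
#'   [replicate_consensus_and_merge()]).
#' @param extension gene 3' extension for assignment (nt).
#' @return list: `pacs` (merged, filtered, gene-assigned PAC table),
#'   `per_sample` (per-sample cluster tables with filter flags),
#'   `pas_by_sample` (per-sample `PasCount`s).
#' @export
call_pacs <- function(ex, genotype_map, genome, annotation = genome,
                      exclude = NULL, bandwidth = 15, min_reads = 2L,
                      min_reps = 2L, extension = 200L) {
  if (is.null(exclude) && inherits(genome, "ToyGenome")) {
    exclude <- genome$decoy_contigs
  }
  samples <- names(genotype_map)
  per_sample <- list()
  pas_by_sample <- list()
  for (s in samples) {
    fg <- ex$pas$genuine[ex$pas$genuine$sample == s, , drop = FALSE]
    mp <- ex$pas$misprimed[ex$pas$misprimed$sample == s, , drop = FALSE]
    bg <- ex$body_ends[ex$body_ends$sample == s, , drop = FALSE]
    pas_by_sample[[s]] <- structure(list(genuine = fg, misprimed = mp),
                                    class = "PasCount")
    if (nrow(fg) == 0L) {
      per_sample[[s]] <- data.frame(contig = character(),
                                    start = integer(), end = integer(),
                                    strand = character(),
                                    n_reads = integer(),
                                    genuine_reads = integer(),
                                    misprimed_reads = integer(),
                                    fp_removed = logical())
      next
    }
    track <- subtractive_kde(fg, bg, bandwidth = bandwidth)
    cl <- call_clusters(track, min_reads = min_reads)
    per_sample[[s]] <- cluster_fp_filter(cl, pas_by_sample[[s]])
  }
  merged <- replicate_consensus_and_merge(per_sample, genotype_map,
                                          pas_by_sample, min_reps)
  merged <- exclude_contigs(merged, contigs = exclude)
  merged <- assign_pacs_to_genes(merged, annotation, extension)
  list(pacs = merged, per_sample = per_sample,
       pas_by_sample = pas_by_sample)
}

#' Export merged PACs as BED
#'
#' Writes the merged PAC table as a BED6 file (0-based half-open; name is
#' the assigned gene id, score the total read support).
#'
#' @param pacs a merged PAC table (see [call_pacs()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pac_bed <- function(pacs, path) {
  gr <- pac_granges(pacs)
  gr$name <- ifelse(is.na(pacs$gene_id), ".", pacs$gene_id)
  score <- if ("total_support" %in% names(pacs)) pacs$total_support else 0L
  gr$score <- pmin(score, 1000L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
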