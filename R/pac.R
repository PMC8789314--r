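## Poly(A)-site-cluster (PAC) calling: subtractive kernel density
## estimation against gene-body background, cluster filters, replicate
## consensus, merging, and gene assignment.

#' Subtractive kernel density estimation of poly(A) signal
#'
#' Estimates, per contig and strand, a Gaussian kernel density of
#' poly(A)-supported read 3' ends (foreground) and of tail-less gene-body
#' read 3' ends (the negative control) on the nucleotide grid, and
#' subtracts the scaled background from the foreground:
#' `signal = KDE(foreground) - scale * KDE(background)`. Each raw density
#' sums to its track's read count (the kernel is normalised to unit mass);
#' the default scale is the foreground/background read-count ratio per
#' contig and strand, which makes the subtraction scale-free.
#'
#' @param pas_counts one sample's genuine PAS track: data.frame `contig`,
#'   `pos`, `strand`, `count`.
#' @param body_ends same layout, 3' ends of the sample's gene-body reads.
#' @param bandwidth Gaussian kernel sd in nt (default 15).
#' @param background_scale fixed scale, or `NULL` for the read-count ratio.
#' @return An object of class `DensityTrack`: per-(contig, strand)
#'   components with `grid_start`, `fg_density`, `bg_density`, `signal`,
#'   and the raw foreground counts.
#' @export
subtractive_kde <- function(pas_counts, body_ends, bandwidth = 15,
                            background_scale = NULL) {
  half <- as.integer(ceiling(4 * bandwidth))
  kern <- dnorm(-half:half, sd = bandwidth)
  kern <- kern / sum(kern)

  comp_key <- function(df) paste(df$contig, df$strand, sep = ":")
  fg_keys <- unique(comp_key(pas_counts))
  comps <- list()
  for (key in fg_keys) {
    fg <- pas_counts[comp_key(pas_counts) == key, , drop = FALSE]
    bg <- body_ends[comp_key(body_ends) == key, , drop = FALSE]
    lo <- min(fg$pos) - half
    hi <- max(fg$pos) + half
    grid_n <- hi - lo + 1L

    dens <- function(pos, count) {
      ## direct short-kernel convolution on a grid padded by the kernel
      ## half-width, so no boundary values are lost
      x <- numeric(grid_n + 2L * half)
      on <- pos >= lo & pos <= hi
      if (any(on)) {
        idx <- pos[on] - lo + 1L + half
        x[idx] <- x[idx] + count[on]
      }
      y <- stats::filter(x, kern, method = "convolution", sides = 2L)
      as.numeric(y[(half + 1L):(half + grid_n)])
    }
    fg_d <- dens(fg$pos, fg$count)
    bg_d <- dens(bg$pos, bg$count)
    scale <- if (!is.null(background_scale)) background_scale else {
      if (sum(bg$count) > 0) sum(fg$count) / sum(bg$count) else 0
    }
    comps[[key]] <- list(contig = fg$contig[1], strand = fg$strand[1],
                         grid_start = lo, fg_density = fg_d,
                         bg_density = bg_d, scale = scale,
                         signal = fg_d - scale * bg_d,
                         fg_counts = fg[, c("pos", "count")])
  }
  structure(list(components = comps, bandwidth = bandwidth),
            class = "DensityTrack")
}

#' Call per-sample poly(A)-site clusters from a density track
#'
#' Clusters are maximal runs of positive subtracted signal, trimmed to the
#' span of the supporting PAS reads, and must contain at least `min_reads`
#' genuine reads.
#'
#' @param track a [subtractive_kde()] result.
#' @param min_reads minimum genuine read support per cluster (default 2).
#' @return data.frame `contig`, `start`, `end` (1-based closed), `strand`,
#'   `n_reads`.
#' @export
call_clusters <- function(track, min_reads = 2L) {
  out <- list()
  for (cmp in track$components) {
    pos_ok <- cmp$signal > 0
    if (!any(pos_ok)) next
    r <- rle(pos_ok)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    glo <- cmp$grid_start + run_start[r$values] - 1L
    ghi <- cmp$grid_start + run_end[r$values] - 1L
    ## read support per run via sorted positions and prefix sums
    ord <- order(cmp$fg_counts$pos)
    pos <- cmp$fg_counts$pos[ord]
    cs0 <- c(0, cumsum(cmp$fg_counts$count[ord]))
    i0 <- findInterval(glo - 1L, pos)
    i1 <- findInterval(ghi, pos)
    n_reads <- cs0[i1 + 1L] - cs0[i0 + 1L]
    keep <- i1 > i0 & n_reads >= min_reads
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      contig = cmp$contig,
      start = pos[i0[keep] + 1L],   # trimmed to the supporting read span
      end = pos[i1[keep]],
      strand = cmp$strand,
      n_reads = as.integer(n_reads[keep]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_reads = integer()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

pac_granges <- function(pacs) {
  GenomicRanges::GRanges(pacs$contig,
                         IRanges::IRanges(pacs$start, pacs$end),
                         strand = pacs$strand)
}

## total counts of a track overlapping each PAC interval (same strand)
overlap_track_counts <- function(pacs, track) {
  out <- integer(nrow(pacs))
  if (nrow(track) == 0L || nrow(pacs) == 0L) return(out)
  pg <- pac_granges(pacs)
  tg <- GenomicRanges::GRanges(track$contig,
                               IRanges::IRanges(track$pos, width = 1L),
                               strand = track$strand)
  hits <- GenomicRanges::findOverlaps(tg, pg)
  agg <- tapply(track$count[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Cluster-level false-positive filter against mispriming
#'
#' A cluster is removed in its entirety iff the misprime-filtered reads
#' overlapping it outnumber the genuine reads overlapping it (strictly).
#'
#' @param pacs a [call_clusters()] result.
#' @param pas a `PasCount` for the same sample (genuine + misprimed
#'   tracks).
#' @return `pacs` with `genuine_reads`, `misprimed_reads`, and the logical
#'   `fp_removed`.
#' @export
cluster_fp_filter <- function(pacs, pas) {
  pacs$genuine_reads <- overlap_track_counts(pacs, pas$genuine)
  pacs$misprimed_reads <- overlap_track_counts(pacs, pas$misprimed)
  pacs$fp_removed <- pacs$misprimed_reads > pacs$genuine_reads
  pacs
}

#' Replicate consensus across genotypes and interval merge
#'
#' Within each genotype, a per-sample cluster is supported when clusters
#' overlapping it (>= 1 bp, same strand) exist in at least `min_reps`
#' replicates (itself included). Clusters must additionally overlap a
#' supported cluster of every other genotype. All surviving clusters are
#' then coalesced with standard merge semantics (overlapping or touching
#' intervals unite), and per-sample read support is re-aggregated onto the
#' merged intervals.
#'
#' @param pacs_by_sample named list (sample id -> [call_clusters()] table);
#'   rows flagged `fp_removed` are ignored when present.
#' @param genotype_map named character vector, sample id -> genotype; every
#'   genotype needs >= 2 samples.
#' @param pas_by_sample optional named list of `PasCount` objects used to
#'   re-aggregate per-sample support from the genuine tracks (otherwise
#'   overlapping cluster read counts are summed).
#' @param min_reps replicate-support threshold (default 2).
#' @return data.frame of merged PACs: `pac_id`, `contig`, `start`, `end`,
#'   `strand`, one `support_<sample>` column per sample, `total_support`.
#' @export
replicate_consensus_and_merge <- function(pacs_by_sample, genotype_map,
                                          pas_by_sample = NULL,
                                          min_reps = 2L) {
  samples <- names(pacs_by_sample)
  stopifnot(!is.null(samples), all(samples %in% names(genotype_map)))
  geno <- genotype_map[samples]
  tab <- table(geno)
  if (any(tab < 2)) {
    stop("replicate consensus needs >= 2 replicates per genotype; got: ",
         paste(names(tab), tab, sep = "=", collapse = ", "))
  }

  grs <- lapply(pacs_by_sample, function(p) {
    if ("fp_removed" %in% names(p)) p <- p[!p$fp_removed, , drop = FALSE]
    pac_granges(p)
  })

  ## replicate support within genotype
  supported <- lapply(samples, function(s) {
    gr <- grs[[s]]
    if (length(gr) == 0L) return(gr[0])
    mates <- samples[geno == geno[[s]] & samples != s]
    nsup <- rep(1L, length(gr))
    for (m in mates) {
      nsup <- nsup + (GenomicRanges::countOverlaps(gr, grs[[m]]) > 0L)
    }
    gr[nsup >= min_reps]
  })
  names(supported) <- samples

  by_geno <- lapply(unique(geno), function(g) {
    x <- supported[samples[geno == g]]
    do.call(c, unname(x))
  })
  names(by_geno) <- unique(geno)

  ## a cluster survives iff supported in its genotype and overlapping a
  ## supported cluster of every other genotype
  final <- lapply(samples, function(s) {
    gr <- supported[[s]]
    if (length(gr) == 0L) return(gr)
    keep <- rep(TRUE, length(gr))
    for (g in setdiff(names(by_geno), geno[[s]])) {
      keep <- keep & GenomicRanges::countOverlaps(gr, by_geno[[g]]) > 0L
    }
    gr[keep]
  })
  merged <- GenomicRanges::reduce(do.call(c, unname(final)))
  merged <- merged[order(as.character(GenomeInfoDb::seqnames(merged)),
                         GenomicRanges::start(merged))]

  out <- data.frame(
    pac_id = sprintf("PAC%04d", seq_along(merged)),
    contig = as.character(GenomeInfoDb::seqnames(merged)),
    start = GenomicRanges::start(merged),
    end = GenomicRanges::end(merged),
    strand = as.character(GenomicRanges::strand(merged)),
    stringsAsFactors = FALSE)

  for (s in samples) {
    sup <- if (!is.null(pas_by_sample)) {
      trk <- pas_by_sample[[s]]
      if (inherits(trk, "PasCount")) trk <- trk$genuine
      if ("sample" %in% names(trk)) trk <- trk[trk$sample == s, ,
                                               drop = FALSE]
      overlap_track_counts(out, trk)
    } else {
      p <- pacs_by_sample[[s]]
      if ("fp_removed" %in% names(p)) p <- p[!p$fp_removed, , drop = FALSE]
      cnt <- integer(nrow(out))
      if (nrow(p)) {
        hits <- GenomicRanges::findOverlaps(pac_granges(p), merged)
        agg <- tapply(p$n_reads[S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits), sum)
        cnt[as.integer(names(agg))] <- as.integer(agg)
      }
      cnt
    }
    out[[paste0("support_", s)]] <- sup
  }
  out$total_support <- rowSums(out[, paste0("support_", samples),
                                   drop = FALSE])
  out
}

#' Drop clusters on excluded contigs or loci
#'
#' Removes clusters on organelle/rDNA-analogue contigs or overlapping
#' excluded intervals, reporting how many were dropped.
#'
#' @param pacs a PAC table (`contig`, `start`, `end`, `strand`).
#' @param contigs contig names to exclude entirely.
#' @param ranges optional data.frame (`contig`, `start`, `end`) of excluded
#'   loci (e.g. rDNA arrays inside a nuclear contig).
#' @return the retained rows; the number removed is attached as attribute
#'   `"n_excluded"` and reported via `message()`.
#' @export
exclude_contigs <- function(pacs, contigs = character(0), ranges = NULL) {
  drop <- pacs$contig %in% contigs
  if (!is.null(ranges) && nrow(ranges) > 0 && nrow(pacs) > 0) {
    pg <- GenomicRanges::GRanges(pacs$contig,
                                 IRanges::IRanges(pacs$start, pacs$end))
    rg <- GenomicRanges::GRanges(ranges$contig,
                                 IRanges::IRanges(ranges$start, ranges$end))
    drop <- drop | GenomicRanges::countOverlaps(pg, rg,
                                                ignore.strand = TRUE) > 0L
  }
  message(sum(drop), " cluster(s) removed on excluded contigs/loci")
  out <- pacs[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Assign merged PACs to genes
#'
#' A PAC is assigned to the gene whose annotated span, extended 3'-ward by
#' `extension` nt (poly(A) sites fall downstream of annotated ends), it
#' overlaps on the matching strand. When several genes overlap, the gene
#' whose annotated 3' end is nearest to the PAC wins; unassigned PACs are
#' kept with `gene_id = NA`.
#'
#' @param pacs merged PAC table.
#' @param annotation gene models (see [pileup_counts()]).
#' @param extension 3' extension in nt (default 200).
#' @return `pacs` with a `gene_id` column.
#' @export
assign_pacs_to_genes <- function(pacs, annotation, extension = 200L) {
  genes <- as_genes_df(annotation)
  ext <- genes
  ext$end <- ifelse(ext$strand == "+", ext$end + extension, ext$end)
  ext$start <- ifelse(ext$strand == "-", ext$start - extension, ext$start)
  gg <- genes_granges(ext)
  pg <- pac_granges(pacs)
  hits <- GenomicRanges::findOverlaps(pg, gg)
  gene_id <- rep(NA_character_, nrow(pacs))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    g3 <- ifelse(genes$strand == "+", genes$end, genes$start)
    d <- ifelse(g3[s] >= pacs$start[q] & g3[s] <= pacs$end[q], 0L,
                pmin(abs(pacs$start[q] - g3[s]), abs(pacs$end[q] - g3[s])))
    ord <- order(q, d, genes$gene_id[s])
    first <- !duplicated(q[ord])
    gene_id[q[ord][first]] <- genes$gene_id[s[ord][first]]
  }
  pacs$gene_id <- gene_id
  if (anyNA(gene_id)) {
    message(sum(is.na(gene_id)), " PAC(s) not assignable to a gene")
  }
  pacs
}
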