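## Genotype comparisons of poly(A) usage: dominant-PAC shifts, distances
## between most-common PASs, distance binning, and Fisher-exact enrichment.

#' Summarise PAC usage per gene and genotype
#'
#' For every gene with assigned PACs, aggregates genuine read support per
#' PAC and genotype (summed over the genotype's replicates), and determines
#' the most-common PAS per genotype: the single position within all of the
#' gene's PACs carrying the most reads (ties make it undeterminable for
#' that genotype).
#'
#' @param pacs merged PAC table with `gene_id` (see
#'   [assign_pacs_to_genes()]); unassigned PACs are ignored.
#' @param pas_by_sample named list (sample id -> `PasCount` or genuine
#'   track data.frame).
#' @param genotype_map named character vector, sample id -> genotype.
#' @param genotypes the two genotype labels in (reference, test) order;
#'   defaults to the sorted unique genotypes.
#' @return An object of class `GenePacSummary`: `genes` (gene_id, strand,
#'   n_pacs), `pac_totals` (per gene x PAC read totals per genotype), `mcp`
#'   (per gene x genotype most-common PAS, count and tie flag), and
#'   `genotypes`.
#' @export
gene_pac_summary <- function(pacs, pas_by_sample, genotype_map,
                             genotypes = NULL) {
  pacs <- pacs[!is.na(pacs$gene_id), , drop = FALSE]
  samples <- names(pas_by_sample)
  geno <- genotype_map[samples]
  if (is.null(genotypes)) genotypes <- sort(unique(unname(geno)))
  stopifnot(length(genotypes) == 2L, all(geno %in% genotypes))

  ## per-genotype per-position counts restricted to PAC intervals
  tracks <- lapply(genotypes, function(g) {
    t_list <- lapply(samples[geno == g], function(s) {
      trk <- pas_by_sample[[s]]
      if (inherits(trk, "PasCount")) trk <- trk$genuine
      if ("sample" %in% names(trk)) trk <- trk[trk$sample == s, ,
                                               drop = FALSE]
      trk[, c("contig", "pos", "strand", "count")]
    })
    t_all <- do.call(rbind, t_list)
    if (nrow(t_all) == 0L) return(t_all)
    agg <- aggregate(count ~ contig + pos + strand, t_all, sum)
    agg
  })
  names(tracks) <- genotypes

  pg <- pac_granges(pacs)
  pac_totals <- data.frame(gene_id = pacs$gene_id, pac_id = pacs$pac_id,
                           stringsAsFactors = FALSE)
  mcp_rows <- list()
  for (g in genotypes) {
    trk <- tracks[[g]]
    pac_totals[[paste0("total_", g)]] <- overlap_track_counts(pacs, trk)
    ## most-common PAS per gene: position with max summed count over all
    ## of the gene's PACs
    if (nrow(trk) == 0L) next
    tg <- GenomicRanges::GRanges(trk$contig,
                                 IRanges::IRanges(trk$pos, width = 1L),
                                 strand = trk$strand)
    hits <- GenomicRanges::findOverlaps(tg, pg)
    df <- data.frame(gene_id = pacs$gene_id[S4Vectors::subjectHits(hits)],
                     pos = trk$pos[S4Vectors::queryHits(hits)],
                     count = trk$count[S4Vectors::queryHits(hits)])
    ## a position inside two merged PACs of one gene cannot double-count:
    ## merged PACs are disjoint, so (gene, pos) pairs are unique here
    for (gid in unique(df$gene_id)) {
      sub <- df[df$gene_id == gid, , drop = FALSE]
      mx <- max(sub$count)
      at <- sub$pos[sub$count == mx]
      mcp_rows[[length(mcp_rows) + 1L]] <- data.frame(
        gene_id = gid, genotype = g,
        pos = if (length(at) == 1L) at else NA_integer_,
        count = mx, tie = length(at) > 1L, stringsAsFactors = FALSE)
    }
  }
  mcp <- if (length(mcp_rows)) do.call(rbind, mcp_rows) else
    data.frame(gene_id = character(), genotype = character(),
               pos = integer(), count = integer(), tie = logical())

  genes <- aggregate(list(n_pacs = pacs$pac_id),
                     by = list(gene_id = pacs$gene_id), FUN = length)
  strand_of <- tapply(pacs$strand, pacs$gene_id, function(s) s[1])
  genes$strand <- unname(strand_of[genes$gene_id])

  structure(list(genes = genes, pac_totals = pac_totals, mcp = mcp,
                 genotypes = genotypes),
            class = "GenePacSummary")
}

#' @export
print.GenePacSummary <- function(x, ...) {
  cat("GenePacSummary:", nrow(x$genes), "genes,",
      nrow(x$pac_totals), "PACs, genotypes",
      paste(x$genotypes, collapse = " vs "), "\n")
  invisible(x)
}

#' Dominant-PAC shifts between genotypes
#'
#' For genes with more than one PAC, the dominant PAC per genotype is the
#' one with the most reads (summed over replicates); the gene is shifted
#' iff the dominant identities differ. Read-count ties exclude the gene
#' (`"tie"`) rather than being broken arbitrarily; single-PAC genes are
#' excluded as `"single-PAC"`.
#'
#' @param summary a [gene_pac_summary()].
#' @return data.frame per gene: dominant PAC ids per genotype, `shifted`
#'   (logical, `NA` when excluded), `excluded_reason`.
#' @export
dominant_pac_shift <- function(summary) {
  stopifnot(inherits(summary, "GenePacSummary"))
  g1 <- summary$genotypes[1]; g2 <- summary$genotypes[2]
  out <- list()
  for (i in seq_len(nrow(summary$genes))) {
    gid <- summary$genes$gene_id[i]
    pt <- summary$pac_totals[summary$pac_totals$gene_id == gid, ,
                             drop = FALSE]
    row <- data.frame(gene_id = gid, dominant_1 = NA_character_,
                      dominant_2 = NA_character_, shifted = NA,
                      excluded_reason = NA_character_,
                      stringsAsFactors = FALSE)
    if (nrow(pt) <= 1L) {
      row$excluded_reason <- "single-PAC"
    } else {
      dom <- function(tot) {
        mx <- max(tot)
        at <- which(tot == mx)
        if (length(at) != 1L) NA_character_ else pt$pac_id[at]
      }
      d1 <- dom(pt[[paste0("total_", g1)]])
      d2 <- dom(pt[[paste0("total_", g2)]])
      row$dominant_1 <- d1; row$dominant_2 <- d2
      if (is.na(d1) || is.na(d2)) {
        row$excluded_reason <- "tie"
      } else {
        row$shifted <- d1 != d2
      }
    }
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  names(res)[2:3] <- paste0("dominant_", c(g1, g2))
  res
}

#' Signed distance between most-common PASs of two genotypes
#'
#' For genes whose most-common PAS is determinable (a unique read-count
#' maximum) in both genotypes, computes `d = pos(test) - pos(reference)` in
#' gene orientation: negative is upstream (5'), positive downstream (3');
#' the genomic difference is sign-flipped for minus-strand genes.
#'
#' @param summary a [gene_pac_summary()] (`genotypes[1]` is the reference).
#' @return data.frame per gene: `d` (`NA` when excluded),
#'   `excluded_reason` (`"undeterminable"` for ties/missing).
#' @export
most_common_pas_distance <- function(summary) {
  stopifnot(inherits(summary, "GenePacSummary"))
  g1 <- summary$genotypes[1]; g2 <- summary$genotypes[2]
  m <- summary$mcp
  out <- data.frame(gene_id = summary$genes$gene_id,
                    d = NA_integer_,
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    gid <- out$gene_id[i]
    r1 <- m[m$gene_id == gid & m$genotype == g1, , drop = FALSE]
    r2 <- m[m$gene_id == gid & m$genotype == g2, , drop = FALSE]
    if (nrow(r1) != 1L || nrow(r2) != 1L || r1$tie || r2$tie) {
      out$excluded_reason[i] <- "undeterminable"
      next
    }
    d <- r2$pos - r1$pos
    if (summary$genes$strand[i] == "-") d <- -d
    out$d[i] <- d
  }
  out
}

#' Bin PAS-shift distances
#'
#' Bins signed distances into `+/-10`, `+/-100`, `+/-1000`, and `>1000`
#' magnitude classes keeping the sign (`|d| <= 10` maps to the `10` class,
#' `10 < |d| <= 100` to `100`, and so on; `d = 0` counts as `+10`). Bin
#' counts always partition the input. Also returns the per-nucleotide
#' histogram of `d` within a `+/-window` nt window.
#'
#' @param d vector of signed distances (NAs dropped).
#' @param window half-width of the per-nucleotide histogram (default 40).
#' @return list: `bins` (named count vector over the 8 signed classes,
#'   5'-most first) and `window` (data.frame `d`, `count`).
#' @export
bin_distances <- function(d, window = 40L) {
  d <- d[!is.na(d)]
  levs <- c("< -1000", "-1000", "-100", "-10",
            "+10", "+100", "+1000", "> +1000")
  mag <- cut(abs(d), c(-1, 10, 100, 1000, Inf),
             labels = c("10", "100", "1000", ">1000"))
  neg <- d < 0
  lab <- character(length(d))
  lab[!neg] <- c("10" = "+10", "100" = "+100", "1000" = "+1000",
                 ">1000" = "> +1000")[as.character(mag[!neg])]
  lab[neg] <- c("10" = "-10", "100" = "-100", "1000" = "-1000",
                ">1000" = "< -1000")[as.character(mag[neg])]
  bins <- table(factor(lab, levels = levs))
  hist <- data.frame(d = seq(-window, window))
  hist$count <- vapply(hist$d, function(x) sum(d == x), 0L)
  list(bins = bins, window = hist)
}

#' Fisher's exact test for target-set enrichment
#'
#' Two-sided exact test on a 2x2 contingency table of set membership
#' against an event (e.g. permissive-target membership vs. a shifted
#' dominant PAC), with the odds ratio computed as the cross-product ratio
#' (Haldane 0.5 correction applied when a cell is zero).
#'
#' @param in_set,event logical vectors over the same genes, or `in_set` a
#'   2x2 integer matrix (rows: in set / not, columns: event / not) with
#'   `event` missing.
#' @return list: `odds_ratio`, `p_value`, `table`. An empty margin gives
#'   `NA` results with a warning.
#' @examples
#' fisher_enrichment(matrix(c(10L, 90L, 40L, 60L), 2, byrow = TRUE))
#' @export
fisher_enrichment <- function(in_set, event = NULL) {
  if (is.matrix(in_set)) {
    stopifnot(is.null(event), all(dim(in_set) == 2L))
    m <- in_set
  } else {
    stopifnot(is.logical(in_set), is.logical(event),
              length(in_set) == length(event))
    m <- matrix(c(sum(in_set & event), sum(in_set & !event),
                  sum(!in_set & event), sum(!in_set & !event)),
                nrow = 2L, byrow = TRUE)
  }
  dimnames(m) <- list(set = c("in", "out"), event = c("yes", "no"))
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    warning("empty margin in the 2x2 table; enrichment undefined")
    return(list(odds_ratio = NA_real_, p_value = NA_real_, table = m))
  }
  p <- fisher.test(m)$p.value
  or_ <- if (any(m == 0L)) {
    ((m[1, 1] + 0.5) * (m[2, 2] + 0.5)) /
      ((m[1, 2] + 0.5) * (m[2, 1] + 0.5))
  } else {
    (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  }
  list(odds_ratio = or_, p_value = p, table = m)
}
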