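#' Simulate an oligo-dT-primed (Smart-seq2) 3'-end experiment
#'
#' Generates per-sample read sets over a toy genome with three read classes
#' and full ground truth:
#'
#' * **tailed** reads end at a true PAS of the gene (selected by the
#'   sample genotype's usage weights, with Gaussian positional jitter,
#'   rounded) and carry an appended untemplated poly(A) tail of at least 9
#'   nt with a small (<= 6%) interior non-A rate;
#' * **misprimed** reads end at an internal-priming decoy position and
#'   carry a genomically templated pure-A tail -- indistinguishable from a
#'   real tail until the genomic downstream window is examined;
#' * **body** reads are tail-less gene-body fragments (the background track
#'   for subtractive density estimation).
#'
#' Class counts per gene are multinomial with the requested fractions, so
#' tailed + misprimed + body always equals the gene's read total. Genes
#' without a decoy position get their misprimed allocation reassigned to
#' body reads. A paired mate (an upstream gene-body fragment) is recorded
#' for every read.
#'
#' @param genome a [build_toy_genome()] result.
#' @param sample_sheet a [make_sample_sheet()] table whose `group` values
#'   are genotypes of the genome (`genome$genotypes`).
#' @param reads_per_gene scalar or range `c(lo, hi)`: reads per gene per
#'   sample (drawn uniformly from the range).
#' @param tail_length_dist list `(min, size, mu)`: tail length is
#'   `min + rnbinom(size, mu)` (a shifted negative binomial with floor
#'   `min`, default 9 -- the detector's threshold).
#' @param pas_jitter_sd Gaussian sd (nt) of tailed-read 3' ends around the
#'   true PAS.
#' @param misprime_fraction,body_fraction expected fractions of misprimed
#'   and body reads; the remainder is tailed. Must lie in `[0, 1]` and sum
#'   to at most 1.
#' @param tail_nona_rate per-base interior non-A rate in untemplated tails
#'   (capped so no tail exceeds a 6% mismatch rate).
#' @param body_length aligned body length of every read (nt).
#' @param base_quality constant Phred quality of simulated bases.
#' @param seed integer seed.
#' @return list with `reads` (read-level table: `read_id`, `sample`,
#'   `gene_id`, `class`, `contig`, `strand`, `seq`, `qual`, `body_start`,
#'   `body_end`, `true_end`, `true_pas` (the unjittered PAS a tailed read
#'   was drawn from), `tail_length`, `mate_seq`, `mate_start`, `mate_end`)
#'   and `truth` (the ground-truth columns only).
#' @export
simulate_smartseq_experiment <- function(genome, sample_sheet,
                                         reads_per_gene = c(100L, 300L),
                                         tail_length_dist = list(
                                           min = 9L, size = 2, mu = 8),
                                         pas_jitter_sd = 5,
                                         misprime_fraction = 0.15,
                                         body_fraction = 0.5,
                                         tail_nona_rate = 0.02,
                                         body_length = 60L,
                                         base_quality = 35L,
                                         seed = 1) {
  stopifnot(inherits(genome, "ToyGenome"),
            misprime_fraction >= 0, body_fraction >= 0,
            misprime_fraction + body_fraction <= 1,
            all(sample_sheet$group %in% genome$genotypes))
  set.seed(seed)
  if (length(reads_per_gene) == 1L) {
    reads_per_gene <- rep(reads_per_gene, 2L)
  }
  tail_min <- tail_length_dist$min
  frac <- c(tailed = 1 - misprime_fraction - body_fraction,
            misprimed = misprime_fraction, body = body_fraction)
  clen <- nchar(genome$contigs)

  ## sense-orientation sequences of the `len` bases ending at each `end3`
  ## (vectorised; one reverse-complement call per batch)
  sense_seqs <- function(contig, end3, len, strand) {
    if (strand == "+") {
      substring(genome$contigs[[contig]], end3 - len + 1L, end3)
    } else {
      revcomp(substring(genome$contigs[[contig]], end3, end3 + len - 1L))
    }
  }

  make_tails <- function(n, pure_a) {
    len <- tail_min + rnbinom(n, size = tail_length_dist$size,
                              mu = tail_length_dist$mu)
    tails <- strrep("A", len)
    if (!pure_a) {
      ## interior non-A substitutions, capped at the 6% detector rate;
      ## boundary bases stay A
      nbad <- rbinom(n, pmax(len - 2L, 0L), tail_nona_rate)
      nbad <- pmin(nbad, floor(0.06 * len))
      for (i in which(nbad > 0L)) {
        at <- sample(2:(len[i] - 1L), nbad[i])
        for (a in at) {
          substr(tails[i], a, a) <- sample(c("C", "G", "T"), 1L)
        }
      }
    }
    tails
  }

  rows <- list()
  rid <- 0L
  for (j in seq_len(nrow(sample_sheet))) {
    smp <- sample_sheet[j, ]
    wcol <- paste0("weight_", smp$group)
    for (gi in seq_len(nrow(genome$genes))) {
      g <- genome$genes[gi, ]
      pas <- genome$pas[genome$pas$gene_id == g$gene_id, , drop = FALSE]
      if (nrow(pas) == 0L) {
        stop("gene ", g$gene_id, " has no true PAS for genotype ",
             smp$group)
      }
      dec <- genome$decoys[genome$decoys$gene_id == g$gene_id, ,
                           drop = FALSE]
      n_total <- safe_sample(reads_per_gene[1]:reads_per_gene[2], 1L)
      n <- drop(stats::rmultinom(1L, n_total, frac))
      if (nrow(dec) == 0L) {
        n["body"] <- n["body"] + n["misprimed"]
        n["misprimed"] <- 0L
      }

      ends <- integer(0); cls <- character(0); true_end <- integer(0)
      tails <- character(0); true_pas <- integer(0)
      if (n["tailed"] > 0L) {
        pi <- sample.int(nrow(pas), n["tailed"], replace = TRUE,
                         prob = pas[[wcol]])
        e <- as.integer(round(pas$pos[pi] + rnorm(n["tailed"],
                                                  0, pas_jitter_sd)))
        e <- pmin(pmax(e, g$start + body_length), g$end)
        ends <- c(ends, e); true_end <- c(true_end, e)
        true_pas <- c(true_pas, pas$pos[pi])
        cls <- c(cls, rep("tailed", n["tailed"]))
        tails <- c(tails, make_tails(n["tailed"], pure_a = FALSE))
      }
      if (n["misprimed"] > 0L) {
        di <- sample.int(nrow(dec), n["misprimed"], replace = TRUE)
        e <- dec$pos[di]
        ends <- c(ends, e); true_end <- c(true_end, e)
        true_pas <- c(true_pas, rep(NA_integer_, n["misprimed"]))
        cls <- c(cls, rep("misprimed", n["misprimed"]))
        tails <- c(tails, make_tails(n["misprimed"], pure_a = TRUE))
      }
      if (n["body"] > 0L) {
        off <- sample(0:(g$end - g$start + 1L - body_length), n["body"],
                      replace = TRUE)
        e <- if (g$strand == "+") g$end - off else g$start + off
        ends <- c(ends, e); true_end <- c(true_end, e)
        true_pas <- c(true_pas, rep(NA_integer_, n["body"]))
        cls <- c(cls, rep("body", n["body"]))
        tails <- c(tails, rep("", n["body"]))
      }
      if (length(ends) == 0L) next

      ## clamp ends so body and (for '-') downstream tail template fit
      ends <- pmin(pmax(ends, body_length + 1L),
                   clen[[g$contig]] - body_length)
      body <- sense_seqs(g$contig, ends, body_length, g$strand)
      seq <- paste0(body, tails)
      body_start <- if (g$strand == "+") ends - body_length + 1L else ends
      body_end <- if (g$strand == "+") ends else ends + body_length - 1L

      ## mate: an upstream gene-body fragment
      mate_end3 <- pmin(pmax(ends - 150L, g$start + body_length),
                        clen[[g$contig]] - body_length)
      mate_seq <- sense_seqs(g$contig, mate_end3, body_length, g$strand)
      mate_start <- if (g$strand == "+") mate_end3 - body_length + 1L else
        mate_end3
      mate_end <- if (g$strand == "+") mate_end3 else
        mate_end3 + body_length - 1L

      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("rd%08d", rid + seq_along(ends)),
        sample = smp$sample_id, gene_id = g$gene_id, class = cls,
        contig = g$contig, strand = g$strand,
        seq = seq, qual = const_qual(base_quality, nchar(seq)),
        body_start = as.integer(body_start),
        body_end = as.integer(body_end),
        true_end = as.integer(true_end),
        true_pas = as.integer(true_pas),
        tail_length = nchar(tails),
        mate_seq = mate_seq,
        mate_start = as.integer(mate_start),
        mate_end = as.integer(mate_end),
        stringsAsFactors = FALSE)
      rid <- rid + length(ends)
    }
  }
  reads <- do.call(rbind, rows)
  rownames(reads) <- NULL
  list(reads = reads,
       truth = reads[, c("read_id", "sample", "gene_id", "class",
                         "contig", "strand", "true_end", "true_pas",
                         "tail_length")])
}

#' Write simulated reads as FASTQ (and the truth table as TSV)
#'
#' @param sim a [simulate_smartseq_experiment()] result.
#' @param dir output directory; one `<sample>_R1.fastq` / `_R2.fastq` pair
#'   per sample plus `smartseq_truth.tsv`.
#' @return invisibly, the vector of files written.
#' @export
write_smartseq_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (sid in unique(sim$reads$sample)) {
    r <- sim$reads[sim$reads$sample == sid, ]
    f1 <- file.path(dir, paste0(sid, "_R1.fastq"))
    f2 <- file.path(dir, paste0(sid, "_R2.fastq"))
    writeLines(rbind(paste0("@", r$read_id, "/1"), r$seq, "+", r$qual), f1)
    writeLines(rbind(paste0("@", r$read_id, "/2"), r$mate_seq, "+",
                     const_qual(35L, nchar(r$mate_seq))), f2)
    files <- c(files, f1, f2)
  }
  tf <- file.path(dir, "smartseq_truth.tsv")
  write.table(sim$truth, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, tf))
}

#' Precision/recall of called positions against ground truth
#'
#' Matches called to true positions greedily by distance (closest pairs
#' first), one-to-one, within `tolerance` nt; data.frame inputs are matched
#' within each (contig, strand).
#'
#' @param called,truth numeric position vectors, or data.frames with
#'   `contig`, `pos`, `strand`.
#' @param tolerance maximum |distance| (nt) for a match, >= 0.
#' @return list `precision`, `recall`, `n_called`, `n_truth`, `n_matched`.
#'   Empty truth gives `recall = NA` (undefined); empty calls give
#'   `precision = NA`.
#' @examples
#' evaluate_recovery(c(100, 500), c(101, 250, 700), tolerance = 5)
#' @export
evaluate_recovery <- function(called, truth, tolerance) {
  stopifnot(tolerance >= 0)
  if (is.data.frame(called) || is.data.frame(truth)) {
    stopifnot(is.data.frame(called), is.data.frame(truth))
    keys <- unique(rbind(called[, c("contig", "strand")],
                         truth[, c("contig", "strand")]))
    m <- 0L
    for (i in seq_len(nrow(keys))) {
      cp <- called$pos[called$contig == keys$contig[i] &
                         called$strand == keys$strand[i]]
      tp <- truth$pos[truth$contig == keys$contig[i] &
                        truth$strand == keys$strand[i]]
      m <- m + match_points(cp, tp, tolerance)
    }
    n_called <- nrow(called); n_truth <- nrow(truth)
  } else {
    m <- match_points(called, truth, tolerance)
    n_called <- length(called); n_truth <- length(truth)
  }
  list(precision = if (n_called > 0) m / n_called else NA_real_,
       recall = if (n_truth > 0) m / n_truth else NA_real_,
       n_called = n_called, n_truth = n_truth, n_matched = m)
}

## greedy one-to-one matching by distance; returns the number of matches
match_points <- function(called, truth, tolerance) {
  if (length(called) == 0L || length(truth) == 0L) return(0L)
  d <- abs(outer(called, truth, "-"))
  pairs <- which(d <= tolerance, arr.ind = TRUE)
  if (nrow(pairs) == 0L) return(0L)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_c <- logical(length(called)); used_t <- logical(length(truth))
  m <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (!used_c[i] && !used_t[j]) {
      used_c[i] <- TRUE; used_t[j] <- TRUE
      m <- m + 1L
    }
  }
  m
}
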