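## Untemplated poly(A)-tail detection, trimming, filtering, and per-position
## poly(A)-site (PAS) counting.

## Longest valid terminal run finder, vectorised over reads. A terminal run
## of length k with m mismatches is valid iff k >= min_len, m/k <= max_rate,
## and both boundary bases -- the read terminus and the inner end of the run
## -- match the tail base (a tail may not begin or end in a mismatch; this
## stops degenerate tails padded by non-A). The scan alternately strips
## maximal terminal A-runs (one vectorised regex pass) and consumes single
## mismatch bases; the mismatch budget floor(max_rate * length) bounds the
## number of passes.
##
## `pattern`/`side`: "A*$" with side = "3" scans 3' poly(A); "^T*" with
## side = "5" scans 5' poly(T). Returns list(len, mism) per read.
terminal_runs <- function(seqs, pattern, side, min_len, max_rate) {
  n <- length(seqs)
  L <- nchar(seqs)
  best_k <- integer(n)
  best_m <- integer(n)
  rem <- seqs
  k <- integer(n)
  m <- integer(n)
  max_m <- floor(max_rate * L + 1e-9)
  active <- rep(TRUE, n)
  first <- TRUE
  while (any(active)) {
    stripped <- sub(pattern, "", rem[active])
    run <- nchar(rem[active]) - nchar(stripped)
    rem[active] <- stripped
    k[active] <- k[active] + run
    if (first) {
      ## a read whose terminal base mismatches can never carry a tail
      drop <- active
      drop[active] <- run == 0L
      active <- active & !drop
      first <- FALSE
      if (!any(active)) break
      run <- run[run > 0L]
    }
    ## candidate: inner boundary is a match (run > 0), floor reached,
    ## mismatch fraction within the rate (integer-safe comparison)
    cand <- active
    cand[active] <- run > 0L
    ok <- cand & k >= min_len & m <= max_rate * k + 1e-9
    best_k[ok] <- k[ok]
    best_m[ok] <- m[ok]
    ## extend past one mismatch base where the budget allows
    ext <- active & nchar(rem) > 0L & m + 1L <= max_m
    active <- ext
    if (!any(active)) break
    rem[active] <- if (side == "3") {
      substr(rem[active], 1L, nchar(rem[active]) - 1L)
    } else {
      substr(rem[active], 2L, nchar(rem[active]))
    }
    k[active] <- k[active] + 1L
    m[active] <- m[active] + 1L
  }
  list(len = best_k, mism = best_m)
}

#' Detect and trim untemplated poly(A)/poly(T) tails
#'
#' Labels a read as poly(A)-containing when it carries a terminal run of at
#' least `min_len` 3'-terminal A (or 5'-terminal T) nucleotides with a
#' mismatch rate of at most `max_mismatch_rate`, and removes the run. The
#' tail is the longest valid terminal run; runs may contain interior
#' mismatches but may not begin or end with one. When a read has both a
#' valid 3'A and 5'T run the longer one is taken (tie: 3'A). Reads trimmed
#' at the 5' end (`end == "5T"`) are antisense to the transcript and are
#' flagged for reverse-complementation downstream.
#'
#' @param seqs character vector of raw (pre-alignment) read sequences.
#' @param quals optional character vector of Phred+33 quality strings.
#' @param min_len minimum tail length (default 9).
#' @param max_mismatch_rate maximum mismatch fraction within the tail
#'   (default 0.06).
#' @return data.frame, one row per read: `end` (`"3A"`, `"5T"`, or `NA` for
#'   no tail), `tail_length`, `mismatches_in_tail`, `trimmed_seq`,
#'   `trimmed_qual`, `trimmed_length`, `trimmed_mean_quality` (arithmetic
#'   mean Phred of the retained portion).
#' @examples
#' trim_polya_tails(c("ACGTACGTAAAAAAAAA", "ACGTACGTAAAA"))
#' @export
trim_polya_tails <- function(seqs, quals = NULL, min_len = 9L,
                             max_mismatch_rate = 0.06) {
  n <- length(seqs)
  has_qual <- !is.null(quals)
  if (has_qual) stopifnot(length(quals) == n)
  L <- nchar(seqs)
  a3 <- terminal_runs(seqs, "A*$", "3", min_len, max_mismatch_rate)
  t5 <- terminal_runs(seqs, "^T*", "5", min_len, max_mismatch_rate)
  use3 <- a3$len > 0L & a3$len >= t5$len   # ties go to the 3' A tail
  use5 <- t5$len > a3$len

  end <- rep(NA_character_, n)
  end[use3] <- "3A"
  end[use5] <- "5T"
  k <- integer(n)
  k[use3] <- a3$len[use3]
  k[use5] <- t5$len[use5]
  mism <- integer(n)
  mism[use3] <- a3$mism[use3]
  mism[use5] <- t5$mism[use5]

  from <- ifelse(use5, k + 1L, 1L)
  to <- ifelse(use3, L - k, L)
  out <- data.frame(end = end, tail_length = k, mismatches_in_tail = mism,
                    trimmed_seq = substr(seqs, from, to),
                    trimmed_qual = if (has_qual) substr(quals, from, to)
                      else NA_character_,
                    trimmed_length = 0L,
                    trimmed_mean_quality = NA_real_,
                    stringsAsFactors = FALSE)
  out$trimmed_length <- nchar(out$trimmed_seq)
  if (has_qual) {
    tl <- out$trimmed_length
    out$trimmed_mean_quality <- vapply(seq_len(n), function(i) {
      if (tl[i] == 0L) return(NA_real_)
      mean(as.integer(charToRaw(out$trimmed_qual[i])) - 33L)
    }, 0)
  }
  out
}

#' @rdname trim_polya_tails
#' @param seq,qual a single read's sequence and quality string.
#' @return `trim_polya_tail()` returns a one-row list for a tailed read, or
#'   `NULL` when the read has no valid tail.
#' @export
trim_polya_tail <- function(seq, qual = NULL, min_len = 9L,
                            max_mismatch_rate = 0.06) {
  r <- trim_polya_tails(seq, qual, min_len, max_mismatch_rate)
  if (is.na(r$end[1])) return(NULL)
  as.list(r[1, ])
}

#' Length/quality filter for trimmed poly(A) reads
#'
#' A trimmed read is kept iff its retained portion is longer than
#' `min_length` and has a mean Phred quality greater than
#' `min_mean_quality` (both strict). Reads without quality strings are
#' discarded with a warning. Mate pairs of kept reads are retained by the
#' caller.
#'
#' @param tails a [trim_polya_tails()] result.
#' @param min_length,min_mean_quality strict lower bounds (defaults 20, 25).
#' @return `tails` with a logical `pass_filters` column (tailed reads only;
#'   untailed reads are `FALSE`).
#' @export
filter_trimmed_read <- function(tails, min_length = 20L,
                                min_mean_quality = 25) {
  tailed <- !is.na(tails$end)
  mq <- tails$trimmed_mean_quality
  no_qual <- tailed & is.na(mq)
  if (any(no_qual)) {
    warning(sum(no_qual), " tailed read(s) without qualities discarded")
  }
  tails$pass_filters <- tailed & !is.na(mq) &
    tails$trimmed_length > min_length & mq > min_mean_quality
  tails
}

#' Locate the poly(A) site of an aligned trimmed read
#'
#' The PAS is the 3'-most aligned genomic base in gene orientation: the
#' alignment end for plus-strand genes, the alignment start for minus-strand
#' genes. Up to `max_terminal_mismatches` soft-clipped or mismatched bases
#' at the 3' terminus do not shift the call: when `softclip3` is at most the
#' allowance, the call advances past the clipped bases; larger clips leave
#' the call at the aligned end.
#'
#' @param aln data.frame of aligned trimmed reads: `contig`, `aln_start`,
#'   `aln_end` (1-based closed), `strand` (gene strand), and optional
#'   `softclip3` (3'-terminal unaligned bases, default 0).
#' @param max_terminal_mismatches allowance for 3'-terminal soft-clips.
#' @return `aln` with a `pas` column (genomic position).
#' @export
locate_pas <- function(aln, max_terminal_mismatches = 2L) {
  sc <- if ("softclip3" %in% names(aln)) aln$softclip3 else
    rep(0L, nrow(aln))
  adv <- ifelse(sc <= max_terminal_mismatches, sc, 0L)
  aln$pas <- ifelse(aln$strand == "+", aln$aln_end + adv,
                    aln$aln_start - adv)
  aln
}

#' Classify poly(A) sites as genuine or oligo-dT mispriming artifacts
#'
#' A PAS is classified `misprimed` iff the 15-nt window immediately
#' downstream of it (gene orientation, sense strand: positions PAS+1 ..
#' PAS+15) has a purine (A/G) fraction of at least `purine_min` -- the
#' signature of a genomic stretch at which the oligo-dT primer can anneal
#' internally. Windows truncated by a contig end use the available bases;
#' with fewer than 8 available bases the read is classified `genuine` with
#' a warning. Classification is a pure function of (genome, position,
#' strand).
#'
#' @param genome genome sequence (`ToyGenome`, named character vector, or
#'   FASTA path).
#' @param contig,pos,strand vectors describing the PAS calls.
#' @param purine_min inclusive purine-fraction threshold (default 0.8).
#' @param window downstream window width (default 15).
#' @return character vector, `"genuine"` or `"misprimed"`.
#' @export
mispriming_read_filter <- function(genome, contig, pos, strand,
                                   purine_min = 0.8, window = 15L) {
  seqs <- contig_seqs(genome)
  n <- length(pos)
  stopifnot(length(contig) == n, length(strand) == n)
  out <- character(n)
  short <- 0L
  for (i in seq_len(n)) {
    s <- seqs[[contig[i]]]
    win <- if (strand[i] == "+") {
      clamped_substring(s, pos[i] + 1L, pos[i] + window)
    } else {
      clamped_substring(s, pos[i] - window, pos[i] - 1L)
    }
    if (nchar(win) < 8L) {
      short <- short + 1L
      out[i] <- "genuine"
      next
    }
    cc <- strsplit(win, "")[[1]]
    ## sense-strand purines: A/G on '+', complement of T/C on '-'
    pur <- if (strand[i] == "+") cc %in% c("A", "G") else cc %in% c("T", "C")
    out[i] <- if (mean(pur) >= purine_min) "misprimed" else "genuine"
  }
  if (short > 0L) {
    warning(short, " PAS call(s) too close to a contig end (< 8 downstream ",
            "bases); classified genuine")
  }
  out
}

#' Build per-position poly(A)-site count tracks
#'
#' Aggregates located reads into per-position, per-sample counts, split
#' into the genuine track and the companion misprime-filtered track (kept,
#' not discarded: the cluster-level false-positive filter compares the two).
#'
#' @param located data.frame with `contig`, `pas`, `strand`, `sample`, and
#'   `status` (`"genuine"`/`"misprimed"`).
#' @return An object of class `PasCount`: list of two data.frames
#'   (`genuine`, `misprimed`), each `contig`, `pos`, `strand`, `sample`,
#'   `count`.
#' @export
count_pas <- function(located) {
  agg <- function(df) {
    if (nrow(df) == 0L) {
      return(data.frame(contig = character(), pos = integer(),
                        strand = character(), sample = character(),
                        count = integer()))
    }
    out <- aggregate(list(count = rep(1L, nrow(df))),
                     by = list(contig = df$contig, pos = df$pas,
                               strand = df$strand, sample = df$sample),
                     FUN = sum)
    out[order(out$sample, out$contig, out$pos), , drop = FALSE]
  }
  structure(list(genuine = agg(located[located$status == "genuine", ]),
                 misprimed = agg(located[located$status == "misprimed", ])),
            class = "PasCount")
}

#' @export
print.PasCount <- function(x, ...) {
  cat("PasCount:", sum(x$genuine$count), "genuine reads at",
      nrow(x$genuine), "positions;", sum(x$misprimed$count),
      "misprime-filtered reads at", nrow(x$misprimed), "positions\n")
  invisible(x)
}

#' Run the poly(A)-read extraction pipeline on simulated reads
#'
#' Trims tails, applies the length/quality filter, reconstructs each
#' trimmed read's aligned 3' end from the simulator's body placement
#' (over-trimming into genomic A-runs moves the call upstream; untrimmed
#' untemplated bases become 3' soft-clips), locates the PAS, applies the
#' mispriming filter, and counts per-position tracks. Gene-body (untailed)
#' read 3' ends are returned separately as the background track for
#' subtractive density estimation.
#'
#' @param reads a [simulate_smartseq_experiment()] reads table.
#' @param genome the genome the reads were simulated from.
#' @param min_tail,max_mismatch_rate,min_length,min_mean_quality see
#'   [trim_polya_tails()] and [filter_trimmed_read()].
#' @param max_terminal_mismatches see [locate_pas()].
#' @param purine_min see [mispriming_read_filter()].
#' @return list: `tails` (per-read trim results), `located` (kept tailed
#'   reads with `pas` and `status`), `pas` (a [count_pas()] `PasCount`),
#'   `body_ends` (background track data.frame), `summary` (read-accounting
#'   counts: reads in, tailed, kept, genuine, misprimed).
#' @export
extract_polya <- function(reads, genome, min_tail = 9L,
                          max_mismatch_rate = 0.06, min_length = 20L,
                          min_mean_quality = 25, max_terminal_mismatches = 2L,
                          purine_min = 0.8) {
  tails <- trim_polya_tails(reads$seq, reads$qual, min_tail,
                            max_mismatch_rate)
  tails <- filter_trimmed_read(tails, min_length, min_mean_quality)
  keep <- which(tails$pass_filters)

  body_len <- reads$body_end - reads$body_start + 1L
  overtrim <- pmax(0L, body_len - tails$trimmed_length)
  softclip3 <- pmax(0L, tails$trimmed_length - body_len)
  aln <- data.frame(
    contig = reads$contig[keep],
    aln_start = ifelse(reads$strand[keep] == "+",
                       reads$body_start[keep],
                       reads$body_start[keep] + overtrim[keep]),
    aln_end = ifelse(reads$strand[keep] == "+",
                     reads$body_end[keep] - overtrim[keep],
                     reads$body_end[keep]),
    strand = reads$strand[keep],
    softclip3 = softclip3[keep],
    sample = reads$sample[keep],
    read_id = reads$read_id[keep],
    stringsAsFactors = FALSE)
  aln <- locate_pas(aln, max_terminal_mismatches)
  aln$status <- mispriming_read_filter(genome, aln$contig, aln$pas,
                                       aln$strand, purine_min)
  pas <- count_pas(aln)

  ## background: 3' ends of untailed (gene-body) reads
  body <- reads[is.na(tails$end), , drop = FALSE]
  body_ends <- data.frame(
    contig = body$contig,
    pas = ifelse(body$strand == "+", body$body_end, body$body_start),
    strand = body$strand, sample = body$sample,
    status = "genuine", stringsAsFactors = FALSE)
  body_track <- count_pas(body_ends)$genuine

  list(tails = tails, located = aln, pas = pas, body_ends = body_track,
       summary = list(reads_in = nrow(reads),
                      tailed = sum(!is.na(tails$end)),
                      kept = length(keep),
                      genuine = sum(aln$status == "genuine"),
                      misprimed = sum(aln$status == "misprimed")))
}
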