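# Shared fixtures, built in code.

# A two-gene toy annotation on one hand-written contig, with one gene per
# strand, for pileup and PAS orientation tests.
tiny_annotation <- function() {
  data.frame(
    gene_id = c("gplus", "gminus"),
    contig = "ctg",
    start = c(101L, 701L),
    end = c(500L, 1100L),
    strand = c("+", "-"),
    stringsAsFactors = FALSE
  )
}

# Deterministic random contig with controlled bases at chosen positions.
tiny_contig <- function(len = 1300L, seed = 99, force = NULL) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (nm in names(force)) s[as.integer(nm)] <- force[[nm]]
  paste(s, collapse = "")
}

# Write reads (contig, start, seq) to an indexed BAM; returns the path.
reads_to_bam <- function(reads, contig_lengths, prefix) {
  tribepas:::write_alignments(reads, contig_lengths, prefix,
                              read_length = max(nchar(reads$seq)))
}

# Reads of fixed length covering `pos` on a contig string, with the base at
# `pos` replaced by `base` (forward strand).
reads_at <- function(contig_seq, contig_name, pos, bases, len = 50L) {
  start <- pos - (len %/% 2L)
  seqs <- vapply(bases, function(b) {
    s <- substring(contig_seq, start, start + len - 1L)
    substr(s, pos - start + 1L, pos - start + 1L) <- b
    s
  }, "", USE.NAMES = FALSE)
  data.frame(contig = contig_name, start = start, seq = seqs,
             stringsAsFactors = FALSE)
}

# Brute-force poly(A)/poly(T) tail oracle: enumerate every terminal run
# length and apply the validity rules (floor, mismatch rate, boundary
# matches) to each, independent of the implementation's regex-stripping
# scan. The longest valid run wins; ties between ends go to 3'A.
oracle_tail <- function(seq, min_len = 9L, max_rate = 0.06) {
  cc <- strsplit(seq, "")[[1]]
  L <- length(cc)
  k <- seq_len(L)
  # 3' suffixes of length k, scanned from the read terminus inwards
  rc <- rev(cc)
  mism3 <- cumsum(rc != "A")
  ok3 <- k >= min_len & rc[1] == "A" & rc[k] == "A" &
    mism3 <= max_rate * k + 1e-9
  k3 <- if (any(ok3)) max(k[ok3]) else 0L
  # 5' prefixes of length k
  mism5 <- cumsum(cc != "T")
  ok5 <- k >= min_len & cc[1] == "T" & cc[k] == "T" &
    mism5 <= max_rate * k + 1e-9
  k5 <- if (any(ok5)) max(k[ok5]) else 0L
  if (k3 == 0L && k5 == 0L) {
    return(list(end = NA_character_, len = 0L, mism = 0L))
  }
  if (k3 >= k5) list(end = "3A", len = k3, mism = mism3[k3])
  else list(end = "5T", len = k5, mism = mism5[k5])
}

# Random read sequences with planted tails for the trimming oracle test.
random_tailed_reads <- function(n, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(30:80, 1)
    body <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                         prob = c(0.35, 0.2, 0.15, 0.3)), collapse = "")
    style <- sample(3, 1)
    if (style == 1) return(body)                       # maybe no tail
    k <- sample(5:25, 1)
    tail <- sample(c("A", "C", "G", "T"), k, replace = TRUE,
                   prob = c(0.9, 0.03, 0.03, 0.04))
    if (style == 2) paste0(body, paste(tail, collapse = ""))
    else paste0(paste(chartr("ACGT", "TGCA", tail), collapse = ""), body)
  }, "")
}

# Build a GenePacSummary object directly (for shift/distance unit tests).
manual_summary <- function(genes, pac_totals, mcp, genotypes) {
  structure(list(genes = genes, pac_totals = pac_totals, mcp = mcp,
                 genotypes = genotypes),
            class = "GenePacSummary")
}

# Exhaustive two-sided Fisher p by hypergeometric enumeration.
fisher_oracle_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  supp <- max(0L, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(supp, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
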