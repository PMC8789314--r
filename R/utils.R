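## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

## complement of a vector of single bases (character)
comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

## reverse complement of sequence strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## split sequence strings into character matrices is avoided; most code works
## on per-read character vectors via strsplit.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

## Phred+33 decoding
phred_values <- function(qual) {
  lapply(qual, function(q) as.integer(charToRaw(q)) - 33L)
}

## substring of a contig sequence, clamped to the contig; returns "" when the
## clamped window is empty
clamped_substring <- function(seq, start, end) {
  n <- nchar(seq)
  start <- max(1L, start)
  end <- min(n, end)
  if (start > end) return("")
  substring(seq, start, end)
}

## fetch contig sequences from a ToyGenome, a named character vector, or a
## FASTA file path
contig_seqs <- function(genome) {
  if (inherits(genome, "ToyGenome")) return(genome$contigs)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("`genome` must be a ToyGenome, a named character vector of contigs, ",
       "or a FASTA file path")
}

## GRanges from a genes data.frame (1-based closed coordinates)
genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}

as_genes_df <- function(annotation) {
  if (inherits(annotation, "ToyGenome")) return(annotation$genes)
  if (inherits(annotation, "GRanges")) {
    return(data.frame(
      gene_id = annotation$gene_id,
      contig = as.character(GenomeInfoDb::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      stringsAsFactors = FALSE
    ))
  }
  stopifnot(is.data.frame(annotation))
  annotation
}

## quality string of constant Phred q
const_qual <- function(q, n) {
  vapply(n, function(len) strrep(rawToChar(as.raw(q + 33L)), len), "")
}

## sample() that treats a length-1 x as the single candidate, not as 1:x
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

## beta-binomial sampler parameterised by mean proportion p and intra-class
## correlation rho (rho = 0 reduces to binomial)
rbetabinom <- function(n, size, p, rho) {
  p <- rep_len(p, n)
  rho <- rep_len(rho, n)
  size <- rep_len(size, n)
  out <- integer(n)
  bb <- rho > 0 & p > 0 & p < 1
  if (any(!bb)) out[!bb] <- rbinom(sum(!bb), size[!bb], p[!bb])
  if (any(bb)) {
    a <- p[bb] * (1 - rho[bb]) / rho[bb]
    b <- (1 - p[bb]) * (1 - rho[bb]) / rho[bb]
    out[bb] <- rbinom(sum(bb), size[bb], rbeta(sum(bb), a, b))
  }
  out
}
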