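#' Construct a BaseCountMatrix
#'
#' Per-position, per-sample counts of A/C/G/T observed on the annotated
#' transcript strand: the substrate of all editing tests. For minus-strand
#' genes counts are stored complemented so that an A-to-G edit is always
#' recorded as reference `A`, alternative `G`, regardless of genomic strand.
#'
#' @param sites data.frame with `contig`, `pos` (1-based), `strand`, `ref`
#'   (reference base in transcript orientation).
#' @param counts integer array `[n_sites, n_samples, 4]` with base dimension
#'   named `A,C,G,T` (transcript orientation).
#' @param samples sample sheet (`sample_id`, `group`, ... ) aligned with the
#'   second dimension of `counts`.
#' @return An object of class `BaseCountMatrix`.
#' @export
base_count_matrix <- function(sites, counts, samples) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "strand", "ref") %in% names(sites)),
            length(dim(counts)) == 3L,
            dim(counts)[1] == nrow(sites),
            dim(counts)[2] == nrow(samples),
            dim(counts)[3] == 4L)
  if (is.null(dimnames(counts)[[3]])) dimnames(counts)[[3]] <- BASES
  stopifnot(identical(dimnames(counts)[[3]], BASES), all(counts >= 0))
  dimnames(counts)[[2]] <- samples$sample_id
  structure(list(sites = sites, counts = counts, samples = samples),
            class = "BaseCountMatrix")
}

#' @export
print.BaseCountMatrix <- function(x, ...) {
  cat("BaseCountMatrix:", nrow(x$sites), "positions x",
      nrow(x$samples), "samples\n")
  invisible(x)
}

## site x sample coverage (sum over bases)
bcm_coverage <- function(bcm) {
  apply(bcm$counts, c(1, 2), sum)
}

## site x sample counts of one base (transcript orientation)
bcm_base <- function(bcm, base) {
  m <- bcm$counts[, , base, drop = FALSE]
  dim(m) <- dim(bcm$counts)[1:2]
  dimnames(m) <- dimnames(bcm$counts)[1:2]
  m
}

## site x sample counts of the per-site reference base
bcm_ref_counts <- function(bcm) {
  out <- matrix(0L, nrow(bcm$sites), nrow(bcm$samples))
  for (b in BASES) {
    i <- bcm$sites$ref == b
    if (any(i)) out[i, ] <- bcm_base(bcm, b)[i, , drop = FALSE]
  }
  out
}

## site x sample counts of an arbitrary per-site base vector
bcm_alt_counts <- function(bcm, alt) {
  stopifnot(length(alt) == nrow(bcm$sites))
  out <- matrix(0L, nrow(bcm$sites), nrow(bcm$samples))
  for (b in BASES) {
    i <- alt == b
    if (any(i)) out[i, ] <- bcm_base(bcm, b)[i, , drop = FALSE]
  }
  out
}

## subset a BaseCountMatrix by site index
bcm_subset <- function(bcm, i) {
  base_count_matrix(bcm$sites[i, , drop = FALSE],
                    bcm$counts[i, , , drop = FALSE],
                    bcm$samples)
}

#' Position key string for site tables
#'
#' @param sites data.frame with `contig`, `pos`, `strand`.
#' @return character vector `"contig:pos:strand"`.
#' @export
site_key <- function(sites) {
  paste(sites$contig, sites$pos, sites$strand, sep = ":")
}
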