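mk_track <- function(pos, count, strand = "+", contig = "c", sample = "s1") {
  data.frame(contig = contig, pos = pos, strand = strand, sample = sample,
             count = count, stringsAsFactors = FALSE)
}

test_that("subtractive KDE obeys its identities", {
  fg <- mk_track(c(480L, 500L, 520L), c(5L, 10L, 5L))
  # zero background: signal equals the foreground density
  tr <- subtractive_kde(fg, fg[0, ])
  cmp <- tr$components[[1]]
  expect_equal(cmp$signal, cmp$fg_density)
  # density mass equals the read count (unit-mass kernel, padded grid)
  expect_equal(sum(cmp$fg_density), sum(fg$count), tolerance = 1e-6)
  # identical foreground and background at scale 1: signal is identically 0
  tr2 <- subtractive_kde(fg, fg, background_scale = 1)
  expect_true(all(abs(tr2$components[[1]]$signal) < 1e-12))
})

test_that("a concentrated peak over uniform background yields one cluster", {
  set.seed(61)
  pos <- as.integer(round(rnorm(100, 500, 5)))
  fg <- mk_track(as.integer(names(table(pos))), as.integer(table(pos)))
  bgp <- sample(1:2000, 400, replace = TRUE)
  bg <- mk_track(as.integer(names(table(bgp))), as.integer(table(bgp)))
  tr <- subtractive_kde(fg, bg)
  cl <- call_clusters(tr)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$start <= 500 & cl$end >= 500)
  # cluster is trimmed to the span of supporting reads
  expect_gte(cl$start, min(pos))
  expect_lte(cl$end, max(pos))
})

test_that("separated positive runs give separate clusters; singletons drop", {
  fg <- mk_track(c(200L, 201L, 202L, 600L, 601L, 602L), rep(2L, 6))
  tr <- subtractive_kde(fg, fg[0, ])
  cl <- call_clusters(tr, min_reads = 2L)
  expect_equal(nrow(cl), 2L)
  # a single isolated read never forms a cluster at min_reads = 2
  cl1 <- call_clusters(subtractive_kde(mk_track(900L, 1L), fg[0, ]),
                       min_reads = 2L)
  expect_equal(nrow(cl1), 0L)
})

test_that("cluster false-positive filter compares the two tracks strictly", {
  pacs <- data.frame(contig = "c", start = c(100L, 300L, 500L),
                     end = c(120L, 320L, 520L), strand = "+",
                     n_reads = c(4L, 6L, 3L), stringsAsFactors = FALSE)
  pas <- structure(list(
    genuine = mk_track(c(110L, 310L, 510L), c(4L, 6L, 3L)),
    misprimed = mk_track(c(115L, 315L), c(6L, 6L))), class = "PasCount")
  out <- cluster_fp_filter(pacs, pas)
  expect_equal(out$fp_removed, c(TRUE, FALSE, FALSE))
  expect_equal(out$genuine_reads, c(4L, 6L, 3L))
  expect_equal(out$misprimed_reads, c(6L, 6L, 0L))
})

test_that("replicate consensus requires 2-of-3 in both genotypes", {
  mk_pac <- function(starts, ends) {
    data.frame(contig = "c", start = starts, end = ends, strand = "+",
               n_reads = 5L, stringsAsFactors = FALSE)
  }
  # cluster A at [100,150]: in 2/3 wt and 2/3 mut reps
  # cluster B at [400,450]: in 3/3 wt but 1/3 mut -> discarded
  pacs <- list(
    wt_1 = mk_pac(c(100L, 400L), c(150L, 450L)),
    wt_2 = mk_pac(c(140L, 400L), c(180L, 450L)),
    wt_3 = mk_pac(400L, 450L),
    mut_1 = mk_pac(c(100L, 400L), c(150L, 450L)),
    mut_2 = mk_pac(100L, 150L),
    mut_3 = mk_pac(900L, 950L))
  gm <- c(wt_1 = "wt", wt_2 = "wt", wt_3 = "wt",
          mut_1 = "mut", mut_2 = "mut", mut_3 = "mut")
  merged <- replicate_consensus_and_merge(pacs, gm)
  # only the A region survives; overlapping intervals coalesce
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 100L)
  expect_equal(merged$end, 180L)
  # fewer than 2 replicates in a genotype is an error
  expect_error(
    replicate_consensus_and_merge(pacs[c("wt_1", "wt_2", "mut_1")],
                                  gm[c("wt_1", "wt_2", "mut_1")]),
    "2 replicates")
})

test_that("merging a merged set is a no-op", {
  base <- data.frame(contig = "c", start = c(100L, 300L),
                     end = c(200L, 350L), strand = "+", n_reads = 10L,
                     stringsAsFactors = FALSE)
  pacs <- list(a_1 = base, a_2 = base, b_1 = base, b_2 = base)
  gm <- c(a_1 = "a", a_2 = "a", b_1 = "b", b_2 = "b")
  m1 <- replicate_consensus_and_merge(pacs, gm)
  again <- lapply(pacs, function(x) m1[, c("contig", "start", "end",
                                           "strand")])
  for (s in names(again)) again[[s]]$n_reads <- 10L
  m2 <- replicate_consensus_and_merge(again, gm)
  expect_equal(m2[, c("contig", "start", "end", "strand")],
               m1[, c("contig", "start", "end", "strand")])
})

test_that("excluded contigs and loci are dropped and counted", {
  pacs <- data.frame(contig = c("chr1", "mito", "chr1"),
                     start = c(100L, 10L, 5000L),
                     end = c(150L, 60L, 5100L), strand = "+",
                     stringsAsFactors = FALSE)
  expect_message(
    out <- exclude_contigs(pacs, contigs = "mito",
                           ranges = data.frame(contig = "chr1",
                                               start = 4900L,
                                               end = 5050L)),
    "2 cluster")
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(attr(out, "n_excluded"), 2L)
})

test_that("gene assignment uses 3' extension and nearest 3' end", {
  genes <- data.frame(gene_id = c("g1", "g2"), contig = "c",
                      start = c(1000L, 2000L), end = c(1800L, 2800L),
                      strand = "+", stringsAsFactors = FALSE)
  pacs <- data.frame(contig = "c",
                     start = c(1700L, 1900L, 1850L, 5000L),
                     end = c(1750L, 1950L, 2100L, 5050L),
                     strand = "+", stringsAsFactors = FALSE)
  expect_message(out <- assign_pacs_to_genes(pacs, genes, extension = 200L),
                 "not assignable")
  expect_equal(out$gene_id[1], "g1")   # inside the 3' UTR
  expect_equal(out$gene_id[2], "g1")   # 100-150 nt past the end, extended
  # overlaps both g1 (extended) and g2; g1's 3' end (1800) is nearer than
  # g2's (2800)
  expect_equal(out$gene_id[3], "g1")
  expect_true(is.na(out$gene_id[4]))
  # strand mismatch prevents assignment
  pacs_m <- data.frame(contig = "c", start = 1700L, end = 1750L,
                       strand = "-", stringsAsFactors = FALSE)
  expect_message(out2 <- assign_pacs_to_genes(pacs_m, genes))
  expect_true(is.na(out2$gene_id))
})
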