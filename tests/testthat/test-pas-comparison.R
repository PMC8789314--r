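test_that("dominant-PAC shifts follow the max-reads rule with ties excluded", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      n_pacs = c(2L, 2L, 2L, 1L),
                      strand = "+", stringsAsFactors = FALSE)
  pac_totals <- data.frame(
    gene_id = c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
    pac_id = c("P1", "P2", "P3", "P4", "P5", "P6", "P7"),
    total_wt = c(30L, 10L, 25L, 5L, 9L, 4L, 11L),
    total_mut = c(8L, 20L, 22L, 6L, 15L, 15L, 9L))
  s <- manual_summary(genes, pac_totals, data.frame(), c("wt", "mut"))
  out <- dominant_pac_shift(s)
  expect_equal(out$shifted[out$gene_id == "g1"], TRUE)
  expect_equal(out$shifted[out$gene_id == "g2"], FALSE)
  expect_equal(out$excluded_reason[out$gene_id == "g3"], "tie")
  expect_equal(out$excluded_reason[out$gene_id == "g4"], "single-PAC")
  expect_true(is.na(out$shifted[out$gene_id == "g3"]))
})

test_that("most-common-PAS distances respect gene orientation", {
  genes <- data.frame(gene_id = c("gp", "gm", "gt"), n_pacs = 2L,
                      strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  mcp <- data.frame(
    gene_id = c("gp", "gp", "gm", "gm", "gt", "gt"),
    genotype = rep(c("wt", "mut"), 3),
    pos = c(1000L, 1007L, 1000L, 993L, 500L, NA),
    count = 20L, tie = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  s <- manual_summary(genes, data.frame(), mcp, c("wt", "mut"))
  out <- most_common_pas_distance(s)
  expect_equal(out$d[out$gene_id == "gp"], 7L)
  # minus strand: genomic 1000 -> 993 is downstream of the gene: d = +7
  expect_equal(out$d[out$gene_id == "gm"], 7L)
  expect_equal(out$excluded_reason[out$gene_id == "gt"], "undeterminable")
  # identical positions give d = 0
  mcp0 <- mcp[1:2, ]; mcp0$pos <- 800L
  s0 <- manual_summary(genes[1, ], data.frame(), mcp0, c("wt", "mut"))
  expect_equal(most_common_pas_distance(s0)$d, 0L)
})

test_that("distance bins partition with signs kept and are antisymmetric", {
  d <- c(7L, -7L, 0L, 10L, 11L, -250L, 1000L, -1001L, 5000L)
  b <- bin_distances(d)
  expect_equal(sum(b$bins), length(d))
  expect_equal(unname(b$bins[["+10"]]), 3L)    # 7, 0, 10
  expect_equal(unname(b$bins[["-10"]]), 1L)
  expect_equal(unname(b$bins[["+100"]]), 1L)   # 11
  expect_equal(unname(b$bins[["-1000"]]), 1L)  # -250
  expect_equal(unname(b$bins[["+1000"]]), 1L)  # 1000
  expect_equal(unname(b$bins[["< -1000"]]), 1L)
  expect_equal(unname(b$bins[["> +1000"]]), 1L)
  # genotype swap negates d: magnitude bins are fixed
  b2 <- bin_distances(-d)
  mag <- function(x) {
    c(x[["+10"]] + x[["-10"]], x[["+100"]] + x[["-100"]],
      x[["+1000"]] + x[["-1000"]], x[["> +1000"]] + x[["< -1000"]])
  }
  expect_equal(mag(b2$bins), mag(b$bins))
  # per-nucleotide window histogram counts what it should
  expect_equal(b$window$count[b$window$d == 7], 1L)
  expect_equal(sum(b$window$count), sum(abs(d) <= 40))
  # partition property on random inputs
  set.seed(71)
  dr <- sample(c(-3000:3000), 500)
  expect_equal(sum(bin_distances(dr)$bins), 500L)
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  m <- matrix(c(10L, 90L, 40L, 60L), 2, byrow = TRUE)
  r <- fisher_enrichment(m)
  expect_lt(abs(r$p_value - fisher_oracle_p(m)), 1e-10)
  # transposition invariance
  expect_equal(fisher_enrichment(t(m))$p_value, r$p_value)
  # equal proportions: OR = 1, p = 1
  r2 <- fisher_enrichment(matrix(c(10L, 20L, 30L, 60L), 2, byrow = TRUE))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)
  # a zero cell triggers the 0.5 correction
  r3 <- fisher_enrichment(matrix(c(0L, 10L, 5L, 5L), 2, byrow = TRUE))
  expect_equal(r3$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  # empty margin: undefined with a warning
  expect_warning(r4 <- fisher_enrichment(matrix(c(0L, 0L, 5L, 5L), 2,
                                                byrow = TRUE)))
  expect_true(is.na(r4$p_value))
  # logical-vector interface builds the same table
  in_set <- rep(c(TRUE, FALSE), c(100, 100))
  event <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 90, 40, 60))
  expect_equal(fisher_enrichment(in_set, event)$p_value, r$p_value)
})

test_that("gene summaries aggregate per-genotype reads inside PACs", {
  pacs <- data.frame(pac_id = c("P1", "P2"), contig = "c",
                     start = c(100L, 300L), end = c(120L, 320L),
                     strand = "+", gene_id = "g1", stringsAsFactors = FALSE)
  trk <- function(pos, count, sample) {
    data.frame(contig = "c", pos = pos, strand = "+", sample = sample,
               count = count, stringsAsFactors = FALSE)
  }
  pas <- list(wt_1 = trk(c(110L, 310L), c(5L, 1L), "wt_1"),
              wt_2 = trk(110L, 4L, "wt_2"),
              mut_1 = trk(c(111L, 310L), c(1L, 6L), "mut_1"),
              mut_2 = trk(310L, 5L, "mut_2"))
  gm <- c(wt_1 = "wt", wt_2 = "wt", mut_1 = "mut", mut_2 = "mut")
  s <- gene_pac_summary(pacs, pas, gm, genotypes = c("wt", "mut"))
  pt <- s$pac_totals
  expect_equal(pt$total_wt[pt$pac_id == "P1"], 9L)
  expect_equal(pt$total_mut[pt$pac_id == "P2"], 11L)
  sh <- dominant_pac_shift(s)
  expect_true(sh$shifted)
  # most-common PAS per genotype: wt at 110 (9 reads), mut at 310 (11)
  d <- most_common_pas_distance(s)
  expect_equal(d$d, 200L)
})
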