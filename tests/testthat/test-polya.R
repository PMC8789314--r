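test_that("tail detection honours the 9-nt floor and 6% mismatch rate", {
  body <- "CGTCGTCGTCGTCGTCGTCG"
  # exactly nine terminal As: accepted
  r <- trim_polya_tail(paste0(body, strrep("A", 9)))
  expect_equal(r$end, "3A")
  expect_equal(r$tail_length, 9L)
  expect_equal(r$trimmed_seq, body)
  # eight terminal As: below the floor
  expect_null(trim_polya_tail(paste0(body, strrep("A", 8))))
  # 17-mer with one interior non-A (1/17 ~ 5.9% <= 6%)
  tail17 <- paste0(strrep("A", 8), "C", strrep("A", 8))
  r <- trim_polya_tail(paste0(body, tail17))
  expect_equal(r$tail_length, 17L)
  expect_equal(r$mismatches_in_tail, 1L)
  # mismatches too dense: every suffix of length >= 9 violates either the
  # 6% rate or the boundary-match rule, so no tail is called at all
  tail_bad <- paste0(strrep("A", 6), "C", "A", "C", strrep("A", 8))
  expect_null(trim_polya_tail(paste0(body, tail_bad)))
})

test_that("trimming equals the brute-force longest-valid-suffix oracle", {
  reads <- random_tailed_reads(2000, seed = 51)
  got <- trim_polya_tails(reads)
  for (i in seq_along(reads)) {
    o <- oracle_tail(reads[i])
    if (o$len == 0L) {
      expect_true(is.na(got$end[i]), label = reads[i])
    } else {
      expect_equal(got$end[i], o$end, label = reads[i])
      expect_equal(got$tail_length[i], o$len, label = reads[i])
      expect_equal(got$mismatches_in_tail[i], o$mism, label = reads[i])
    }
  }
  # reconstruction: trimmed read plus removed tail is the input
  t3 <- !is.na(got$end) & got$end == "3A"
  expect_true(all(substr(reads[t3], 1, got$trimmed_length[t3]) ==
                    got$trimmed_seq[t3]))
  t5 <- !is.na(got$end) & got$end == "5T"
  expect_true(all(substr(reads[t5], got$tail_length[t5] + 1,
                         nchar(reads[t5])) == got$trimmed_seq[t5]))
})

test_that("5'T tails are detected and flagged for reorientation", {
  r <- trim_polya_tail(paste0(strrep("T", 12), "CGTCGTCGTCGTCGTCGTCG"))
  expect_equal(r$end, "5T")
  expect_equal(r$tail_length, 12L)
})

test_that("length/quality filter uses strict inequalities", {
  mk <- function(len, q, tail = 9L) {
    list(seq = paste0(strrep("C", len), strrep("A", tail)),
         qual = strrep(rawToChar(as.raw(q + 33L)), len + tail))
  }
  a <- mk(21, 30); b <- mk(20, 40); c_ <- mk(30, 25)
  tails <- trim_polya_tails(c(a$seq, b$seq, c_$seq),
                            c(a$qual, b$qual, c_$qual))
  tails <- filter_trimmed_read(tails)
  expect_equal(tails$pass_filters, c(TRUE, FALSE, FALSE))
  # missing qualities: discarded with a warning
  expect_warning(out <- filter_trimmed_read(trim_polya_tails(a$seq)),
                 "without qualities")
  expect_false(out$pass_filters)
})

test_that("PAS location follows gene orientation and terminal allowance", {
  aln <- data.frame(contig = "c", aln_start = c(941L, 941L, 941L, 941L),
                    aln_end = c(1000L, 999L, 1000L, 997L),
                    strand = c("+", "+", "-", "+"),
                    softclip3 = c(0L, 1L, 0L, 3L))
  out <- locate_pas(aln)
  expect_equal(out$pas[1], 1000L)   # perfect alignment
  expect_equal(out$pas[2], 1000L)   # 1 clipped terminal base: same call
  expect_equal(out$pas[3], 941L)    # minus-strand gene: leftmost base
  expect_equal(out$pas[4], 997L)    # clip beyond allowance does not advance
})

test_that("mispriming classification matches direct purine recounting", {
  # hand-built contig: window content is exact by construction
  win12 <- paste0(strrep("A", 12), "CTC")   # 12/15 purines = 0.80
  win11 <- paste0(strrep("A", 11), "CTCT")  # 11/15 ~ 0.73
  win15 <- strrep("G", 15)
  s <- paste0(strrep("C", 100), win12, strrep("C", 85), win11,
              strrep("C", 85), win15, strrep("C", 100))
  genome <- c(ctg = s)
  pos <- c(100L, 200L, 300L)
  cls <- mispriming_read_filter(genome, rep("ctg", 3), pos, rep("+", 3))
  expect_equal(cls, c("misprimed", "genuine", "misprimed"))
  # minus strand: downstream means lower coordinates, purines are
  # complements; plant a T/C-rich stretch before position 500
  s2 <- paste0(strrep("G", 480), strrep("T", 19), strrep("G", 100))
  cls2 <- mispriming_read_filter(c(ctg = s2), "ctg", 500L, "-")
  expect_equal(cls2, "misprimed")
  # truncated window near the contig end: classified genuine with warning
  expect_warning(
    cls3 <- mispriming_read_filter(genome, "ctg",
                                   nchar(s) - 3L, "+"),
    "contig end")
  expect_equal(cls3, "genuine")
})

test_that("PAS counting conserves reads across the two tracks", {
  located <- data.frame(
    contig = "c", pas = c(10L, 10L, 10L, 20L, 20L), strand = "+",
    sample = "s1",
    status = c("genuine", "genuine", "misprimed", "genuine", "misprimed"),
    stringsAsFactors = FALSE)
  pc <- count_pas(located)
  expect_equal(pc$genuine$count[pc$genuine$pos == 10], 2L)
  expect_equal(pc$misprimed$count[pc$misprimed$pos == 10], 1L)
  expect_equal(sum(pc$genuine$count) + sum(pc$misprimed$count),
               nrow(located))
  # zero tailed reads: empty tracks
  pc0 <- count_pas(located[0, ])
  expect_equal(nrow(pc0$genuine), 0L)
})
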