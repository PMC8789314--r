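# Pileup counts from hand-constructed BAMs with known base compositions.

ann <- tiny_annotation()
ctg <- tiny_contig(force = list("300" = "A", "900" = "T", "320" = "C"))
genome <- c(ctg = ctg)
clen <- c(ctg = nchar(ctg))
sheet <- data.frame(sample_id = c("fus_1", "fus_2", "ctl_1", "ctl_2"),
                    group = c("fusion", "fusion", "control", "control"),
                    replicate = c(1, 2, 1, 2),
                    stringsAsFactors = FALSE)

make_bams <- function(read_sets, prefix) {
  paths <- setNames(character(length(read_sets)), names(read_sets))
  for (s in names(read_sets)) {
    paths[s] <- reads_to_bam(read_sets[[s]], clen,
                             file.path(tempdir(), paste0(prefix, "_", s)))
  }
  paths
}

test_that("plus-strand counts and minus-strand complementation are exact", {
  reads <- list(
    fus_1 = rbind(reads_at(ctg, "ctg", 300, rep(c("A", "G"), c(7, 3))),
                  reads_at(ctg, "ctg", 900, rep(c("T", "C"), c(5, 3)))),
    fus_2 = reads_at(ctg, "ctg", 300, rep("A", 12)),
    ctl_1 = reads_at(ctg, "ctg", 300, rep("A", 12)),
    ctl_2 = reads_at(ctg, "ctg", 300, rep("A", 12))
  )
  bams <- make_bams(reads, "strand")
  bcm <- pileup_counts(bams, genome, ann, sheet, min_coverage = 5)

  i300 <- which(bcm$sites$pos == 300)
  expect_equal(bcm$sites$ref[i300], "A")
  expect_equal(bcm$sites$strand[i300], "+")
  expect_equal(unname(bcm$counts[i300, "fus_1", c("A", "G")]), c(7L, 3L))

  # genomic T with 3 C reads inside the minus-strand gene is reported as
  # reference A with G = 3 (reverse-complement oracle: we wrote T/C on the
  # forward strand ourselves)
  i900 <- which(bcm$sites$pos == 900)
  expect_equal(bcm$sites$strand[i900], "-")
  expect_equal(bcm$sites$ref[i900], "A")
  expect_equal(unname(bcm$counts[i900, "fus_1", c("A", "G")]), c(5L, 3L))
})

test_that("coverage mask requires min_coverage in a fusion sample", {
  reads <- list(
    fus_1 = reads_at(ctg, "ctg", 300, rep("A", 4)),   # below threshold
    fus_2 = reads_at(ctg, "ctg", 300, rep("A", 4)),
    ctl_1 = reads_at(ctg, "ctg", 300, rep(c("A", "G"), c(30, 10))),
    ctl_2 = reads_at(ctg, "ctg", 300, rep("A", 30))
  )
  bams <- make_bams(reads, "mask")
  bcm <- pileup_counts(bams, genome, ann, sheet, min_coverage = 10)
  expect_false(300 %in% bcm$sites$pos)
  bcm2 <- pileup_counts(bams, genome, ann, sheet, min_coverage = 4)
  expect_true(300 %in% bcm2$sites$pos)
})

test_that("positions under genes on both strands are dropped", {
  ann2 <- rbind(ann, data.frame(gene_id = "gopp", contig = "ctg",
                                start = 250L, end = 350L, strand = "-"))
  reads <- list(
    fus_1 = reads_at(ctg, "ctg", 300, rep(c("A", "G"), c(8, 4))),
    fus_2 = reads_at(ctg, "ctg", 300, rep("A", 12)),
    ctl_1 = reads_at(ctg, "ctg", 300, rep("A", 12)),
    ctl_2 = reads_at(ctg, "ctg", 300, rep("A", 12))
  )
  bams <- make_bams(reads, "ambig")
  bcm <- pileup_counts(bams, genome, ann2, sheet, min_coverage = 5)
  expect_false(300 %in% bcm$sites$pos)
})

test_that("candidate detection follows the any-fusion-mismatch rule", {
  reads <- list(
    fus_1 = rbind(reads_at(ctg, "ctg", 300, rep(c("A", "G"), c(11, 1))),
                  reads_at(ctg, "ctg", 320, rep("C", 12))),
    fus_2 = rbind(reads_at(ctg, "ctg", 300, rep("A", 12)),
                  reads_at(ctg, "ctg", 320, rep("C", 12))),
    ctl_1 = rbind(reads_at(ctg, "ctg", 300, rep("A", 12)),
                  reads_at(ctg, "ctg", 320, rep(c("C", "T"), c(6, 6)))),
    ctl_2 = rbind(reads_at(ctg, "ctg", 300, rep("A", 12)),
                  reads_at(ctg, "ctg", 320, rep("C", 12)))
  )
  bams <- make_bams(reads, "cand")
  bcm <- pileup_counts(bams, genome, ann, sheet, min_coverage = 5)
  cand <- detect_candidate_positions(bcm)
  # one G read in one fusion sample is enough
  expect_true(300 %in% cand$pos)
  expect_equal(cand$alt[cand$pos == 300], "G")
  # mismatches only in control samples do not create a candidate
  expect_true(320 %in% bcm$sites$pos)
  expect_false(320 %in% cand$pos)
})

test_that("zero mismatches give an empty candidate list", {
  reads <- list(fus_1 = reads_at(ctg, "ctg", 300, rep("A", 12)),
                fus_2 = reads_at(ctg, "ctg", 300, rep("A", 12)),
                ctl_1 = reads_at(ctg, "ctg", 300, rep("A", 12)),
                ctl_2 = reads_at(ctg, "ctg", 300, rep("A", 12)))
  bams <- make_bams(reads, "clean")
  bcm <- pileup_counts(bams, genome, ann, sheet, min_coverage = 5)
  expect_equal(nrow(detect_candidate_positions(bcm)), 0L)
})
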