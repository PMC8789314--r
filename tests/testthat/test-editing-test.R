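g <- build_toy_genome(n_genes = 20, seed = 41)
sheet5 <- make_sample_sheet(c("fusion", "control"), n_reps = 5, seed = 42)

test_that("identical counts in both groups give log2FC = 0", {
  alt <- matrix(c(3L, 3L, 3L, 3L), 1)
  size <- matrix(c(30L, 30L, 30L, 30L), 1)
  res <- test_differential_editing(alt, size, c("f", "f", "c", "c"),
                                   "f", "c")
  expect_equal(res$log2fc, 0)
  expect_true(res$p_raw > 0.5)
})

test_that("p-values are valid and BH ordering is monotone", {
  tr <- make_editing_truth(g, n_sites = 60,
                           prop = list(fusion = c(0.01, 0.2),
                                       control = 0.005),
                           min_spacing = 20, seed = 43)
  bcm <- simulate_editing_counts(tr, sheet5, coverage_mean = 60, seed = 44)
  res <- call_editing_sites(bcm, "fusion")
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1, na.rm = TRUE))
  expect_true(all(res$p_adj >= res$p_raw - 1e-12, na.rm = TRUE))
  ok <- !is.na(res$p_raw)
  expect_equal(order(res$p_raw[ok]), order(res$p_adj[ok], res$p_raw[ok]))
  # proportions are proportions and G+A bounded by coverage
  expect_true(all(res$prop_fusion >= 0 & res$prop_fusion <= 1))
  expect_true(all(res$prop_control >= 0 & res$prop_control <= 1))
})

test_that("the beta-binomial fit agrees with an independent implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(45)
  size <- rpois(10, 80)
  alt <- tribepas:::rbetabinom(10, size, 0.15, 0.05)
  grp <- rep(c(1, 0), each = 5)
  f <- tribepas:::bb_fit(alt, size, cbind(1, grp))
  dat <- data.frame(alt = alt, ref = size - alt, grp = grp)
  m <- glmmTMB::glmmTMB(cbind(alt, ref) ~ grp, data = dat,
                        family = glmmTMB::betabinomial())
  expect_equal(-f$negll, as.numeric(stats::logLik(m)), tolerance = 1e-4)
  expect_equal(unname(f$theta[1:2]), unname(glmmTMB::fixef(m)$cond),
               tolerance = 1e-3)
})

test_that("power rises with coverage and effect size", {
  props <- c(0.05, 0.15, 0.4)
  covs <- c(20, 60, 180)
  pow <- matrix(NA_real_, 3, 3)
  for (a in seq_along(props)) {
    for (b in seq_along(covs)) {
      tr <- make_editing_truth(
        g, n_sites = 40,
        prop = list(fusion = props[a], control = 0.003),
        min_spacing = 10, seed = 46)
      bcm <- simulate_editing_counts(tr, sheet5, coverage_mean = covs[b],
                                     seed = 100 + 10 * a + b)
      alt <- tribepas:::bcm_alt_counts(bcm, tr$alt)
      size <- alt + tribepas:::bcm_ref_counts(bcm)
      res <- test_differential_editing(alt, size, sheet5$group,
                                       "fusion", "control")
      pow[a, b] <- mean(res$p_raw < 0.01, na.rm = TRUE)
    }
  }
  # allow small monte-carlo wiggle on the monotonicity grid
  expect_true(all(diff(pow[, 3]) >= -0.05))   # in effect size
  expect_true(all(diff(pow[3, ]) >= -0.05))   # in coverage
  expect_gt(pow[3, 3], 0.9)
  expect_lt(pow[1, 1], pow[3, 3])
})

test_that("A-to-G and SNP filters follow the classification rules", {
  sites <- data.frame(
    contig = "c", pos = 1:4, strand = "+",
    ref = c("C", "A", "A", "A"), alt = c("T", "G", "G", "G"),
    stringsAsFactors = FALSE)
  # columns: 2 fusion then 2 control samples
  alt <- rbind(c(10L, 12L, 0L, 0L),    # C->T, strong: dropped by base rule
               c(99L, 99L, 99L, 99L),  # ~1.0 everywhere: homozygous SNP
               c(30L, 30L, 40L, 40L),  # 0.3/0.4 in controls: control SNP
               c(30L, 30L, 0L, 0L))    # classic edit: retained
  size <- matrix(100L, 4, 4)
  sheet <- data.frame(sample_id = c("f1", "f2", "c1", "c2"),
                      group = c("fusion", "fusion", "control", "control"))
  out <- classify_and_filter_sites(sites, alt, size, sheet)
  expect_equal(out$is_AtoG, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$is_SNP, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$pass_filters, c(FALSE, FALSE, FALSE, TRUE))
  # user SNP mask removes listed positions
  out2 <- classify_and_filter_sites(sites, alt, size, sheet,
                                    snp_mask = data.frame(contig = "c",
                                                          pos = 4L))
  expect_false(out2$pass_filters[4])
})

test_that("background comparison gates on control significance", {
  sheet <- make_sample_sheet(c("single", "triple"), n_reps = 5,
                             adar_mean = 10, seed = 47)
  tr <- make_editing_truth(g, n_sites = 20,
                           prop = list(single = 0.1, triple = 0.35),
                           min_spacing = 10, seed = 48)
  bcm <- simulate_editing_counts(tr, sheet, coverage_mean = 150, seed = 49)
  keys <- site_key(tr)
  res_all <- compare_backgrounds(bcm, "triple", "single",
                                 control_sig = keys)
  expect_gt(mean(res_all$reported), 0.8)   # strong true difference
  # the same sites fail when not significant vs control anywhere
  res_none <- compare_backgrounds(bcm, "triple", "single",
                                  control_sig = character(0))
  expect_false(any(res_none$reported))
  expect_equal(res_all$p_adj, res_none$p_adj)
})

test_that("a constant covariate is dropped with a warning", {
  alt <- matrix(c(5L, 6L, 1L, 0L), 1)
  size <- matrix(50L, 1, 4)
  expect_warning(
    test_differential_editing(alt, size, c("f", "f", "c", "c"), "f", "c",
                              covariate = rep(2, 4)),
    "constant")
})

test_that("site-to-gene aggregation respects gene intervals", {
  genes <- data.frame(gene_id = c("gA", "gB"), contig = "c",
                      start = c(1L, 200L), end = c(100L, 300L),
                      strand = "+", stringsAsFactors = FALSE)
  sites <- data.frame(contig = "c", pos = c(250L, 260L, 270L, 150L),
                      strand = "+", significant = TRUE,
                      stringsAsFactors = FALSE)
  res <- sites_to_target_genes(sites, genes)
  expect_equal(res$targets$gene_id, "gB")
  expect_equal(res$targets$n_sites, 3L)
  expect_equal(nrow(res$intergenic), 1L)
  expect_equal(res$intergenic$pos, 150L)
  # zero significant sites: empty set
  sites$significant <- FALSE
  expect_equal(nrow(sites_to_target_genes(sites, genes)$targets), 0L)
})
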