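## Beta-binomial regression machinery.
##
## The editing model: at one site, the alternative-base count of sample i is
## beta-binomial with mean proportion p_i and intra-site correlation rho
## shared across samples, logit(p_i) = x_i' beta. Differential editing is a
## likelihood-ratio test between nested design matrices; the statistic is
## referred to an F(df1, n - k) distribution (k = mean parameters of the
## full model), which corrects the small-sample anticonservativeness of the
## chi-square reference at typical replicate numbers.

bb_negll <- function(theta, alt, size, X) {
  k <- ncol(X)
  p <- plogis(drop(X %*% theta[seq_len(k)]))
  rho <- plogis(theta[k + 1L])
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  -sum(lchoose(size, alt) + lbeta(alt + a, size - alt + b) - lbeta(a, b))
}

bb_fit <- function(alt, size, X, rho_init = 0.05) {
  phat <- (sum(alt) + 0.5) / (sum(size) + 1)
  init <- c(qlogis(phat), rep(0, ncol(X) - 1L), qlogis(rho_init))
  o <- optim(init, bb_negll, alt = alt, size = size, X = X,
             method = "Nelder-Mead",
             control = list(maxit = 1000L, reltol = 1e-10))
  list(theta = o$par, negll = o$value, convergence = o$convergence)
}

## LRT p-value between nested beta-binomial models, F reference
bb_lrt <- function(alt, size, X0, X1) {
  f0 <- bb_fit(alt, size, X0)
  f1 <- bb_fit(alt, size, X1)
  stat <- max(0, 2 * (f0$negll - f1$negll))
  df1 <- ncol(X1) - ncol(X0)
  df2 <- length(alt) - ncol(X1)
  pf(stat / df1, df1, df2, lower.tail = FALSE)
}

## pooled editing proportion with the 1-read pseudocount on alternative and
## reference totals
pooled_prop <- function(alt_total, ref_total) {
  (alt_total + 1) / (alt_total + ref_total + 2)
}

#' Replicate-aware test of differential editing proportion
#'
#' Tests, per site, whether the alternative-base proportion differs between
#' two groups, using a beta-binomial likelihood-ratio test with a common
#' intra-site correlation across replicates (an F reference with `n - k`
#' denominator degrees of freedom keeps the test calibrated at small
#' replicate numbers). The effect size is
#' `log2FC = log2(p_test / p_ref)` on pooled proportions, with a 1-read
#' pseudocount added to each group's alternative and reference totals.
#'
#' @param alt,size integer matrices (sites x samples) of alternative-base
#'   counts and total coverage.
#' @param group character/factor of length `ncol(alt)`.
#' @param test_level,ref_level the two group levels compared; `log2fc > 0`
#'   means more edited in `test_level`.
#' @param covariate optional numeric per-sample covariate; it is z-scored
#'   across the samples in the comparison before entering the model (and
#'   dropped with a warning when constant).
#' @return data.frame with one row per site: `p_raw`, `log2fc`,
#'   `prop_test`, `prop_ref`, `skipped` (a group had zero coverage).
#' @examples
#' alt <- rbind(c(5L, 6L, 0L, 1L))
#' size <- rbind(c(50L, 60L, 55L, 52L))
#' test_differential_editing(alt, size, c("f", "f", "c", "c"), "f", "c")
#' @export
test_differential_editing <- function(alt, size, group, test_level,
                                      ref_level, covariate = NULL) {
  stopifnot(is.matrix(alt), is.matrix(size),
            identical(dim(alt), dim(size)),
            length(group) == ncol(alt))
  use <- group %in% c(test_level, ref_level)
  if (sum(group == test_level) < 2L || sum(group == ref_level) < 2L) {
    stop("need >= 2 samples in each compared group")
  }
  alt <- alt[, use, drop = FALSE]
  size <- size[, use, drop = FALSE]
  grp <- as.integer(group[use] == test_level)

  X0 <- cbind(intercept = rep(1, length(grp)))
  if (!is.null(covariate)) {
    covariate <- covariate[use]
    if (sd(covariate) == 0) {
      warning("covariate is constant across samples; dropped")
      covariate <- NULL
    } else {
      z <- (covariate - mean(covariate)) / sd(covariate)
      X0 <- cbind(X0, cov = z)
    }
  }
  X1 <- cbind(X0[, 1, drop = FALSE], group = grp,
              X0[, -1, drop = FALSE])

  n <- nrow(alt)
  p_raw <- rep(NA_real_, n)
  skipped <- logical(n)
  at <- alt[, grp == 1L, drop = FALSE]
  st <- size[, grp == 1L, drop = FALSE]
  ar <- alt[, grp == 0L, drop = FALSE]
  sr <- size[, grp == 0L, drop = FALSE]
  prop_test <- pooled_prop(rowSums(at), rowSums(st) - rowSums(at))
  prop_ref <- pooled_prop(rowSums(ar), rowSums(sr) - rowSums(ar))
  log2fc <- log2(prop_test / prop_ref)

  for (i in seq_len(n)) {
    if (sum(st[i, ]) == 0L || sum(sr[i, ]) == 0L) {
      skipped[i] <- TRUE
      next
    }
    p_raw[i] <- bb_lrt(alt[i, ], size[i, ], X0, X1)
  }
  if (any(skipped)) {
    message(sum(skipped), " site(s) skipped: a group had zero coverage")
  }
  data.frame(p_raw = p_raw, log2fc = log2fc, prop_test = prop_test,
             prop_ref = prop_ref, skipped = skipped)
}

#' Classify tested sites and filter to non-SNP A-to-G edits
#'
#' Keeps only transcript-orientation A-to-G sites, drops positions in a
#' user-supplied SNP mask, and additionally drops heuristic SNPs: positions
#' whose pooled alternative proportion is at least `snp_control_prop` in the
#' control samples (an edit should be near-absent there), or at least
#' `snp_global_prop` in every sample of every group (the homozygous
#' pattern).
#'
#' @param sites data.frame of tested sites with `contig`, `pos`, `strand`,
#'   `ref`, `alt`.
#' @param alt,size matrices (sites x samples) aligned with `sites`.
#' @param sample_sheet sample sheet aligned with the matrix columns.
#' @param control_group group label of the free-ADAR control samples; when
#'   absent from the sheet the control-proportion heuristic is skipped.
#' @param snp_mask optional data.frame (`contig`, `pos`) of known variants.
#' @param snp_control_prop,snp_global_prop heuristic thresholds.
#' @return `sites` with logical columns `is_AtoG`, `is_SNP`, and
#'   `pass_filters` (`is_AtoG & !is_SNP`).
#' @export
classify_and_filter_sites <- function(sites, alt, size, sample_sheet,
                                      control_group = "control",
                                      snp_mask = NULL,
                                      snp_control_prop = 0.35,
                                      snp_global_prop = 0.8) {
  stopifnot(nrow(sites) == nrow(alt), identical(dim(alt), dim(size)))
  is_atog <- sites$ref == "A" & sites$alt == "G"

  in_mask <- rep(FALSE, nrow(sites))
  if (!is.null(snp_mask) && nrow(snp_mask) > 0) {
    in_mask <- paste(sites$contig, sites$pos) %in%
      paste(snp_mask$contig, snp_mask$pos)
  }

  ctrl <- sample_sheet$group == control_group
  high_ctrl <- rep(FALSE, nrow(sites))
  if (any(ctrl)) {
    a <- rowSums(alt[, ctrl, drop = FALSE])
    s <- rowSums(size[, ctrl, drop = FALSE])
    high_ctrl <- s > 0 & a / pmax(s, 1L) >= snp_control_prop
  }
  with_cov <- size > 0
  prop <- ifelse(with_cov, alt / pmax(size, 1L), NA)
  high_everywhere <- apply(prop >= snp_global_prop | !with_cov, 1, all) &
    apply(with_cov, 1, any)

  is_snp <- in_mask | high_ctrl | high_everywhere
  sites$is_AtoG <- is_atog
  sites$is_SNP <- is_snp
  sites$pass_filters <- is_atog & !is_snp
  sites
}

#' Call significant editing sites against free-ADAR controls
#'
#' The full fusion-vs-control calling pipeline on a [base_count_matrix()]:
#' candidate detection (any mismatch in any fusion sample), the
#' beta-binomial differential test per candidate, Benjamini-Hochberg
#' adjustment across all tested candidates, and A-to-G/SNP filtering. A
#' site is `significant` when `p_adj < p_adj_max`, `log2fc > lfc_min`, and
#' it passes the A-to-G/SNP filters.
#'
#' @param bcm a [base_count_matrix()].
#' @param fusion_group,control_group group labels in `bcm$samples`.
#' @param p_adj_max,lfc_min significance thresholds (defaults 0.01 and 1).
#' @inheritParams classify_and_filter_sites
#' @return data.frame of tested candidates (`EditingSite` table): position
#'   key, `alt`, pooled proportions, `log2fc`, `p_raw`, `p_adj`, filter
#'   flags, `significant`.
#' @export
call_editing_sites <- function(bcm, fusion_group, control_group = "control",
                               p_adj_max = 0.01, lfc_min = 1,
                               snp_mask = NULL, snp_control_prop = 0.35,
                               snp_global_prop = 0.8) {
  fusion_samples <-
    bcm$samples$sample_id[bcm$samples$group == fusion_group]
  cand <- detect_candidate_positions(bcm, fusion_samples)
  if (nrow(cand) == 0L) {
    out <- cbind(cand, prop_fusion = numeric(0), prop_control = numeric(0),
                 log2fc = numeric(0), p_raw = numeric(0),
                 p_adj = numeric(0), is_AtoG = logical(0),
                 is_SNP = logical(0), pass_filters = logical(0),
                 significant = logical(0))
    return(out)
  }
  sub <- bcm_subset(bcm, cand$site_idx)
  alt <- bcm_alt_counts(sub, cand$alt)
  size <- alt + bcm_ref_counts(sub)

  res <- test_differential_editing(alt, size, bcm$samples$group,
                                   fusion_group, control_group)
  out <- cand
  out$prop_fusion <- res$prop_test
  out$prop_control <- res$prop_ref
  out$log2fc <- res$log2fc
  out$p_raw <- res$p_raw
  out$p_adj <- p.adjust(res$p_raw, method = "BH")
  out <- classify_and_filter_sites(out, alt, size, bcm$samples,
                                   control_group, snp_mask,
                                   snp_control_prop, snp_global_prop)
  out$significant <- !is.na(out$p_adj) & out$p_adj < p_adj_max &
    out$log2fc > lfc_min & out$pass_filters
  out
}

#' Compare editing between mutant backgrounds with an ADAR covariate
#'
#' Runs the same beta-binomial test family between two genetic backgrounds
#' (e.g. triple vs. single mutant) with the z-scored per-sample ADAR
#' transgene abundance as an extra covariate, absorbing dosage-driven
#' variation in editing. A position is reported as differentially edited
#' iff `p_adj < p_adj_max`, `|log2fc| > lfc_min`, and it is a significant
#' site against the free-ADAR control in at least one of the two
#' backgrounds (`control_sig`).
#'
#' @param bcm a [base_count_matrix()] over the samples of both backgrounds.
#' @param test_group,ref_group background labels (`log2fc > 0` means more
#'   edited in `test_group`).
#' @param control_sig character vector of position keys
#'   (`"contig:pos:strand"`, see [call_editing_sites()] rows via
#'   `site_key()`) significant against the free-ADAR control in at least
#'   one background; `NULL` disables the gate (all positions eligible).
#' @param use_covariate include the z-scored `adar_abundance` covariate.
#' @param p_adj_max,lfc_min reporting thresholds (defaults 0.1 and 0.25).
#' @param alt_base alternative base tested (default `"G"`, the A-to-G mark).
#' @return data.frame with per-position test results and the logical column
#'   `reported`.
#' @export
compare_backgrounds <- function(bcm, test_group, ref_group,
                                control_sig = NULL, use_covariate = TRUE,
                                p_adj_max = 0.1, lfc_min = 0.25,
                                alt_base = "G") {
  use <- bcm$samples$group %in% c(test_group, ref_group)
  stopifnot(any(use))
  covariate <- NULL
  if (use_covariate) {
    if (!"adar_abundance" %in% names(bcm$samples)) {
      stop("`use_covariate = TRUE` requires `adar_abundance` in the samples")
    }
    covariate <- bcm$samples$adar_abundance
  }
  alt <- bcm_alt_counts(bcm, rep(alt_base, nrow(bcm$sites)))
  size <- alt + bcm_ref_counts(bcm)
  res <- test_differential_editing(alt, size, bcm$samples$group,
                                   test_group, ref_group, covariate)
  out <- cbind(bcm$sites, res)
  out$p_adj <- p.adjust(out$p_raw, method = "BH")
  eligible <- if (is.null(control_sig)) TRUE else
    site_key(out) %in% control_sig
  out$reported <- !is.na(out$p_adj) & out$p_adj < p_adj_max &
    abs(out$log2fc) > lfc_min & eligible
  out
}

#' Aggregate editing sites to target genes
#'
#' A gene is a HyperTRIBE target iff at least one significant filtered
#' editing site lies within its annotated span (matching strand). Sites
#' outside every gene are reported in an `intergenic` bucket rather than
#' silently dropped.
#'
#' @param sites an `EditingSite` table (rows with `significant == TRUE` are
#'   used; pass a pre-filtered table to override).
#' @param annotation gene models (see [pileup_counts()]).
#' @return list with `targets` (data.frame `gene_id`, `n_sites`),
#'   `site_genes` (per-site gene assignment), and `intergenic` (sites in no
#'   gene).
#' @export
sites_to_target_genes <- function(sites, annotation) {
  genes <- as_genes_df(annotation)
  if ("significant" %in% names(sites)) sites <- sites[sites$significant, ]
  if (nrow(sites) == 0L) {
    return(list(targets = data.frame(gene_id = character(),
                                     n_sites = integer()),
                site_genes = data.frame(),
                intergenic = sites))
  }
  gr <- genes_granges(genes)
  sgr <- GenomicRanges::GRanges(sites$contig,
                                IRanges::IRanges(sites$pos, width = 1L),
                                strand = sites$strand)
  hits <- GenomicRanges::findOverlaps(sgr, gr)
  sg <- data.frame(site = S4Vectors::queryHits(hits),
                   gene_id = genes$gene_id[S4Vectors::subjectHits(hits)])
  tab <- table(sg$gene_id)
  targets <- data.frame(gene_id = names(tab), n_sites = as.integer(tab),
                        stringsAsFactors = FALSE)
  targets <- targets[order(targets$gene_id), , drop = FALSE]
  rownames(targets) <- NULL
  list(targets = targets,
       site_genes = sg,
       intergenic = sites[setdiff(seq_len(nrow(sites)), sg$site), ,
                          drop = FALSE])
}
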