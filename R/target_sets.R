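## Set algebra over target gene lists and expression-filter classification.

#' Build permissive/stringent/non-target gene sets
#'
#' Combines HyperTRIBE target sets for two readers (ECT2, ECT3) with an
#' iCLIP target set over the expressed-gene universe:
#' permissive = (ect2_ht or ect3_ht or ect2_iclip) restricted to expressed
#' genes; stringent = HyperTRIBE targets of either reader that also have
#' iCLIP support; non-target = expressed genes outside the permissive set.
#'
#' @param ect2_ht,ect3_ht,ect2_iclip character vectors of gene ids.
#' @param expressed character vector: the expressed-gene universe (must be
#'   non-empty).
#' @return An object of class `TargetSetCollection`: list with `expressed`,
#'   `ect2_ht`, `ect3_ht`, `ect2_iclip` (restricted to expressed),
#'   `permissive`, `stringent`, `non_target`.
#' @examples
#' ts <- build_target_sets(c("a", "b"), c("b", "c"), c("b", "d"),
#'                         letters[1:5])
#' ts$stringent
#' @export
build_target_sets <- function(ect2_ht, ect3_ht, ect2_iclip, expressed) {
  expressed <- unique(expressed)
  if (length(expressed) == 0L) stop("`expressed` gene universe is empty")
  e2 <- intersect(unique(ect2_ht), expressed)
  e3 <- intersect(unique(ect3_ht), expressed)
  ic <- intersect(unique(ect2_iclip), expressed)
  permissive <- union(union(e2, e3), ic)
  stringent <- intersect(union(e2, e3), ic)
  structure(list(expressed = expressed, ect2_ht = e2, ect3_ht = e3,
                 ect2_iclip = ic, permissive = permissive,
                 stringent = stringent,
                 non_target = setdiff(expressed, permissive)),
            class = "TargetSetCollection")
}

#' @export
print.TargetSetCollection <- function(x, ...) {
  cat("TargetSetCollection:", length(x$expressed), "expressed;",
      length(x$permissive), "permissive,", length(x$stringent),
      "stringent,", length(x$non_target), "non-target\n")
  invisible(x)
}

#' Check the structural invariants of a TargetSetCollection
#'
#' Asserts that stringent is a subset of permissive, that permissive and
#' non-target are disjoint, that together they cover the expressed
#' universe, and that permissive equals the evidence union restricted to
#' expressed genes. Errors on violation; invisibly `TRUE` otherwise.
#'
#' @param x a [build_target_sets()] result.
#' @export
validate_target_sets <- function(x) {
  stopifnot(inherits(x, "TargetSetCollection"))
  ok <- all(x$stringent %in% x$permissive) &&
    length(intersect(x$permissive, x$non_target)) == 0L &&
    setequal(union(x$permissive, x$non_target), x$expressed) &&
    setequal(x$permissive,
             intersect(union(union(x$ect2_ht, x$ect3_ht), x$ect2_iclip),
                       x$expressed))
  if (!ok) stop("TargetSetCollection invariants violated")
  invisible(TRUE)
}

#' Reader-specificity classes from single- and triple-mutant backgrounds
#'
#' Classifies targets by which reader edits them and in which genetic
#' background: strictly ECT2-specific genes are ECT2 targets in the single
#' mutant never touched by ECT3 (in either background); `acquired` genes
#' are reader-specific targets that the other reader picks up only in the
#' triple mutant; genes edited by either reader only in the triple
#' background are putative targets of the third reader (ECT4), which is
#' knocked out there.
#'
#' @param ect2_single,ect2_triple,ect3_single,ect3_triple character
#'   vectors of target gene ids per reader and background.
#' @return list of disjoint character vectors: `ect2_strict`,
#'   `ect3_strict`, `ect2_acquired_by_ect3`, `ect3_acquired_by_ect2`,
#'   `putative_ect4`.
#' @export
specificity_classes <- function(ect2_single, ect2_triple,
                                ect3_single, ect3_triple) {
  list(
    ect2_strict = setdiff(ect2_single, union(ect3_single, ect3_triple)),
    ect3_strict = setdiff(ect3_single, union(ect2_single, ect2_triple)),
    ect2_acquired_by_ect3 =
      intersect(setdiff(ect2_single, ect3_single), ect3_triple),
    ect3_acquired_by_ect2 =
      intersect(setdiff(ect3_single, ect2_single), ect2_triple),
    putative_ect4 = setdiff(union(ect2_triple, ect3_triple),
                            union(ect2_single, ect3_single))
  )
}

#' Proportion of cell-type marker genes that are targets
#'
#' For each single-cell cluster, the fraction of its marker genes contained
#' in the target set (the overlay statistic for cell-type congruence).
#'
#' @param markers_by_cluster named list of marker gene-id vectors.
#' @param targets character vector of target gene ids.
#' @return named numeric vector of proportions in `[0, 1]`; clusters with
#'   no markers get `NA`.
#' @export
marker_target_proportion <- function(markers_by_cluster, targets) {
  vapply(markers_by_cluster, function(m) {
    m <- unique(m)
    if (length(m) == 0L) return(NA_real_)
    length(intersect(m, targets)) / length(m)
  }, 0)
}

#' Expression filtering and differential-expression classification
#'
#' Applies the expression filters used before differential-expression
#' classification and labels kept genes from an externally fitted DE table
#' (model fitting itself is out of scope). mRNA mode keeps genes with at
#' least `min_expr` TPM in every sample and a total of at least
#' `min_total` TPM; small-RNA mode drops genes below `min_expr` RPM in all
#' samples. Kept genes are classified `up` iff `fdr < fdr_max` and
#' `fc > fc_up`, `down` iff `fdr < fdr_max` and `fc < 1/fc_up`, otherwise
#' `unchanged`; kept genes missing from the stats table are `untested`.
#'
#' @param expr numeric matrix, genes x samples (TPM or RPM by mode).
#' @param stats data.frame with `gene_id`, `fc` (linear fold change,
#'   mutant/wild-type), `fdr`.
#' @param mode `"mrna"` or `"srna"`.
#' @param min_expr,min_total,fc_up,fdr_max thresholds (defaults 1, 5, 1.5,
#'   0.05; boundaries strict).
#' @return data.frame of kept genes with `class` in
#'   `up`/`down`/`unchanged`/`untested`.
#' @export
filter_and_classify_expression <- function(expr, stats,
                                           mode = c("mrna", "srna"),
                                           min_expr = 1, min_total = 5,
                                           fc_up = 1.5, fdr_max = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  keep <- if (mode == "mrna") {
    apply(expr >= min_expr, 1, all) & rowSums(expr) >= min_total
  } else {
    !apply(expr < min_expr, 1, all)
  }
  genes <- rownames(expr)[keep]
  i <- match(genes, stats$gene_id)
  fc <- stats$fc[i]; fdr <- stats$fdr[i]
  class <- ifelse(is.na(i), "untested",
                  ifelse(fdr < fdr_max & fc > fc_up, "up",
                         ifelse(fdr < fdr_max & fc < 1 / fc_up, "down",
                                "unchanged")))
  data.frame(gene_id = genes, fc = fc, fdr = fdr, class = class,
             stringsAsFactors = FALSE)
}
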