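# Tumor-vs-normal differential expression on log2-scale abundances, with
# BH-FDR control and the |log2FC| > 1 & FDR < 0.05 calling rule.

de_result <- function(gene_id, log2fc, p_value, n_used, test_name) {
  structure(
    data.frame(
      gene_id = gene_id, log2fc = log2fc, p_value = p_value,
      fdr = NA_real_, n_used = as.integer(n_used), test_name = test_name,
      significant = NA, stringsAsFactors = FALSE
    ),
    class = c("de_result", "data.frame")
  )
}

require_log2_scale <- function(matrix) {
  if (matrix$scale == "tpm") {
    validation_error(
      "matrix is on the raw tpm scale; apply log2_transform() before testing"
    )
  }
}

# Complete tumor/normal pairs for one gene, keyed by pair_id.
extract_pairs <- function(matrix, annotations, gene) {
  v <- expr_values(matrix, gene)
  ann <- annotations[!is.na(annotations$pair_id) &
    annotations$sample_id %in% names(v), , drop = FALSE]
  tum <- ann[ann$condition == "tumor", , drop = FALSE]
  nor <- ann[ann$condition == "normal", , drop = FALSE]
  pids <- intersect(tum$pair_id, nor$pair_id)
  tv <- v[tum$sample_id[match(pids, tum$pair_id)]]
  nv <- v[nor$sample_id[match(pids, nor$pair_id)]]
  keep <- !is.na(tv) & !is.na(nv)
  list(tumor = unname(tv[keep]), normal = unname(nv[keep]), pair_id = pids[keep])
}

# Two-sided Wilcoxon p-values. Exact when n <= 25 and the data are tie-free
# (wilcox.test's exact distribution); with ties at small n the exact
# conditional distribution is enumerated directly over sign assignments /
# group relabelings of the mid-ranks; otherwise the normal approximation
# with continuity correction and mid-rank variance adjustment applies.
wilcox_p <- function(x, y, paired, n_exact_max = 25, n_enum_max = 12) {
  two_sided <- function(stat_all, stat_obs) {
    min(1, 2 * min(mean(stat_all <= stat_obs), mean(stat_all >= stat_obs)))
  }
  if (paired) {
    d <- (x - y)
    d <- d[d != 0] # zero differences carry no sign information
    n <- length(d)
    if (n == 0) return(1)
    r <- rank(abs(d))
    if (!anyDuplicated(r) && n <= n_exact_max) {
      return(suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
      ))
    }
    if (n <= n_enum_max) {
      w_obs <- sum(r[d > 0])
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      return(two_sided(as.numeric(signs %*% r), w_obs))
    }
    return(suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)$p.value
    ))
  }
  n1 <- length(x)
  n_tot <- n1 + length(y)
  r <- rank(c(x, y))
  if (!anyDuplicated(r) && max(n1, length(y)) <= n_exact_max) {
    return(suppressWarnings(
      stats::wilcox.test(x, y, exact = TRUE)$p.value
    ))
  }
  if (n_tot <= n_enum_max + 2) {
    w_obs <- sum(r[seq_len(n1)])
    combos <- utils::combn(n_tot, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    return(two_sided(w_all, w_obs))
  }
  suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
}

#' Paired tumor-vs-normal differential expression for one gene
#'
#' The effect size is the mean over complete pairs of (tumor - normal) on the
#' log2 scale; the p-value comes from the selected paired test. The default
#' `signed_rank` is the Wilcoxon test appropriate for paired designs;
#' `rank_sum` applies the two-sample rank-sum test to the paired samples, and
#' `paired_t` the paired t-test (as used for proteomic log-ratio tables).
#'
#' @param matrix An `ExpressionMatrix` on a log2 scale.
#' @param annotations Validated annotation data.frame with `pair_id`s.
#' @param gene Gene id to test.
#' @param test One of `"signed_rank"`, `"rank_sum"`, `"paired_t"`.
#' @return A one-row `de_result` data.frame with `gene_id`, `log2fc`,
#'   `p_value`, `fdr` (NA until [bh_fdr()]), `n_used`, `test_name`,
#'   `significant` (NA until [call_significant()]).
#' @export
paired_de <- function(matrix, annotations, gene,
                      test = c("signed_rank", "rank_sum", "paired_t")) {
  test <- match.arg(test)
  require_log2_scale(matrix)
  pairs <- extract_pairs(matrix, annotations, gene)
  n <- length(pairs$tumor)
  if (n < 3) {
    insufficient_data_error(
      "gene '", gene, "': ", n, " complete pairs (>=3 required)"
    )
  }
  d <- pairs$tumor - pairs$normal
  lfc <- mean(d)
  p <- switch(test,
    signed_rank = if (all(d == 0)) 1 else wilcox_p(pairs$tumor, pairs$normal, paired = TRUE),
    rank_sum = if (all(d == 0)) 1 else wilcox_p(pairs$tumor, pairs$normal, paired = FALSE),
    paired_t = {
      if (stats::sd(d) == 0) {
        degenerate_input_error("gene '", gene, "': zero variance of paired differences")
      }
      stats::t.test(pairs$tumor, pairs$normal, paired = TRUE)$p.value
    }
  )
  de_result(gene, lfc, p, n, test)
}

#' Unpaired two-group differential expression for one gene
#'
#' Rank-sum (Mann-Whitney) comparison of two independent groups, e.g.,
#' unpaired tumor samples against normal-tissue references from another
#' cohort. Effect size is the difference of group means on the log2 scale.
#'
#' @param matrix_a `ExpressionMatrix` for group A (e.g., tumors), log2 scale.
#' @param matrix_b `ExpressionMatrix` for group B (e.g., normals), log2 scale.
#' @param gene Gene id present in both matrices.
#' @return A one-row `de_result` data.frame; `n_used` is the total number of
#'   non-missing values used.
#' @export
unpaired_de <- function(matrix_a, matrix_b, gene) {
  require_log2_scale(matrix_a)
  require_log2_scale(matrix_b)
  a <- expr_values(matrix_a, gene)
  b <- expr_values(matrix_b, gene)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) {
    insufficient_data_error(
      "gene '", gene, "': groups of ", length(a), " and ", length(b),
      " samples (>=3 each required)"
    )
  }
  lfc <- mean(a) - mean(b)
  p <- if (identical(sort(a), sort(b))) 1 else wilcox_p(a, b, paired = FALSE)
  de_result(gene, lfc, p, length(a) + length(b), "rank_sum")
}

#' One-way ANOVA of expression across tumor stages
#'
#' Classical fixed-effects F-test of a gene's expression across stage groups
#' (I--IV). Stage groups with fewer than 2 samples are dropped with a
#' warning; at least two groups must remain.
#'
#' @inheritParams paired_de
#' @return The ANOVA p-value.
#' @export
stage_anova <- function(matrix, annotations, gene) {
  v <- expr_values(matrix, gene)
  ann <- annotations[annotations$sample_id %in% names(v), , drop = FALSE]
  x <- v[ann$sample_id]
  stage <- ann$stage
  keep <- !is.na(x) & !is.na(stage)
  x <- x[keep]
  stage <- stage[keep]
  sizes <- table(stage)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(
      "dropping stage group(s) with <2 samples: ",
      paste(small, collapse = ", ")
    )
    keep <- !stage %in% small
    x <- x[keep]
    stage <- stage[keep]
  }
  if (length(unique(stage)) < 2) {
    insufficient_data_error("gene '", gene, "': fewer than 2 usable stage groups")
  }
  fit <- stats::lm(x ~ factor(stage))
  stats::anova(fit)[["Pr(>F)"]][1]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, monotonicity-enforced and capped at 1, preserving
#' the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    validation_error("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the fold-change + FDR significance-calling rule
#'
#' A gene is called significant iff `|log2fc| > lfc_threshold` and
#' `fdr < fdr_threshold`, both strict.
#'
#' @param de_results Data.frame with `log2fc` and `fdr` columns (rows of
#'   [paired_de()]/[unpaired_de()] output after [bh_fdr()]).
#' @param lfc_threshold Fold-change threshold on the log2 scale (default 1,
#'   i.e., 2-fold).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return `de_results` with its `significant` column filled.
#' @export
call_significant <- function(de_results, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(de_results), all(c("log2fc", "fdr") %in% names(de_results)))
  de_results$significant <- abs(de_results$log2fc) > lfc_threshold &
    de_results$fdr < fdr_threshold
  de_results
}

#' log2(x + pseudocount) transform of a TPM-scale matrix
#'
#' @param matrix An `ExpressionMatrix` on the `tpm` scale (non-negative).
#' @param pseudocount Added before the log (default 1).
#' @return An `ExpressionMatrix` on the `log2_tpm_p1` scale.
#' @export
log2_transform <- function(matrix, pseudocount = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "tpm") {
    validation_error("log2_transform expects a tpm-scale matrix, got ", matrix$scale)
  }
  if (any(matrix$values < 0, na.rm = TRUE)) {
    validation_error("negative values cannot be log-transformed")
  }
  expression_matrix(log2(matrix$values + pseudocount), "log2_tpm_p1")
}

#' Differential-expression table over many genes
#'
#' Convenience wrapper running [paired_de()] or [unpaired_de()] per gene,
#' adjusting with [bh_fdr()] and calling significance. Genes failing their
#' preconditions (too few pairs) are skipped with a warning count.
#'
#' @param matrix `ExpressionMatrix` (tumor + normal columns for paired mode;
#'   group A for unpaired mode).
#' @param annotations Annotations (paired mode only).
#' @param genes Gene ids to test; default all genes in `matrix`.
#' @param mode `"paired"` or `"unpaired"`.
#' @param matrix_b Group-B matrix (unpaired mode only).
#' @param test Paired test selector, see [paired_de()].
#' @param lfc_threshold,fdr_threshold Passed to [call_significant()].
#' @return A `de_result` data.frame, one row per tested gene.
#' @export
de_table <- function(matrix, annotations = NULL, genes = NULL,
                     mode = c("paired", "unpaired"), matrix_b = NULL,
                     test = "signed_rank",
                     lfc_threshold = 1, fdr_threshold = 0.05) {
  mode <- match.arg(mode)
  genes <- genes %||% gene_ids(matrix)
  rows <- list()
  skipped <- 0L
  for (g in genes) {
    res <- tryCatch(
      if (mode == "paired") {
        paired_de(matrix, annotations, g, test = test)
      } else {
        unpaired_de(matrix, matrix_b, g)
      },
      sulfscan_insufficient_data = function(e) NULL
    )
    if (is.null(res)) skipped <- skipped + 1L else rows[[g]] <- res
  }
  if (skipped) warning(skipped, " gene(s) skipped for insufficient data")
  if (!length(rows)) insufficient_data_error("no gene could be tested")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p_value)
  call_significant(out, lfc_threshold, fdr_threshold)
}
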