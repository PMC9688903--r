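# Target-vs-all correlations and the permutation test for enrichment of a
# signature's correlations (e.g., a CAF signature against SULF1).

#' Pearson correlation of a target gene with every other gene
#'
#' Correlates the target row against all other rows using pairwise-complete
#' samples (missing protein measurements are common in proteomic tables).
#' Genes with fewer than `min_overlap` complete sample pairs get a missing
#' correlation, with a logged count; the target is excluded from its own
#' table.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param target_id Gene/protein id of the correlation target.
#' @param min_overlap Minimum number of complete sample pairs (default 10).
#' @return Data.frame with `gene_id`, `r`, `n_overlap`.
#' @export
correlate_target <- function(matrix, target_id, min_overlap = 10) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  v <- matrix$values
  if (!target_id %in% rownames(v)) {
    validation_error("target '", target_id, "' not present in matrix")
  }
  target <- v[target_id, ]
  if (stats::sd(target, na.rm = TRUE) == 0 || all(is.na(target))) {
    degenerate_input_error("target '", target_id, "' has zero variance")
  }
  others <- v[setdiff(rownames(v), target_id), , drop = FALSE]
  r <- suppressWarnings(
    stats::cor(t(others), target, use = "pairwise.complete.obs")[, 1]
  )
  overlap <- as.integer((!is.na(others)) %*% (!is.na(target)))
  low <- overlap < min_overlap
  if (any(low & !is.na(r))) {
    message(sum(low), " gene(s) below the overlap threshold; correlation set to NA")
  }
  r[low] <- NA_real_
  data.frame(
    gene_id = rownames(others), r = unname(r), n_overlap = overlap,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Permutation test for signature correlation enrichment
#'
#' The observed statistic is the mean correlation over signature genes (with
#' non-missing r). Each permutation draws, without replacement, a random
#' subset of the full correlation table of the same effective size and
#' records its mean; the default one-sided p-value is
#' `(1 + #\{null >= observed\}) / (1 + B)`, so it is never exactly zero.
#'
#' @param correlations Output of [correlate_target()].
#' @param signature A `SignatureSet`. Signature genes absent from the table
#'   are dropped with a warning.
#' @param b Number of permutations (>= 100; the reference design uses
#'   10,000).
#' @param seed Integer seed making the null fully reproducible.
#' @param alternative `"greater"` (default: signature mean larger than
#'   random subsets) or `"two_sided"`.
#' @param exclude_signature If TRUE, random subsets are drawn from
#'   non-signature genes only; default FALSE draws from the full universe,
#'   signature members included.
#' @param fisher_z If TRUE, average Fisher z-transformed correlations instead
#'   of raw r (default FALSE).
#' @return An object of class `perm_result` with `observed_mean_r`,
#'   `null_means`, `p_value`, `b`, `signature_size`, `universe_size`, `seed`.
#' @export
permutation_enrichment <- function(correlations, signature, b = 10000, seed = NULL,
                                   alternative = c("greater", "two_sided"),
                                   exclude_signature = FALSE, fisher_z = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(is.data.frame(correlations), all(c("gene_id", "r") %in% names(correlations)))
  if (b < 100) validation_error("b must be >= 100")
  if (inherits(signature, "SignatureSet")) sig_genes <- signature$gene_ids else sig_genes <- as.character(signature)
  absent <- setdiff(sig_genes, correlations$gene_id)
  if (length(absent)) {
    warning(length(absent), " signature gene(s) absent from the correlation table")
    sig_genes <- setdiff(sig_genes, absent)
  }
  tab <- correlations[!is.na(correlations$r), , drop = FALSE]
  rr <- if (fisher_z) atanh(pmin(pmax(tab$r, -1 + 1e-12), 1 - 1e-12)) else tab$r
  in_sig <- tab$gene_id %in% sig_genes
  m <- sum(in_sig)
  if (m < 5) validation_error("effective signature size ", m, " < 5")
  observed <- mean(rr[in_sig])
  pool <- if (exclude_signature) rr[!in_sig] else rr
  if (length(pool) < m) validation_error("universe smaller than signature")
  draw_nulls <- function() {
    vapply(seq_len(b), function(i) mean(pool[sample.int(length(pool), m)]), numeric(1))
  }
  null_means <- if (!is.null(seed)) with_seed(seed, draw_nulls()) else draw_nulls()
  p <- switch(alternative,
    greater = (1 + sum(null_means >= observed)) / (1 + b),
    two_sided = {
      center <- mean(null_means)
      (1 + sum(abs(null_means - center) >= abs(observed - center))) / (1 + b)
    }
  )
  structure(
    list(
      observed_mean_r = observed,
      null_means = null_means,
      p_value = p,
      b = as.integer(b),
      signature_size = m,
      universe_size = nrow(tab),
      seed = seed,
      alternative = alternative
    ),
    class = "perm_result"
  )
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf(
    "Signature correlation enrichment: mean r = %.4f over %d genes\n  null mean = %.4f (B = %d draws from %d genes), %s p = %.3g\n",
    x$observed_mean_r, x$signature_size, mean(x$null_means), x$b,
    x$universe_size, x$alternative, x$p_value
  ))
  invisible(x)
}

#' Count strong correlations overall and within a signature
#'
#' @param correlations Output of [correlate_target()].
#' @param r_threshold Correlation threshold in (-1, 1); counts use strict
#'   `r > r_threshold`.
#' @param signature A `SignatureSet` (or character vector of gene ids).
#' @return List with `n_above` and `n_above_in_signature`.
#' @export
threshold_count <- function(correlations, r_threshold, signature) {
  if (r_threshold <= -1 || r_threshold >= 1) {
    validation_error("r_threshold must lie in (-1, 1)")
  }
  sig_genes <- if (inherits(signature, "SignatureSet")) signature$gene_ids else as.character(signature)
  above <- !is.na(correlations$r) & correlations$r > r_threshold
  list(
    n_above = sum(above),
    n_above_in_signature = sum(above & correlations$gene_id %in% sig_genes)
  )
}
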