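# Paired patient-vs-xenograft comparison. A gene supplied by the stroma
# collapses in the xenograft (human stroma is lost on engraftment); a
# tumor-cell-intrinsic gene persists or rises with tumor expansion.

#' Paired Wilcoxon comparison of patient and PDX expression
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences (exact when
#' n <= 25 and the differences are tie-free), medians of both arms on the
#' raw TPM scale, and counts of pairs in each direction (ties excluded from
#' both counts).
#'
#' @param patient_values Numeric TPM values, named by patient id.
#' @param pdx_values Numeric TPM values for the matched xenografts, named by
#'   the same patient ids (order may differ).
#' @param gene Optional gene id recorded in the result.
#' @return An object of class `pdx_pair_result` with `gene_id`, `n_pairs`,
#'   `median_patient`, `median_pdx`, `p_value`, `n_decreased` (PDX <
#'   patient), `n_increased`.
#' @export
pdx_paired_test <- function(patient_values, pdx_values, gene = NA_character_) {
  if (is.null(names(patient_values)) || is.null(names(pdx_values))) {
    validation_error("patient and PDX values must be named by patient id")
  }
  if (!setequal(names(patient_values), names(pdx_values))) {
    bad <- c(
      setdiff(names(patient_values), names(pdx_values)),
      setdiff(names(pdx_values), names(patient_values))
    )
    validation_error("unmatched patient id: ", bad[1])
  }
  pdx_values <- pdx_values[names(patient_values)]
  n <- length(patient_values)
  if (n < 5) insufficient_data_error("need >= 5 pairs, got ", n)
  d <- pdx_values - patient_values
  if (all(d == 0)) {
    warning("all paired differences are zero")
    p <- 1
  } else {
    p <- wilcox_p(as.numeric(pdx_values), as.numeric(patient_values), paired = TRUE)
  }
  structure(
    list(
      gene_id = gene,
      n_pairs = n,
      median_patient = stats::median(patient_values),
      median_pdx = stats::median(pdx_values),
      p_value = p,
      n_decreased = sum(d < 0),
      n_increased = sum(d > 0)
    ),
    class = "pdx_pair_result"
  )
}

#' @export
print.pdx_pair_result <- function(x, ...) {
  cat(sprintf(
    "%s patient vs PDX (n = %d pairs): median %.1f -> %.1f TPM, decreased in %d, increased in %d, signed-rank p = %.3g\n",
    if (is.na(x$gene_id)) "gene" else x$gene_id, x$n_pairs,
    x$median_patient, x$median_pdx, x$n_decreased, x$n_increased, x$p_value
  ))
  invisible(x)
}

#' Long-format log10(1+TPM) table for patient/PDX heat display
#'
#' @param matrix_patient `ExpressionMatrix` of patient tumors (tpm scale).
#' @param matrix_pdx `ExpressionMatrix` of matched xenografts (tpm scale),
#'   sharing patient ids as column names.
#' @param genes Gene ids to include.
#' @return Data.frame with one row per patient x arm and one `log10(1+TPM)`
#'   column per gene, ordered patient-by-patient.
#' @export
pdx_heat_summary <- function(matrix_patient, matrix_pdx, genes) {
  shared <- intersect(sample_ids(matrix_patient), sample_ids(matrix_pdx))
  if (!length(shared)) validation_error("no shared patient ids")
  rows <- list()
  for (pid in shared) {
    for (arm in c("patient", "pdx")) {
      m <- if (arm == "patient") matrix_patient else matrix_pdx
      vals <- vapply(genes, function(g) log10(1 + expr_values(m, g)[pid]), numeric(1))
      rows[[paste(pid, arm)]] <- data.frame(
        patient_id = pid, arm = arm, t(vals),
        stringsAsFactors = FALSE, check.names = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
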