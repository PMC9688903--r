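# Single-cell attribution statistics: which cell type expresses a gene, how
# often, and how strongly. Positivity means stored expression strictly > 0
# on the log2(TPM+1) scale, i.e., any detected transcript.

cells_of_type <- function(cell_table, cell_type) {
  stopifnot(inherits(cell_table, "CellTable"))
  cells <- names(cell_table$cell_type)[cell_table$cell_type == cell_type]
  if (!length(cells)) {
    validation_error("no cells of type '", cell_type, "'")
  }
  cells
}

gene_column <- function(cell_table, gene, cells) {
  if (!gene %in% colnames(cell_table$values)) {
    validation_error("gene '", gene, "' not present in cell table")
  }
  as.numeric(cell_table$values[cells, gene])
}

#' Percent positivity of a gene within one cell type
#'
#' A cell is positive when its stored expression is strictly greater than
#' zero (equivalently TPM > 0). The percent is reported on the 0-100 scale;
#' `percent_reported` rounds to integer precision for display while the full
#' value is retained.
#'
#' @param cell_table A `CellTable`.
#' @param gene Gene id.
#' @param cell_type Cell-type label.
#' @return An object of class `positivity_result` with `cell_type`,
#'   `gene_id`, `n_cells`, `n_positive`, `percent_positive`,
#'   `percent_reported`, `mean_all`, `mean_positive` (NA when no cell is
#'   positive).
#' @export
percent_positive <- function(cell_table, gene, cell_type) {
  cells <- cells_of_type(cell_table, cell_type)
  v <- gene_column(cell_table, gene, cells)
  n <- length(v)
  n_pos <- sum(v > 0)
  structure(
    list(
      cell_type = cell_type,
      gene_id = gene,
      n_cells = n,
      n_positive = n_pos,
      percent_positive = 100 * n_pos / n,
      percent_reported = round(100 * n_pos / n),
      mean_all = mean(v),
      mean_positive = if (n_pos > 0) mean(v[v > 0]) else NA_real_
    ),
    class = "positivity_result"
  )
}

#' @export
print.positivity_result <- function(x, ...) {
  cat(sprintf(
    "%s in %s: %d%% positive (n = %d of %d); mean %.3f overall, %s among positives\n",
    x$gene_id, x$cell_type, x$percent_reported, x$n_positive, x$n_cells,
    x$mean_all,
    if (is.na(x$mean_positive)) "undefined" else sprintf("%.3f", x$mean_positive)
  ))
  invisible(x)
}

#' Mean expression of a gene within one cell type
#'
#' @inheritParams percent_positive
#' @param positives_only If TRUE, average over positive cells only.
#' @return The arithmetic mean (log2(TPM+1) scale).
#' @export
mean_expression <- function(cell_table, gene, cell_type, positives_only = FALSE) {
  cells <- cells_of_type(cell_table, cell_type)
  v <- gene_column(cell_table, gene, cells)
  if (positives_only) {
    v <- v[v > 0]
    if (!length(v)) {
      degenerate_input_error(
        "no positive cells for '", gene, "' in '", cell_type, "'"
      )
    }
  }
  mean(v)
}

#' Compare a gene's expression between two cell types
#'
#' Two-sided unpaired t-test between the cells (or positive cells) of two
#' types. The default is the Welch unequal-variance test; `var_equal = TRUE`
#' gives the classical pooled test.
#'
#' @inheritParams percent_positive
#' @param type_a,type_b Cell-type labels to compare.
#' @param positives_only Restrict both groups to positive cells.
#' @param var_equal Pooled-variance test instead of Welch.
#' @return The two-sided p-value.
#' @export
compare_cell_types <- function(cell_table, gene, type_a, type_b,
                               positives_only = FALSE, var_equal = FALSE) {
  va <- gene_column(cell_table, gene, cells_of_type(cell_table, type_a))
  vb <- gene_column(cell_table, gene, cells_of_type(cell_table, type_b))
  if (positives_only) {
    va <- va[va > 0]
    vb <- vb[vb > 0]
  }
  if (length(va) < 2 || length(vb) < 2) {
    insufficient_data_error(
      "need >= 2 cells per type; got ", length(va), " and ", length(vb)
    )
  }
  if (identical(va, vb)) return(1)
  stats::t.test(va, vb, var.equal = var_equal)$p.value
}

#' Per-patient positivity of a gene within one cell type
#'
#' @inheritParams percent_positive
#' @param min_cells Patients with fewer cells of the type than this are
#'   flagged (`low_cells = TRUE`), not removed. Default 10.
#' @return List with `table` (per-patient `patient_id`, `n_cells`,
#'   `n_positive`, `percent_positive`, `low_cells`) and `range`
#'   (`c(min, max)` percent over patients).
#' @export
per_patient_positivity <- function(cell_table, gene, cell_type, min_cells = 10) {
  cells <- cells_of_type(cell_table, cell_type)
  v <- gene_column(cell_table, gene, cells)
  pat <- cell_table$patient_id[cells]
  agg <- lapply(split(v, pat), function(x) {
    c(n = length(x), pos = sum(x > 0))
  })
  tab <- data.frame(
    patient_id = names(agg),
    n_cells = vapply(agg, `[[`, numeric(1), "n"),
    n_positive = vapply(agg, `[[`, numeric(1), "pos"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$percent_positive <- 100 * tab$n_positive / tab$n_cells
  tab$low_cells <- tab$n_cells < min_cells
  list(
    table = tab,
    range = c(min(tab$percent_positive), max(tab$percent_positive))
  )
}

#' Positivity summary across all cell types
#'
#' Runs [percent_positive()] for one gene over every cell type in the table.
#'
#' @inheritParams percent_positive
#' @return Data.frame with one row per cell type.
#' @export
positivity_table <- function(cell_table, gene) {
  types <- sort(unique(cell_table$cell_type))
  rows <- lapply(types, function(ct) {
    r <- percent_positive(cell_table, gene, ct)
    data.frame(
      cell_type = r$cell_type, gene_id = r$gene_id, n_cells = r$n_cells,
      n_positive = r$n_positive, percent_positive = r$percent_positive,
      mean_all = r$mean_all, mean_positive = r$mean_positive,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
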