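# Fixture builders used across test files. Everything is constructed in
# code; nothing is read from stored binary data.

# A CellTable with exact per-type positive counts for one or two genes.
# counts: named list, one entry per cell type:
#   list(n = total cells, positives = c(GENE = n_positive, ...),
#        value = expression given to positive cells (default 2))
make_count_cell_table <- function(counts, genes = NULL, n_patients = 3) {
  genes <- genes %||% unique(unlist(lapply(counts, function(s) names(s$positives))))
  total <- sum(vapply(counts, function(s) s$n, numeric(1)))
  values <- matrix(0, nrow = total, ncol = length(genes),
                   dimnames = list(sprintf("c%05d", seq_len(total)), genes))
  types <- character(0)
  offset <- 0L
  for (ct in names(counts)) {
    spec <- counts[[ct]]
    for (g in names(spec$positives)) {
      k <- spec$positives[[g]]
      if (k > 0) {
        values[offset + seq_len(k), g] <- spec$value %||% 2
      }
    }
    types <- c(types, rep(ct, spec$n))
    offset <- offset + spec$n
  }
  patients <- sprintf("PAT%d", (seq_len(total) - 1) %% n_patients + 1)
  cell_table(Matrix::Matrix(values, sparse = TRUE), types, patients)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-gene paired tumor/normal fixture with pairing annotations.
make_paired_fixture <- function(tumor, normal, gene = "SULF1") {
  n <- length(tumor)
  vals <- matrix(c(tumor, normal), nrow = 1,
                 dimnames = list(gene, c(sprintf("T%d", 1:n), sprintf("N%d", 1:n))))
  ann <- validate_annotations(data.frame(
    sample_id = colnames(vals),
    condition = rep(c("tumor", "normal"), each = n),
    pair_id = rep(sprintf("P%d", 1:n), 2)
  ))
  list(matrix = expression_matrix(vals, "log2_tpm_p1"), annotations = ann)
}

# Small random right-censored survival fixture (exponential times).
make_survival_fixture <- function(n, event_frac = 0.7) {
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n)),
    time = round(rexp(n, 1 / 500), 1) + 0.1,
    event = as.integer(runif(n) < event_frac),
    stringsAsFactors = FALSE
  )
}

# Write an expression TSV from a plain matrix of strings (verbatim cells).
write_raw_tsv <- function(header, rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}
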