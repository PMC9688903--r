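# Readers and writers for the tabular and sparse formats every stage shares.
# TSV throughout (UTF-8, header row); MatrixMarket for single-cell matrices;
# one-gene-per-line text for signatures. Missing values are blank cells or
# "NA" on read and blank cells on write.

# Shortest decimal representation that parses back to the same double.
# Pass at 15 significant digits first, escalate per-cell to 16 then 17.
format_numeric <- function(x) {
  out <- rep("", length(x))
  ok <- is.na(x)
  out[ok] <- ""
  for (digits in c(15L, 16L, 17L)) {
    todo <- which(!ok)
    if (!length(todo)) break
    cand <- sprintf(paste0("%.", digits, "g"), x[todo])
    good <- as.numeric(cand) == x[todo]
    out[todo[good]] <- cand[good]
    ok[todo[good]] <- TRUE
    if (digits == 17L) {
      out[todo[!good]] <- cand[!good]
      ok[todo[!good]] <- TRUE
    }
  }
  out
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) io_error("file not found: ", path)
  utils::read.delim(
    path,
    sep = "\t", header = TRUE, colClasses = "character",
    check.names = FALSE, na.strings = NULL, quote = "",
    comment.char = ""
  )
}

#' Read a genes-by-samples expression TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Blank cells and the literal `NA` become missing values; any other
#' non-numeric cell is a parse error reported with its row/column
#' coordinates. Duplicate gene or sample ids are rejected by name.
#'
#' @param path Path to the TSV file.
#' @param scale Declared value scale (see [expression_matrix()]).
#' @return An [expression_matrix()] object.
#' @export
read_expression_tsv <- function(path, scale) {
  raw <- read_tsv_raw(path)
  if (ncol(raw) < 2) parse_error("expression TSV needs a gene column plus >=1 sample: ", path)
  genes <- raw[[1]]
  samples <- names(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  miss <- cells == "" | cells == "NA"
  num <- suppressWarnings(as.numeric(cells))
  bad <- !miss & is.na(num)
  if (any(bad)) {
    idx <- which(bad)[1]
    r <- (idx - 1) %% nrow(cells) + 1
    c <- (idx - 1) %/% nrow(cells) + 1
    parse_error(
      "non-numeric cell '", cells[idx], "' at gene '", genes[r],
      "' (row ", r, "), sample '", samples[c], "' (column ", c, ")"
    )
  }
  values <- matrix(num, nrow = nrow(cells), dimnames = list(genes, samples))
  expression_matrix(values, scale)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: values are written with the shortest
#' decimal representation that round-trips exactly, missing entries as blank
#' cells, so `read(write(x))` reproduces `x` and repeated writes are
#' byte-identical.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param id_column Header label for the gene-id column.
#' @return The path, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_column = "gene_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x$values)), collapse = "\t"), con)
  body <- matrix(format_numeric(x$values), nrow = nrow(x$values))
  lines <- paste(rownames(x$values), apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample-annotation TSV
#'
#' Required columns `sample_id` and `condition`; optional `pair_id`, `stage`,
#' `age`, `gender`, `node_status`, `compartment`. All type invariants —
#' including that each `pair_id` marks exactly one tumor and one normal
#' sample — are enforced on read.
#'
#' @param path Path to the TSV file.
#' @return A validated annotation data.frame (see [validate_annotations()]).
#' @export
read_annotations_tsv <- function(path) {
  raw <- read_tsv_raw(path)
  raw[raw == "" | raw == "NA"] <- NA
  validate_annotations(raw)
}

#' Read a survival-endpoint TSV
#'
#' Columns `patient_id`, `time` (days, > 0), `event` (0/1) and optionally
#' `endpoint` (defaults to `"PFI"`).
#'
#' @inheritParams read_annotations_tsv
#' @param endpoint Endpoint label used when the column is absent.
#' @return A validated survival data.frame (see [validate_survival()]).
#' @export
read_survival_tsv <- function(path, endpoint = "PFI") {
  raw <- read_tsv_raw(path)
  raw[raw == "" | raw == "NA"] <- NA
  validate_survival(raw, endpoint = endpoint)
}

#' Read a sparse single-cell table (MatrixMarket + sidecars)
#'
#' `mtx_path` holds the cells-by-genes coordinate matrix; `cells_path` and
#' `genes_path` list the row and column ids (one per line, in matrix order);
#' `meta_path` is a TSV with columns `cell_id`, `cell_type`, `patient_id`.
#' Every matrix cell must appear in the metadata; negative entries and
#' dimension mismatches are rejected.
#'
#' @param mtx_path MatrixMarket coordinate file.
#' @param genes_path One gene id per line.
#' @param cells_path One cell id per line.
#' @param meta_path Per-cell metadata TSV.
#' @return A [cell_table()] object.
#' @export
read_cell_table <- function(mtx_path, genes_path, cells_path, meta_path) {
  for (p in c(mtx_path, genes_path, cells_path, meta_path)) {
    if (!file.exists(p)) io_error("file not found: ", p)
  }
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  genes <- genes[genes != ""]
  cells <- readLines(cells_path)
  cells <- cells[cells != ""]
  if (nrow(m) != length(cells)) {
    validation_error(
      "matrix has ", nrow(m), " rows but ", length(cells), " cell ids"
    )
  }
  if (ncol(m) != length(genes)) {
    validation_error(
      "matrix has ", ncol(m), " columns but ", length(genes), " gene ids"
    )
  }
  if (any(m@x < 0)) validation_error("negative entry in cell matrix")
  dimnames(m) <- list(cells, genes)
  meta <- read_tsv_raw(meta_path)
  for (col in c("cell_id", "cell_type", "patient_id")) {
    if (!col %in% names(meta)) validation_error("cell metadata missing column '", col, "'")
  }
  missing <- setdiff(cells, meta$cell_id)
  if (length(missing)) {
    validation_error("cell '", missing[1], "' absent from metadata")
  }
  idx <- match(cells, meta$cell_id)
  cell_table(m, meta$cell_type[idx], meta$patient_id[idx])
}

#' Write a cell table as MatrixMarket plus sidecar files
#'
#' @param x A `CellTable`.
#' @param dir Output directory (created if needed). Writes `matrix.mtx`,
#'   `genes.txt`, `cells.txt`, `meta.tsv`.
#' @return The directory, invisibly.
#' @export
write_cell_table <- function(x, dir) {
  stopifnot(inherits(x, "CellTable"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$values, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$values), file.path(dir, "genes.txt"))
  writeLines(rownames(x$values), file.path(dir, "cells.txt"))
  meta <- data.frame(
    cell_id = rownames(x$values),
    cell_type = unname(x$cell_type),
    patient_id = unname(x$patient_id),
    stringsAsFactors = FALSE
  )
  write_results_tsv(meta, file.path(dir, "meta.tsv"))
  invisible(dir)
}

#' Read a gene signature from plain text
#'
#' One gene id per line; blank lines ignored.
#'
#' @param path Path to the text file.
#' @param name Signature name; defaults to the file name without extension.
#' @return A [signature_set()] object.
#' @export
read_signature_txt <- function(path, name = NULL) {
  if (!file.exists(path)) io_error("file not found: ", path)
  genes <- readLines(path)
  genes <- trimws(genes)
  genes <- genes[genes != ""]
  signature_set(name %||% sub("\\.[^.]*$", "", basename(path)), genes)
}

#' Write a result table as a deterministic TSV
#'
#' Column order is preserved as given, numeric values are rendered at 6
#' significant digits with trailing zeros trimmed (0.0312500 becomes
#' `0.03125`), missing values as blank cells, and the file is
#' newline-terminated — so writing the same table twice is byte-identical.
#'
#' @param table A data.frame (any stage's result table).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results_tsv <- function(table, path) {
  stopifnot(is.data.frame(table))
  cols <- lapply(table, function(col) {
    if (is.numeric(col)) {
      out <- format_numeric(signif(col, 6))
    } else {
      out <- as.character(col)
      out[is.na(out)] <- ""
    }
    out
  })
  con <- tryCatch(
    file(path, open = "wt", encoding = "UTF-8"),
    error = function(e) io_error("cannot write to ", path, ": ", conditionMessage(e)),
    warning = function(w) io_error("cannot write to ", path)
  )
  on.exit(close(con))
  writeLines(paste(names(table), collapse = "\t"), con)
  if (nrow(table)) {
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
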