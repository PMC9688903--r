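# Canonical data containers consumed by every analysis stage.

EXPRESSION_SCALES <- c("tpm", "log2_tpm_p1", "log2_rsem_p1", "log2_ratio")

#' Construct an expression matrix with a declared value scale
#'
#' The central container for bulk expression/proteomic data: a dense
#' genes-by-samples numeric matrix together with the semantics of its values.
#' Supported scales are raw `tpm`, `log2_tpm_p1` (log2(TPM+1)),
#' `log2_rsem_p1` (log2(RSEM+1)) and `log2_ratio` (protein log2-ratio to an
#' internal control, as in isobaric-label proteomics).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique rownames (gene ids) and colnames (sample ids). `NA` entries are
#'   allowed and treated as missing downstream.
#' @param scale One of `"tpm"`, `"log2_tpm_p1"`, `"log2_rsem_p1"`,
#'   `"log2_ratio"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("SULF1", "SULF2"), paste0("S", 1:3)))
#' expression_matrix(m, "tpm")
expression_matrix <- function(values, scale) {
  scale <- match.arg(scale, EXPRESSION_SCALES)
  if (!is.matrix(values) || !is.numeric(values)) {
    validation_error("'values' must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    validation_error("'values' must carry gene rownames and sample colnames")
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    validation_error("duplicated gene id: ", dup_g[1])
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    validation_error("duplicated sample id: ", dup_s[1])
  }
  if (scale == "tpm" && any(values < 0, na.rm = TRUE)) {
    validation_error("tpm values must be non-negative")
  }
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [scale: %s, %d missing]\n",
    nrow(x$values), ncol(x$values), x$scale, sum(is.na(x$values))
  ))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

# Named per-sample vector for one gene; errors if the gene is absent.
expr_values <- function(x, gene) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!gene %in% rownames(x$values)) {
    validation_error("gene '", gene, "' not present in expression matrix")
  }
  x$values[gene, ]
}

#' Validate a sample-annotation table
#'
#' Annotations join to expression columns by `sample_id` (never by position).
#' Required columns: `sample_id`, `condition` (`tumor`/`normal`). Optional:
#' `pair_id` (each value must label exactly one tumor and one normal sample),
#' `stage` (I--IV), `age` (years), `gender`, `node_status`
#' (`positive`/`negative`), `compartment` (`tumor_region`/`stroma`). Missing
#' optional values are allowed throughout.
#'
#' @param df A data.frame.
#' @return The validated data.frame (invisibly classed as before; columns are
#'   normalized to character/numeric as appropriate).
#' @export
validate_annotations <- function(df) {
  if (!is.data.frame(df)) validation_error("annotations must be a data.frame")
  for (col in c("sample_id", "condition")) {
    if (!col %in% names(df)) validation_error("annotations missing required column '", col, "'")
  }
  df$sample_id <- as.character(df$sample_id)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) validation_error("duplicated sample id: ", dup[1])
  df$condition <- as.character(df$condition)
  bad <- setdiff(unique(df$condition), c("tumor", "normal"))
  if (length(bad)) validation_error("unknown condition label: ", bad[1])
  if (!"pair_id" %in% names(df)) df$pair_id <- NA_character_
  df$pair_id <- as.character(df$pair_id)
  df$pair_id[!is.na(df$pair_id) & df$pair_id == ""] <- NA_character_
  for (pid in unique(df$pair_id[!is.na(df$pair_id)])) {
    conds <- df$condition[!is.na(df$pair_id) & df$pair_id == pid]
    if (!(sum(conds == "tumor") == 1 && sum(conds == "normal") == 1)) {
      validation_error(
        "pair_id '", pid, "' must label exactly one tumor and one normal sample"
      )
    }
  }
  if ("stage" %in% names(df)) {
    df$stage <- as.character(df$stage)
    df$stage[!is.na(df$stage) & df$stage == ""] <- NA_character_
    bad <- setdiff(unique(df$stage[!is.na(df$stage)]), c("I", "II", "III", "IV"))
    if (length(bad)) validation_error("unknown stage label: ", bad[1])
  } else {
    df$stage <- NA_character_
  }
  if ("age" %in% names(df)) {
    df$age <- suppressWarnings(as.numeric(df$age))
  } else {
    df$age <- NA_real_
  }
  if (!"gender" %in% names(df)) df$gender <- NA_character_
  df$gender <- as.character(df$gender)
  df$gender[!is.na(df$gender) & df$gender == ""] <- NA_character_
  if ("node_status" %in% names(df)) {
    df$node_status <- as.character(df$node_status)
    df$node_status[!is.na(df$node_status) & df$node_status == ""] <- NA_character_
    bad <- setdiff(unique(df$node_status[!is.na(df$node_status)]), c("positive", "negative"))
    if (length(bad)) validation_error("unknown node_status label: ", bad[1])
  } else {
    df$node_status <- NA_character_
  }
  if ("compartment" %in% names(df)) {
    df$compartment <- as.character(df$compartment)
    df$compartment[!is.na(df$compartment) & df$compartment == ""] <- NA_character_
    bad <- setdiff(unique(df$compartment[!is.na(df$compartment)]), c("tumor_region", "stroma"))
    if (length(bad)) validation_error("unknown compartment label: ", bad[1])
  } else {
    df$compartment <- NA_character_
  }
  df
}

#' Validate survival records
#'
#' One row per patient with a time-to-event endpoint (e.g., TCGA
#' progression-free interval). Times are in days and must be strictly
#' positive; the event indicator must be 0/1 or logical.
#'
#' @param df A data.frame with columns `patient_id`, `time`, `event` and
#'   optionally `endpoint`.
#' @param endpoint Default endpoint label used when the column is absent.
#' @return Validated data.frame with `event` as integer 0/1.
#' @export
validate_survival <- function(df, endpoint = "PFI") {
  if (!is.data.frame(df)) validation_error("survival records must be a data.frame")
  for (col in c("patient_id", "time", "event")) {
    if (!col %in% names(df)) validation_error("survival records missing column '", col, "'")
  }
  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup)) validation_error("duplicated patient id: ", dup[1])
  df$time <- as.numeric(df$time)
  if (any(is.na(df$time)) || any(df$time <= 0)) {
    bad <- df$patient_id[is.na(df$time) | df$time <= 0][1]
    validation_error("non-positive or missing time for patient ", bad)
  }
  ev <- df$event
  if (is.logical(ev)) ev <- as.integer(ev)
  ev <- as.numeric(ev)
  if (any(is.na(ev)) || !all(ev %in% c(0, 1))) {
    validation_error("event indicator must be 0/1")
  }
  df$event <- as.integer(ev)
  if (!"endpoint" %in% names(df)) df$endpoint <- endpoint
  df$endpoint <- as.character(df$endpoint)
  df
}

#' Construct a sparse single-cell expression table
#'
#' Cells-by-genes sparse matrix of log2(TPM+1) values with one cell-type
#' label and one patient label per cell. Stored values must be non-negative;
#' zero entries mean "not detected" and define positivity downstream.
#'
#' @param values A sparse (or dense) cells x genes matrix with unique
#'   rownames (cell ids) and colnames (gene ids); coerced to `dgCMatrix`.
#' @param cell_type Character vector of per-cell type labels, in row order or
#'   named by cell id.
#' @param patient_id Character vector of per-cell patient labels, same rules.
#' @return An object of class `CellTable`.
#' @export
cell_table <- function(values, cell_type, patient_id) {
  values <- methods::as(methods::as(methods::as(values, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  cids <- rownames(values)
  gids <- colnames(values)
  if (is.null(cids) || is.null(gids)) {
    validation_error("cell table needs cell rownames and gene colnames")
  }
  if (anyDuplicated(cids)) validation_error("duplicated cell id: ", cids[duplicated(cids)][1])
  if (anyDuplicated(gids)) validation_error("duplicated gene id: ", gids[duplicated(gids)][1])
  if (any(values@x < 0)) validation_error("cell expression values must be non-negative")
  align <- function(v, what) {
    v <- as.character(v)
    if (!is.null(names(v))) {
      missing <- setdiff(cids, names(v))
      if (length(missing)) validation_error("no ", what, " for cell ", missing[1])
      v <- v[cids]
    } else if (length(v) != length(cids)) {
      validation_error(what, " must have one entry per cell")
    }
    if (any(is.na(v))) validation_error("missing ", what, " for cell ", cids[is.na(v)][1])
    names(v) <- cids
    v
  }
  structure(
    list(
      values = values,
      cell_type = align(cell_type, "cell_type"),
      patient_id = align(patient_id, "patient_id")
    ),
    class = "CellTable"
  )
}

#' @export
print.CellTable <- function(x, ...) {
  cat(sprintf(
    "CellTable: %d cells x %d genes, %d stored values; %d cell types, %d patients\n",
    nrow(x$values), ncol(x$values), length(x$values@x),
    length(unique(x$cell_type)), length(unique(x$patient_id))
  ))
  invisible(x)
}

#' Construct a named gene-signature set
#'
#' @param name Signature name (e.g., `"CAF1"`).
#' @param gene_ids Non-empty character vector of unique gene identifiers.
#' @return An object of class `SignatureSet`.
#' @export
signature_set <- function(name, gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (!length(gene_ids)) validation_error("signature '", name, "' is empty")
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) validation_error("duplicated signature gene: ", dup[1])
  structure(list(name = name, gene_ids = gene_ids), class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}
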