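# Seedable generators reproducing the statistical structure each analysis
# stage assumes: paired log-normal expression with planted fold-changes,
# proportional-hazards survival with a threshold effect, zero-inflated
# per-cell-type single-cell expression, a latent-factor signature universe,
# and patient/PDX pairs losing their stromal component. Every generator is a
# pure function of its parameters and seed.

#' Generate a paired tumor/normal expression cohort
#'
#' Normal-tissue values are Normal(baseline, sigma) on the log2 scale; the
#' matched tumor value adds the planted log2 fold-change plus independent
#' Normal(0, sigma) noise. Emits the expression matrix together with pairing
#' annotations.
#'
#' @param n_pairs Number of tumor/normal pairs (>= 3).
#' @param lfc_by_gene Named numeric vector of planted log2 fold-changes (one
#'   entry per gene).
#' @param sigma Per-measurement noise SD on the log2 scale (>= 0).
#' @param baseline Mean normal-tissue expression (log2 scale).
#' @param seed Integer seed.
#' @return List with `matrix` (`ExpressionMatrix`, scale `log2_rsem_p1`) and
#'   `annotations` (validated annotation data.frame with `pair_id`s).
#' @export
gen_paired_cohort <- function(n_pairs, lfc_by_gene, sigma = 1, baseline = 6, seed = 1) {
  if (n_pairs < 3) validation_error("n_pairs must be >= 3")
  if (sigma < 0) validation_error("sigma must be >= 0")
  if (is.null(names(lfc_by_gene))) {
    names(lfc_by_gene) <- sprintf("GENE%03d", seq_along(lfc_by_gene))
  }
  with_seed(seed, {
    genes <- names(lfc_by_gene)
    tumor_ids <- sprintf("P%03d_T", seq_len(n_pairs))
    normal_ids <- sprintf("P%03d_N", seq_len(n_pairs))
    normal <- matrix(
      stats::rnorm(length(genes) * n_pairs, baseline, sigma),
      nrow = length(genes), dimnames = list(genes, normal_ids)
    )
    tumor <- normal + lfc_by_gene +
      matrix(stats::rnorm(length(genes) * n_pairs, 0, sigma), nrow = length(genes))
    colnames(tumor) <- tumor_ids
    ann <- data.frame(
      sample_id = c(tumor_ids, normal_ids),
      condition = rep(c("tumor", "normal"), each = n_pairs),
      pair_id = rep(sprintf("P%03d", seq_len(n_pairs)), 2),
      stringsAsFactors = FALSE
    )
    list(
      matrix = expression_matrix(cbind(tumor, normal), "log2_rsem_p1"),
      annotations = validate_annotations(ann)
    )
  })
}

#' Generate a survival cohort with a planted biomarker threshold effect
#'
#' Expression is log-normal; the hazard is
#' `baseline_rate * exp(beta * [x > cutoff] + beta_age * age_std)` with the
#' cutoff at the given expression quantile. Event times are exponential given
#' the hazard, censoring is independent exponential at `censor_rate`, and the
#' observed time is the minimum of the two.
#'
#' @param n Number of patients.
#' @param beta Planted log hazard ratio of the high-expression group.
#' @param cutoff_quantile Expression quantile defining the true threshold
#'   (default 0.5, the median).
#' @param baseline_rate Baseline hazard in events/day (default 1e-3).
#' @param censor_rate Censoring hazard in 1/day (default 5e-4).
#' @param beta_age Log hazard ratio per SD of age (default 0.2).
#' @param seed Integer seed.
#' @return List with `expression` (named vector), `records` (validated
#'   survival data.frame), `covariates` (data.frame `age`, `gender`),
#'   `cutoff` (the planted threshold value).
#' @export
gen_survival_cohort <- function(n, beta, cutoff_quantile = 0.5,
                                baseline_rate = 1e-3, censor_rate = 5e-4,
                                beta_age = 0.2, seed = 1) {
  if (baseline_rate <= 0 || censor_rate <= 0) validation_error("rates must be > 0")
  if (cutoff_quantile <= 0 || cutoff_quantile >= 1) {
    validation_error("cutoff_quantile must lie in (0, 1)")
  }
  with_seed(seed, {
    ids <- sprintf("PT%04d", seq_len(n))
    x <- stats::rlnorm(n, meanlog = 2, sdlog = 1)
    names(x) <- ids
    age <- stats::rnorm(n, 60, 10)
    gender <- stats::rbinom(n, 1, 0.5)
    cutoff <- stats::quantile(x, cutoff_quantile, names = FALSE)
    high <- as.numeric(x > cutoff)
    hazard <- baseline_rate * exp(beta * high + beta_age * (age - 60) / 10)
    t_event <- stats::rexp(n, hazard)
    t_censor <- stats::rexp(n, censor_rate)
    records <- data.frame(
      patient_id = ids,
      time = pmax(pmin(t_event, t_censor), 1e-6),
      event = as.integer(t_event <= t_censor),
      endpoint = "PFI",
      stringsAsFactors = FALSE
    )
    list(
      expression = x,
      records = validate_survival(records),
      covariates = data.frame(age = age, gender = gender),
      cutoff = cutoff
    )
  })
}

#' Default per-cell-type simulation parameters
#'
#' Positivity fractions and positive-cell means for the genes `SULF1` and
#' `SULF2` across four cell types, mirroring the attribution pattern of an
#' HNSC tumor microenvironment: SULF1 concentrated in fibroblasts, SULF2 in
#' tumor epithelial cells, both low in lymphoid cells.
#'
#' @return Named list of per-type specs usable by [gen_cell_population()].
#' @export
default_cell_spec <- function() {
  list(
    tumor = list(
      n = 2215,
      pos_frac = c(SULF1 = 0.14, SULF2 = 0.63),
      mu = c(SULF1 = 1.232, SULF2 = 1.812),
      sigma = c(SULF1 = 0.8, SULF2 = 0.9)
    ),
    fibroblast = list(
      n = 1440,
      pos_frac = c(SULF1 = 0.48, SULF2 = 0.21),
      mu = c(SULF1 = 2.291, SULF2 = 1.826),
      sigma = c(SULF1 = 1.0, SULF2 = 0.9)
    ),
    t_cell = list(
      n = 1237,
      pos_frac = c(SULF1 = 0.03, SULF2 = 0.10),
      mu = c(SULF1 = 0.8, SULF2 = 1.0),
      sigma = c(SULF1 = 0.5, SULF2 = 0.6)
    ),
    macrophage = list(
      n = 686,
      pos_frac = c(SULF1 = 0.10, SULF2 = 0.25),
      mu = c(SULF1 = 1.0, SULF2 = 1.2),
      sigma = c(SULF1 = 0.6, SULF2 = 0.7)
    )
  )
}

# Normal(mu, sigma) truncated to (0, Inf) via inverse-CDF sampling.
rtruncnorm_pos <- function(n, mu, sigma) {
  lo <- stats::pnorm(0, mu, sigma)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mu, sigma)
}

#' Generate a zero-inflated single-cell population
#'
#' Each cell of a type is positive for a gene with the type's `pos_frac`;
#' positive values follow Normal(mu, sigma) truncated above zero on the
#' log2(TPM+1) scale (so the realized positive-cell mean slightly exceeds
#' `mu` when `mu/sigma` is small); non-positive cells store exact zeros.
#' Cells are assigned round-robin to patients.
#'
#' @param types Named list of per-type specs: each a list with `n` and
#'   per-gene vectors (or scalars) `pos_frac`, `mu`, `sigma`. See
#'   [default_cell_spec()].
#' @param genes Gene ids; default taken from the first type's `pos_frac`
#'   names.
#' @param n_patients Number of patients receiving cells (default 18).
#' @param seed Integer seed.
#' @return A [cell_table()] object.
#' @export
gen_cell_population <- function(types = default_cell_spec(), genes = NULL,
                                n_patients = 18, seed = 1) {
  genes <- genes %||% names(types[[1]]$pos_frac) %||% "GENE"
  per_gene <- function(spec, field, g) {
    v <- spec[[field]]
    if (length(v) == 1 && is.null(names(v))) return(unname(v))
    if (!g %in% names(v)) validation_error("no ", field, " for gene ", g)
    unname(v[g])
  }
  with_seed(seed, {
    blocks <- list()
    meta_type <- character(0)
    for (ct in names(types)) {
      spec <- types[[ct]]
      n <- spec$n
      block <- matrix(0, nrow = n, ncol = length(genes),
                      dimnames = list(NULL, genes))
      for (g in genes) {
        pf <- per_gene(spec, "pos_frac", g)
        if (pf < 0 || pf > 1) validation_error("pos_frac must lie in [0, 1]")
        pos <- stats::runif(n) < pf
        block[pos, g] <- rtruncnorm_pos(sum(pos), per_gene(spec, "mu", g),
                                        per_gene(spec, "sigma", g))
      }
      blocks[[ct]] <- block
      meta_type <- c(meta_type, rep(ct, n))
    }
    values <- do.call(rbind, blocks)
    n_cells <- nrow(values)
    rownames(values) <- sprintf("cell%05d", seq_len(n_cells))
    patients <- sprintf("HN%02d", (seq_len(n_cells) - 1) %% n_patients + 1)
    cell_table(Matrix::Matrix(values, sparse = TRUE), meta_type, patients)
  })
}

#' Generate a latent-factor signature universe
#'
#' One latent factor F per sample; the target gene and every signature gene
#' load on F with the given loading (value `loading * F + sqrt(1 - loading^2)
#' * noise`, so the expected pairwise target-signature correlation is
#' `loading^2`); all other genes are independent noise. Rows are
#' standardized.
#'
#' @param n_samples Number of samples (default 110).
#' @param n_sig Signature size (default 206).
#' @param n_other Non-signature, non-target genes (default 9867, making a
#'   10,073-gene universe around the target).
#' @param loading Factor loading in `[0, 1)`; 0 plants no enrichment.
#' @param seed Integer seed.
#' @return List with `matrix` (`ExpressionMatrix`, scale `log2_ratio`),
#'   `signature` (`SignatureSet`) and `target_id`.
#' @export
gen_signature_universe <- function(n_samples = 110, n_sig = 206, n_other = 9867,
                                   loading = 0.6, seed = 1) {
  if (loading < 0 || loading >= 1) validation_error("loading must lie in [0, 1)")
  with_seed(seed, {
    f <- stats::rnorm(n_samples)
    resid <- sqrt(1 - loading^2)
    sig_genes <- sprintf("SIG%04d", seq_len(n_sig))
    other_genes <- sprintf("BG%05d", seq_len(n_other))
    target <- loading * f + resid * stats::rnorm(n_samples)
    sig <- matrix(
      loading * rep(f, each = n_sig) +
        resid * stats::rnorm(n_sig * n_samples),
      nrow = n_sig, dimnames = list(sig_genes, NULL)
    )
    other <- matrix(
      stats::rnorm(n_other * n_samples),
      nrow = n_other, dimnames = list(other_genes, NULL)
    )
    values <- rbind(matrix(target, nrow = 1, dimnames = list("TARGET", NULL)), sig, other)
    values <- t(scale(t(values)))
    colnames(values) <- sprintf("S%03d", seq_len(n_samples))
    list(
      matrix = expression_matrix(values, "log2_ratio"),
      signature = signature_set("signature", sig_genes),
      target_id = "TARGET"
    )
  })
}

#' Generate paired patient/PDX TPM values
#'
#' Each patient's tumor expression is the sum of a tumor-cell component and a
#' stromal component; the xenograft retains only the tumor-cell component
#' times a log-normal growth factor (human stroma is lost on engraftment).
#' With `stromal_gene = TRUE` roughly 95% of the patient signal sits in the
#' stromal component (so the PDX value collapses); with `FALSE` the signal is
#' tumor-intrinsic and the xenograft amplifies it about two-fold.
#'
#' @param n Number of patient/PDX pairs (>= 5).
#' @param stromal_gene Logical: is the simulated gene supplied by stroma?
#' @param seed Integer seed.
#' @return List with `patient` and `pdx` (named TPM vectors).
#' @export
gen_pdx_pairs <- function(n = 42, stromal_gene = TRUE, seed = 1) {
  if (n < 5) validation_error("n must be >= 5")
  with_seed(seed, {
    ids <- sprintf("PDX%02d", seq_len(n))
    if (stromal_gene) {
      tumor_comp <- stats::rlnorm(n, log(2), 0.8)
      stroma_comp <- stats::rlnorm(n, log(50), 0.6)
      growth <- stats::rlnorm(n, 0, 0.4)
    } else {
      tumor_comp <- stats::rlnorm(n, log(50), 0.6)
      stroma_comp <- stats::rlnorm(n, log(2.5), 0.6)
      growth <- stats::rlnorm(n, log(2), 0.5)
    }
    patient <- tumor_comp + stroma_comp
    pdx <- tumor_comp * growth
    names(patient) <- ids
    names(pdx) <- ids
    list(patient = patient, pdx = pdx)
  })
}
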