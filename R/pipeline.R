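# Orchestrates the full study workflow from one configuration: simulate (or
# load) inputs, run differential expression, survival, signature enrichment,
# cell attribution and the PDX comparison, and write per-stage TSVs plus a
# consolidated summary. Every exclusion (skipped gene, dropped stratum) is
# logged; the run is a pure function of the config and root seed.

#' Default pipeline configuration
#'
#' All stages enabled on synthetic inputs, with the study's canonical
#' thresholds: |log2FC| > 1 and FDR < 0.05 for significance calling, >= 25%
#' of patients in each survival arm, r > 0.55 for the strong-correlation
#' count, and 10,000 permutations for the signature test (reduce `perms` for
#' quick runs).
#'
#' @param seed Root seed; each stage derives its own substream.
#' @param outdir Output directory.
#' @return A config list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 42, outdir = "sulfscan_run") {
  list(
    seed = seed,
    outdir = outdir,
    thresholds = list(
      lfc = 1, fdr = 0.05, min_frac = 0.25, r_threshold = 0.55, perms = 10000
    ),
    stages = list(
      de = list(
        enabled = TRUE, n_pairs = 50,
        lfc_by_gene = c(SULF1 = 2.5, SULF2 = 1.3, CTRL1 = 0, CTRL2 = 0),
        sigma = 1
      ),
      survival = list(
        enabled = TRUE, n = 400, beta = log(2), cutoff_quantile = 0.5
      ),
      signature = list(
        enabled = TRUE, n_samples = 110, n_sig = 100, n_other = 900,
        loading = 0.6
      ),
      cells = list(enabled = TRUE),
      pdx = list(enabled = TRUE, n = 42)
    )
  )
}

#' Run the full analysis pipeline
#'
#' @param config A config list (see [default_pipeline_config()]) or the path
#'   to a JSON file holding one.
#' @return The output directory, invisibly. Writes per-stage TSVs
#'   (`de.tsv`, `survival.tsv`, `signature.tsv`, `cells.tsv`, `pdx.tsv`), a
#'   `run.log`, and a `summary.tsv` of headline statistics with a stable
#'   schema (`stage`, `statistic`, `value`).
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (!is.null(config$stages$de$lfc_by_gene)) {
      config$stages$de$lfc_by_gene <- unlist(config$stages$de$lfc_by_gene)
    }
  }
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logf <- function(...) writeLines(paste0(...), log_con)
  logf("sulfscan pipeline, package version ", as.character(utils::packageVersion("sulfscan")))
  logf("root seed: ", config$seed)

  th <- config$thresholds
  summary_rows <- list()
  add_summary <- function(stage, statistic, value) {
    summary_rows[[length(summary_rows) + 1]] <<- data.frame(
      stage = stage, statistic = statistic, value = value,
      stringsAsFactors = FALSE
    )
  }
  run_stage <- function(name, body) {
    tryCatch(body(), error = function(e) {
      logf("stage ", name, " FAILED: ", conditionMessage(e))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  st <- config$stages

  if (isTRUE(st$de$enabled)) {
    run_stage("de", function() {
      cfg <- st$de
      cohort <- gen_paired_cohort(
        cfg$n_pairs, cfg$lfc_by_gene, sigma = cfg$sigma,
        seed = substream_seed(config$seed, "de")
      )
      de <- withCallingHandlers(
        de_table(cohort$matrix, cohort$annotations,
          lfc_threshold = th$lfc, fdr_threshold = th$fdr
        ),
        warning = function(w) {
          logf("de: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        }
      )
      write_results_tsv(de, file.path(outdir, "de.tsv"))
      logf("de: ", nrow(de), " genes tested, ", sum(de$significant), " significant")
      add_summary("de", "n_genes_tested", nrow(de))
      add_summary("de", "n_significant", sum(de$significant))
      for (i in which(de$significant)) {
        add_summary("de", paste0("log2fc_", de$gene_id[i]), de$log2fc[i])
      }
    })
  }

  if (isTRUE(st$survival$enabled)) {
    run_stage("survival", function() {
      cfg <- st$survival
      coh <- gen_survival_cohort(
        cfg$n, cfg$beta, cutoff_quantile = cfg$cutoff_quantile,
        seed = substream_seed(config$seed, "survival")
      )
      cp <- minp_cutpoint(coh$expression, coh$records, min_frac = th$min_frac)
      cov <- cbind(
        data.frame(high = as.numeric(coh$expression > cp$cutoff)),
        coh$covariates
      )
      cox <- cox_fit(coh$records, cov)
      hr <- cox$coefficients$hazard_ratio[cox$coefficients$term == "high"]
      surv_tab <- data.frame(
        statistic = c("cutoff", "logrank_p", "n_high", "n_low", "hr_high", "cox_p_high"),
        value = c(
          cp$cutoff, cp$p_value, cp$n_high, cp$n_low, hr,
          cox$coefficients$p_value[cox$coefficients$term == "high"]
        ),
        stringsAsFactors = FALSE
      )
      write_results_tsv(surv_tab, file.path(outdir, "survival.tsv"))
      logf(
        "survival: cutoff ", signif(cp$cutoff, 4), ", log-rank p ",
        signif(cp$p_value, 3), ", HR(high) ", signif(hr, 4)
      )
      add_summary("survival", "logrank_p", cp$p_value)
      add_summary("survival", "hr_high", hr)
    })
  }

  if (isTRUE(st$signature$enabled)) {
    run_stage("signature", function() {
      cfg <- st$signature
      uni <- gen_signature_universe(
        cfg$n_samples, cfg$n_sig, cfg$n_other, cfg$loading,
        seed = substream_seed(config$seed, "signature")
      )
      cors <- correlate_target(uni$matrix, uni$target_id)
      perm <- permutation_enrichment(
        cors, uni$signature,
        b = th$perms, seed = substream_seed(config$seed, "signature_perm")
      )
      counts <- threshold_count(cors, th$r_threshold, uni$signature)
      sig_tab <- data.frame(
        statistic = c(
          "observed_mean_r", "perm_p", "n_above_threshold",
          "n_above_in_signature"
        ),
        value = c(
          perm$observed_mean_r, perm$p_value, counts$n_above,
          counts$n_above_in_signature
        ),
        stringsAsFactors = FALSE
      )
      write_results_tsv(sig_tab, file.path(outdir, "signature.tsv"))
      logf(
        "signature: mean r ", signif(perm$observed_mean_r, 4),
        ", permutation p ", signif(perm$p_value, 3)
      )
      add_summary("signature", "observed_mean_r", perm$observed_mean_r)
      add_summary("signature", "perm_p", perm$p_value)
    })
  }

  if (isTRUE(st$cells$enabled)) {
    run_stage("cells", function() {
      ct <- gen_cell_population(seed = substream_seed(config$seed, "cells"))
      tabs <- lapply(c("SULF1", "SULF2"), function(g) positivity_table(ct, g))
      cells_tab <- do.call(rbind, tabs)
      write_results_tsv(cells_tab, file.path(outdir, "cells.tsv"))
      for (g in c("SULF1", "SULF2")) {
        for (type in c("tumor", "fibroblast")) {
          r <- percent_positive(ct, g, type)
          logf(
            "cells: ", g, " in ", type, ": ", r$percent_reported,
            "% positive (", r$n_positive, "/", r$n_cells, ")"
          )
          add_summary("cells", paste0(g, "_", type, "_pct_positive"), r$percent_positive)
        }
      }
    })
  }

  if (isTRUE(st$pdx$enabled)) {
    run_stage("pdx", function() {
      cfg <- st$pdx
      seeds <- substream_seed(config$seed, "pdx")
      stromal <- gen_pdx_pairs(cfg$n, stromal_gene = TRUE, seed = seeds)
      intrinsic <- gen_pdx_pairs(cfg$n, stromal_gene = FALSE, seed = seeds + 1L)
      res_s <- pdx_paired_test(stromal$patient, stromal$pdx, gene = "stromal")
      res_i <- pdx_paired_test(intrinsic$patient, intrinsic$pdx, gene = "tumor_intrinsic")
      pdx_tab <- data.frame(
        gene_id = c(res_s$gene_id, res_i$gene_id),
        n_pairs = c(res_s$n_pairs, res_i$n_pairs),
        median_patient = c(res_s$median_patient, res_i$median_patient),
        median_pdx = c(res_s$median_pdx, res_i$median_pdx),
        p_value = c(res_s$p_value, res_i$p_value),
        n_decreased = c(res_s$n_decreased, res_i$n_decreased),
        n_increased = c(res_s$n_increased, res_i$n_increased),
        stringsAsFactors = FALSE
      )
      write_results_tsv(pdx_tab, file.path(outdir, "pdx.tsv"))
      logf(
        "pdx: stromal gene decreased in ", res_s$n_decreased, "/", res_s$n_pairs,
        "; tumor-intrinsic increased in ", res_i$n_increased, "/", res_i$n_pairs
      )
      add_summary("pdx", "stromal_n_decreased", res_s$n_decreased)
      add_summary("pdx", "intrinsic_n_increased", res_i$n_increased)
    })
  }

  summary_tab <- if (length(summary_rows)) {
    do.call(rbind, summary_rows)
  } else {
    data.frame(
      stage = character(0), statistic = character(0), value = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  write_results_tsv(summary_tab, file.path(outdir, "summary.tsv"))
  logf("pipeline complete")
  invisible(outdir)
}
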