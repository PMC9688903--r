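test_that("paired_de recovers effect size and degenerate cases", {
  fx <- make_paired_fixture(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  res <- paired_de(fx$matrix, fx$annotations, "SULF1")
  expect_equal(res$log2fc, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_used, 6L)

  base <- c(2.1, 3.7, 1.4, 5.2, 4.8, 2.9)
  fx <- make_paired_fixture(base + 1, base)
  res <- paired_de(fx$matrix, fx$annotations, "SULF1")
  expect_equal(res$log2fc, 1)
  expect_equal(res$p_value, 0.03125) # frozen from the 2^6 enumeration oracle

  # fewer than 3 complete pairs
  fx <- make_paired_fixture(c(1, 2), c(3, 4))
  expect_error(paired_de(fx$matrix, fx$annotations, "SULF1"),
               class = "sulfscan_insufficient_data")

  # zero-variance differences under the paired t-test
  fx <- make_paired_fixture(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_error(paired_de(fx$matrix, fx$annotations, "SULF1", test = "paired_t"),
               class = "sulfscan_degenerate_input")

  # raw tpm must be transformed first
  fx$matrix$scale <- "tpm"
  expect_error(paired_de(fx$matrix, fx$annotations, "SULF1"),
               "log2_transform", class = "sulfscan_validation_error")
})

test_that("unpaired_de matches the exact rank-sum distribution", {
  mk <- function(v, ids) {
    expression_matrix(
      matrix(v, 1, dimnames = list("SULF1", ids)), "log2_tpm_p1"
    )
  }
  a <- mk(c(1, 2, 3), c("a1", "a2", "a3"))
  b <- mk(c(4, 5, 6), c("b1", "b2", "b3"))
  res <- unpaired_de(a, b, "SULF1")
  expect_equal(res$log2fc, -3)
  expect_equal(res$p_value, 0.1) # 2/20 of the C(6,3) rank assignments

  same <- unpaired_de(a, mk(c(3, 1, 2), c("c1", "c2", "c3")), "SULF1")
  expect_equal(same$log2fc, 0)
  expect_equal(same$p_value, 1)

  expect_error(unpaired_de(a, mk(c(1, 2), c("d1", "d2")), "SULF1"),
               class = "sulfscan_insufficient_data")
})

test_that("stage ANOVA is the classical one-way F-test", {
  mk_stage <- function(values, stages) {
    ids <- sprintf("S%02d", seq_along(values))
    list(
      matrix = expression_matrix(
        matrix(values, 1, dimnames = list("SULF2", ids)), "log2_tpm_p1"
      ),
      annotations = validate_annotations(
        data.frame(sample_id = ids, condition = "tumor", stage = stages)
      )
    )
  }
  # equal group means with spread: F = 0, p = 1
  fx <- mk_stage(c(1, 3, 0, 4, -1, 5), rep(c("I", "II", "III"), each = 2))
  expect_equal(stage_anova(fx$matrix, fx$annotations, "SULF2"), 1)

  # two groups: F equals the square of the pooled t statistic
  set.seed(11)
  v <- rnorm(8)
  fx <- mk_stage(v, rep(c("I", "II"), each = 4))
  p_anova <- stage_anova(fx$matrix, fx$annotations, "SULF2")
  tt <- t.test(v[1:4], v[5:8], var.equal = TRUE)
  expect_equal(p_anova, tt$p.value, tolerance = 1e-12)

  # undersized group dropped with warning; below 2 groups errors
  fx <- mk_stage(c(1, 2, 3, 4, 9), c("I", "I", "II", "II", "III"))
  expect_warning(stage_anova(fx$matrix, fx$annotations, "SULF2"), "III")
  fx <- mk_stage(c(1, 2, 9), c("I", "I", "III"))
  expect_warning(
    expect_error(stage_anova(fx$matrix, fx$annotations, "SULF2"),
                 class = "sulfscan_insufficient_data")
  )
})

test_that("stage ANOVA detects a planted trend across stages", {
  set.seed(21)
  means <- c(I = 0, II = 1, III = 2, IV = 3)
  stages <- rep(names(means), each = 10)
  v <- rnorm(40, means[stages], 0.5)
  ids <- sprintf("S%02d", 1:40)
  m <- expression_matrix(matrix(v, 1, dimnames = list("SULF1", ids)), "log2_tpm_p1")
  ann <- validate_annotations(data.frame(sample_id = ids, condition = "tumor", stage = stages))
  expect_lt(stage_anova(m, ann, "SULF1"), 0.001)
})

test_that("BH adjustment matches the hand step-up and is equivariant", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "sulfscan_validation_error")

  set.seed(31)
  p <- runif(7)
  perm <- sample(7)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_equal(bh_fdr(p), oracle_bh(p))
  # adjusted value never below its own p
  expect_true(all(bh_fdr(p) >= p))
})

test_that("significance calling uses strict fold-change and FDR thresholds", {
  de <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    log2fc = c(2.78, -0.77, 1.0),
    fdr = c(5.73e-12, 9.36e-2, 0.001)
  )
  out <- call_significant(de)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("log2 transform maps tpm values and updates the scale", {
  m <- expression_matrix(
    matrix(c(0, 1, 3, 1023), 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
    "tpm"
  )
  out <- log2_transform(m)
  expect_equal(out$values[, "s1"], c(a = 0, b = 1))
  expect_equal(out$values["b", "s2"], 10)
  expect_identical(out$scale, "log2_tpm_p1")
  expect_error(log2_transform(out), class = "sulfscan_validation_error")
})

test_that("planted fold-changes are recovered across a gene panel", {
  set.seed(41)
  lfc <- c(SULF1 = 2.5, SULF2 = 1.2,
           setNames(rnorm(28, 0, 1.5), sprintf("G%02d", 1:28)))
  coh <- gen_paired_cohort(50, lfc, sigma = 1, seed = 99)
  de <- de_table(coh$matrix, coh$annotations)
  est <- de$log2fc[match(names(lfc), de$gene_id)]
  expect_gt(cor(est, unname(lfc)), 0.95)
  expect_true(de$significant[de$gene_id == "SULF1"])
})
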