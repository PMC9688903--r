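simple_cells <- function(values, type = "tumor", gene = "SULF1",
                         patients = NULL) {
  n <- length(values)
  m <- Matrix::Matrix(matrix(values, ncol = 1,
                             dimnames = list(sprintf("c%03d", 1:n), gene)),
                      sparse = TRUE)
  cell_table(m, rep(type, n), patients %||% rep("pat1", n))
}

test_that("positivity and means follow direct arithmetic", {
  ct <- simple_cells(c(0, 0, 2, 4))
  res <- percent_positive(ct, "SULF1", "tumor")
  expect_equal(res$n_positive, 2)
  expect_equal(res$percent_positive, 50)
  expect_equal(res$mean_all, 1.5)
  expect_equal(res$mean_positive, 3)
  expect_equal(mean_expression(ct, "SULF1", "tumor"), 1.5)
  expect_equal(mean_expression(ct, "SULF1", "tumor", positives_only = TRUE), 3)

  # all-zero gene: 0% positive, undefined positive mean
  ct0 <- simple_cells(c(0, 0, 0))
  res0 <- percent_positive(ct0, "SULF1", "tumor")
  expect_equal(res0$percent_positive, 0)
  expect_true(is.na(res0$mean_positive))
  expect_error(mean_expression(ct0, "SULF1", "tumor", positives_only = TRUE),
               class = "sulfscan_degenerate_input")

  # constant expression: both means equal the constant
  ctc <- simple_cells(rep(2.5, 5))
  resc <- percent_positive(ctc, "SULF1", "tumor")
  expect_equal(resc$mean_all, 2.5)
  expect_equal(resc$mean_positive, 2.5)

  expect_error(percent_positive(ct, "SULF1", "fibroblast"),
               class = "sulfscan_validation_error")
  expect_error(percent_positive(ct, "NOPE", "tumor"),
               class = "sulfscan_validation_error")
})

test_that("positivity depends only on the sign of stored values", {
  set.seed(61)
  v <- round(rexp(50) * (runif(50) < 0.4), 3)
  p1 <- percent_positive(simple_cells(v), "SULF1", "tumor")$percent_positive
  p2 <- percent_positive(simple_cells(v * 7.3), "SULF1", "tumor")$percent_positive
  expect_equal(p1, p2)
})

test_that("mean_all equals positivity-weighted positive mean for zero-inflated data", {
  set.seed(62)
  v <- rexp(40) * (runif(40) < 0.5)
  res <- percent_positive(simple_cells(v), "SULF1", "tumor")
  expect_equal(res$mean_all, res$percent_positive / 100 * res$mean_positive)
})

test_that("between-type comparison matches the closed-form Welch test", {
  m <- Matrix::Matrix(
    matrix(c(1.2, 3.4, 2.2, 0.5, 1.1, 0.2), ncol = 1,
           dimnames = list(sprintf("c%d", 1:6), "SULF1")),
    sparse = TRUE
  )
  ct <- cell_table(m, rep(c("tumor", "fibroblast"), each = 3), rep("p1", 6))
  p <- compare_cell_types(ct, "SULF1", "tumor", "fibroblast")
  expect_equal(p, oracle_welch_p(c(1.2, 3.4, 2.2), c(0.5, 1.1, 0.2)),
               tolerance = 1e-12)

  # identical expression vectors: p = 1
  ct_same <- cell_table(
    Matrix::Matrix(matrix(rep(c(1, 2, 3), 2), ncol = 1,
                          dimnames = list(sprintf("c%d", 1:6), "G")), sparse = TRUE),
    rep(c("a", "b"), each = 3), rep("p1", 6)
  )
  expect_equal(compare_cell_types(ct_same, "G", "a", "b"), 1)

  # only one positive fibroblast: positives-only comparison is impossible
  sparse <- cell_table(
    Matrix::Matrix(matrix(c(1.2, 3.4, 2.2, 0.5, 0, 0), ncol = 1,
                          dimnames = list(sprintf("d%d", 1:6), "SULF1")),
                   sparse = TRUE),
    rep(c("tumor", "fibroblast"), each = 3), rep("p1", 6)
  )
  expect_error(compare_cell_types(sparse, "SULF1", "tumor", "fibroblast",
                                  positives_only = TRUE),
               class = "sulfscan_insufficient_data")
})

test_that("a planted expression gap between types is detected", {
  spec <- list(
    tumor = list(n = 500, pos_frac = 0.6, mu = 1.0, sigma = 0.5),
    fibroblast = list(n = 500, pos_frac = 0.6, mu = 2.0, sigma = 0.5)
  )
  ct <- gen_cell_population(spec, genes = "G", seed = 63)
  p <- compare_cell_types(ct, "G", "tumor", "fibroblast", positives_only = TRUE)
  expect_lt(p, 1e-6)
})

test_that("per-patient positivity reports counts, ranges and flags", {
  v <- c(rep(c(1, 0), c(1, 9)), rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(9, 1)))
  pats <- rep(c("A", "B", "C"), each = 10)
  ct <- simple_cells(v, patients = pats)
  res <- per_patient_positivity(ct, "SULF1", "tumor")
  expect_equal(res$range, c(10, 90))
  expect_equal(res$table$percent_positive[res$table$patient_id == "B"], 50)
  expect_false(any(res$table$low_cells))

  # single patient: min = max
  ct1 <- simple_cells(c(1, 0, 1))
  res1 <- per_patient_positivity(ct1, "SULF1", "tumor")
  expect_equal(res1$range[1], res1$range[2])
  expect_true(all(res1$table$low_cells))

  # pooled percent equals the cell-weighted mean of per-patient percents
  pooled <- percent_positive(ct, "SULF1", "tumor")$percent_positive
  weighted <- with(res$table, sum(percent_positive * n_cells) / sum(n_cells))
  expect_equal(pooled, weighted)
})

test_that("generator recovers planted positivity and positive means per type", {
  ct <- gen_cell_population(seed = 64)
  spec <- default_cell_spec()
  for (type in names(spec)) {
    for (gene in c("SULF1", "SULF2")) {
      res <- percent_positive(ct, gene, type)
      pf <- spec[[type]]$pos_frac[[gene]]
      n <- spec[[type]]$n
      se_bin <- sqrt(pf * (1 - pf) / n)
      expect_lt(abs(res$percent_positive / 100 - pf), 3 * se_bin + 1e-9)
      if (res$n_positive > 10) {
        mom <- truncnorm_moments(spec[[type]]$mu[[gene]], spec[[type]]$sigma[[gene]])
        se_mean <- mom["sd"] / sqrt(res$n_positive)
        expect_lt(abs(res$mean_positive - mom["mean"]), 3 * se_mean)
      }
    }
  }
})
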