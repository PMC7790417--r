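test_that("insulin status is classified by the SSPG cutoff, boundary to IR", {
  expect_equal(classify_insulin_status(84), "IS")
  expect_equal(classify_insulin_status(210), "IR")
  expect_equal(classify_insulin_status(140), "IR")
  expect_equal(classify_insulin_status(c(84, 210, 139.9, 140.0)),
               c("IS", "IR", "IS", "IR"))
  expect_error(classify_insulin_status(-1), "sspg")
})

test_that("expression filter applies the CPM-in-fraction rule and is idempotent", {
  # 10 samples, library ~1e6 each via a large filler gene
  n <- 10
  filler <- matrix(1e6, 1, n)
  zero <- matrix(0, 1, n)
  in3 <- matrix(c(rep(2, 3), rep(0, 7)), 1, n)   # CPM ~2 in 3 of 10
  in2 <- matrix(c(rep(2, 2), rep(0, 8)), 1, n)   # CPM ~2 in 2 of 10
  counts <- rbind(filler, zero, in3, in2)
  rownames(counts) <- c("filler", "zero", "in3", "in2")
  colnames(counts) <- paste0("s", 1:n)
  kept <- filter_low_expression(counts, min_cpm = 1, min_frac = 0.30)
  expect_setequal(rownames(kept), c("filler", "in3"))  # 3 >= ceil(3), 2 < 3
  expect_identical(kept, filter_low_expression(kept))  # idempotent
})

test_that("TMM factors: null cases, product one, and independent oracle", {
  set.seed(1)
  base <- matrix(rnbinom(200 * 4, mu = 50, size = 5), 200, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  same <- base[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  expect_equal(unname(tmm_factors(same)), rep(1, 3))
  scaled <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  expect_equal(unname(tmm_factors(scaled)), c(1, 1), tolerance = 1e-12)
  expect_equal(prod(tmm_factors(base)), 1, tolerance = 1e-10)

  # straightforward loop implementation of the weighted trimmed mean
  tmm_oracle <- function(counts, ref) {
    lib <- colSums(counts)
    f <- numeric(ncol(counts))
    for (j in seq_len(ncol(counts))) {
      ok <- counts[, j] > 0 & counts[, ref] > 0
      o <- counts[ok, j] / lib[j]; r <- counts[ok, ref] / lib[ref]
      M <- log2(o / r); A <- (log2(o) + log2(r)) / 2
      v <- (lib[j] - counts[ok, j]) / (lib[j] * counts[ok, j]) +
        (lib[ref] - counts[ok, ref]) / (lib[ref] * counts[ok, ref])
      n <- length(M)
      keepM <- rank(M) >= floor(n * 0.3) + 1 & rank(M) <= n - floor(n * 0.3)
      keepA <- rank(A) >= floor(n * 0.05) + 1 & rank(A) <= n - floor(n * 0.05)
      keep <- keepM & keepA
      f[j] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    }
    f / exp(mean(log(f)))
  }
  expect_equal(unname(tmm_factors(base, ref_column = 2)),
               tmm_oracle(base, 2), tolerance = 1e-12)
})

test_that("TMM factors agree with edgeR on a random matrix", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  counts <- matrix(rnbinom(500 * 6, mu = 80, size = 3), 500, 6,
                   dimnames = list(NULL, paste0("s", 1:6)))
  ours <- tmm_factors(counts)
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("log-CPM follows the stated closed form and voom's scale", {
  counts <- matrix(c(0, 1e6, 2, 1e6 - 2), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  lc <- log_cpm(counts, factors = c(1, 1))
  # count 0, library 1e6, factor 1, prior 0.5
  expect_equal(lc["a", "s1"], log2(0.5 / (1e6 + 1) * 1e6))
  eq <- matrix(5, 4, 3)
  expect_true(all(abs(log_cpm(eq) - log_cpm(eq)[1, 1]) < 1e-12))

  set.seed(3)
  cc <- matrix(rnbinom(300 * 5, mu = 60, size = 5), 300, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  f <- tmm_factors(cc)
  v <- limma::voom(cc, lib.size = colSums(cc) * f)
  expect_equal(unname(log_cpm(cc, f)), unname(v$E), tolerance = 1e-10)
})

test_that("covariate adjustment removes planted effects and stays orthogonal", {
  set.seed(11)
  n <- 60
  meta <- data.frame(
    batch = rep(c("B1", "B2"), each = n / 2),
    age = rnorm(n, 55, 8),
    sex = sample(c("M", "F"), n, replace = TRUE))
  delta <- 2
  slope <- 0.05
  Y <- matrix(rnorm(100 * n, sd = 0.5), 100, n)
  Y <- Y + delta * outer(rep(1, 100), as.numeric(meta$batch == "B2"))
  Y <- Y + slope * outer(rep(1, 100), meta$age - mean(meta$age))
  rownames(Y) <- paste0("g", 1:100); colnames(Y) <- paste0("s", 1:n)

  res <- adjust_covariates(Y, meta, fixed = c("age", "sex"),
                           random = "batch")
  gap <- rowMeans(res$values[, meta$batch == "B2"]) -
    rowMeans(res$values[, meta$batch == "B1"])
  expect_lt(mean(abs(gap)), 0.05 * delta)
  slopes <- apply(res$values, 1, function(y) coef(lm(y ~ meta$age))[2])
  expect_lt(mean(abs(slopes)), 2 * 0.5 / (sd(meta$age) * sqrt(n)))
  # exact orthogonality to the fixed design
  X <- model.matrix(~ age + sex, meta)
  ip <- abs(crossprod(t(res$values), X))
  norms <- sqrt(rowSums(res$values^2)) %o% sqrt(colSums(X^2))
  expect_lt(max(ip / norms), 1e-8)
  expect_lt(max(abs(rowMeans(res$values))), 1e-10)
})

test_that("covariate adjustment handles degenerate designs", {
  Y <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  meta <- data.frame(batch = rep(c("A", "B"), 5))
  # no covariates: centered input
  res <- adjust_covariates(Y, meta)
  expect_equal(res$values, Y - rowMeans(Y))
  # confounded categorical covariates warn
  meta2 <- data.frame(batch = rep(c("A", "B"), each = 5),
                      rna_kit = rep(c("K1", "K2"), each = 5))
  expect_warning(adjust_covariates(Y, meta2, fixed = "rna_kit",
                                   random = "batch"), "confounded")
})

test_that("per-patient averaging is the arithmetic clone mean", {
  vals <- matrix(c(1, 3, 5, 2, 4, 6), 1, 6)
  rownames(vals) <- "g1"; colnames(vals) <- paste0("s", 1:6)
  res <- structure(list(values = vals, unit_kind = "sample",
                        gene_ids = "g1", unit_ids = colnames(vals),
                        fixed = character(0), random = character(0)),
                   class = "ResidualMatrix")
  app <- average_per_patient(res, c("d1", "d1", "d2", "d2", "d2", "d3"))
  expect_equal(unname(app$values[1, ]), c(2, 11 / 3, 6))
  expect_equal(ncol(app$values), 3)
  # single clone is copied unchanged
  expect_equal(app$values[1, "d3"], 6)
  ch <- small_cohort()
  app2 <- average_per_patient(small_residuals(), ch$metadata$donor_id)
  expect_equal(ncol(app2$values), ch$truth$params$n_donors)
})
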