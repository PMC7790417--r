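#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test cutree dist hclust lm lm.fit model.matrix
#'   optimize p.adjust pchisq phyper pnorm pt quantile rbinom rnbinom rnorm
#'   runif sd setNames var wilcox.test complete.cases
#' @importFrom utils head read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Distance correlation between two numeric vectors
#'
#' Nonparametric dependence measure used by the additive-noise edge
#' orientation test: zero iff (asymptotically) the two variables are
#' independent, positive under any form of dependence, linear or not.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar distance correlation in \[0, 1\].
#' @keywords internal
dcor_xy <- function(x, y) {
  n <- length(x)
  stop_if_not(length(y) == n && n >= 2, "x and y must have equal length >= 2")
  center <- function(v) {
    d <- abs(outer(v, v, "-"))
    d - outer(rowMeans(d), colMeans(d), "+") + mean(d)
  }
  A <- center(x)
  B <- center(y)
  dcov2 <- mean(A * B)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# Adjusted Rand index between two labelings (Hubert & Arabie form).
adjusted_rand <- function(a, b) {
  stop_if_not(length(a) == length(b), "labelings must have equal length")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw a deterministic integer sub-seed from a base seed and a stage label,
# kept below 2^31 so it is a valid R integer. All pipeline stages derive
# their RNG state this way from the single global seed.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 1103 + h * 12289) %% 2147483629L)
}
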