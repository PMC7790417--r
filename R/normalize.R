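#' Classify insulin status from SSPG
#'
#' Steady-state plasma glucose (SSPG, mg/dl) at or above the cutoff is
#' called insulin resistant (IR), below it insulin sensitive (IS). The
#' boundary value itself is assigned to IR so the resistant class is
#' closed.
#'
#' @param sspg Numeric vector of SSPG values in mg/dl (>= 0).
#' @param cutoff Classification cutoff in mg/dl (default 140).
#' @return Character vector of "IR"/"IS".
#' @export
classify_insulin_status <- function(sspg, cutoff = 140) {
  stop_if_not(all(sspg >= 0), "sspg must be >= 0")
  ifelse(sspg >= cutoff, "IR", "IS")
}

cpm_raw <- function(counts) {
  lib <- colSums(counts)
  stop_if_not(all(lib > 0), "every sample needs positive total counts")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' Keeps genes with at least `min_cpm` counts-per-million in at least
#' `ceiling(min_frac * n_samples)` samples; gene order is preserved.
#'
#' @param counts Integer matrix, genes x samples.
#' @param min_cpm CPM threshold (default 1).
#' @param min_frac Minimum fraction of samples (default 0.30).
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_cpm = 1, min_frac = 0.30) {
  need <- ceiling(min_frac * ncol(counts))
  keep <- rowSums(cpm_raw(counts) >= min_cpm) >= need
  if (!any(keep)) warning("no genes pass the expression filter")
  counts[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each sample against a reference sample, the
#' log2 library-size-adjusted fold changes (M) of genes surviving a 30%
#' two-sided trim on M and a 5% trim on average abundance (A) are combined
#' in a precision-weighted mean; the factor is 2 to that mean. Factors are
#' normalized so their geometric mean (hence product) is 1. When no
#' reference is supplied, the sample whose upper quartile of scaled counts
#' is closest to the mean upper quartile is used.
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param ref_column Optional reference column index or name.
#' @param logratio_trim Two-sided trim fraction on M (default 0.30).
#' @param sum_trim Two-sided trim fraction on A (default 0.05).
#' @return Named numeric vector of per-sample scale factors.
#' @export
tmm_factors <- function(counts, ref_column = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05) {
  lib <- colSums(counts)
  stop_if_not(all(lib > 0), "sample with zero total counts")
  if (is.null(ref_column)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref_column <- which.min(abs(uq - mean(uq)))
  }
  ref <- counts[, ref_column]
  nref <- lib[ref_column]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]
    nobs <- lib[j]
    ok <- obs > 0 & ref > 0
    if (!any(ok)) return(1)
    M <- log2((obs[ok] / nobs) / (ref[ok] / nref))
    A <- (log2(obs[ok] / nobs) + log2(ref[ok] / nref)) / 2
    # asymptotic (delta-method) inverse variance of M
    v <- (nobs - obs[ok]) / (nobs * obs[ok]) +
      (nref - ref[ok]) / (nref * ref[ok])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1
    hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    fj <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(fj)) 1 else 2^fj
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Log2 counts-per-million
#'
#' `log2((count + prior_count) / (lib * factor + 2 * prior_count) * 1e6)`,
#' the TMM-adjusted effective library size with a small prior count guarding
#' zeros.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Per-sample scale factors from [tmm_factors()]; defaults to
#'   all 1.
#' @param prior_count Prior count added to every observation (default 0.5).
#' @return Numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  factors <- factors %||% rep(1, ncol(counts))
  eff <- colSums(counts) * factors
  log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
}

# Projection residual-maker for a fixed-effect design (QR based).
fixed_projection <- function(X) {
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  list(Q = Q, rank = qr_x$rank)
}

#' Residualize expression on fixed and random (shrunken) covariates
#'
#' Per gene, fixed-effect covariates are projected out exactly (OLS) while
#' random-effect covariates (typically sequencing batch and RNA kit) get
#' ridge-shrunken level effects with a single variance-ratio penalty chosen
#' by restricted maximum likelihood per gene — a partial-pooling analogue of
#' a mixed model that stays deterministic and closed-form. Residuals have
#' per-gene mean zero and are exactly orthogonal to the fixed-effect design.
#'
#' @param logcpm Numeric matrix, genes x samples (log2-CPM).
#' @param metadata Sample metadata data.frame aligned with columns.
#' @param fixed Character vector of fixed-effect covariate names.
#' @param random Character vector of random-effect covariate names
#'   (categorical).
#' @return A `ResidualMatrix`: list with `values` (genes x units),
#'   `unit_kind = "sample"`, `gene_ids`, `unit_ids`, and the covariates
#'   adjusted.
#' @export
adjust_covariates <- function(logcpm, metadata,
                              fixed = character(0),
                              random = character(0)) {
  stop_if_not(ncol(logcpm) == nrow(metadata),
              "metadata rows must match expression columns")
  miss <- setdiff(c(fixed, random), names(metadata))
  stop_if_not(length(miss) == 0,
              paste("covariates missing from metadata:",
                    paste(miss, collapse = ", ")))
  for (cv in c(fixed, random)) {
    v <- metadata[[cv]]
    if (!is.numeric(v) && length(unique(v)) < 2)
      stop(sprintf("categorical covariate '%s' has < 2 levels", cv))
  }
  # confounding check: a covariate constant within another's levels
  cats <- Filter(function(cv) !is.numeric(metadata[[cv]]), c(fixed, random))
  if (length(cats) >= 2) {
    for (i in seq_len(length(cats) - 1)) for (j in (i + 1):length(cats)) {
      a <- metadata[[cats[i]]]; b <- metadata[[cats[j]]]
      if (all(tapply(a, b, function(z) length(unique(z))) == 1) &&
          length(unique(a)) > 1)
        warning(sprintf("covariates '%s' and '%s' are confounded",
                        cats[i], cats[j]))
    }
  }

  n <- ncol(logcpm)
  X <- if (length(fixed) > 0) {
    model.matrix(~ ., data = metadata[, fixed, drop = FALSE])
  } else {
    matrix(1, n, 1)
  }
  proj <- fixed_projection(X)
  Q <- proj$Q
  # residualize against fixed effects: R = Y - (Y Q) Q'
  Yf <- logcpm - (logcpm %*% Q) %*% t(Q)

  if (length(random) > 0) {
    Z <- do.call(cbind, lapply(random, function(cv) {
      f <- factor(metadata[[cv]])
      stats::model.matrix(~ 0 + f)
    }))
    Zt <- Z - Q %*% (t(Q) %*% Z)
    sv <- svd(Zt)
    pos <- sv$d > 1e-8
    U <- sv$u[, pos, drop = FALSE]
    d2 <- sv$d[pos]^2
    np <- n - proj$rank
    C <- Yf %*% U                      # genes x q component scores
    tot <- rowSums(Yf^2)
    w2 <- tot - rowSums(C^2)           # energy orthogonal to Z
    Yr <- Yf
    for (g in seq_len(nrow(Yf))) {
      ci2 <- C[g, ]^2
      reml <- function(lg) {
        gam <- exp(lg)
        s2 <- (sum(ci2 / (1 + gam * d2)) + w2[g]) / np
        np * log(s2) + sum(log(1 + gam * d2))
      }
      opt <- tryCatch(optimize(reml, c(-12, 12)),
                      error = function(e) list(minimum = 0))
      gam <- exp(opt$minimum)
      shrink <- gam * d2 / (1 + gam * d2)
      Yr[g, ] <- Yf[g, ] - as.vector(U %*% (shrink * C[g, ]))
    }
  } else {
    Yr <- Yf
  }
  Yr <- Yr - rowMeans(Yr)
  structure(list(values = Yr, unit_kind = "sample",
                 gene_ids = rownames(logcpm),
                 unit_ids = colnames(logcpm),
                 fixed = fixed, random = random),
            class = "ResidualMatrix")
}

#' @export
print.ResidualMatrix <- function(x, ...) {
  cat(sprintf("<ResidualMatrix> %d genes x %d %ss\n",
              nrow(x$values), ncol(x$values), x$unit_kind))
  invisible(x)
}

#' Average residuals per patient (ApP stream)
#'
#' Each donor column is the arithmetic mean of that donor's sample columns.
#'
#' @param residuals A sample-level `ResidualMatrix` (AS stream).
#' @param donor_map Character vector of donor ids, one per sample column.
#' @return A donor-level `ResidualMatrix` (`unit_kind = "donor"`).
#' @export
average_per_patient <- function(residuals, donor_map) {
  stop_if_not(length(donor_map) == ncol(residuals$values),
              "every sample must map to a donor")
  donors <- unique(donor_map)
  V <- vapply(donors, function(d) {
    rowMeans(residuals$values[, donor_map == d, drop = FALSE])
  }, numeric(nrow(residuals$values)))
  V <- matrix(V, nrow = nrow(residuals$values),
              dimnames = list(rownames(residuals$values), donors))
  structure(list(values = V, unit_kind = "donor",
                 gene_ids = residuals$gene_ids, unit_ids = donors,
                 fixed = residuals$fixed, random = residuals$random),
            class = "ResidualMatrix")
}
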