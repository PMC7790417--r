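#' Two-group differential expression on residuals
#'
#' Per-gene linear model of residual expression on group (IR vs IS),
#' optionally with a blocking factor (e.g. paired designs). With
#' `moderate = TRUE` (default) gene-wise variances are shrunk toward a
#' common prior by the standard empirical-Bayes inverse-gamma scheme
#' (via limma's `lmFit`/`eBayes`), augmenting the residual degrees of
#' freedom by the estimated prior df; with `moderate = FALSE` ordinary
#' pooled-variance t statistics are returned.
#'
#' @param residuals A `ResidualMatrix` or plain numeric matrix
#'   (genes x units).
#' @param group Factor/character vector of group labels per unit; the log2
#'   fold change is `IR - IS` when the labels are IR/IS, otherwise
#'   second level minus first.
#' @param moderate Apply empirical-Bayes variance moderation (default TRUE).
#' @param block Optional blocking factor (paired design).
#' @return A `DEResult` data.frame: gene, logFC, t, p, fdr, rank (rank 1 =
#'   smallest p, ties broken by order).
#' @export
fit_de <- function(residuals, group, moderate = TRUE, block = NULL) {
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  group <- as.character(group)
  stop_if_not(length(unique(group)) == 2, "need exactly two groups")
  lev <- if (all(sort(unique(group)) == c("IR", "IS"))) c("IS", "IR")
         else sort(unique(group))
  gf <- factor(group, levels = lev)
  stop_if_not(all(table(gf) >= 1), "both groups must be non-empty")
  if (!moderate && any(table(gf) < 2) && is.null(block))
    stop("a group of size 1 requires moderation")
  design <- if (is.null(block)) {
    model.matrix(~ gf)
  } else {
    model.matrix(~ factor(block) + gf)
  }
  coef_name <- paste0("gf", lev[2])
  fit <- limma::lmFit(Y, design)
  if (moderate) {
    fit <- limma::eBayes(fit)
    tt <- fit$t[, coef_name]
    pp <- fit$p.value[, coef_name]
  } else {
    se <- fit$stdev.unscaled[, coef_name] * fit$sigma
    cf <- fit$coefficients[, coef_name]
    tt <- ifelse(se > 1e-12, cf / se,
                 ifelse(abs(cf) < 1e-12, 0, sign(cf) * Inf))
    pp <- 2 * pt(-abs(tt), df = fit$df.residual)
  }
  lfc <- fit$coefficients[, coef_name]
  ord <- order(pp)
  rk <- integer(length(pp))
  rk[ord] <- seq_along(pp)
  res <- data.frame(gene = rownames(Y), logFC = unname(lfc),
                    t = unname(tt), p = unname(pp),
                    fdr = bh_adjust(unname(pp)), rank = rk,
                    stringsAsFactors = FALSE)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with enforced monotonicity; ties
#' keep equal adjusted values.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values (same length and order).
#' @export
bh_adjust <- function(pvalues) {
  stop_if_not(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Compare two DE rankings (AS vs ApP concordance)
#'
#' Takes the union of each result's `top_n` most significant genes and, on
#' that union, reports the Spearman correlation of the two results' ranks
#' and a paired Wilcoxon signed-rank test of the rank differences.
#'
#' @param de_a,de_b `DEResult` tables over a shared gene universe.
#' @param top_n Number of top genes taken from each result (default 500).
#' @return List with `rho`, `signed_rank_p`, and `table` (gene, rank_a,
#'   rank_b).
#' @export
compare_rankings <- function(de_a, de_b, top_n = 500) {
  stop_if_not(top_n <= nrow(de_a) && top_n <= nrow(de_b),
              "top_n exceeds the number of genes")
  common <- intersect(de_a$gene, de_b$gene)
  stop_if_not(length(common) > 0, "no shared gene universe")
  ra <- setNames(de_a$rank, de_a$gene)
  rb <- setNames(de_b$rank, de_b$gene)
  top <- union(de_a$gene[de_a$rank <= top_n], de_b$gene[de_b$rank <= top_n])
  top <- intersect(top, common)
  tab <- data.frame(gene = top, rank_a = unname(ra[top]),
                    rank_b = unname(rb[top]), stringsAsFactors = FALSE)
  rho <- cor(tab$rank_a, tab$rank_b, method = "spearman")
  sr <- tryCatch(
    wilcox.test(tab$rank_a, tab$rank_b, paired = TRUE, exact = FALSE)$p.value,
    error = function(e) NA_real_)
  list(rho = rho, signed_rank_p = sr, table = tab)
}

#' Significant or top-ranked DE gene list
#'
#' Genes at `fdr < cutoff`; when none pass and `fallback_n` is given, the
#' `fallback_n` smallest-p genes are returned instead — the convention used
#' for the average-per-patient stream, where donor-level power may leave
#' the FDR list empty.
#'
#' @param de A `DEResult`.
#' @param cutoff FDR cutoff (default 0.05).
#' @param fallback_n Optional top-N fallback size (e.g. 500).
#' @return Character vector of gene ids.
#' @export
de_gene_list <- function(de, cutoff = 0.05, fallback_n = NULL) {
  hits <- de$gene[de$fdr < cutoff]
  if (!is.null(fallback_n) && length(hits) == 0) {
    hits <- de$gene[de$rank <= fallback_n]
  }
  hits
}
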