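#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency
#' `|cor|^power`, computes node connectivity, and fits the scale-free
#' criterion: regress log10(frequency) on log10(mean connectivity) over
#' equal-width connectivity bins; the signed R-squared is negated when the
#' slope is positive. Returns the smallest power reaching `r2_cutoff`;
#' otherwise a plateau rule applies: a power with R-squared >= 0.78 is
#' accepted when the next candidate improves it by < 0.01. If no candidate
#' reaches 0.5 a warning is issued and the argmax returned.
#'
#' @param residuals `ResidualMatrix` or numeric matrix (genes x units).
#' @param candidate_powers Numeric vector of powers to try.
#' @param r2_cutoff Scale-free fit cutoff (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @return List with `power` (chosen), and `fit_table` (power, r2, slope,
#'   mean_k).
#' @export
pick_soft_threshold <- function(residuals,
                                candidate_powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_cutoff = 0.8, n_bins = 10) {
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  stop_if_not(nrow(Y) >= 20, "need at least 20 genes")
  ac <- abs(safe_cor(Y))
  fits <- vapply(candidate_powers, function(pw) {
    A <- ac^pw
    diag(A) <- 0
    k <- rowSums(A)
    scale_free_fit(k, n_bins)
  }, c(r2 = 0, slope = 0, mean_k = 0))
  tab <- data.frame(power = candidate_powers, r2 = fits["r2", ],
                    slope = fits["slope", ], mean_k = fits["mean_k", ])
  chosen <- NULL
  hit <- which(tab$r2 >= r2_cutoff)
  if (length(hit) > 0) {
    chosen <- tab$power[hit[1]]
  } else {
    # plateau: nearly there and the next step adds < 0.01
    for (i in seq_len(nrow(tab) - 1)) {
      if (tab$r2[i] >= 0.78 && (tab$r2[i + 1] - tab$r2[i]) < 0.01) {
        chosen <- tab$power[i]
        break
      }
    }
  }
  if (is.null(chosen)) {
    if (max(tab$r2) < 0.5)
      warning("no candidate power reaches scale-free R^2 of 0.5")
    chosen <- tab$power[which.max(tab$r2)]
  }
  list(power = chosen, fit_table = tab)
}

# Scale-free topology R^2 (signed) for a connectivity vector.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(c(r2 = 0, slope = 0, mean_k = mean(k)))
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mk <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(c(r2 = 0, slope = 0, mean_k = mean(k)))
  x <- log10(mk[ok]); y <- log10(freq[ok] / sum(freq[ok]))
  fit <- lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  c(r2 = unname(if (slope > 0) -r2 else r2), slope = unname(slope),
    mean_k = mean(k))
}

# Pearson correlation that maps zero-variance genes to 0 with a warning.
safe_cor <- function(Y) {
  sds <- apply(Y, 1, sd)
  if (any(sds == 0)) {
    warning("constant gene(s): correlations set to 0")
    Y <- Y[, , drop = FALSE]
    cc <- suppressWarnings(cor(t(Y)))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    return(cc)
  }
  cor(t(Y))
}

#' Unsigned adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |cor(i,j)|^power` (Pearson, unsigned) and
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with a
#' unit diagonal. High TOM means two genes share neighbours as well as
#' being directly correlated.
#'
#' @param residuals `ResidualMatrix` or numeric matrix (genes x units);
#'   ignored when `cor_matrix` is supplied.
#' @param power Soft-threshold power (>= 1).
#' @param cor_matrix Optional precomputed correlation matrix.
#' @return Symmetric TOM matrix in \[0, 1\].
#' @export
adjacency_and_tom <- function(residuals, power, cor_matrix = NULL) {
  stop_if_not(power >= 1, "power must be >= 1")
  cc <- cor_matrix %||% safe_cor(
    if (inherits(residuals, "ResidualMatrix")) residuals$values
    else residuals)
  A <- abs(cc)^power
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(cc)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`
#' with a static tree cut. When `cut_height` is not given, a deterministic
#' scan over the merge-height range picks the height yielding the most
#' clusters of at least `min_module_size` genes (ties broken toward larger
#' covered gene count) — module cores sit in a merge band well below the
#' late merges that absorb unclustered background genes, and this scan
#' finds that band without a tuning parameter. When `expr` is supplied the
#' cores are then refined the way the standard weighted co-expression
#' workflow does: cores whose eigengenes (first principal component of the
#' core's expression) correlate above `merge_cor` are merged, and every
#' gene is finally assigned to the module with its highest absolute
#' eigengene correlation (module membership, kME) when that exceeds
#' `kme_min`, else left unassigned. Clusters below `min_module_size` get
#' label 0; labels are ordered by decreasing size.
#'
#' @param tom TOM matrix from [adjacency_and_tom()].
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static cut height; default data-driven scan.
#' @param expr Optional expression matrix (genes x units, same genes as
#'   `tom`) enabling eigengene merging and kME assignment.
#' @param kme_min Minimum |kME| for final assignment (default 0.3).
#' @param merge_cor Eigengene correlation above which cores merge
#'   (default 0.4).
#' @return Named integer vector gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = NULL,
                           expr = NULL, kme_min = 0.3, merge_cor = 0.4) {
  hc <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    grid <- unique(quantile(hc$height, seq(0.3, 0.999, length.out = 120)))
    bestn <- -1; bestcov <- -1
    for (h in grid) {
      sz <- table(cutree(hc, h = h))
      sz <- sz[sz >= min_module_size]
      if (length(sz) > bestn ||
          (length(sz) == bestn && sum(sz) > bestcov)) {
        bestn <- length(sz); bestcov <- sum(sz); cut_height <- h
      }
    }
  }
  raw <- cutree(hc, h = cut_height)
  if (is.null(names(raw))) names(raw) <- rownames(tom)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  lab <- setNames(ifelse(raw %in% keep, raw, 0L), names(raw))

  if (!is.null(expr) && any(lab > 0)) {
    Y <- if (inherits(expr, "ResidualMatrix")) expr$values else expr
    Y <- Y[names(lab), , drop = FALSE]
    eigengene <- function(mem)
      svd(scale(t(Y[mem, , drop = FALSE])), nu = 1, nv = 0)$u[, 1]
    repeat {
      labs <- sort(unique(lab[lab > 0]))
      if (length(labs) < 2) break
      E <- vapply(labs, function(m) eigengene(names(lab)[lab == m]),
                  numeric(ncol(Y)))
      cm <- abs(cor(E))
      diag(cm) <- 0
      if (max(cm) < merge_cor) break
      mx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      lab[lab == labs[mx[2]]] <- labs[mx[1]]
    }
    labs <- sort(unique(lab[lab > 0]))
    E <- matrix(vapply(labs, function(m) eigengene(names(lab)[lab == m]),
                       numeric(ncol(Y))), ncol = length(labs))
    kme <- abs(cor(t(Y), E))
    bi <- max.col(kme, ties.method = "first")
    lab <- setNames(
      ifelse(kme[cbind(seq_len(nrow(kme)), bi)] >= kme_min,
             labs[bi], 0L), names(lab))
  }

  sizes <- table(lab[lab > 0])
  sizes <- sizes[sizes >= min_module_size]
  out <- setNames(integer(length(lab)), names(lab))
  if (length(sizes) > 0) {
    ord <- names(sizes)[order(-sizes)]
    for (i in seq_along(ord)) out[lab == as.integer(ord[i])] <- i
  }
  out
}

#' Permutation background for within-module correlations
#'
#' Each of `n_perm` permutations independently shuffles the sample order of
#' every gene row, breaking all inter-gene correlation while preserving the
#' gene marginals. Absolute permuted correlations of the module's gene
#' pairs, pooled over permutations, form the null; the p-value of a real
#' pair is `(1 + #{null >= observed}) / (1 + #null)`.
#'
#' @param residuals `ResidualMatrix` or numeric matrix (genes x units).
#' @param module_assignment Named gene -> label vector (label 0 skipped).
#' @param n_perm Number of permutations (default 10).
#' @param seed Integer seed.
#' @return Named list per module label: data.frame (gene_a, gene_b, cor, p).
#' @export
permutation_background <- function(residuals, module_assignment,
                                   n_perm = 10, seed = 1) {
  stop_if_not(n_perm >= 1, "n_perm must be >= 1")
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  labs <- sort(unique(module_assignment[module_assignment > 0]))
  out <- list()
  with_seed(seed, {
    for (m in labs) {
      genes <- names(module_assignment)[module_assignment == m]
      genes <- intersect(genes, rownames(Y))
      if (length(genes) < 2) next
      sub <- Y[genes, , drop = FALSE]
      obs <- cor(t(sub))
      null_abs <- numeric(0)
      for (b in seq_len(n_perm)) {
        perm <- t(apply(sub, 1, sample))
        pc <- cor(t(perm))
        null_abs <- c(null_abs, abs(pc[upper.tri(pc)]))
      }
      null_sorted <- sort(null_abs)
      ut <- which(upper.tri(obs), arr.ind = TRUE)
      oc <- abs(obs[upper.tri(obs)])
      # #{null >= obs} via binary search on the sorted null
      ge <- length(null_sorted) -
        findInterval(oc - 1e-12, null_sorted)
      p <- (1 + ge) / (1 + length(null_sorted))
      out[[as.character(m)]] <- data.frame(
        gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
        cor = obs[upper.tri(obs)], p = p, stringsAsFactors = FALSE)
    }
  })
  out
}

#' Module enrichment against gene sets and module selection
#'
#' One-sided hypergeometric tail test of each module's overlap with each
#' gene set, with the analyzed genes as universe, BH-corrected across all
#' module-by-set tests. A module is selected when any set whose name
#' matches one of the `relevant_patterns` (case-insensitive substring)
#' passes `fdr_cutoff` — the operational form of "enriched for terms
#' relevant to insulin-resistance traits".
#'
#' @param module_assignment Named gene -> label vector.
#' @param gene_sets Named list of gene id vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of analyzed gene ids.
#' @param relevant_patterns Patterns marking insulin-resistance-relevant
#'   sets.
#' @param fdr_cutoff Selection cutoff (default 0.05).
#' @return List with `table` (module, set, overlap, module_size, set_size,
#'   p, fdr, relevant) and `selected_modules` (integer labels).
#' @export
module_enrichment <- function(module_assignment, gene_sets, universe,
                              relevant_patterns = c("glucose", "lipid",
                                                    "cholesterol",
                                                    "electron_transport",
                                                    "glycolysis", "insulin"),
                              fdr_cutoff = 0.05) {
  labs <- sort(unique(module_assignment[module_assignment > 0]))
  rows <- list()
  for (s in names(gene_sets)) {
    set_u <- intersect(gene_sets[[s]], universe)
    if (length(set_u) == 0) {
      warning(sprintf("gene set '%s' does not intersect the universe", s))
      next
    }
    for (m in labs) {
      mod <- intersect(names(module_assignment)[module_assignment == m],
                       universe)
      ov <- length(intersect(mod, set_u))
      p <- phyper(ov - 1, length(set_u),
                  length(universe) - length(set_u), length(mod),
                  lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = m, set = s, overlap = ov, module_size = length(mod),
        set_size = length(set_u), p = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(list(table = data.frame(), selected_modules = integer(0)))
  }
  tab$fdr <- bh_adjust(tab$p)
  tab$relevant <- Reduce(`|`, lapply(relevant_patterns, function(pt) {
    grepl(pt, tab$set, ignore.case = TRUE)
  }))
  sel <- sort(unique(tab$module[tab$relevant & tab$fdr < fdr_cutoff]))
  list(table = tab, selected_modules = sel)
}

#' Build one group-specific co-expression network
#'
#' Convenience wrapper running soft-threshold selection, TOM, module
#' detection, the permutation background and (optionally) enrichment-based
#' module selection on one residual matrix.
#'
#' @param residuals `ResidualMatrix` or matrix (genes x units) restricted
#'   to one group's units.
#' @param gene_sets Optional named list of gene sets for module selection.
#' @param r2_cutoff Scale-free fit cutoff.
#' @param min_module_size Minimum module size.
#' @param n_perm Permutations for the correlation background.
#' @param seed Integer seed.
#' @param relevant_patterns Passed to [module_enrichment()].
#' @return A `CoexpressionNetwork` list: power, fit_table, tom,
#'   module_assignment, background, enrichment, selected_modules.
#' @export
coexpression_network <- function(residuals, gene_sets = NULL,
                                 r2_cutoff = 0.8, min_module_size = 30,
                                 n_perm = 10, seed = 1,
                                 relevant_patterns = c("glucose", "lipid",
                                                       "cholesterol",
                                                       "electron_transport",
                                                       "glycolysis",
                                                       "insulin")) {
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  st <- pick_soft_threshold(Y, r2_cutoff = r2_cutoff)
  tom <- adjacency_and_tom(Y, st$power)
  mods <- detect_modules(tom, min_module_size = min_module_size, expr = Y)
  bg <- permutation_background(Y, mods, n_perm = n_perm, seed = seed)
  enr <- NULL
  sel <- sort(unique(mods[mods > 0]))
  if (!is.null(gene_sets)) {
    enr <- module_enrichment(mods, gene_sets, universe = rownames(Y),
                             relevant_patterns = relevant_patterns)
    sel <- enr$selected_modules
  }
  structure(list(power = st$power, fit_table = st$fit_table, tom = tom,
                 module_assignment = mods, background = bg,
                 enrichment = enr, selected_modules = sel),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf(
    "<CoexpressionNetwork> power %.1f, %d genes, %d modules (%s selected)\n",
    x$power, nrow(x$tom), max(x$module_assignment),
    paste(x$selected_modules, collapse = ",")))
  invisible(x)
}
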