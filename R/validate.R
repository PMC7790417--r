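#' Assign network layers downstream of a perturbed node
#'
#' Layer of a gene = shortest directed path length from the target
#' (diamonds take the minimum); the target itself is layer 0; unreachable
#' genes are omitted.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param target Perturbed node id.
#' @return Named integer vector gene -> layer (target included at 0).
#' @export
assign_layers <- function(network, target) {
  stop_if_not(target %in% network$nodes,
              sprintf("unknown target '%s'", target))
  g <- as_igraph(network, directed = TRUE)
  d <- igraph::distances(g, v = target, mode = "out")[1, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Layer-wise differential expression decay summary
#'
#' Per layer (1..`max_layer`, deeper layers pooled into the last row):
#' gene count, percentage of DE genes (FDR below `fdr`), mean absolute
#' log2 fold change and mean -log10 FDR. Monotonicity flags record whether
#' each statistic is non-increasing across layers — the signature of a
#' perturbation attenuating with network distance.
#'
#' @param layers Named gene -> layer vector from [assign_layers()].
#' @param de `DEResult` covering the layered genes (genes without DE rows
#'   are excluded and counted).
#' @param fdr DE call cutoff (default 0.05).
#' @param max_layer Last separate layer; deeper genes pool here
#'   (default 6).
#' @return A `PerturbationReport` list: `table` (layer, n_genes, pct_de,
#'   mean_abs_lfc, mean_neglog_fdr), `monotone` flags, `n_missing`.
#' @export
layerwise_summary <- function(layers, de, fdr = 0.05, max_layer = 6) {
  down <- layers[layers >= 1]
  in_de <- names(down) %in% de$gene
  n_missing <- sum(!in_de)
  down <- down[in_de]
  lay <- pmin(down, max_layer)
  idx <- match(names(down), de$gene)
  rows <- lapply(sort(unique(lay)), function(L) {
    sel <- idx[lay == L]
    data.frame(layer = L, n_genes = length(sel),
               pct_de = 100 * mean(de$fdr[sel] < fdr),
               mean_abs_lfc = mean(abs(de$logFC[sel])),
               mean_neglog_fdr = mean(-log10(pmax(de$fdr[sel], 1e-300))))
  })
  tab <- do.call(rbind, rows)
  mono <- function(x) all(diff(x) <= 1e-12)
  flags <- if (is.null(tab) || nrow(tab) < 2) {
    c(pct_de = TRUE, mean_abs_lfc = TRUE, mean_neglog_fdr = TRUE)
  } else {
    c(pct_de = mono(tab$pct_de), mean_abs_lfc = mono(tab$mean_abs_lfc),
      mean_neglog_fdr = mono(tab$mean_neglog_fdr))
  }
  structure(list(table = tab, monotone = flags, n_missing = n_missing),
            class = "PerturbationReport")
}

#' @export
print.PerturbationReport <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("monotone: %s\n",
              paste(names(x$monotone)[x$monotone], collapse = ", ")))
  invisible(x)
}

#' Enrichment of DE genes downstream of a target
#'
#' One-sided Fisher exact (hypergeometric upper tail) test of the DE genes
#' among the directed descendants of `target` versus the rest of the
#' universe.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param target Perturbed node id.
#' @param de_genes Character vector of DE gene ids.
#' @param universe Character vector of network nodes with DE measurements.
#' @return One-sided p-value.
#' @export
downstream_enrichment <- function(network, target, de_genes, universe) {
  layers <- assign_layers(network, target)
  desc <- setdiff(names(layers)[layers >= 1], target)
  if (length(desc) == 0) stop("target has no descendants")
  universe <- setdiff(unique(universe), target)
  desc <- intersect(desc, universe)
  de_u <- intersect(de_genes, universe)
  ov <- length(intersect(desc, de_u))
  phyper(ov - 1, length(de_u), length(universe) - length(de_u),
         length(desc), lower.tail = FALSE)
}

#' Partition two DE gene sets into specific and shared components
#'
#' @param de_a,de_b Character vectors of gene ids (e.g. IR-specific and
#'   IS-specific perturbation responses).
#' @return List with counts `a_only`, `shared`, `b_only` and the member
#'   vectors.
#' @export
overlap_partition <- function(de_a, de_b) {
  de_a <- unique(de_a); de_b <- unique(de_b)
  shared <- intersect(de_a, de_b)
  list(a_only = length(setdiff(de_a, de_b)),
       shared = length(shared),
       b_only = length(setdiff(de_b, de_a)),
       members = list(a_only = setdiff(de_a, de_b), shared = shared,
                      b_only = setdiff(de_b, de_a)))
}
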