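#' Expand seed genes through a prior interaction network
#'
#' Breadth-first neighborhood extraction: returns the seeds plus every
#' node within graph distance `k` of any seed, traversing prior edges as
#' undirected (interaction databases mix directed and undirected edges,
#' so the inclusive reading is used). Seeds absent from the prior are kept
#' with a warning.
#'
#' @param prior `DirectedNetwork` prior (direction ignored).
#' @param seeds Character vector of seed gene ids (module genes).
#' @param k Maximum number of steps (default 3); `k = 0` returns the seeds.
#' @param de_genes Optional DE gene ids unioned in afterwards (the
#'   expansion frontier is the module seeds only).
#' @return A `SeedSet` list: `genes`, `provenance` (named: module / DE /
#'   expanded, strongest tag kept in that order), `k_used`.
#' @export
expand_seeds <- function(prior, seeds, k = 3, de_genes = NULL) {
  stop_if_not(k >= 0, "k must be >= 0")
  stop_if_not(nrow(prior$edges) > 0, "prior network is empty")
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, prior$nodes)
  if (length(missing) > 0)
    warning(sprintf("%d seed(s) absent from the prior network",
                    length(missing)))
  expanded <- character(0)
  present <- intersect(seeds, prior$nodes)
  if (k > 0 && length(present) > 0) {
    g <- as_igraph(prior, directed = FALSE)
    d <- igraph::distances(g, v = present, mode = "all")
    reach <- colnames(d)[apply(d, 2, min) <= k]
    expanded <- setdiff(reach, seeds)
  }
  genes <- c(seeds, setdiff(de_genes %||% character(0), seeds), expanded)
  genes <- unique(genes)
  prov <- setNames(rep("expanded", length(genes)), genes)
  prov[intersect(genes, de_genes %||% character(0))] <- "DE"
  prov[seeds] <- "module"
  structure(list(genes = genes, provenance = prov, k_used = k),
            class = "SeedSet")
}

#' @export
print.SeedSet <- function(x, ...) {
  tb <- table(x$provenance)
  cat(sprintf("<SeedSet> %d genes (k = %d): %s\n", length(x$genes),
              x$k_used,
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}
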