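#' Downstream neighborhood of a node
#'
#' All nodes reachable from `node` by a directed path of length at most
#' `h`, excluding the node itself.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param node Node id.
#' @param h Maximum path length (>= 1).
#' @return Character vector of node ids.
#' @export
downstream_neighborhood <- function(network, node, h) {
  stop_if_not(node %in% network$nodes, sprintf("unknown node '%s'", node))
  g <- as_igraph(network, directed = TRUE)
  d <- igraph::distances(g, v = node, mode = "out")[1, ]
  setdiff(names(d)[is.finite(d) & d >= 1 & d <= h], node)
}

#' Background subnetwork around a target gene list
#'
#' The induced subgraph on the targets present in the network plus every
#' node with a directed path of length at most `K` to any target (the
#' K-step upstream neighborhood) — the universe within which key driver
#' enrichment is assessed.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param targets Character vector of target gene ids.
#' @param K Upstream step limit (default 6).
#' @return A `DirectedNetwork` induced subgraph.
#' @export
background_subnetwork <- function(network, targets, K = 6) {
  present <- intersect(targets, network$nodes)
  stop_if_not(length(present) > 0, "no target intersects the network")
  g <- as_igraph(network, directed = TRUE)
  d <- igraph::distances(g, v = present, mode = "in")
  upstream <- colnames(d)[apply(d, 2, min) <= K]
  keep <- union(present, upstream)
  e <- network$edges[network$edges$source %in% keep &
                       network$edges$target %in% keep, , drop = FALSE]
  directed_network(e, nodes = keep, directed = TRUE)
}

#' Key driver analysis
#'
#' Within the background subnetwork of the target list, every node is
#' tested for enrichment of its h-step downstream neighborhood (h = 1..K)
#' for the targets, by a one-sided Fisher exact (hypergeometric upper
#' tail) test with the subnetwork's nodes as universe. The candidate node
#' itself is excluded from its own universe, neighborhood and overlap, so a
#' target gene cannot enrich on itself. BH correction is applied jointly
#' across all (node, h) tests; key drivers are nodes significant at any h.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param targets Character vector of target gene ids.
#' @param K Maximum step size (default 6).
#' @param fdr FDR cutoff for the key driver call (default 0.05).
#' @return A `KdaTable` list: `table` (node, h, neighborhood, overlap,
#'   universe, targets_in_universe, p, fdr) and `kd_set`.
#' @export
run_kda <- function(network, targets, K = 6, fdr = 0.05) {
  sub <- background_subnetwork(network, targets, K = K)
  nodes <- sub$nodes
  targets_in <- intersect(targets, nodes)
  if (length(setdiff(nodes, targets_in)) < 2)
    warning("degenerate universe: fewer than 2 non-target nodes")
  g <- as_igraph(sub, directed = TRUE)
  D <- igraph::distances(g, mode = "out")
  is_t <- nodes %in% targets_in
  rows <- vector("list", length(nodes) * K)
  ri <- 0
  for (vi in seq_along(nodes)) {
    dv <- D[nodes[vi], ]
    U <- length(nodes)
    # the node's own target membership never counts toward its enrichment
    Tn <- sum(is_t) - is_t[vi]
    for (h in seq_len(K)) {
      nb <- which(is.finite(dv) & dv >= 1 & dv <= h)
      nb <- setdiff(nb, vi)
      ov <- sum(is_t[nb])
      p <- phyper(ov - 1, Tn, U - Tn, length(nb), lower.tail = FALSE)
      ri <- ri + 1
      rows[[ri]] <- data.frame(node = nodes[vi], h = h,
                               neighborhood = length(nb), overlap = ov,
                               universe = U, targets_in_universe = Tn,
                               p = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows[seq_len(ri)])
  tab$fdr <- bh_adjust(tab$p)
  kd_set <- sort(unique(tab$node[tab$fdr < fdr]))
  structure(list(table = tab, kd_set = kd_set, K = K,
                 universe_nodes = nodes, targets = targets_in),
            class = "KdaTable")
}

#' @export
print.KdaTable <- function(x, ...) {
  cat(sprintf("<KdaTable> %d nodes x K=%d tests, %d key drivers\n",
              length(x$universe_nodes), x$K, length(x$kd_set)))
  invisible(x)
}

#' Count key driver appearances across analyses
#'
#' A gene's appearance count is the number of (network, target list)
#' analyses in which it was called a key driver; repeated appearances
#' across independently learned networks are the main evidence for a
#' driver. Also reports the AS/ApP stream intersection and the genes at or
#' above the appearance threshold (3 by convention).
#'
#' @param kda_results Named list of `KdaTable`s; names like "AS_IR_de" are
#'   used to split streams (an element's stream is the part before the
#'   first underscore).
#' @param threshold Minimum appearances for the consensus list (default 3).
#' @return List with `appearances` (named counts), `consensus` (genes at or
#'   above threshold), `stream_intersection` (genes appearing in both AS
#'   and ApP analyses).
#' @export
count_appearances <- function(kda_results, threshold = 3) {
  stop_if_not(length(kda_results) >= 1, "need at least one KDA result")
  all_kd <- lapply(kda_results, function(r) r$kd_set)
  genes <- sort(unique(unlist(all_kd)))
  app <- setNames(vapply(genes, function(g) {
    sum(vapply(all_kd, function(s) g %in% s, NA))
  }, 0L), genes)
  app <- sort(app, decreasing = TRUE)
  streams <- sub("_.*$", "", names(kda_results) %||% rep("", 0))
  inter <- character(0)
  if (all(c("AS", "ApP") %in% streams)) {
    as_kd <- unique(unlist(all_kd[streams == "AS"]))
    app_kd <- unique(unlist(all_kd[streams == "ApP"]))
    inter <- intersect(as_kd, app_kd)
  }
  list(appearances = app, consensus = names(app)[app >= threshold],
       stream_intersection = sort(inter))
}

#' DE proximity score of a key driver
#'
#' Sum over differentially expressed genes reachable from `kd` by a
#' directed path of the inverse shortest-path length 1/d; unreachable
#' genes contribute 0 and the driver itself is excluded. High scores mean
#' many DE genes sit a short directed distance downstream.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param kd Key driver node id.
#' @param de_genes Character vector of DE gene ids.
#' @return Numeric score (>= 0).
#' @export
de_proximity <- function(network, kd, de_genes) {
  stop_if_not(kd %in% network$nodes, sprintf("unknown node '%s'", kd))
  g <- as_igraph(network, directed = TRUE)
  d <- igraph::distances(g, v = kd, mode = "out")[1, ]
  d <- d[setdiff(intersect(de_genes, names(d)), kd)]
  sum(1 / d[is.finite(d) & d >= 1])
}

#' KD dominance score
#'
#' Difference between the inverse-path-length sums from `kd` to the other
#' key drivers downstream of it and from upstream key drivers to it:
#' positive scores mark drivers that sit above their peers in the
#' hierarchy.
#'
#' @param network `DirectedNetwork` / `CausalNetwork`.
#' @param kd Key driver node id (member of `kd_set`).
#' @param kd_set Character vector of all key drivers.
#' @return Numeric score (sign carries the hierarchy direction).
#' @export
kd_dominance <- function(network, kd, kd_set) {
  stop_if_not(kd %in% network$nodes, sprintf("unknown node '%s'", kd))
  others <- setdiff(intersect(kd_set, network$nodes), kd)
  if (length(others) == 0) return(0)
  g <- as_igraph(network, directed = TRUE)
  down <- igraph::distances(g, v = kd, mode = "out")[1, others]
  up <- igraph::distances(g, v = kd, mode = "in")[1, others]
  sum(1 / down[is.finite(down) & down >= 1]) -
    sum(1 / up[is.finite(up) & up >= 1])
}

#' Rank key drivers by appearances and path scores
#'
#' Builds the summary ranking table: per gene, appearance count across
#' analyses, DE-proximity score (summed over the supplied networks) and
#' KD-dominance score, sorted by appearances then DE proximity.
#'
#' @param networks Named list of `CausalNetwork`s.
#' @param kda_results Named list of `KdaTable`s (names aligned with the
#'   analyses run).
#' @param de_lists Named list (by network name) of DE gene id vectors used
#'   for the proximity score.
#' @param threshold Appearance threshold for inclusion (default 3).
#' @return Data.frame (gene, appearances, de_proximity, kd_dominance).
#' @export
kd_scores <- function(networks, kda_results, de_lists, threshold = 3) {
  app <- count_appearances(kda_results, threshold = threshold)
  genes <- app$consensus
  if (length(genes) == 0)
    return(data.frame(gene = character(0), appearances = integer(0),
                      de_proximity = numeric(0), kd_dominance = numeric(0)))
  prox <- vapply(genes, function(g) {
    sum(vapply(names(networks), function(nm) {
      net <- networks[[nm]]
      if (!g %in% net$nodes) return(0)
      de_proximity(net, g, de_lists[[nm]] %||% character(0))
    }, 0))
  }, 0)
  dom <- vapply(genes, function(g) {
    sum(vapply(networks, function(net) {
      if (!g %in% net$nodes) return(0)
      kd_dominance(net, g, genes)
    }, 0))
  }, 0)
  out <- data.frame(gene = genes,
                    appearances = unname(app$appearances[genes]),
                    de_proximity = unname(prox),
                    kd_dominance = unname(dom),
                    stringsAsFactors = FALSE)
  out[order(-out$appearances, -out$de_proximity), , drop = FALSE]
}
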