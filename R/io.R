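#' Read a genes-by-samples count matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix, genes in rows, samples in columns.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a genes-by-samples count (or expression) matrix to TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path Path to a CSV with one row per sample.
#' @return A data.frame.
#' @export
read_metadata_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write sample metadata to CSV
#' @param metadata Data.frame of sample annotations.
#' @param path Output path.
#' @export
write_metadata_csv <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prior interaction network from SIF or 2-column TSV
#'
#' SIF rows are `source  interaction  target`; 2-column rows are
#' `source  target`. Direction is not trusted for priors: the network is
#' marked undirected.
#'
#' @param path Path to the edge-list file.
#' @return A `DirectedNetwork` (see [directed_network()]) with
#'   `directed = FALSE`.
#' @export
read_sif <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) >= 3) {
    edges <- data.frame(source = df[[1]], target = df[[3]],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = df[[1]], target = df[[2]],
                        stringsAsFactors = FALSE)
  }
  directed_network(edges, directed = FALSE)
}

#' Write a network to SIF (`source  interaction  target`)
#' @param network A `DirectedNetwork`.
#' @param path Output path.
#' @param interaction Interaction label to stamp on every row.
#' @export
write_sif <- function(network, path, interaction = "interacts") {
  df <- data.frame(network$edges$source, interaction, network$edges$target)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB layout: set name, description, then member genes, all
#' tab-separated, one set per line.
#'
#' @param path Path to a .gmt file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a directed (or undirected) network object
#'
#' Lightweight edge-list container used for priors, truth DAGs and learned
#' networks. Nodes are gene ids; edges optionally carry a provenance or
#' orientation tag.
#'
#' @param edges Data.frame with columns `source`, `target` and optionally
#'   extra annotation columns.
#' @param nodes Character vector of node ids; defaults to the ids appearing
#'   in `edges`.
#' @param directed Logical; whether edge direction is meaningful.
#' @return An object of class `DirectedNetwork`.
#' @export
directed_network <- function(edges, nodes = NULL, directed = TRUE) {
  stop_if_not(all(c("source", "target") %in% names(edges)),
              "edges must have source and target columns")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  nodes <- unique(c(nodes, edges$source, edges$target))
  structure(list(edges = edges, nodes = nodes, directed = directed),
            class = "DirectedNetwork")
}

#' @export
print.DirectedNetwork <- function(x, ...) {
  cat(sprintf("<DirectedNetwork> %d nodes, %d %s edges\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# igraph view of a DirectedNetwork; isolated nodes are kept.
as_igraph <- function(network, directed = network$directed) {
  igraph::graph_from_data_frame(
    network$edges[, c("source", "target")],
    directed = directed, vertices = data.frame(name = network$nodes))
}

#' Write a directed network as an edge-list TSV
#' @param network A `DirectedNetwork`.
#' @param path Output path.
#' @export
write_edgelist <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
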