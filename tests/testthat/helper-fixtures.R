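# Shared fixtures, built lazily once per test run, plus independent oracles
# used across files. Oracles deliberately use plain loops so they share no
# code path with the package implementation.

.fix <- new.env()

small_params <- function(seed = 42) {
  sim_params(n_donors = 30, clones_per_donor = 2, n_genes = 300,
             n_modules = 3, module_size = c(40, 60), n_kd = 3,
             kd_out_degree = c(10, 15), seed = seed)
}

small_cohort <- function() {
  if (is.null(.fix$cohort)) .fix$cohort <- simulate_cohort(small_params())
  .fix$cohort
}

small_residuals <- function() {
  if (is.null(.fix$res)) {
    ch <- small_cohort()
    kept <- filter_low_expression(ch$counts)
    lc <- log_cpm(kept, tmm_factors(kept))
    .fix$res <- adjust_covariates(lc, ch$metadata,
                                  fixed = c("sex", "age", "bmi"),
                                  random = c("batch", "rna_kit"))
  }
  .fix$res
}

small_prior <- function() {
  if (is.null(.fix$prior))
    .fix$prior <- simulate_prior_network(small_cohort()$truth,
                                         extra_edge_frac = 0.5, seed = 7)
  .fix$prior
}

# random DAG as an edge data.frame over nodes n1..n (edges respect index
# order, so acyclicity holds by construction)
random_dag <- function(n, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n))
  src <- character(0); tgt <- character(0)
  for (i in seq_len(n - 1)) {
    to <- which(runif(n - i) < p_edge) + i
    src <- c(src, rep(nodes[i], length(to)))
    tgt <- c(tgt, nodes[to])
  }
  list(edges = data.frame(source = src, target = tgt,
                          stringsAsFactors = FALSE),
       nodes = nodes)
}

# Floyd-Warshall shortest directed path lengths (brute force oracle)
fw_distances <- function(edges, nodes) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (e in seq_len(nrow(edges)))
    D[edges$source[e], edges$target[e]] <- 1
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# exact hypergeometric upper-tail by summation over the support
hyper_tail_oracle <- function(overlap, n_targets, universe, draw) {
  if (draw == 0 || n_targets == 0) return(if (overlap <= 0) 1 else 0)
  kmax <- min(draw, n_targets)
  if (overlap > kmax) return(0)
  ks <- max(overlap, max(0, draw - (universe - n_targets))):kmax
  sum(exp(lchoose(n_targets, ks) + lchoose(universe - n_targets, draw - ks) -
            lchoose(universe, draw)))
}

# definitional BH step-up (independent of stats::p.adjust)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, n * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# undirected BFS ball of radius k around seed set (expansion oracle)
bfs_ball <- function(edges, nodes, seeds, k) {
  adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (e in seq_len(nrow(edges))) {
    a <- edges$source[e]; b <- edges$target[e]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- intersect(seeds, nodes)
  frontier <- seen
  steps <- 0
  while (steps < k && length(frontier) > 0) {
    steps <- steps + 1
    frontier <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, frontier)
  }
  sort(unique(c(seeds, seen)))
}
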