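#' Cis-eQTL scan for structural network priors
#'
#' Per gene, residual expression is regressed on the dosage of every marker
#' within `window` bp of the gene's transcription start site (after a minor
#' allele frequency filter); the best marker's association is recorded and
#' Benjamini-Hochberg correction is applied across genes. Genes significant
#' at `fdr_cutoff` become root genes: during network learning they accept
#' no parents, since a cis variant is an exogenous source of variation.
#'
#' @param dosages Numeric matrix markers x donors (0/1/2 dosages).
#' @param residuals Donor-level `ResidualMatrix` (ApP stream) or matrix
#'   whose columns match the dosage donors.
#' @param gene_positions Data.frame (gene, chr, tss).
#' @param marker_positions Data.frame (marker, chr, pos).
#' @param window Cis window in bp around the TSS (default 1e6, inclusive).
#' @param maf_min Minor-allele-frequency filter (default 0.01).
#' @param fdr_cutoff Root-gene significance cutoff (default 0.05).
#' @return An `EqtlPrior` list: `table` (gene, marker, beta, p, fdr) and
#'   `root_genes`.
#' @export
cis_eqtl_scan <- function(dosages, residuals, gene_positions,
                          marker_positions, window = 1e6,
                          maf_min = 0.01, fdr_cutoff = 0.05) {
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  donors <- intersect(colnames(Y), colnames(dosages))
  stop_if_not(length(donors) >= 3, "need >= 3 shared donors")
  Y <- Y[, donors, drop = FALSE]
  D <- dosages[, donors, drop = FALSE]
  maf <- rowMeans(D) / 2
  maf <- pmin(maf, 1 - maf)
  D <- D[maf >= maf_min & apply(D, 1, sd) > 0, , drop = FALSE]
  n <- length(donors)

  rows <- list()
  mp <- marker_positions[marker_positions$marker %in% rownames(D), ]
  for (gi in seq_len(nrow(gene_positions))) {
    g <- gene_positions$gene[gi]
    if (!g %in% rownames(Y)) next
    here <- mp$chr == gene_positions$chr[gi] &
      abs(mp$pos - gene_positions$tss[gi]) <= window
    mk <- mp$marker[here]
    if (length(mk) == 0) next
    y <- Y[g, ]
    r <- as.vector(cor(y, t(D[mk, , drop = FALSE])))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    pp <- 2 * pt(-abs(tt), df = n - 2)
    best <- which.min(pp)
    beta <- r[best] * sd(y) / sd(D[mk[best], ])
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, marker = mk[best], beta = beta, p = pp[best],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(gene = character(0),
                                      marker = character(0),
                                      beta = numeric(0), p = numeric(0))
  tab$fdr <- if (nrow(tab) > 0) bh_adjust(tab$p) else numeric(0)
  structure(list(table = tab, root_genes = tab$gene[tab$fdr < fdr_cutoff]),
            class = "EqtlPrior")
}

#' @export
print.EqtlPrior <- function(x, ...) {
  cat(sprintf("<EqtlPrior> %d genes scanned, %d root genes\n",
              nrow(x$table), length(x$root_genes)))
  invisible(x)
}

# --- internal scoring machinery -------------------------------------------
# Gaussian BIC on standardized data: node score = -n/2 log(rss/n) minus
# 0.5 log(n) per parent. Only differences matter, so constants are dropped.

node_rss <- function(C, y, P) {
  if (length(P) == 0) return(C[y, y])
  b <- solve(C[P, P, drop = FALSE], C[P, y])
  max(C[y, y] - sum(C[y, P] * b), 1e-12)
}

# Vectorized score gain of adding each candidate parent x to node y.
add_deltas <- function(C, y, P, n, pen, allowed_col) {
  p <- ncol(C)
  rss_old <- node_rss(C, y, P)
  if (length(P) == 0) {
    cyx <- C[y, ]
    vx <- rep(1, p)
  } else {
    B <- solve(C[P, P, drop = FALSE])
    CP <- C[P, , drop = FALSE]
    BC <- B %*% CP
    cyx <- C[y, ] - as.vector(C[y, P, drop = FALSE] %*% BC)
    vx <- 1 - colSums(CP * BC)
  }
  rss_new <- rss_old - ifelse(vx > 1e-10, cyx^2 / vx, 0)
  delta <- -0.5 * n * (log(pmax(rss_new, 1e-12)) - log(rss_old)) - pen
  delta[!allowed_col] <- -Inf
  delta[c(y, P)] <- -Inf
  delta[vx <= 1e-10] <- -Inf
  delta
}

del_deltas <- function(C, y, P, n, pen) {
  rss_old <- node_rss(C, y, P)
  vapply(seq_along(P), function(i) {
    rss_new <- node_rss(C, y, P[-i])
    -0.5 * n * (log(rss_new) - log(rss_old)) + pen
  }, 0)
}

# Children adjacency lists from parent lists.
children_of <- function(pa, p) {
  ch <- rep(list(integer(0)), p)
  for (y in seq_len(p)) for (x in pa[[y]]) ch[[x]] <- c(ch[[x]], y)
  ch
}

# Transitive closure (R[i, j] = directed path i -> j) of an acyclic graph:
# descendants are accumulated bottom-up in reverse topological order.
reach_from_edges <- function(pa, p) {
  ch <- children_of(pa, p)
  indeg <- lengths(pa)
  # Kahn topological order
  order <- integer(0)
  queue <- which(indeg == 0)
  indeg2 <- indeg
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (c2 in ch[[v]]) {
      indeg2[c2] <- indeg2[c2] - 1
      if (indeg2[c2] == 0) queue <- c(queue, c2)
    }
  }
  R <- matrix(FALSE, p, p)
  for (v in rev(order)) {
    kids <- ch[[v]]
    if (length(kids) == 0) next
    row <- R[v, ]
    row[kids] <- TRUE
    if (length(kids) == 1) row <- row | R[kids, ]
    else row <- row | (colSums(R[kids, , drop = FALSE]) > 0)
    R[v, ] <- row
  }
  R
}

# Is there a directed path x ~> y that does not use the direct edge x -> y?
path_avoiding_edge <- function(pa, p, x, y) {
  ch <- children_of(pa, p)
  ch[[x]] <- setdiff(ch[[x]], y)
  seen <- logical(p)
  frontier <- ch[[x]]
  while (length(frontier) > 0) {
    if (y %in% frontier) return(TRUE)
    seen[frontier] <- TRUE
    frontier <- unique(unlist(ch[frontier]))
    frontier <- frontier[!seen[frontier]]
  }
  FALSE
}

hill_climb <- function(C, n, allowed, roots_idx, max_parents, init_pa = NULL) {
  p <- ncol(C)
  pen <- 0.5 * log(n)
  pa <- init_pa %||% rep(list(integer(0)), p)
  R <- reach_from_edges(pa, p)
  is_root <- seq_len(p) %in% roots_idx

  addc <- vector("list", p) # cached add-delta vectors per target node
  delc <- vector("list", p)
  recache <- function(y) {
    if (is_root[y]) {
      addc[[y]] <<- rep(-Inf, p)
      delc[[y]] <<- numeric(0)
      return(invisible())
    }
    addc[[y]] <<- if (length(pa[[y]]) >= max_parents) rep(-Inf, p)
                  else add_deltas(C, y, pa[[y]], n, pen, allowed[, y])
    delc[[y]] <<- del_deltas(C, y, pa[[y]], n, pen)
  }
  for (y in seq_len(p)) recache(y)

  apply_add <- function(x, y) {
    pa[[y]] <<- c(pa[[y]], x)
    pre <- c(which(R[, x]), x)
    post <- c(which(R[y, ]), y)
    R[pre, post] <<- TRUE
    recache(y)
  }
  apply_del <- function(x, y) {
    pa[[y]] <<- setdiff(pa[[y]], x)
    R <<- reach_from_edges(pa, p)
    recache(y)
  }

  repeat {
    best <- list(delta = 1e-8, kind = "none")
    for (y in seq_len(p)) {
      av <- addc[[y]]
      if (!all(av == -Inf)) {
        # cycle mask: cannot add x -> y when y already reaches x
        av[R[y, ]] <- -Inf
        bx <- which.max(av)
        if (av[bx] > best$delta)
          best <- list(delta = av[bx], kind = "add", x = bx, y = y)
      }
      if (length(delc[[y]]) > 0) {
        bi <- which.max(delc[[y]])
        if (delc[[y]][bi] > best$delta)
          best <- list(delta = delc[[y]][bi], kind = "del",
                       x = pa[[y]][bi], y = y)
      }
    }
    # reversals: del(x->y) + add(y as parent of x); collect candidate gains
    # and verify cycle legality lazily, best first
    rev_gain <- numeric(0); rev_x <- integer(0); rev_y <- integer(0)
    for (y in seq_len(p)) {
      for (i in seq_along(pa[[y]])) {
        x <- pa[[y]][i]
        if (is_root[x] || length(pa[[x]]) >= max_parents) next
        gain <- delc[[y]][i] + addc[[x]][y]
        if (is.finite(gain) && gain > best$delta) {
          rev_gain <- c(rev_gain, gain)
          rev_x <- c(rev_x, x); rev_y <- c(rev_y, y)
        }
      }
    }
    if (length(rev_gain) > 0) {
      for (i in order(-rev_gain)) {
        if (rev_gain[i] <= best$delta) break
        if (!path_avoiding_edge(pa, p, rev_x[i], rev_y[i])) {
          best <- list(delta = rev_gain[i], kind = "rev",
                       x = rev_x[i], y = rev_y[i])
          break
        }
      }
    }
    if (best$kind == "none") break
    if (best$kind == "add") apply_add(best$x, best$y)
    if (best$kind == "del") apply_del(best$x, best$y)
    if (best$kind == "rev") {
      apply_del(best$x, best$y)
      apply_add(best$y, best$x)
    }
  }
  score <- sum(vapply(seq_len(p), function(y) {
    -0.5 * n * log(node_rss(C, y, pa[[y]])) - pen * length(pa[[y]])
  }, 0))
  list(pa = pa, score = score)
}

#' Learn a causal network over the seeding genes
#'
#' Greedy hill climbing over add/delete/reverse edge moves maximizing the
#' Gaussian BIC, under three constraints: the graph stays acyclic, cis-eQTL
#' root genes accept no parents, and candidate edges are restricted to gene
#' pairs adjacent in the prior network or sharing a co-expression module
#' (the search-space prior). The best of `restarts` seeded restarts is
#' returned; score-equivalent edges are then oriented by the additive-noise
#' test (see [orient_equivalent_edges()]) when `orient = TRUE`.
#'
#' @param residuals `ResidualMatrix` or matrix (genes x units).
#' @param seed_set `SeedSet` from [expand_seeds()] or a character vector of
#'   gene ids.
#' @param prior Optional `DirectedNetwork` prior restricting candidate
#'   edges.
#' @param eqtl Optional `EqtlPrior`; its `root_genes` accept no parents.
#' @param modules Optional named gene -> label vector; same-module pairs
#'   are candidate edges.
#' @param max_parents Maximum parents per node (default 3).
#' @param restarts Number of seeded restarts (default 2).
#' @param seed Integer seed.
#' @param orient Run the additive-noise orientation pass (default TRUE).
#' @param bic_tol Score-equivalence tolerance for that pass (default 2).
#' @return A `CausalNetwork`: nodes, directed `edges` (source, target,
#'   orientation_source), `score`, `roots`.
#' @export
learn_network <- function(residuals, seed_set, prior = NULL, eqtl = NULL,
                          modules = NULL, max_parents = 3, restarts = 2,
                          seed = 1, orient = TRUE, bic_tol = 2) {
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  want <- if (inherits(seed_set, "SeedSet")) seed_set$genes
          else as.character(seed_set)
  absent <- setdiff(want, rownames(Y))
  if (length(absent) > 0)
    warning(sprintf("%d seed gene(s) absent from residuals; dropped",
                    length(absent)))
  genes <- intersect(want, rownames(Y))
  stop_if_not(length(genes) >= 2, "need >= 2 seed genes with data")
  X <- t(Y[genes, , drop = FALSE])
  n <- nrow(X)
  if (n < 30) warning("fewer than 30 units; network learning is unstable")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    genes <- genes[sds > 0]
    X <- X[, sds > 0, drop = FALSE]
    warning("constant gene(s) dropped")
  }
  X <- scale(X)
  p <- ncol(X)
  C <- crossprod(X) / (n - 1)

  allowed <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  restricted <- FALSE
  if (!is.null(prior)) {
    restricted <- TRUE
    pe <- prior$edges
    keep <- pe$source %in% genes & pe$target %in% genes
    if (any(keep)) {
      ij <- cbind(match(pe$source[keep], genes), match(pe$target[keep], genes))
      allowed[ij] <- TRUE
      allowed[ij[, 2:1, drop = FALSE]] <- TRUE
    }
  }
  if (!is.null(modules)) {
    restricted <- TRUE
    labs <- modules[genes]
    labs[is.na(labs)] <- 0
    for (m in unique(labs[labs > 0])) {
      i <- which(labs == m)
      allowed[i, i] <- TRUE
    }
  }
  if (!restricted) allowed[] <- TRUE
  diag(allowed) <- FALSE

  roots <- intersect(if (!is.null(eqtl)) eqtl$root_genes else character(0),
                     genes)
  roots_idx <- match(roots, genes)

  best <- NULL
  for (r in seq_len(max(restarts, 1))) {
    init <- NULL
    if (r > 1) {
      init <- with_seed(derive_seed(seed, paste0("restart", r)), {
        pa0 <- rep(list(integer(0)), p)
        cand <- which(allowed, arr.ind = TRUE)
        cand <- cand[!(cand[, 2] %in% roots_idx), , drop = FALSE]
        if (nrow(cand) > 0) {
          pick <- cand[sample(nrow(cand), min(nrow(cand), p %/% 3)), ,
                       drop = FALSE]
          R0 <- matrix(FALSE, p, p)
          for (e in seq_len(nrow(pick))) {
            x <- pick[e, 1]; y <- pick[e, 2]
            if (R0[y, x] || x == y) next
            if (length(pa0[[y]]) >= max_parents || x %in% pa0[[y]]) next
            pa0[[y]] <- c(pa0[[y]], x)
            pre <- c(which(R0[, x]), x); post <- c(which(R0[y, ]), y)
            R0[pre, post] <- TRUE
          }
        }
        pa0
      })
    }
    fit <- hill_climb(C, n, allowed, roots_idx, max_parents, init_pa = init)
    if (is.null(best) || fit$score > best$score) best <- fit
  }

  edges <- do.call(rbind, lapply(seq_len(p), function(y) {
    if (length(best$pa[[y]]) == 0) return(NULL)
    data.frame(source = genes[best$pa[[y]]], target = genes[y],
               orientation_source = "score", stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(source = character(0), target = character(0),
                        orientation_source = character(0))
  net <- structure(list(edges = edges, nodes = genes, directed = TRUE,
                        score = best$score, roots = roots,
                        n_units = n, max_parents = max_parents),
                   class = c("CausalNetwork", "DirectedNetwork"))
  if (orient && nrow(edges) > 0)
    net <- orient_equivalent_edges(net, Y[genes, , drop = FALSE],
                                   bic_tol = bic_tol)
  net
}

#' Orient score-equivalent edges with an additive-noise test
#'
#' For each edge whose reversal leaves the network BIC within `bic_tol`
#' (statistically equivalent structures), a cubic-polynomial regression is
#' fitted in both directions and the direction whose residuals are less
#' dependent on the predictor (distance correlation) is kept — the
#' additive-noise criterion exploiting the nonlinearity of biochemical
#' response curves. Near-ties and linear-Gaussian pairs are declared
#' unresolvable and keep their original orientation. Reversals that would
#' create a cycle, or point into a root gene, are skipped.
#'
#' @param network A `CausalNetwork`.
#' @param residuals Matrix or `ResidualMatrix` with the network's genes.
#' @param bic_tol Score-equivalence tolerance (default 2).
#' @param dcor_margin Minimum distance-correlation difference required to
#'   call a direction (default 0.05, above the finite-sample fluctuation
#'   of the difference for linear-Gaussian pairs at n of a few hundred).
#' @return The network with edges possibly reversed;
#'   `orientation_source = "bottom_up"` marks edges the test decided.
#' @export
orient_equivalent_edges <- function(network, residuals, bic_tol = 2,
                                    dcor_margin = 0.05) {
  Y <- if (inherits(residuals, "ResidualMatrix")) residuals$values
       else residuals
  genes <- network$nodes
  X <- scale(t(Y[genes, , drop = FALSE]))
  n <- nrow(X)
  C <- crossprod(X) / (n - 1)
  pen <- 0.5 * log(n)
  edges <- network$edges
  pa <- lapply(genes, function(g) match(edges$source[edges$target == g],
                                        genes))
  names(pa) <- genes
  roots <- network$roots

  for (e in seq_len(nrow(edges))) {
    xg <- edges$source[e]; yg <- edges$target[e]
    if (xg %in% roots) next
    xi <- match(xg, genes); yi <- match(yg, genes)
    if (length(pa[[xg]]) >= (network$max_parents %||% 3)) next
    d_rev <- del_deltas(C, yi, pa[[yg]], n, pen)[match(xi, pa[[yg]])] +
      add_deltas(C, xi, pa[[xg]], n, pen,
                 rep(TRUE, length(genes)))[yi]
    if (!is.finite(d_rev) || abs(d_rev) >= bic_tol) next
    # cycle check: alternate path x ~> y without the direct edge
    if (path_avoiding_edge(pa, length(genes), xi, yi)) next
    x <- X[, xi]; y <- X[, yi]
    r_fwd <- stats::residuals(lm(y ~ poly(x, 3)))
    r_bwd <- stats::residuals(lm(x ~ poly(y, 3)))
    d_fwd <- dcor_xy(x, r_fwd)
    d_bwd <- dcor_xy(y, r_bwd)
    if (d_bwd < d_fwd - dcor_margin) {
      # reverse: evidence favors y -> x
      pa[[yg]] <- setdiff(pa[[yg]], xi)
      pa[[xg]] <- c(pa[[xg]], yi)
      edges$source[e] <- yg
      edges$target[e] <- xg
      edges$orientation_source[e] <- "bottom_up"
    } else if (d_fwd < d_bwd - dcor_margin) {
      edges$orientation_source[e] <- "bottom_up"
    }
    # otherwise: unresolvable; original orientation and tag kept
  }
  network$edges <- edges
  network
}

#' @export
print.CausalNetwork <- function(x, ...) {
  cat(sprintf("<CausalNetwork> %d nodes, %d edges, %d roots, score %.1f\n",
              length(x$nodes), nrow(x$edges), length(x$roots), x$score))
  invisible(x)
}
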