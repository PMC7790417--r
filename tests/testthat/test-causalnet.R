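test_that("cis scan window, null calibration and planted power behave", {
  set.seed(31)
  n <- 100
  donors <- paste0("d", 1:n)
  # two markers: one exactly at the 1 Mb boundary, one 1 bp beyond
  dos <- matrix(rbinom(2 * n, 2, 0.4), 2, n,
                dimnames = list(c("mIn", "mOut"), donors))
  genes <- data.frame(gene = "g1", chr = "1", tss = 5e6)
  markers <- data.frame(marker = c("mIn", "mOut"), chr = "1",
                        pos = c(5e6 + 1e6, 5e6 + 1e6 + 1))
  y <- matrix(rnorm(n), 1, n, dimnames = list("g1", donors))
  sc <- cis_eqtl_scan(dos, y, genes, markers)
  expect_equal(sc$table$marker, "mIn")   # boundary in, 1,000,001 out

  # power: planted beta = 1.0 detected in >= 9/10 simulations
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    d1 <- matrix(rbinom(n, 2, 0.3), 1, n, dimnames = list("m1", donors))
    yy <- matrix(1.0 * d1[1, ] + rnorm(n), 1, n,
                 dimnames = list("g1", donors))
    sc2 <- cis_eqtl_scan(d1, yy, genes,
                         data.frame(marker = "m1", chr = "1", pos = 5.2e6))
    hits <- hits + ("g1" %in% sc2$root_genes)
  }
  expect_gte(hits, 9)

  # genome-wide null: essentially nothing at FDR < 0.05
  set.seed(77)
  ng <- 60
  dosN <- matrix(rbinom(ng * n, 2, 0.4), ng, n,
                 dimnames = list(paste0("m", 1:ng), donors))
  yN <- matrix(rnorm(ng * n), ng, n,
               dimnames = list(paste0("g", 1:ng), donors))
  gp <- data.frame(gene = paste0("g", 1:ng), chr = "1",
                   tss = 2.5e6 * (1:ng))
  mp <- data.frame(marker = paste0("m", 1:ng), chr = "1",
                   pos = 2.5e6 * (1:ng) + 1e5)
  scN <- cis_eqtl_scan(dosN, yN, gp, mp)
  expect_lte(length(scN$root_genes), 1)
})

test_that("network learning handles null, exogenous and root-constrained pairs", {
  # all-independent variables: empty edge set
  set.seed(41)
  Y0 <- matrix(rnorm(5 * 400), 5, 400,
               dimnames = list(paste0("g", 1:5), NULL))
  net0 <- learn_network(Y0, paste0("g", 1:5), restarts = 1, seed = 1)
  expect_equal(nrow(net0$edges), 0)

  # nonlinear exogenous cause: learned and oriented x -> y in >= 90%
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(200)
    y <- x^3 / 3 + rnorm(200, sd = 0.4)
    net <- learn_network(rbind(x = x, y = y), c("x", "y"),
                         restarts = 1, seed = s)
    e <- net$edges
    ok <- ok + (nrow(e) == 1 && e$source == "x" && e$target == "y")
  }
  expect_gte(ok, 18)

  # a correlated partner of a root gene: edge always leaves the root
  eq <- structure(list(root_genes = "r"), class = "EqtlPrior")
  for (s in 1:5) {
    set.seed(s)
    r <- rnorm(120)
    z <- 0.8 * r + rnorm(120, sd = 0.5)
    net <- learn_network(rbind(r = r, z = z), c("r", "z"), eqtl = eq,
                         restarts = 2, seed = s)
    expect_true(all(net$edges$target != "r"))
    expect_equal(nrow(net$edges), 1)
    expect_equal(net$edges$source, "r")
  }
})

test_that("additive-noise orientation resolves cubic but not Gaussian pairs", {
  set.seed(55)
  x <- rnorm(300)
  y <- x^3 / 3 + rnorm(300, sd = 0.3)
  net <- structure(list(
    edges = data.frame(source = "y", target = "x",
                       orientation_source = "score",
                       stringsAsFactors = FALSE),
    nodes = c("x", "y"), directed = TRUE, roots = character(0),
    score = 0, max_parents = 3),
    class = c("CausalNetwork", "DirectedNetwork"))
  fixed <- orient_equivalent_edges(net, rbind(x = x, y = y), bic_tol = 1e9)
  expect_equal(fixed$edges$source, "x")
  expect_equal(fixed$edges$target, "y")
  expect_equal(fixed$edges$orientation_source, "bottom_up")

  # exactly bivariate Gaussian: unresolvable, original orientation kept
  a <- rnorm(300)
  b <- 0.7 * a + rnorm(300, sd = 0.6)
  netg <- net
  netg$nodes <- c("a", "b")
  netg$edges <- data.frame(source = "b", target = "a",
                           orientation_source = "score",
                           stringsAsFactors = FALSE)
  keptg <- orient_equivalent_edges(netg, rbind(a = a, b = b), bic_tol = 1e9)
  expect_equal(keptg$edges$source, "b")
  expect_equal(keptg$edges$orientation_source, "score")
})

test_that("learned networks are acyclic with root in-degree zero", {
  ch <- small_cohort()
  res <- small_residuals()
  pr <- small_prior()
  app <- average_per_patient(res, ch$metadata$donor_id)
  eq <- cis_eqtl_scan(ch$genotypes$dosages, app,
                      ch$genotypes$gene_pos, ch$genotypes$marker_pos)
  ma <- ch$truth$module_assignment[rownames(res$values)]
  ss <- suppressWarnings(expand_seeds(pr, names(ma)[ma > 0], k = 3))
  for (s in 1:3) {
    net <- suppressWarnings(learn_network(res, ss, prior = pr, eqtl = eq,
                                          restarts = 1, seed = s))
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = TRUE,
                                       vertices = data.frame(name = net$nodes))
    expect_true(igraph::is_dag(g))
    expect_equal(sum(net$edges$target %in% net$roots), 0)
    expect_true(max(table(factor(net$edges$target, net$nodes))) <= 3)
  }
})

test_that("structure recovery improves with sample size on planted SEMs", {
  shd <- function(net, truth_edges, nodes) {
    key <- function(e) paste(e$source, e$target)
    got <- key(net$edges); want <- key(truth_edges)
    length(setdiff(got, want)) + length(setdiff(want, got))
  }
  run_at <- function(n, seed) {
    set.seed(seed)
    p <- 10
    nodes <- paste0("v", 1:p)
    # chain-with-branches DAG, sources exogenous and declared as roots
    edges <- data.frame(source = nodes[c(1, 1, 2, 3, 4, 5, 6, 7)],
                        target = nodes[c(2, 3, 4, 5, 6, 7, 8, 9)])
    X <- matrix(rnorm(p * n), p, n, dimnames = list(nodes, NULL))
    for (i in seq_len(nrow(edges)))
      X[edges$target[i], ] <- 0.8 * X[edges$source[i], ] +
        sqrt(1 - 0.64) * X[edges$target[i], ]
    eq <- structure(list(root_genes = c("v1", "v10")), class = "EqtlPrior")
    net <- learn_network(X, nodes, eqtl = eq, restarts = 1, seed = seed)
    shd(net, edges, nodes)
  }
  small <- vapply(1:10, function(s) run_at(50, s), 0)
  large <- vapply(1:10, function(s) run_at(500, s), 0)
  expect_lte(stats::median(large), stats::median(small))
})
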