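test_that("downstream neighborhoods follow hand BFS", {
  net <- directed_network(data.frame(source = c("a", "b", "c"),
                                     target = c("b", "c", "d")))
  expect_setequal(downstream_neighborhood(net, "a", 2), c("b", "c"))
  expect_setequal(downstream_neighborhood(net, "a", 10), c("b", "c", "d"))
  expect_length(downstream_neighborhood(net, "d", 3), 0)
  expect_error(downstream_neighborhood(net, "zz", 1), "unknown")
})

test_that("background subnetwork is the K-step upstream closure", {
  net <- directed_network(data.frame(source = c("a", "b"),
                                     target = c("b", "c")))
  sub <- background_subnetwork(net, "c", K = 1)
  expect_setequal(sub$nodes, c("b", "c"))
  expect_setequal(background_subnetwork(net, c("a", "b", "c"), K = 1)$nodes,
                  c("a", "b", "c"))
  iso <- directed_network(data.frame(source = "a", target = "b"),
                          nodes = c("a", "b", "lone"))
  expect_setequal(background_subnetwork(iso, "lone", K = 3)$nodes, "lone")
  expect_error(background_subnetwork(net, "zz"), "target")
})

test_that("KDA Fisher test equals the closed-form extreme case", {
  # star: v -> 5 targets; 14 decoys each feeding one target keep the
  # universe at 20
  targets <- paste0("t", 1:5)
  decoys <- paste0("d", 1:14)
  edges <- rbind(
    data.frame(source = "v", target = targets),
    data.frame(source = decoys, target = rep(targets[1], 14)))
  net <- directed_network(edges)
  kda <- run_kda(net, targets, K = 1)
  expect_length(kda$universe_nodes, 20)
  row_v <- kda$table[kda$table$node == "v" & kda$table$h == 1, ]
  expect_equal(row_v$overlap, 5)
  expect_equal(row_v$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(row_v$p, hyper_tail_oracle(5, 5, 20, 5), tolerance = 1e-12)
})

test_that("KDA is invariant to node relabeling", {
  dag <- random_dag(30, 0.12, 77)
  net <- directed_network(dag$edges, nodes = dag$nodes)
  set.seed(77)
  targets <- sample(dag$nodes, 8)
  k1 <- run_kda(net, targets, K = 3)
  relab <- setNames(sprintf("x%03d", seq_along(dag$nodes)), dag$nodes)
  e2 <- data.frame(source = unname(relab[dag$edges$source]),
                   target = unname(relab[dag$edges$target]))
  k2 <- run_kda(directed_network(e2, nodes = unname(relab)),
                unname(relab[targets]), K = 3)
  expect_setequal(unname(relab[k1$kd_set]), k2$kd_set)
  t1 <- k1$table[order(k1$table$node, k1$table$h), ]
  t2 <- k2$table[order(match(k2$table$node, relab), k2$table$h), ]
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
})

test_that("random targets rarely produce key drivers", {
  net <- directed_network(random_dag(80, 0.05, 5)$edges)
  set.seed(9)
  empty <- replicate(20, {
    targets <- sample(net$nodes, 15)
    length(suppressWarnings(run_kda(net, targets, K = 6))$kd_set) == 0
  })
  expect_gte(mean(empty), 0.9)
})

test_that("path scores follow hand-computed shortest paths", {
  net <- directed_network(data.frame(source = c("a", "b"),
                                     target = c("b", "c")))
  expect_equal(de_proximity(net, "a", c("b", "c")), 1.5)
  expect_equal(de_proximity(net, "c", c("a", "b")), 0)
  star <- directed_network(data.frame(source = "h",
                                      target = paste0("c", 1:4)))
  expect_equal(de_proximity(star, "h", paste0("c", 1:4)), 4)

  expect_equal(kd_dominance(net, "a", c("a", "b")), 1)
  expect_equal(kd_dominance(net, "b", c("a", "b")), -1)
  iso <- directed_network(data.frame(source = "a", target = "b"),
                          nodes = c("a", "b", "u", "v"))
  expect_equal(kd_dominance(iso, "u", c("u", "v")), 0)
  expect_equal(kd_dominance(iso, "v", c("u", "v")), 0)
})

test_that("pairwise dominance contributions cancel over the KD set", {
  for (seed in 1:5) {
    dag <- random_dag(40, 0.08, seed)
    net <- directed_network(dag$edges, nodes = dag$nodes)
    set.seed(seed)
    kds <- sample(dag$nodes, 8)
    total <- sum(vapply(kds, function(k) kd_dominance(net, k, kds), 0))
    expect_equal(total, 0, tolerance = 1e-12)
  }
})

test_that("appearance counting aggregates across analyses and streams", {
  mk <- function(kd) structure(list(kd_set = kd), class = "KdaTable")
  res <- list(AS_IR_de = mk(c("g1", "g2")), AS_IS_de = mk(c("g1")),
              ApP_IR_de = mk(c("g1", "g3")), ApP_IS_de = mk(c("g1")))
  app <- count_appearances(res, threshold = 3)
  expect_equal(unname(app$appearances["g1"]), 4L)
  expect_equal(app$consensus, "g1")
  expect_setequal(app$stream_intersection, "g1")
  disj <- list(AS_a = mk("g1"), ApP_a = mk("g2"))
  expect_length(count_appearances(disj)$stream_intersection, 0)
})
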