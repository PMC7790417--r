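test_that("simulation is deterministic and validates parameters", {
  p <- small_params(seed = 9)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$dag_edges, b$truth$dag_edges)
  expect_error(sim_params(n_genes = 100, n_modules = 3,
                          module_size = c(40, 60)), "exceed")
  expect_error(sim_params(attenuation = 1.2), "attenuation")
  expect_error(sim_params(dispersion = -1), "dispersion")
})

test_that("planted truth respects its structural invariants", {
  ch <- small_cohort()
  tr <- ch$truth
  g <- igraph::graph_from_data_frame(tr$dag_edges, directed = TRUE)
  expect_true(igraph::is_dag(g))
  for (kd in tr$kd_set) {
    outd <- sum(tr$dag_edges$source == kd)
    expect_gte(outd, 10)
    expect_lte(outd, 15)
  }
  # DE truth sits exactly on KD-downstream genes
  down <- unique(unlist(tr$kd_downstream))
  expect_setequal(names(tr$de_truth)[tr$de_truth != 0], down)
  # donor-level fields are constant within donor
  md <- ch$metadata
  for (f in c("sspg", "group", "sex", "age", "bmi", "ethnicity"))
    expect_true(all(tapply(md[[f]], md$donor_id,
                           function(x) length(unique(x))) == 1))
  expect_true(all(md$sspg[md$group == "IR"] >= 140))
  expect_true(all(md$sspg[md$group == "IS"] < 140))
  expect_true(all(ch$counts >= 0))
  expect_true(all(ch$counts == round(ch$counts)))
})

test_that("null group effect gives no systematic group difference", {
  p <- small_params(seed = 3)
  p$group_effect_size <- 0
  ch <- simulate_cohort(p)
  lc <- log_cpm(ch$counts)
  down <- unique(unlist(ch$truth$kd_downstream))
  group_diff <- function(grp) {
    mean(rowMeans(lc[down, grp == "IR"]) - rowMeans(lc[down, grp == "IS"]))
  }
  obs <- group_diff(ch$metadata$group)
  # donor-level module factors leave correlated noise in the group means;
  # the observed difference must sit inside the donor-permutation null
  donors <- unique(ch$metadata$donor_id)
  set.seed(99)
  null <- replicate(30, {
    g <- setNames(sample(ch$metadata$group[match(donors,
                                                 ch$metadata$donor_id)]),
                  donors)
    group_diff(unname(g[ch$metadata$donor_id]))
  })
  expect_lt(abs(obs), 3 * sd(null) + 0.02)
})

test_that("planted effects point the right way in >=90% of DE genes", {
  ch <- small_cohort()
  lc <- log_cpm(ch$counts)
  de <- ch$truth$de_truth[ch$truth$de_truth != 0]
  diff <- rowMeans(lc[names(de), ch$metadata$group == "IR"]) -
    rowMeans(lc[names(de), ch$metadata$group == "IS"])
  expect_gte(mean(sign(diff) == sign(de)), 0.9)
})

test_that("single-clone cohorts make AS and ApP identical", {
  p <- sim_params(n_donors = 15, clones_per_donor = 1, n_genes = 200,
                  n_modules = 2, module_size = c(30, 40), n_kd = 2,
                  kd_out_degree = c(8, 10), seed = 4)
  ch <- simulate_cohort(p)
  kept <- filter_low_expression(ch$counts)
  lc <- log_cpm(kept, tmm_factors(kept))
  res <- adjust_covariates(lc, ch$metadata, fixed = "sex")
  app <- average_per_patient(res, ch$metadata$donor_id)
  expect_equal(unname(app$values), unname(res$values))
})

test_that("within-module correlation exceeds between-module at defaults", {
  ch <- simulate_cohort(sim_params())   # full default cohort, seed 1
  lc <- log_cpm(ch$counts)
  ma <- ch$truth$module_assignment
  set.seed(1)
  within <- unlist(lapply(1:ch$truth$params$n_modules, function(m) {
    mem <- sample(names(ma)[ma == m], 20)
    cc <- cor(t(lc[mem, ]))
    cc[upper.tri(cc)]
  }))
  mods <- which(ma > 0)
  pick <- replicate(500, sample(names(mods), 2))
  between <- mapply(function(a, b) {
    if (ma[a] == ma[b]) NA else cor(lc[a, ], lc[b, ])
  }, pick[1, ], pick[2, ])
  margin <- mean(abs(within)) - mean(abs(between), na.rm = TRUE)
  expect_gt(margin, 0.1)
})

test_that("prior network adds and removes the stated edge fractions", {
  ch <- small_cohort()
  tr <- ch$truth
  id <- simulate_prior_network(tr, extra_edge_frac = 0, seed = 5)
  expect_setequal(paste(id$edges$source, id$edges$target),
                  paste(tr$dag_edges$source, tr$dag_edges$target))
  half <- simulate_prior_network(tr, extra_edge_frac = 0.5, seed = 5)
  expect_equal(nrow(half$edges), round(1.5 * nrow(tr$dag_edges)))
  half2 <- simulate_prior_network(tr, extra_edge_frac = 0.5, seed = 5)
  expect_identical(half$edges, half2$edges)
  rem <- simulate_prior_network(tr, extra_edge_frac = 0,
                                removal_frac = 0.2, seed = 5)
  expect_equal(nrow(rem$edges), nrow(tr$dag_edges) -
                 round(0.2 * nrow(tr$dag_edges)))
  expect_false(half$directed)
})

test_that("perturbation shifts follow the attenuation schedule", {
  ch <- small_cohort()
  tr <- ch$truth
  pert <- simulate_perturbation(ch, tr, n_per_arm = 4, effect_size = 2.0,
                                seed = 2)
  lay <- pert$layers
  sh <- pert$true_shift
  for (L in 1:3) {
    genes <- names(lay)[lay == L]
    if (length(genes) == 0) next
    expect_equal(unname(abs(sh[genes])), rep(2.0 * 0.5^(L - 1),
                                             length(genes)))
  }
  unreachable <- setdiff(names(tr$module_assignment), names(lay))
  expect_true(all(sh[unreachable] == 0))
  # strict decay of the mean absolute planted shift across layers
  m <- tapply(abs(sh[names(lay)[lay >= 1]]), lay[lay >= 1], mean)
  expect_true(all(diff(m) < 0))
  expect_error(simulate_perturbation(ch, tr, target = "nope"), "unknown")
})

test_that("truth-derived gene sets single out the planted modules", {
  ch <- small_cohort()
  sets <- truth_gene_sets(ch$truth, seed = 3)
  expect_true(any(grepl("GLUCOSE|CHOLESTEROL|LIPID", names(sets))))
  enr <- module_enrichment(ch$truth$module_assignment, sets,
                           universe = names(ch$truth$module_assignment))
  expect_setequal(enr$selected_modules, 1:3)
})
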