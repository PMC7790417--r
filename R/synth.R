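#' Simulation parameters for the synthetic iPSC cohort
#'
#' Bundles every knob of the generator into a validated object. The defaults
#' describe a cohort shaped like a multi-clone iPSC study of insulin
#' resistance: ~100 donors contributing ~3 clonal lines each, donor-level
#' insulin status (IR/IS) with SSPG drawn from the group's distribution,
#' technical covariates (sequencing batch, RNA kit, reprogramming source
#' cell) and biological covariates (sex, age, BMI) with planted effects,
#' block-correlated co-expression modules, and a planted causal DAG whose
#' hub regulators (key drivers) sit upstream of the group-differential genes.
#'
#' @param n_donors Number of donors.
#' @param clones_per_donor Scalar or `c(lo, hi)` range of clonal lines per
#'   donor.
#' @param n_genes Number of genes.
#' @param n_modules Number of co-expression modules.
#' @param module_size `c(lo, hi)` range of module sizes (genes).
#' @param intra_module_corr Target within-module correlation floor induced by
#'   the module latent factor, in (0, 1).
#' @param n_kd Number of planted key drivers (assigned round-robin to
#'   modules).
#' @param kd_out_degree `c(lo, hi)` range of direct (layer-1) children per
#'   key driver.
#' @param group_effect_size Log2 fold change added to IR donors' samples on
#'   every gene downstream of a key driver (random sign per gene).
#' @param covariate_effects Named numeric vector of planted covariate effect
#'   sizes (log2 units; per-year for age, per-unit for BMI).
#' @param sspg_params List with `IS` and `IR` entries, each `c(mean, sd)` in
#'   mg/dl; draws are truncated to the side of the 140 mg/dl cutoff matching
#'   the planted label so metadata stays self-consistent.
#' @param n_eqtl Number of genes given a causal cis marker (key drivers
#'   first, then the upstream regulatory web); default `NULL` means 10% of
#'   genes, a realistic cis-eQTL discovery rate for a cohort of this size.
#' @param eqtl_beta Per-dosage log2 effect of each causal marker on its gene.
#' @param perturb_target Gene id used by [simulate_perturbation()]; defaults
#'   to the first key driver.
#' @param attenuation Multiplier in (0, 1) applied to the perturbation effect
#'   per network layer.
#' @param dispersion Negative-binomial dispersion (1/size) of the counts.
#' @param lib_size_range `c(lo, hi)` range of expected library totals.
#' @param seed Integer seed; identical params + seed give bit-identical
#'   output.
#' @return A `SimulationParams` list.
#' @export
sim_params <- function(n_donors = 100,
                       clones_per_donor = 3,
                       n_genes = 5000,
                       n_modules = 5,
                       module_size = c(80, 120),
                       intra_module_corr = 0.35,
                       n_kd = 5,
                       kd_out_degree = c(25, 35),
                       group_effect_size = 1.0,
                       covariate_effects = c(batch = 0.5, rna_kit = 0.3,
                                             source_cell = 0.3, sex = 0.5,
                                             age = 0.01, bmi = 0.02),
                       sspg_params = list(IS = c(mean = 84, sd = 25),
                                          IR = c(mean = 210, sd = 40)),
                       n_eqtl = NULL,
                       eqtl_beta = 1.0,
                       perturb_target = NULL,
                       attenuation = 0.5,
                       dispersion = 0.15,
                       lib_size_range = c(2e6, 4e6),
                       seed = 1) {
  p <- list(n_donors = n_donors, clones_per_donor = clones_per_donor,
            n_genes = n_genes, n_modules = n_modules,
            module_size = module_size,
            intra_module_corr = intra_module_corr, n_kd = n_kd,
            kd_out_degree = kd_out_degree,
            group_effect_size = group_effect_size,
            covariate_effects = covariate_effects,
            sspg_params = sspg_params, n_eqtl = n_eqtl,
            eqtl_beta = eqtl_beta, perturb_target = perturb_target,
            attenuation = attenuation, dispersion = dispersion,
            lib_size_range = lib_size_range, seed = seed)
  stop_if_not(all(c(n_donors, n_genes, n_modules, n_kd) >= 1),
              "counts must be >= 1")
  stop_if_not(all(clones_per_donor >= 1), "clones_per_donor must be >= 1")
  stop_if_not(intra_module_corr > 0 && intra_module_corr < 1,
              "intra_module_corr must be in (0,1)")
  stop_if_not(attenuation > 0 && attenuation < 1,
              "attenuation must be in (0,1)")
  stop_if_not(dispersion > 0, "dispersion must be > 0")
  stop_if_not(n_modules * max(module_size) <= n_genes,
              "module sizes exceed n_genes")
  class(p) <- "SimulationParams"
  p
}

range_draw <- function(rng) {
  if (length(rng) == 1) rep(rng, 2) else rng
}

# Uniform integer draw from [lo, hi]; safe when lo == hi (no sample()
# scalar expansion).
sample_range <- function(rng, n) {
  vals <- seq(rng[1], rng[2])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# Plant the ground-truth structure: module memberships, the causal DAG
# under each key driver, DE truth, eQTL anchors, genomic positions.
simulate_truth <- function(params) {
  p <- params
  genes <- sprintf("G%04d", seq_len(p$n_genes))
  msz <- range_draw(p$module_size)
  sizes <- sample_range(msz, p$n_modules)
  shuffled <- sample(genes)
  module_assignment <- setNames(integer(p$n_genes), genes)
  idx <- 1
  members <- vector("list", p$n_modules)
  for (m in seq_len(p$n_modules)) {
    members[[m]] <- shuffled[idx:(idx + sizes[m] - 1)]
    module_assignment[members[[m]]] <- m
    idx <- idx + sizes[m]
  }

  kd_module <- ((seq_len(p$n_kd) - 1) %% p$n_modules) + 1
  odr <- range_draw(p$kd_out_degree)
  kd_set <- character(p$n_kd)
  edges_src <- character(0); edges_tgt <- character(0)
  layer_of <- setNames(integer(0), character(0))
  kd_downstream <- vector("list", p$n_kd)
  leftover_pool <- character(0)
  chain_heads <- character(0)

  for (k in seq_len(p$n_kd)) {
    m <- kd_module[k]
    # split the module's pool among its key drivers
    kds_here <- which(kd_module == m)
    pool_all <- members[[m]]
    chunk <- split(pool_all, rep(seq_along(kds_here),
                                 length.out = length(pool_all)))
    pool <- chunk[[match(k, kds_here)]]
    kd <- pool[1]
    kd_set[k] <- kd
    pool <- pool[-1]
    out_deg <- min(sample_range(odr, 1), length(pool))
    layers <- list()
    layers[[1]] <- pool[seq_len(out_deg)]
    pool <- pool[-seq_len(out_deg)]
    d <- 1
    # each deeper layer halves: the module keeps a sizeable complement of
    # co-expressed genes outside the regulator's cascade, as in real
    # modules where only part of a module responds to the group contrast
    while (length(pool) > 0 && d < 4) {
      d <- d + 1
      sz <- min(length(pool), max(1, round(length(layers[[d - 1]]) * 0.5)))
      layers[[d]] <- pool[seq_len(sz)]
      pool <- pool[-seq_len(sz)]
    }
    for (d in seq_along(layers)) {
      for (g in layers[[d]]) {
        parents <- if (d == 1) kd else {
          np <- if (runif(1) < 0.15 && length(layers[[d - 1]]) >= 2) 2 else 1
          sample(layers[[d - 1]], np)
        }
        edges_src <- c(edges_src, parents)
        edges_tgt <- c(edges_tgt, rep(g, length(parents)))
        layer_of[g] <- d
      }
    }
    kd_downstream[[k]] <- unlist(layers)

    # Non-cascade module genes feed this cascade from upstream in short
    # chains (1-2 genes) converging on distinct deep cascade nodes: the
    # regulatory web around a cascade is wider than the cascade itself,
    # and most of it does not respond to the group contrast. Anchoring
    # within the module keeps modules separable for co-expression
    # clustering.
    deep <- unlist(layers[-1])
    if (length(deep) == 0) deep <- layers[[1]]
    if (length(pool) > 0) {
      anchors <- sample(deep)   # cycle through distinct anchors
      ai <- 0
      i <- 1
      while (i <= length(pool)) {
        len <- min(sample(1:2, 1), length(pool) - i + 1)
        chain <- pool[i:(i + len - 1)]
        i <- i + len
        ai <- ai %% length(anchors) + 1
        edges_src <- c(edges_src, chain[1])
        edges_tgt <- c(edges_tgt, anchors[ai])
        chain_heads <- c(chain_heads, chain[1])
        if (len == 2) {
          edges_src <- c(edges_src, chain[2])
          edges_tgt <- c(edges_tgt, chain[1])
        }
      }
      leftover_pool <- c(leftover_pool, pool)
    }
  }
  names(kd_downstream) <- kd_set
  dag_edges <- data.frame(source = edges_src, target = edges_tgt,
                          stringsAsFactors = FALSE)

  downstream_all <- unique(unlist(kd_downstream))
  de_truth <- setNames(numeric(p$n_genes), genes)
  signs <- sample(c(-1, 1), length(downstream_all), replace = TRUE)
  de_truth[downstream_all] <- signs * p$group_effect_size

  # cis-eQTL genes: key drivers first, then the upstream-web chain heads,
  # then other source-like genes — mirroring a cohort where a sizeable
  # minority of expressed genes has a significant cis effect
  n_eqtl <- p$n_eqtl %||% max(p$n_kd, round(0.1 * p$n_genes))
  eqtl_candidates <- unique(c(kd_set, chain_heads,
                              setdiff(leftover_pool, chain_heads),
                              genes[module_assignment == 0]))
  eqtl_genes <- head(eqtl_candidates, n_eqtl)
  gene_pos <- data.frame(gene = genes, chr = "1",
                         tss = 2.5e6 * seq_len(p$n_genes),
                         stringsAsFactors = FALSE)
  causal_marker <- sprintf("M_%s", eqtl_genes)
  eqtl <- data.frame(gene = eqtl_genes, marker = causal_marker,
                     beta = p$eqtl_beta, stringsAsFactors = FALSE)

  target <- p$perturb_target %||% kd_set[1]
  list(module_assignment = module_assignment,
       module_members = members,
       dag_edges = dag_edges,
       kd_set = kd_set,
       kd_downstream = kd_downstream,
       layer_of = layer_of,
       de_truth = de_truth,
       eqtl = eqtl,
       gene_pos = gene_pos,
       perturb = list(target = target, attenuation = p$attenuation))
}

# Per-sample latent signal matrix (genes x samples) on the log2 scale:
# module factor (donor + clone components) plus a unit-variance component
# that propagates down the planted DAG with per-edge weight `w`, so the
# covariance carries both the module blocks and the causal topology.
simulate_signal <- function(truth, params, donor_of, w = 0.7) {
  p <- params
  genes <- names(truth$module_assignment)
  n_s <- length(donor_of)
  donors <- unique(donor_of)
  lambda <- sqrt(p$intra_module_corr / (1 - p$intra_module_corr))

  sig <- matrix(0, length(genes), n_s, dimnames = list(genes, NULL))
  u <- matrix(rnorm(length(genes) * n_s), length(genes), n_s,
              dimnames = list(genes, NULL))
  # propagate along the DAG in topological order
  dg <- igraph::graph_from_data_frame(truth$dag_edges, directed = TRUE,
                                      vertices = data.frame(name = genes))
  ord <- names(igraph::topo_sort(dg, mode = "out"))
  parents <- split(truth$dag_edges$source, truth$dag_edges$target)
  for (g in ord) {
    par <- parents[[g]]
    if (is.null(par)) next
    # variance-normalized sum: each parent keeps weight w/sqrt(k), so a
    # child of several regulators still carries a learnable signal from
    # each of them
    pu <- if (length(par) == 1) u[par, ]
          else colSums(u[par, , drop = FALSE]) / sqrt(length(par))
    u[g, ] <- w * pu + sqrt(1 - w^2) * u[g, ]
  }
  for (m in seq_len(p$n_modules)) {
    mem <- truth$module_members[[m]]
    f_d <- setNames(rnorm(length(donors)), donors)
    f <- sqrt(0.5) * f_d[donor_of] + sqrt(0.5) * rnorm(n_s)
    sig[mem, ] <- lambda * rep(f, each = length(mem))
  }
  sig + u
}

#' Simulate a multi-clone iPSC expression cohort with planted ground truth
#'
#' Counts are negative-binomial with a log2 mean composed of a gene baseline,
#' a per-module latent factor, a DAG-propagated signal, the IR-group effect
#' on key-driver-downstream genes, planted covariate effects, cis-eQTL
#' dosage effects, and clone-level noise. Clones of one donor share the
#' donor's group, covariates, and genotype.
#'
#' @param params A [sim_params()] object.
#' @return List with `counts` (integer matrix genes x samples), `metadata`
#'   (data.frame, one row per sample), `truth` (planted structure: module
#'   assignment, DAG edges, key drivers, DE truth, covariate effects,
#'   perturbation schedule) and `genotypes` (dosage matrix plus marker/gene
#'   position tables for the cis-eQTL scan).
#' @export
simulate_cohort <- function(params = sim_params()) {
  p <- params
  with_seed(p$seed, {
    truth <- simulate_truth(p)
    genes <- names(truth$module_assignment)

    cl <- range_draw(p$clones_per_donor)
    clones <- sample_range(cl, p$n_donors)
    donors <- sprintf("D%03d", seq_len(p$n_donors))
    donor_of <- rep(donors, clones)
    n_s <- length(donor_of)
    sample_id <- paste0(donor_of, "_c",
                        unlist(lapply(clones, seq_len)))

    group <- setNames(sample(rep(c("IR", "IS"), length.out = p$n_donors)),
                      donors)
    sspg <- vapply(donors, function(d) {
      pr <- p$sspg_params[[group[d]]]
      repeat {
        x <- rnorm(1, pr[["mean"]], pr[["sd"]])
        if (x >= 0 &&
            ((group[d] == "IR" && x >= 140) ||
             (group[d] == "IS" && x < 140))) return(x)
      }
    }, 0)
    sex <- setNames(sample(c("M", "F"), p$n_donors, replace = TRUE), donors)
    age <- setNames(round(rnorm(p$n_donors, 58, 8), 1), donors)
    bmi <- setNames(round(rnorm(p$n_donors, 29, 4), 1), donors)
    ethnicity <- setNames(sample(c("EUR", "EAS", "HIS"), p$n_donors,
                                 replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                          donors)
    metadata <- data.frame(
      sample_id = sample_id, donor_id = donor_of,
      sspg = round(sspg[donor_of], 1), group = group[donor_of],
      sex = sex[donor_of], age = age[donor_of], bmi = bmi[donor_of],
      ethnicity = ethnicity[donor_of],
      batch = sample(paste0("B", 1:3), n_s, replace = TRUE),
      rna_kit = sample(paste0("K", 1:2), n_s, replace = TRUE),
      source_cell = sample(c("fibroblast", "blood"), n_s, replace = TRUE),
      stringsAsFactors = FALSE)

    # planted covariate effects on a random 20% of genes each
    covariate_truth <- list()
    cov_shift <- matrix(0, p$n_genes, n_s, dimnames = list(genes, NULL))
    for (cv in names(p$covariate_effects)) {
      eff <- p$covariate_effects[[cv]]
      if (eff == 0) next
      hit <- sample(genes, round(0.2 * p$n_genes))
      vals <- metadata[[cv]]
      if (is.numeric(vals)) {
        slope <- setNames(eff * sample(c(-1, 1), length(hit), TRUE), hit)
        cov_shift[hit, ] <- cov_shift[hit, , drop = FALSE] +
          outer(slope, vals - mean(vals))
        covariate_truth[[cv]] <- slope
      } else {
        lev <- sort(unique(vals))
        offs <- matrix(rnorm(length(hit) * length(lev), 0, eff),
                       length(hit), length(lev),
                       dimnames = list(hit, lev))
        offs <- offs - rowMeans(offs)
        cov_shift[hit, ] <- cov_shift[hit, , drop = FALSE] +
          offs[, vals, drop = FALSE]
        covariate_truth[[cv]] <- offs
      }
    }

    # genotypes: donor-level dosages, causal markers plus null markers
    null_genes <- sample(setdiff(genes, truth$eqtl$gene),
                         min(50, p$n_genes - nrow(truth$eqtl)))
    marker_gene <- c(truth$eqtl$gene, rep(null_genes, each = 2))
    marker_id <- c(truth$eqtl$marker,
                   paste0("N_", rep(null_genes, each = 2), "_",
                          rep(1:2, length(null_genes))))
    tss <- setNames(truth$gene_pos$tss, truth$gene_pos$gene)
    marker_pos <- data.frame(
      marker = marker_id, chr = "1",
      pos = tss[marker_gene] + round(runif(length(marker_id), 1e4, 9e5)) *
        sample(c(-1, 1), length(marker_id), TRUE),
      stringsAsFactors = FALSE)
    maf <- runif(length(marker_id), 0.2, 0.5)
    dosages <- matrix(rbinom(length(marker_id) * p$n_donors, 2,
                             rep(maf, p$n_donors)),
                      length(marker_id), p$n_donors,
                      dimnames = list(marker_id, donors))

    signal <- simulate_signal(truth, p, donor_of)
    x <- matrix(rnorm(p$n_genes, 4, 1.5), p$n_genes, 1)[, rep(1, n_s)] +
      signal + cov_shift +
      matrix(rnorm(p$n_genes * n_s, 0, 0.2), p$n_genes, n_s)
    dimnames(x) <- list(genes, sample_id)
    is_ir <- metadata$group == "IR"
    x[, is_ir] <- x[, is_ir] + truth$de_truth
    eq_dos <- dosages[truth$eqtl$marker, donor_of, drop = FALSE]
    x[truth$eqtl$gene, ] <- x[truth$eqtl$gene, , drop = FALSE] +
      truth$eqtl$beta * (eq_dos - 1)

    lib <- runif(n_s, p$lib_size_range[1], p$lib_size_range[2])
    prop <- 2^x
    mu <- sweep(prop, 2, colSums(prop), "/") * rep(lib, each = p$n_genes)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
                     p$n_genes, n_s, dimnames = dimnames(x))

    truth$covariate_truth <- covariate_truth
    truth$params <- p
    list(counts = counts, metadata = metadata, truth = truth,
         genotypes = list(dosages = dosages, marker_pos = marker_pos,
                          gene_pos = truth$gene_pos))
  })
}

#' Simulate a prior interaction network from the planted DAG
#'
#' Returns the truth DAG's skeleton with a stated fraction of true edges
#' removed and a stated fraction of random extra edges added. Edges are
#' marked undirected: prior interaction databases carry no trusted
#' direction.
#'
#' @param truth Truth component of a [simulate_cohort()] result.
#' @param extra_edge_frac Extra random edges as a fraction of the true
#'   skeleton size.
#' @param removal_frac Fraction of true edges dropped.
#' @param seed Integer seed.
#' @return An undirected `DirectedNetwork`.
#' @export
simulate_prior_network <- function(truth, extra_edge_frac = 0.5,
                                   removal_frac = 0, seed = 1) {
  with_seed(seed, {
    genes <- names(truth$module_assignment)
    skel <- truth$dag_edges
    n_true <- nrow(skel)
    if (removal_frac > 0) {
      drop <- sample(n_true, round(removal_frac * n_true))
      skel <- skel[-drop, , drop = FALSE]
    }
    n_extra <- round((1 + extra_edge_frac) * n_true) - n_true
    have <- c(paste(skel$source, skel$target), paste(skel$target, skel$source))
    extra <- data.frame(source = character(0), target = character(0))
    while (nrow(extra) < n_extra) {
      a <- sample(genes, n_extra)
      b <- sample(genes, n_extra)
      cand <- data.frame(source = a, target = b, stringsAsFactors = FALSE)
      cand <- cand[cand$source != cand$target, ]
      key <- paste(cand$source, cand$target)
      rkey <- paste(cand$target, cand$source)
      keep <- !(key %in% have) & !(rkey %in% have) & !duplicated(key)
      cand <- cand[keep, ]
      have <- c(have, paste(cand$source, cand$target),
                paste(cand$target, cand$source))
      extra <- rbind(extra, cand)
    }
    extra <- extra[seq_len(n_extra), , drop = FALSE]
    edges <- rbind(skel, extra)
    rownames(edges) <- NULL
    directed_network(edges, nodes = genes, directed = FALSE)
  })
}

#' Simulate a paired in-silico inhibition experiment
#'
#' Treated samples shift each gene downstream of `target` by a
#' sign-consistent effect that attenuates geometrically with the gene's
#' layer (shortest directed path from the target in the planted DAG):
#' `effect_size * attenuation^(layer - 1)`. Unreachable genes are
#' unshifted. Treated and control arms are paired by cell line.
#'
#' @param cohort A [simulate_cohort()] result (supplies gene baselines and
#'   noise parameters).
#' @param truth Truth component of the cohort.
#' @param target Gene id to inhibit; defaults to the planted perturbation
#'   target.
#' @param n_per_arm Number of cell lines (each measured treated and
#'   untreated).
#' @param effect_size Base log2 effect on layer-1 genes.
#' @param seed Integer seed.
#' @return List with `treated` and `control` count matrices, `pairs` (line
#'   ids), and `true_shift` (named per-gene planted log2 shift).
#' @export
simulate_perturbation <- function(cohort, truth, target = NULL,
                                  n_per_arm = 12, effect_size = 2.0,
                                  seed = 1) {
  target <- target %||% truth$perturb$target
  stop_if_not(target %in% names(truth$module_assignment),
              sprintf("unknown target id '%s'", target))
  p <- truth$params
  with_seed(seed, {
    genes <- names(truth$module_assignment)
    layer <- perturbation_layers(truth, target)
    shift <- setNames(numeric(length(genes)), genes)
    reach <- names(layer)[layer >= 1]
    sgn <- sample(c(-1, 1), length(reach), replace = TRUE)
    shift[reach] <- sgn * effect_size * p$attenuation^(layer[reach] - 1)

    lines <- sprintf("L%02d", seq_len(n_per_arm))
    donor_of <- lines # one line per pseudo-donor
    base <- rnorm(length(genes), 4, 1.5)
    # shared line-level signal: simulate once, reuse for both arms so the
    # design is genuinely paired
    sig_line <- simulate_signal(truth, p, donor_of)
    arm <- function(extra, tag) {
      x <- base + sig_line + extra +
        matrix(rnorm(length(genes) * n_per_arm, 0, 0.2),
               length(genes), n_per_arm)
      lib <- runif(n_per_arm, p$lib_size_range[1], p$lib_size_range[2])
      prop <- 2^x
      mu <- sweep(prop, 2, colSums(prop), "/") *
        rep(lib, each = length(genes))
      matrix(rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
             length(genes), n_per_arm,
             dimnames = list(genes, paste0(lines, "_", tag)))
    }
    control <- arm(0, "ctrl")
    treated <- arm(shift, "trt")
    list(treated = treated, control = control, pairs = lines,
         true_shift = shift, layers = layer)
  })
}

# Shortest directed path length from `target` to every reachable gene in
# the planted DAG (target itself = 0).
perturbation_layers <- function(truth, target) {
  g <- igraph::graph_from_data_frame(
    truth$dag_edges, directed = TRUE,
    vertices = data.frame(name = names(truth$module_assignment)))
  d <- igraph::distances(g, v = target, mode = "out")[1, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d
}

#' Build truth-derived gene sets for module annotation
#'
#' Produces a GMT-style list in which each planted module has a matching
#' "metabolism-flavoured" set (a sampled fraction of its genes plus random
#' padding) named after insulin-resistance-relevant processes, plus
#' irrelevant noise sets. Used to exercise module enrichment and selection
#' end to end on synthetic data.
#'
#' @param truth Truth component of a [simulate_cohort()] result.
#' @param frac Fraction of each module's genes included in its set.
#' @param n_noise_sets Number of irrelevant random sets.
#' @param seed Integer seed.
#' @return Named list of gene id vectors.
#' @export
truth_gene_sets <- function(truth, frac = 0.9, n_noise_sets = 5, seed = 1) {
  with_seed(seed, {
    genes <- names(truth$module_assignment)
    terms <- c("GLUCOSE_METABOLIC_PROCESS", "CHOLESTEROL_BIOSYNTHESIS",
               "LIPID_METABOLIC_PROCESS", "ELECTRON_TRANSPORT_CHAIN",
               "GLYCOLYSIS", "INSULIN_SIGNALING")
    sets <- list()
    for (m in seq_along(truth$module_members)) {
      mem <- truth$module_members[[m]]
      core <- sample(mem, max(2, round(frac * length(mem))))
      pad <- sample(setdiff(genes, mem), round(0.1 * length(mem)))
      nm <- sprintf("GO_%s", terms[((m - 1) %% length(terms)) + 1])
      if (nm %in% names(sets)) nm <- paste0(nm, "_", m)
      sets[[nm]] <- c(core, pad)
    }
    for (i in seq_len(n_noise_sets)) {
      sets[[sprintf("GO_NEURON_DIFFERENTIATION_%d", i)]] <-
        sample(genes, sample(30:80, 1))
    }
    sets
  })
}
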