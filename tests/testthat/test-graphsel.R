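test_that("drift covariance is symmetric and flags identical populations", {
  set.seed(61)
  freq <- matrix(runif(100, 0.2, 0.8), 2, 50)
  freq <- rbind(freq, freq[2, ])             # third population identical to second
  rownames(freq) <- paste0("p", 1:3)
  w <- drift_covariance(allele_freq_table(freq, 50L))
  expect_equal(w$W, t(w$W))
  expect_equal(w$W[2, 3], w$W[2, 2])
  expect_equal(w$W[3, 3], w$W[2, 2])
})

test_that("drift distances from the covariance track independent drift times", {
  set.seed(62)
  L <- 4000; N <- 400
  q0 <- runif(L, 0.2, 0.8)
  drift_for <- function(q, gens) { for (g in seq_len(gens)) q <- drift_update(q, N); q }
  # three demes drifting independently from one ancestor for 10/30/30 gens
  qa <- drift_for(q0, 10); qb <- drift_for(q0, 30); qc <- drift_for(q0, 30)
  w <- drift_covariance(rbind(a = qa, b = qb, c = qc))
  d <- function(i, j) w$W[i, i] + w$W[j, j] - 2 * w$W[i, j]
  # pairwise distances approximate summed drift time / 2N
  expect_equal(d(1, 2), 40 / (2 * N), tolerance = 0.25)
  expect_equal(d(1, 3), 40 / (2 * N), tolerance = 0.25)
  expect_equal(d(2, 3), 60 / (2 * N), tolerance = 0.25)
  expect_gt(d(2, 3), d(1, 2))
})

test_that("fit_tree recovers additive three-taxon distances exactly", {
  # d_AB=0.3, d_AC=0.4, d_BC=0.5 -> terminal lengths 0.1, 0.2, 0.3
  D <- matrix(c(0, .3, .4, .3, 0, .5, .4, .5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W <- matrix(0, 3, 3, dimnames = dimnames(D))
  diag(W) <- c(0.2, 0.25, 0.3)
  for (i in 1:3) for (j in 1:3) if (i != j) W[i, j] <- (W[i, i] + W[j, j] - D[i, j]) / 2
  g <- fit_tree(W, root = "A")
  ed <- graph_edges(g)
  term <- ed$length[ed$child %in% c("A", "B", "C")]
  expect_equal(sort(term), c(0.1, 0.2, 0.3), tolerance = 1e-9)
  expect_lt(attr(g, "rss"), 1e-18)
  # path distances reproduced exactly
  Tm <- setscape:::graph_leaf_cov(g)
  dd <- outer(diag(Tm), diag(Tm), "+") - 2 * Tm
  expect_equal(unname(dd[c("A","B","C"), c("A","B","C")]), unname(D), tolerance = 1e-9)
})

test_that("fit_tree on a star covariance gives equal terminal lengths", {
  W <- diag(0.2, 4); dimnames(W) <- list(paste0("p", 1:4), paste0("p", 1:4))
  g <- fit_tree(W, root = "p1")
  ed <- graph_edges(g)
  term <- ed$length[ed$child %in% paste0("p", 1:4)]
  expect_equal(max(term) - min(term), 0, tolerance = 1e-9)
})

test_that("fit_tree reproduces noiseless additive distances on larger trees", {
  set.seed(63)
  phy <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.3))
  D <- ape::cophenetic.phylo(phy)
  W <- matrix(0, 6, 6, dimnames = dimnames(D))
  diag(W) <- apply(D, 1, max)
  for (i in 1:6) for (j in 1:6) if (i != j) W[i, j] <- (W[i, i] + W[j, j] - D[i, j]) / 2
  g <- fit_tree(W, root = rownames(D)[1])
  Tm <- setscape:::graph_leaf_cov(g)
  dd <- outer(diag(Tm), diag(Tm), "+") - 2 * Tm
  expect_equal(unname(dd[rownames(D), rownames(D)]), unname(D), tolerance = 1e-7)
})

test_that("fit_tree mostly recovers the topology of a drift simulation", {
  set.seed(64)
  # balanced 6-leaf tree with distinct split times, Gaussian drift approximation
  newick <- "(((A:0.04,B:0.04):0.06,C:0.10):0.05,((D:0.03,E:0.03):0.07,F:0.10):0.05);"
  phy0 <- ape::read.tree(text = newick)
  L <- 3000
  hits <- 0; reps <- 10
  for (r in seq_len(reps)) {
    q0 <- runif(L, 0.25, 0.75)
    g0 <- phylo_to_graph(phy0)
    ed <- graph_edges(g0)
    z <- list(); z[[g0$root]] <- q0
    for (e in seq_len(nrow(ed))) {
      par <- z[[ed$parent[e]]]
      q <- par + rnorm(L, 0, sqrt(ed$length[e] * par * (1 - par)))
      z[[ed$child[e]]] <- pmin(pmax(q, 0.001), 0.999)
    }
    freq <- do.call(rbind, z[phy0$tip.label])
    rownames(freq) <- phy0$tip.label
    g <- fit_tree(drift_covariance(allele_freq_table(freq, 100L)), root = "A")
    phy <- ape::read.tree(text = write_newick(g))
    if (ape::dist.topo(ape::unroot(phy), ape::unroot(phy0)) == 0) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.8)
})

test_that("polygenic scores are 2 * beta %*% freq over significant loci", {
  freq <- rbind(p1 = c(l1 = 0.1, l2 = 0.5), p2 = c(0.9, 0.5))
  t <- allele_freq_table(freq, 50L)
  z <- polygenic_scores(t, c(l1 = 1))
  expect_equal(unname(z), c(0.2, 1.8))
  expect_equal(polygenic_scores(t, c(l1 = 2)), 2 * z)   # linear in beta
  z2 <- polygenic_scores(t, c(l1 = 0, l2 = 0))
  expect_equal(unname(z2), c(0, 0))
  # empty significant set errors with the trait named
  gw <- structure(list(trait = "T9", table = data.frame(), alpha = 0.05,
                       significant = character(0)), class = "gwas_result")
  expect_error(polygenic_scores(t, gw), "T9")
})

test_that("additive variance uses pooled heterozygosity with the diploid factor", {
  freq <- rbind(p1 = c(l1 = 0.2, l2 = 0.6), p2 = c(0.4, 1.0))
  t <- allele_freq_table(freq, 50L)
  beta <- c(l1 = 0.5, l2 = -1)
  qbar <- colMeans(freq)
  expect_equal(additive_variance(t, beta),
               4 * sum(beta^2 * qbar * (1 - qbar)))
})

test_that("edge selection is zero for identical scores, shift-invariant, telescoping", {
  g <- caterpillar_graph(6)
  z <- setNames(rep(2, 6), paste0("pop", 1:6))
  es <- estimate_edge_selection(g, z, v_a = 1)
  expect_equal(unname(es$alpha), rep(0, length(es$alpha)), tolerance = 1e-10)
  set.seed(65)
  z2 <- setNames(rnorm(6), paste0("pop", 1:6))
  es2 <- estimate_edge_selection(g, z2, v_a = 1)
  es3 <- estimate_edge_selection(g, z2 + 100, v_a = 1)
  expect_equal(es2$alpha, es3$alpha)
  # telescoping along the root-to-leaf path with the per-edge null SDs
  path_edges <- c("a1-a2", "a2-a3", "a3-a4", "a4-a5", "a5-pop6")
  expect_true(all(path_edges %in% names(es2$alpha)))
  lhs <- sum(es2$alpha[path_edges] * sqrt(es2$v_a * es2$v_null[path_edges]))
  expect_equal(lhs, unname(es2$zhat["pop6"] - es2$zhat["a1"]), tolerance = 1e-9)
})

test_that("edge selection alpha is standard normal under the Brownian null", {
  set.seed(66)
  g <- caterpillar_graph(8, c_int = 0.02, c_term = 0.015)
  alphas <- replicate(600, {
    z <- simulate_bm_leaves(g, v_a = 2.5)
    estimate_edge_selection(g, z, v_a = 2.5)$alpha
  })
  expect_lt(abs(mean(alphas)), 0.06)
  expect_equal(sd(as.vector(alphas)), 1, tolerance = 0.06)
  per_edge_sd <- apply(alphas, 1, sd)
  expect_true(all(per_edge_sd > 0.85 & per_edge_sd < 1.15))
})

test_that("zero-length edges carry zero alpha and do not break the solver", {
  g <- caterpillar_graph(5)
  g$length["pop2"] <- 0
  set.seed(67)
  z <- setNames(rnorm(5), paste0("pop", 1:5))
  es <- estimate_edge_selection(g, z, v_a = 1)
  expect_equal(unname(es$alpha["a2-pop2"]), 0)
  expect_true(all(is.finite(es$alpha)))
})

test_that("admixture children are tied to the weighted parent mixture", {
  # pop3 receives 40% ancestry from a3 (ancestor of pop4/pop5 side)
  g <- caterpillar_graph(5)
  g2 <- admixture_graph(g$parent, g$length, g$root,
                        admix = data.frame(child = "pop3", parent = "a4",
                                           weight = 0.4))
  set.seed(68)
  z <- setNames(rnorm(5), paste0("pop", 1:5))
  es <- estimate_edge_selection(g2, z, v_a = 1)
  expect_true(all(is.finite(es$alpha)))
  # null calibration still holds with the admixture edge in place
  alphas <- replicate(400, {
    zz <- simulate_bm_leaves(g2, v_a = 1)
    estimate_edge_selection(g2, zz, v_a = 1)$alpha
  })
  expect_lt(abs(mean(alphas)), 0.08)
  expect_equal(sd(as.vector(alphas)), 1, tolerance = 0.08)
})

test_that("greedy migration search is identity at 0 and nonincreasing in RSS", {
  set.seed(69)
  g <- caterpillar_graph(5, c_int = 0.05, c_term = 0.02)
  # fabricate an observed covariance from the true graph + one admixture
  gt <- admixture_graph(g$parent, g$length, g$root,
                        admix = data.frame(child = "pop5", parent = "a2",
                                           weight = 0.3))
  W <- setscape:::graph_leaf_cov(gt)
  w <- structure(list(W = W, n_loci = 1000), class = "drift_cov")
  g0 <- add_migration_edges(g, w, n_mig = 0)
  expect_null(g0$admix)
  g1 <- add_migration_edges(g, w, n_mig = 1)
  rss <- attr(g1, "rss_path")
  expect_true(all(diff(rss) <= 1e-12))
  expect_equal(g1$admix$child, "pop5")       # target identified
  expect_equal(g1$admix$weight, 0.3, tolerance = 0.1)
})

test_that("migration target is identified in noisy drift simulations", {
  set.seed(70)
  hits <- 0; reps <- 6
  for (r in seq_len(reps)) {
    g <- caterpillar_graph(4, c_int = 0.06, c_term = 0.03)
    gt <- admixture_graph(g$parent, g$length, g$root,
                          admix = data.frame(child = "pop4", parent = "a2",
                                             weight = 0.3))
    # Gaussian drift frequencies under the admixture model
    L <- 4000
    q0 <- runif(L, 0.3, 0.7)
    ed <- graph_edges(gt)
    z <- list(); z[[gt$root]] <- q0
    aw <- setNames(gt$admix$weight, gt$admix$child)
    ap <- setNames(gt$admix$parent, gt$admix$child)
    for (e in seq_len(nrow(ed))) {
      ch <- ed$child[e]
      wgt <- if (ch %in% names(aw)) aw[[ch]] else 0
      base <- (1 - wgt) * z[[ed$parent[e]]] +
        (if (wgt > 0) wgt * z[[ap[[ch]]]] else 0)
      q <- base + rnorm(L, 0, sqrt(ed$length[e] * q0 * (1 - q0)))
      z[[ch]] <- pmin(pmax(q, 0.001), 0.999)
    }
    freq <- do.call(rbind, z[gt$leaves]); rownames(freq) <- gt$leaves
    w <- drift_covariance(allele_freq_table(freq, 200L))
    gf <- fit_tree(w, root = "pop1")
    gm <- add_migration_edges(gf, w, n_mig = 1)
    if (!is.null(gm$admix) && nrow(gm$admix) == 1 && gm$admix$child == "pop4")
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.5)
})
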