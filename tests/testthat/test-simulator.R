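test_that("effective selection coefficient interpolates the two endpoints", {
  expect_equal(effective_s(1, 0.01), 0.01)
  expect_equal(effective_s(0, 0.01), 1 / 1.01 - 1)   # -0.00990099..., -0.01 at 2 dp
  expect_equal(round(effective_s(0, 0.01), 2), -0.01)
  mid <- (effective_s(1, 0.01) + effective_s(0, 0.01)) / 2
  expect_equal(effective_s(0.5, 0.01), mid)
})

test_that("genic selection update has fixed boundaries and is monotone in s", {
  expect_equal(selection_update(0, 0.3), 0)
  expect_equal(selection_update(1, -0.3), 1)
  expect_equal(selection_update(0.5, 0), 0.5)
  expect_equal(selection_update(0.5, 0.01), 0.5 * 1.01 / 1.005)
  expect_equal(selection_update(0.5, 0.01), 0.50248756, tolerance = 1e-7)
  s_grid <- seq(-0.5, 0.5, by = 0.1)
  expect_true(all(diff(selection_update(0.3, s_grid)) > 0))
})

test_that("equilibrium frequency draws are bounded and logit-uniform", {
  set.seed(21)
  Ne <- 500
  q <- sample_equilibrium_frequencies(1e5, Ne)
  expect_true(all(q >= 1 / (2 * Ne) & q <= 1 - 1 / (2 * Ne)))
  lo <- qlogis(1 / (2 * Ne))
  u <- (qlogis(q) - lo) / (-2 * lo)
  expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)
  expect_equal(median(q), 0.5, tolerance = 0.03)     # symmetric density
})

test_that("binomial drift has the right first two moments", {
  set.seed(22)
  expect_true(all(drift_update(rep(0, 50), 100) == 0))
  N <- 200; q0 <- 0.3
  draws <- drift_update(rep(q0, 1e4), N)
  se_mean <- sqrt(q0 * (1 - q0) / (2 * N)) / sqrt(1e4)
  expect_lt(abs(mean(draws) - q0), 3 * se_mean)
  expect_equal(var(draws), q0 * (1 - q0) / (2 * N), tolerance = 0.05)
})

test_that("colonization draws founders binomially and fills the deme", {
  p <- tiny_sim_params(K = 3)
  set.seed(23)
  st <- setscape:::new_sim_state(p)
  st$generation <- 10L
  st$freq[1, seq_len(st$L)] <- 1            # source fixed
  st2 <- colonize_next_deme(st, p)
  expect_equal(st2$occupied, 2L)
  expect_true(all(st2$freq[2, seq_len(st2$L)] == 1))
  expect_equal(st2$sizes[2], p$Ne_cap)
  expect_equal(st2$founded_gen[2], 10L)
  # founder count: 1% of a 1e4 source = 100 diploids = 200 allele copies
  p4 <- sim_params(K = 2, Ne_anc = 1e4, Ne_cap = 1e4, total_generations = 10,
                   n_init_neutral_pool = 2000, adaptive_mut_per_gen = 0)
  st4 <- setscape:::new_sim_state(p4)
  st4$freq[1, seq_len(st4$L)] <- 0.5
  st4b <- colonize_next_deme(st4, p4)
  f <- st4b$freq[2, seq_len(st4b$L)]
  expect_true(all(abs(f * 200 - round(f * 200)) < 1e-9))  # multiples of 1/200
  expect_equal(var(f), 0.25 / 200, tolerance = 0.1)
})

test_that("mutation injection seeds one deme at the configured frequency", {
  p <- tiny_sim_params(K = 4, adaptive_mut_per_gen = 2, neutral_mut_rate_per_gen = 0)
  set.seed(24)
  st <- setscape:::new_sim_state(p)
  st$occupied <- 3L
  st$generation <- 5L
  L0 <- st$L
  st2 <- spawn_mutations(st, p)
  expect_equal(st2$L, L0 + 2L)
  for (j in L0 + 1:2) {
    col <- st2$freq[, j]
    expect_equal(sum(col > 0), 1)
    expect_equal(col[col > 0], p$init_new_freq)
    expect_true(which(col > 0) <= 3)        # only occupied demes
    expect_false(is.na(st2$latent[j]))
    expect_lte(p$gamma_G, 0)
  }
  p0 <- tiny_sim_params(K = 4, adaptive_mut_per_gen = 0, neutral_mut_rate_per_gen = 0)
  expect_equal(spawn_mutations(st, p0)$L, st$L)
})

test_that("the colonization schedule matches the study scenario", {
  # K=25, expansion every 10 generations: deme 25 founded at 240, run ends 260
  p <- sim_params(K = 25, Ne_anc = 300, Ne_cap = 150, total_generations = 260,
                  n_init_neutral_pool = 40, neutral_mut_rate_per_gen = 0,
                  adaptive_mut_per_gen = 0, seed = 25)
  st <- run_simulation(p)
  expect_equal(st$founded_gen, c(0L, seq(10L, 240L, by = 10L)))
  expect_equal(st$generation, 260L)
  expect_equal(st$occupied, 25L)
})

test_that("default environmental profiles reproduce the 25-deme scenario", {
  E <- default_env_profiles(25)
  expect_equal(unname(which(E[, 1] == 1)), 5:10)
  expect_true(all(E[1:14, 2] == 0))
  expect_equal(unname(E[25, 2]), 1)
  expect_true(all(diff(E[15:25, 2]) > 0))
})

test_that("frequencies stay in [0,1] across random parameterizations", {
  set.seed(26)
  for (rep in 1:4) {
    p <- tiny_sim_params(K = sample(3:5, 1),
                         adaptive_mut_per_gen = sample(0:3, 1),
                         neutral_mut_rate_per_gen = runif(1, 0, 2),
                         s = runif(1, 0, 0.1))
    st <- run_simulation(p)
    expect_true(all(st$freq >= 0 & st$freq <= 1))
  }
})

test_that("neutral drift is a martingale: mean final frequency tracks start", {
  set.seed(27)
  q0 <- 0.4
  reps <- 250
  finals <- replicate(reps, {
    q <- q0
    for (g in 1:15) q <- drift_update(q, 100)
    q
  })
  se <- sd(finals) / sqrt(reps)
  expect_lt(abs(mean(finals) - q0), 3 * se)
})

test_that("population trait means follow 2*gamma_G*q over causal loci", {
  p <- tiny_sim_params(K = 3, adaptive_mut_per_gen = 1, seed = 28)
  st <- run_simulation(p)
  tr <- compute_traits(st)
  reg <- registry(st)
  expect_equal(dim(tr), c(3, p$n_env_types * p$traits_per_env))
  # manual recomputation for the first trait
  ada <- which(reg$class == "adaptive" & reg$trait == 1)
  manual <- if (length(ada)) rowSums(2 * p$gamma_G * st$freq[, ada, drop = FALSE])
            else rep(0, 3)
  expect_equal(unname(tr[, 1]), unname(manual))
  # a single causal locus at q = 0.5 with gamma_G = -1 gives latent value -1
  st$freq[, ada] <- 0
  if (length(ada)) {
    st$freq[1, ada[1]] <- 0.5
    expect_equal(unname(compute_traits(st)[1, 1]), 2 * p$gamma_G * 0.5)
    expect_equal(unname(compute_traits(st)[2, 1]), 0)
  }
  # monotone: raising the causal frequency lowers the trait (gamma_G < 0)
  if (length(ada)) {
    st$freq[1, ada[1]] <- 0.9
    expect_lt(compute_traits(st)[1, 1], 2 * p$gamma_G * 0.5)
  }
})

test_that("observation step samples binomial dosages matching deme frequencies", {
  p <- tiny_sim_params(K = 3, adaptive_mut_per_gen = 2,
                       sample_n_individuals = 200, seed = 29)
  sim <- simulate_range_expansion(p)
  expect_s3_class(sim$genotypes, "genotype_matrix")
  reg <- sim$registry
  # adaptive observed loci bounded by the latent trait count
  expect_lte(sum(reg$class == "adaptive"), p$n_env_types * p$traits_per_env *
               p$latents_per_trait)
  # one observed adaptive locus per latent at most
  expect_false(any(duplicated(reg$latent[reg$class == "adaptive"])))
  # sampled dosage means approximate 2q
  st <- sim$state
  obs <- match(reg$locus_id, st$locus_ids)
  q1 <- st$freq[1, obs[1:50]]
  d1 <- colMeans(sim$genotypes$dosage[sim$genotypes$population == "pop1", 1:50])
  expect_equal(unname(d1), unname(2 * q1), tolerance = 0.15)
  # trait table shapes
  expect_equal(ncol(sim$traits_pop), p$n_env_types * p$traits_per_env)
  expect_equal(nrow(sim$traits_ind), p$K * p$sample_n_individuals)
})

test_that("parameter validation rejects inconsistent scenarios", {
  expect_error(sim_params(K = 10, total_generations = 50), "too short")
  expect_error(sim_params(founder_fraction = 0), "founder_fraction")
  expect_error(sim_params(gamma_G = 0.5), "gamma_G")
  expect_error(sim_params(env_profiles = matrix(2, 25, 2)), "environment values")
})
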