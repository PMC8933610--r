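# fixtures built in code; all sizes kept small so the default run stays fast

genepop_2digit <- function() {
  c("toy genepop fixture",
    "loc1",
    "POP",
    "a1 , 0101",
    "a2 , 0102",
    "POP",
    "b1 , 0202",
    "b2 , 0202")
}

genepop_3digit <- function() {
  c("toy genepop fixture (3-digit)",
    "loc1",
    "POP",
    "a1 , 001001",
    "a2 , 001002",
    "POP",
    "b1 , 002002",
    "b2 , 002002")
}

write_tmp_lines <- function(lines, ext = ".gen") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small random genotype matrix with known populations
random_genotypes <- function(n_per_pop = 6, K = 3, L = 10, maf = NULL) {
  if (is.null(maf)) maf <- runif(L, 0.1, 0.9)
  dosage <- matrix(rbinom(n_per_pop * K * L, 2, rep(maf, each = n_per_pop * K)),
                   n_per_pop * K, L)
  genotype_matrix(dosage, rep(paste0("pop", seq_len(K)), each = n_per_pop))
}

# frequency table from explicit matrices
aft <- function(freq, n = 100L) allele_freq_table(freq, n)

# a small, fast simulation parameter set (neutral unless s/adaptive given)
tiny_sim_params <- function(K = 6, seed = NULL, ...) {
  defaults <- list(K = K, Ne_anc = 1500, Ne_cap = 800,
                   total_generations = (K - 1) * 10 + 20,
                   n_init_neutral_pool = 600,
                   neutral_mut_rate_per_gen = 1,
                   adaptive_mut_per_gen = 0,
                   traits_per_env = 2, latents_per_trait = 2,
                   n_obs_init_neutral = 600, n_obs_new_neutral = 50,
                   sample_n_individuals = 30, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

# hand-built 5-node treemix vertices/edges fixture (3 leaves)
treemix_fixture <- function(migration = FALSE) {
  vf <- tempfile(); ef <- tempfile()
  writeLines(c("0 NA ROOT NOT_MIG NOT_TIP",
               "1 NA NOT_ROOT NOT_MIG NOT_TIP",
               "2 A NOT_ROOT NOT_MIG TIP",
               "3 B NOT_ROOT NOT_MIG TIP",
               "4 C NOT_ROOT NOT_MIG TIP"), vf)
  ed <- c("0 1 0.05 NOT_MIG",
          "1 2 0.1 NOT_MIG",
          "1 3 0.2 NOT_MIG",
          "0 4 0.3 NOT_MIG")
  if (migration) ed <- c(ed, "4 3 0.3 MIG")
  writeLines(ed, ef)
  list(vertices = vf, edges = ef)
}

# caterpillar admixture_graph, for edge-selection tests
caterpillar_graph <- function(K = 6, c_int = 0.03, c_term = 0.01) {
  par <- len <- c()
  for (j in seq_len(K - 2)) {
    par[paste0("a", j + 1)] <- paste0("a", j); len[paste0("a", j + 1)] <- c_int
  }
  for (j in seq_len(K - 1)) {
    par[paste0("pop", j)] <- paste0("a", j); len[paste0("pop", j)] <- c_term
  }
  par[paste0("pop", K)] <- paste0("a", K - 1); len[paste0("pop", K)] <- c_term
  admixture_graph(par, len, root = "a1")
}

# simulate Brownian leaf values on an admixture graph (unit V_A)
simulate_bm_leaves <- function(g, v_a = 1) {
  ed <- graph_edges(g)
  z <- stats::setNames(numeric(length(g$nodes)), g$nodes)
  aw <- if (!is.null(g$admix)) stats::setNames(g$admix$weight, g$admix$child) else NULL
  ap <- if (!is.null(g$admix)) stats::setNames(g$admix$parent, g$admix$child) else NULL
  for (e in seq_len(nrow(ed))) {
    ch <- ed$child[e]
    w <- if (!is.null(aw) && ch %in% names(aw)) aw[[ch]] else 0
    base <- (1 - w) * z[ed$parent[e]] + if (w > 0) w * z[ap[[ch]]] else 0
    z[ch] <- base + stats::rnorm(1, 0, sqrt(v_a * ed$length[e]))
  }
  z[g$leaves]
}
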