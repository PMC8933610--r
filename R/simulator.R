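#' Parameters for the stepping-stone colonization simulator
#'
#' Defaults reproduce the study scenario: 25 linearly arrayed demes; an
#' ancestral deme of `1e5` diploids; every 10 generations 1% of the source
#' deme founds the next vacant deme, which jumps to its capacity of `1e4`
#' in one generation; the run ends at generation 260 (the 25th deme is
#' founded at generation 240). Two environmental factors act on disjoint
#' blocks of 15 polygenic traits each, every trait being the sum of 10
#' monogenic latent traits. Derived adaptive alleles have selection
#' coefficient `s` where the environment is 1 and `1/(1+s) - 1` where it
#' is 0 (adaptation to stress carries a cost in the normal environment).
#'
#' @param K Number of demes.
#' @param Ne_anc Diploid size of the ancestral deme (deme 1).
#' @param Ne_cap Capacity of colonized demes.
#' @param founder_fraction Fraction of the source deme that founds a new
#'   deme.
#' @param expansion_interval Generations between colonization events.
#' @param total_generations Length of the run; must allow all demes to be
#'   founded, i.e. `>= (K - 1) * expansion_interval`.
#' @param s Adaptive selection coefficient in environment value 1.
#' @param n_init_neutral_pool Number of ancestral polymorphic neutral loci,
#'   drawn from the equilibrium frequency spectrum.
#' @param neutral_mut_rate_per_gen Poisson mean of new neutral mutations
#'   per generation.
#' @param adaptive_mut_per_gen New adaptive mutations per generation
#'   (fixed count).
#' @param n_env_types Number of environmental factors.
#' @param traits_per_env Traits under selection of each factor.
#' @param latents_per_trait Monogenic latent traits summed into each trait.
#' @param gamma_G Effect of one derived-allele copy on its latent trait;
#'   must be `<= 0` (derived alleles decrease trait values).
#' @param gamma_E Environment-on-trait selection sign parameter, `<= 0`;
#'   fixes the convention that high environmental values favour derived
#'   alleles (which, with `gamma_G <= 0`, decrease the traits). Only its
#'   sign convention matters to the frequency-level dynamics used here.
#' @param env_profiles `K x n_env_types` matrix of environment values in
#'   `[0, 1]`; default [default_env_profiles()].
#' @param sample_n_individuals Diploid individuals sampled per deme.
#' @param n_obs_init_neutral,n_obs_new_neutral Observed SNP counts for the
#'   initial-neutral and new-neutral classes (one adaptive SNP is observed
#'   per latent trait).
#' @param init_new_freq Initial frequency of a new mutation in its deme of
#'   origin.
#' @param sigma_e Environmental (residual) SD added to individual trait
#'   values; default `NULL` means 0.5 x SD of the genotypic values of each
#'   trait.
#' @param seed Optional integer seed applied at the start of
#'   [run_simulation()].
#' @return A validated object of class `sim_params`.
#' @export
sim_params <- function(K = 25, Ne_anc = 1e5, Ne_cap = 1e4,
                       founder_fraction = 0.01, expansion_interval = 10,
                       total_generations = 260, s = 0.01,
                       n_init_neutral_pool = 12000,
                       neutral_mut_rate_per_gen = 5,
                       adaptive_mut_per_gen = 3,
                       n_env_types = 2, traits_per_env = 15,
                       latents_per_trait = 10,
                       gamma_G = -1, gamma_E = -1,
                       env_profiles = NULL,
                       sample_n_individuals = 50,
                       n_obs_init_neutral = 10000,
                       n_obs_new_neutral = 500,
                       init_new_freq = 0.01,
                       sigma_e = NULL, seed = NULL) {
  p <- list(K = as.integer(K), Ne_anc = Ne_anc, Ne_cap = Ne_cap,
            founder_fraction = founder_fraction,
            expansion_interval = as.integer(expansion_interval),
            total_generations = as.integer(total_generations), s = s,
            n_init_neutral_pool = as.integer(n_init_neutral_pool),
            neutral_mut_rate_per_gen = neutral_mut_rate_per_gen,
            adaptive_mut_per_gen = as.integer(adaptive_mut_per_gen),
            n_env_types = as.integer(n_env_types),
            traits_per_env = as.integer(traits_per_env),
            latents_per_trait = as.integer(latents_per_trait),
            gamma_G = gamma_G, gamma_E = gamma_E,
            env_profiles = env_profiles,
            sample_n_individuals = as.integer(sample_n_individuals),
            n_obs_init_neutral = as.integer(n_obs_init_neutral),
            n_obs_new_neutral = as.integer(n_obs_new_neutral),
            init_new_freq = init_new_freq, sigma_e = sigma_e, seed = seed)
  if (p$K < 2) stop("K must be at least 2")
  if (p$founder_fraction <= 0 || p$founder_fraction >= 1)
    stop("founder_fraction must lie in (0, 1)")
  if (p$s <= -1) stop("s must exceed -1")
  if (p$gamma_G > 0) stop("gamma_G must be <= 0")
  if (p$gamma_E > 0) stop("gamma_E must be <= 0")
  if (p$total_generations < (p$K - 1) * p$expansion_interval)
    stop("total_generations too short to colonize all K demes")
  if (p$init_new_freq <= 0 || p$init_new_freq >= 1)
    stop("init_new_freq must lie in (0, 1)")
  if (is.null(p$env_profiles)) p$env_profiles <- default_env_profiles(p$K, p$n_env_types)
  p$env_profiles <- as.matrix(p$env_profiles)
  if (nrow(p$env_profiles) != p$K || ncol(p$env_profiles) != p$n_env_types)
    stop("env_profiles must be K x n_env_types")
  if (any(p$env_profiles < 0 | p$env_profiles > 1))
    stop("environment values must lie in [0, 1]")
  if (is.null(colnames(p$env_profiles)))
    colnames(p$env_profiles) <- paste0("E", seq_len(p$n_env_types))
  rownames(p$env_profiles) <- paste0("pop", seq_len(p$K))
  class(p) <- "sim_params"
  p
}

#' Default environmental profiles
#'
#' Factor 1 is a local patch: value 1 on demes 5..10 (for `K = 25`; the
#' patch scales as demes `round(K/5)..round(2K/5)` otherwise), 0 elsewhere.
#' Factor 2 is a geographical cline: 0 on demes 1..14 (`round(0.56 K)`),
#' then increasing linearly to 1 at deme `K`. Additional factors, if
#' requested, are zero.
#'
#' @param K Number of demes.
#' @param n_env_types Number of factors.
#' @return `K x n_env_types` matrix.
#' @export
default_env_profiles <- function(K, n_env_types = 2) {
  E <- matrix(0, K, n_env_types,
              dimnames = list(paste0("pop", seq_len(K)),
                              paste0("E", seq_len(n_env_types))))
  patch <- seq(max(2L, round(K / 5)), min(K, round(2 * K / 5)))
  E[patch, 1] <- 1
  if (n_env_types >= 2) {
    m <- round(0.56 * K)
    d <- seq_len(K)
    E[d > m, 2] <- (d[d > m] - m) / (K - m)
  }
  E
}

#' Equilibrium allele frequency spectrum of the ancestral population
#'
#' Draws i.i.d. frequencies from the density `f(q) proportional to
#' 1/(q(1-q))` truncated to `[1/(2 Ne), 1 - 1/(2 Ne)]`. On the logit scale
#' this density is uniform, so draws are made by inverse transform of a
#' uniform logit.
#'
#' @param n_loci Number of draws.
#' @param Ne Diploid population size setting the truncation bounds.
#' @return Numeric vector of frequencies.
#' @export
sample_equilibrium_frequencies <- function(n_loci, Ne) {
  stopifnot(n_loci >= 1, Ne >= 2)
  lo <- 1 / (2 * Ne)
  stats::plogis(stats::runif(n_loci, stats::qlogis(lo), stats::qlogis(1 - lo)))
}

#' Deterministic genic selection update
#'
#' One generation of genic selection on a derived allele at frequency `q`
#' with effective coefficient `s_eff`: `q' = q (1 + s_eff) / (1 + q s_eff)`.
#' The boundaries 0 and 1 are fixed points.
#'
#' @param q Frequency (vectorized).
#' @param s_eff Effective selection coefficient (`> -1`).
#' @return Updated frequencies.
#' @export
selection_update <- function(q, s_eff) {
  q * (1 + s_eff) / (1 + q * s_eff)
}

#' Effective selection coefficient in an environment
#'
#' Linear interpolation between the two endpoint coefficients of the
#' cost-of-adaptation model: `s` when the environment value `E` is 1 and
#' `1/(1+s) - 1` when it is 0 (for `s = 0.01` these are 0.01 and -0.0099,
#' i.e. -0.01 at two decimals).
#'
#' @param E Environment value in `[0, 1]` (vectorized).
#' @param s Selection coefficient in the `E = 1` environment.
#' @return Effective coefficient(s).
#' @export
effective_s <- function(E, s) {
  stopifnot(all(E >= 0 & E <= 1))
  E * s + (1 - E) * (1 / (1 + s) - 1)
}

#' Binomial drift update
#'
#' @param q Frequencies (vectorized over loci).
#' @param deme_size Diploid deme size.
#' @return `X / (2 deme_size)` with `X ~ Binomial(2 deme_size, q)`.
#' @export
drift_update <- function(q, deme_size) {
  stopifnot(deme_size >= 1)
  stats::rbinom(length(q), 2 * deme_size, q) / (2 * deme_size)
}

## internal registry helpers ------------------------------------------------

latent_to_trait <- function(latent, p) (latent - 1L) %/% p$latents_per_trait + 1L
trait_to_env <- function(trait, p) (trait - 1L) %/% p$traits_per_env + 1L

new_sim_state <- function(p) {
  nlat <- p$n_env_types * p$traits_per_env * p$latents_per_trait
  cap <- p$n_init_neutral_pool +
    ceiling(p$total_generations *
              (p$neutral_mut_rate_per_gen + p$adaptive_mut_per_gen) * 1.6) + 64L
  state <- list(
    freq = matrix(0, p$K, cap),
    L = p$n_init_neutral_pool,
    class = c(rep(1L, p$n_init_neutral_pool), rep(NA_integer_, cap - p$n_init_neutral_pool)),
    origin_gen = c(rep(0L, p$n_init_neutral_pool), rep(NA_integer_, cap - p$n_init_neutral_pool)),
    origin_deme = c(rep(1L, p$n_init_neutral_pool), rep(NA_integer_, cap - p$n_init_neutral_pool)),
    latent = rep(NA_integer_, cap),
    sizes = c(p$Ne_anc, rep(0, p$K - 1)),
    occupied = 1L,
    founded_gen = c(0L, rep(NA_integer_, p$K - 1)),
    generation = 0L,
    n_latents = nlat,
    params = p)
  state$freq[1, seq_len(state$L)] <- sample_equilibrium_frequencies(state$L, p$Ne_anc)
  class(state) <- "sim_state"
  state
}

grow_state <- function(state, extra) {
  cap <- ncol(state$freq)
  add <- max(extra, 256L)
  state$freq <- cbind(state$freq, matrix(0, nrow(state$freq), add))
  state$class <- c(state$class, rep(NA_integer_, add))
  state$origin_gen <- c(state$origin_gen, rep(NA_integer_, add))
  state$origin_deme <- c(state$origin_deme, rep(NA_integer_, add))
  state$latent <- c(state$latent, rep(NA_integer_, add))
  state
}

#' Found the next vacant deme
#'
#' `founder_fraction` of the source deme (the most recently occupied one)
#' emigrates to the adjacent vacant deme: founder allele frequencies are
#' binomial draws of `2 * round(founder_fraction * Ne_source)` allele
#' copies, and the new deme's size is set to `Ne_cap` immediately.
#'
#' @param state A `sim_state`.
#' @param params The `sim_params` of the run.
#' @return The updated state.
#' @export
colonize_next_deme <- function(state, params) {
  if (state$occupied >= params$K) stop("no vacant deme remains")
  src <- state$occupied
  d <- src + 1L
  nf <- max(1L, round(params$founder_fraction * state$sizes[src]))
  idx <- seq_len(state$L)
  state$freq[d, idx] <- stats::rbinom(state$L, 2L * nf, state$freq[src, idx]) / (2 * nf)
  state$sizes[d] <- params$Ne_cap
  state$occupied <- d
  state$founded_gen[d] <- state$generation
  state
}

#' Inject new neutral and adaptive mutations
#'
#' Draws `Poisson(neutral_mut_rate_per_gen)` new neutral loci and
#' `adaptive_mut_per_gen` new adaptive loci. Each new locus starts at
#' frequency `init_new_freq` in one uniformly chosen occupied deme and 0
#' elsewhere; each adaptive locus targets a uniformly chosen latent trait
#' with effect `gamma_G`.
#'
#' @inheritParams colonize_next_deme
#' @return The updated state.
#' @export
spawn_mutations <- function(state, params) {
  nn <- stats::rpois(1, params$neutral_mut_rate_per_gen)
  na <- params$adaptive_mut_per_gen
  tot <- nn + na
  if (tot == 0) return(state)
  if (state$L + tot > ncol(state$freq)) state <- grow_state(state, tot)
  idx <- state$L + seq_len(tot)
  demes <- sample.int(state$occupied, tot, replace = TRUE)
  state$freq[cbind(demes, idx)] <- params$init_new_freq
  state$class[idx] <- c(rep(2L, nn), rep(3L, na))
  state$origin_gen[idx] <- state$generation
  state$origin_deme[idx] <- demes
  if (na > 0)
    state$latent[idx[nn + seq_len(na)]] <- sample.int(state$n_latents, na, replace = TRUE)
  state$L <- state$L + tot
  state
}

#' Run the stepping-stone colonization simulation
#'
#' Each generation: (1) on colonization generations (every
#' `expansion_interval`) the next vacant deme is founded; (2) new
#' mutations are injected; (3) adaptive loci undergo genic selection with
#' the deme- and factor-specific effective coefficient
#' `effective_s(E, s)`; (4) every locus drifts binomially at its deme's
#' size. Loci that are monomorphic pooled across occupied demes at the end
#' are flagged as unavailable for observation.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_state` with fields `freq` (demes x loci), a locus
#'   registry (`registry()`), `founded_gen`, `polymorphic`, `sizes`.
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  state <- new_sim_state(params)
  env <- params$env_profiles
  for (g in seq_len(params$total_generations)) {
    state$generation <- g
    if (g %% params$expansion_interval == 0 && state$occupied < params$K)
      state <- colonize_next_deme(state, params)
    state <- spawn_mutations(state, params)
    # selection on adaptive loci, by environmental factor
    ada <- which(state$class[seq_len(state$L)] == 3L)
    if (length(ada)) {
      etype <- trait_to_env(latent_to_trait(state$latent[ada], params), params)
      for (e in seq_len(params$n_env_types)) {
        cols <- ada[etype == e]
        if (!length(cols)) next
        se <- effective_s(env[seq_len(state$occupied), e], params$s)
        for (i in seq_len(state$occupied)) {
          if (se[i] == 0) next
          state$freq[i, cols] <- selection_update(state$freq[i, cols], se[i])
        }
      }
    }
    idx <- seq_len(state$L)
    for (i in seq_len(state$occupied))
      state$freq[i, idx] <- drift_update(state$freq[i, idx], state$sizes[i])
  }
  # trim and label
  idx <- seq_len(state$L)
  state$freq <- state$freq[, idx, drop = FALSE]
  state$class <- state$class[idx]
  state$origin_gen <- state$origin_gen[idx]
  state$origin_deme <- state$origin_deme[idx]
  state$latent <- state$latent[idx]
  cls <- c("neu", "new", "adv")[state$class]
  state$locus_ids <- sprintf("%s%06d", cls, seq_len(state$L))
  dimnames(state$freq) <- list(paste0("pop", seq_len(params$K)), state$locus_ids)
  occ <- seq_len(state$occupied)
  cmin <- apply(state$freq[occ, , drop = FALSE], 2, min)
  cmax <- apply(state$freq[occ, , drop = FALSE], 2, max)
  state$polymorphic <- cmax > 0 & cmin < 1
  state
}

#' @export
print.sim_state <- function(x, ...) {
  cat("sim_state: generation", x$generation, "-", x$occupied, "of",
      x$params$K, "demes occupied,", x$L, "loci (",
      sum(x$polymorphic), "polymorphic )\n")
  invisible(x)
}

#' Locus registry of a simulation
#'
#' @param state A `sim_state` returned by [run_simulation()].
#' @return Data frame with one row per locus: id, class
#'   (`init_neutral` / `new_neutral` / `adaptive`), origin generation and
#'   deme, target latent trait, trait, environmental factor, effect size
#'   and whether the locus is pooled-polymorphic.
#' @export
registry <- function(state) {
  p <- state$params
  trait <- ifelse(is.na(state$latent), NA_integer_, latent_to_trait(state$latent, p))
  data.frame(
    locus_id = state$locus_ids,
    class = c("init_neutral", "new_neutral", "adaptive")[state$class],
    origin_gen = state$origin_gen,
    origin_deme = state$origin_deme,
    latent = state$latent,
    trait = trait,
    env_type = ifelse(is.na(trait), NA_integer_, trait_to_env(trait, p)),
    gamma_G = ifelse(is.na(state$latent), NA_real_, p$gamma_G),
    polymorphic = state$polymorphic,
    stringsAsFactors = FALSE)
}

trait_ids <- function(p) {
  tpe <- p$traits_per_env
  paste0("T", rep(seq_len(p$n_env_types), each = tpe), ".", rep(seq_len(tpe), p$n_env_types))
}

#' Population mean trait values implied by the current frequencies
#'
#' The latent value of a monogenic latent trait in deme `i` is
#' `2 * gamma_G * q` summed over its surviving causal loci; a trait is the
#' sum of its latent traits. A latent trait with no causal locus
#' contributes 0.
#'
#' @param state A `sim_state`.
#' @return `K x n_traits` matrix of population trait means.
#' @export
compute_traits <- function(state) {
  p <- state$params
  ntr <- p$n_env_types * p$traits_per_env
  out <- matrix(0, p$K, ntr,
                dimnames = list(rownames(state$freq), trait_ids(p)))
  ada <- which(state$class == 3L)
  for (l in ada) {
    tr <- latent_to_trait(state$latent[l], p)
    out[, tr] <- out[, tr] + 2 * p$gamma_G * state$freq[, l]
  }
  out
}

#' Observe the simulation: SNP discovery and individual sampling
#'
#' Mimics SNP discovery and population sampling: uniform random subsets of
#' the pooled-polymorphic initial-neutral and new-neutral loci at the
#' configured counts (all available ones if fewer, with a message), plus
#' one surviving adaptive locus per latent trait (the one with the highest
#' across-deme frequency variance; ties broken at random). From every deme,
#' `sample_n_individuals` diploid individuals are sampled with dosages
#' drawn `Binomial(2, q)` independently per locus (Hardy-Weinberg and
#' linkage equilibrium within demes). Individual trait values are the
#' genotypic values from the sampled dosages at all surviving causal loci
#' of a trait plus normal noise `sigma_e`.
#'
#' @param state A completed `sim_state`.
#' @return An object of class `sim_output` with fields `genotypes`
#'   ([genotype_matrix()] of the observed SNPs), `freqs`
#'   ([allele_freq_table()] of the sample), `traits_pop` (true population
#'   means), `traits_ind` (individuals x traits), `env`, `registry`
#'   (observed loci), `founded_gen`, `state`.
#' @export
select_observed_snps <- function(state) {
  p <- state$params
  poly <- state$polymorphic
  pick <- function(cls, n_obs) {
    avail <- which(state$class == cls & poly)
    if (length(avail) <= n_obs) {
      if (length(avail) < n_obs)
        message("only ", length(avail), " polymorphic loci available for class ",
                cls, " (requested ", n_obs, ")")
      return(avail)
    }
    sort(sample(avail, n_obs))
  }
  obs_init <- pick(1L, p$n_obs_init_neutral)
  obs_new <- pick(2L, p$n_obs_new_neutral)
  occ <- seq_len(state$occupied)
  adv_poly <- which(state$class == 3L & poly)
  obs_adv <- integer(0)
  for (lat in seq_len(state$n_latents)) {
    cand <- adv_poly[state$latent[adv_poly] == lat]
    if (!length(cand)) next
    v <- apply(state$freq[occ, cand, drop = FALSE], 2, stats::var)
    best <- cand[v == max(v)]
    obs_adv <- c(obs_adv, if (length(best) > 1) sample(best, 1) else best)
  }
  observed <- c(obs_init, obs_new, obs_adv)
  causal_all <- which(state$class == 3L)          # every causal locus, observed or not
  sampled_cols <- union(observed, causal_all)

  n <- p$sample_n_individuals
  K <- p$K
  Lc <- length(sampled_cols)
  dosage <- matrix(NA_integer_, K * n, Lc)
  for (i in seq_len(K)) {
    q <- state$freq[i, sampled_cols]
    rows <- (i - 1) * n + seq_len(n)
    dosage[rows, ] <- matrix(
      stats::rbinom(n * Lc, 2L, rep(q, each = n)), n, Lc)
  }
  ind_ids <- paste0(rep(rownames(state$freq), each = n), "_i",
                    formatC(rep(seq_len(n), K), width = 2, flag = "0"))
  pop_of <- rep(rownames(state$freq), each = n)
  colnames(dosage) <- state$locus_ids[sampled_cols]
  rownames(dosage) <- ind_ids

  # individual trait values from all causal loci of each trait
  ntr <- p$n_env_types * p$traits_per_env
  gv <- matrix(0, K * n, ntr, dimnames = list(ind_ids, trait_ids(p)))
  for (l in causal_all) {
    tr <- latent_to_trait(state$latent[l], p)
    gv[, tr] <- gv[, tr] + p$gamma_G * dosage[, match(l, sampled_cols)]
  }
  sde <- p$sigma_e
  if (is.null(sde)) sde <- 0.5 * apply(gv, 2, stats::sd)
  sde <- rep(sde, length.out = ntr)
  sde[sde == 0] <- 1e-6
  traits_ind <- gv + matrix(stats::rnorm(length(gv), 0, rep(sde, each = K * n)),
                            nrow(gv), ntr)

  keep <- match(observed, sampled_cols)
  genotypes <- genotype_matrix(dosage[, keep, drop = FALSE], pop_of,
                               individual_ids = ind_ids,
                               locus_ids = state$locus_ids[observed])
  reg <- registry(state)[observed, ]
  out <- list(genotypes = genotypes,
              freqs = frequencies_from_genotypes(genotypes),
              traits_pop = compute_traits(state),
              traits_ind = traits_ind,
              env = p$env_profiles,
              registry = reg,
              founded_gen = state$founded_gen,
              state = state)
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output:", length(x$genotypes$individual_ids), "individuals,",
      length(x$genotypes$locus_ids), "observed SNPs,",
      ncol(x$traits_pop), "traits,", ncol(x$env), "environmental factors\n")
  invisible(x)
}

#' Simulate and observe in one call
#'
#' Convenience wrapper: [run_simulation()] followed by
#' [select_observed_snps()].
#'
#' @param params A [sim_params()] object.
#' @return A `sim_output`.
#' @export
simulate_range_expansion <- function(params) {
  select_observed_snps(run_simulation(params))
}
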