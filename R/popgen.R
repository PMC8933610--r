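#' Unbiased within-population allele matching
#'
#' Probability that two distinct alleles sampled without replacement from
#' one population match: `sum_a n_a (n_a - 1) / (n (n - 1))`.
#'
#' @param counts Integer vector of allele counts at one locus in one
#'   population.
#' @return The matching probability, or `NA` if fewer than two alleles
#'   were sampled.
#' @export
within_matching <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  sum(counts * (counts - 1)) / (n * (n - 1))
}

#' Between-population allele matching
#'
#' Probability that one allele drawn from each of two populations matches:
#' `sum_a p_a q_a`. For a biallelic locus described by counted-allele
#' frequencies `p` and `q` this is `p q + (1 - p)(1 - q)`.
#'
#' @param p,q Counted-allele frequencies in the two populations.
#' @return The matching probability.
#' @export
between_matching <- function(p, q) {
  p * q + (1 - p) * (1 - q)
}

## internal: matching matrices for a whole table ---------------------------

matching_components <- function(t) {
  f <- t$freq
  n <- t$n_alleles
  cA <- round(f * n)
  cB <- n - cA
  MW <- (cA * (cA - 1) + cB * (cB - 1)) / (n * (n - 1))
  MW[is.na(f) | n < 2] <- NA_real_
  # pairwise-average between matching per locus, over pairs with data
  fz <- f; fz[is.na(f)] <- 0
  def <- !is.na(f)
  s1 <- colSums(fz); s2 <- colSums(fz^2)
  g <- 1 - f; gz <- g; gz[is.na(g)] <- 0
  s1m <- colSums(gz); s2m <- colSums(gz^2)
  Kl <- colSums(def)
  pairsum <- ((s1^2 - s2) + (s1m^2 - s2m)) / 2
  MB <- ifelse(Kl >= 2, pairsum / (Kl * (Kl - 1) / 2), NA_real_)
  list(MW = MW, MB = MB)
}

#' Population-specific FST over loci
#'
#' Matching-based moment estimator of the population-specific fixation
#' index: for population `i`,
#' `psFST_i = sum_l (MW_il - MB_l) / sum_l (1 - MB_l)`
#' (a ratio of sums over loci, not a mean of per-locus ratios), where
#' `MW_il` is the unbiased within-population matching and `MB_l` the
#' between-population matching averaged over all population pairs. Smaller
#' values indicate older, more diverse populations; negative values are
#' legal. Standard errors are obtained by bootstrap over loci.
#'
#' @param t An [allele_freq_table()].
#' @param n_boot Bootstrap resamples over loci for the SE (0 disables).
#' @return An object of class `fst_result` with fields `psfst`, `se`,
#'   `locus_global_fst`, `n_loci`, `se_method`.
#' @export
population_specific_fst <- function(t, n_boot = 200) {
  stopifnot(inherits(t, "allele_freq_table"))
  if (nrow(t$freq) < 2) stop("at least two populations are required")
  mc <- matching_components(t)
  MW <- mc$MW; MB <- mc$MB
  Dnum <- sweep(MW, 2, MB, "-")            # NA where either undefined
  Dnum[, is.na(MB)] <- NA_real_
  Dden <- matrix(rep(1 - MB, each = nrow(MW)), nrow(MW))
  Dden[is.na(Dnum)] <- NA_real_
  num <- rowSums(Dnum, na.rm = TRUE)
  den <- rowSums(Dden, na.rm = TRUE)
  if (any(den <= 0))
    stop("psFST undefined: no polymorphic between-population contrast ",
         "for population(s) ", paste(rownames(MW)[den <= 0], collapse = ", "))
  psfst <- stats::setNames(num / den, rownames(MW))
  se <- rep(NA_real_, length(psfst))
  if (n_boot > 0) {
    L <- ncol(MW)
    bs <- matrix(NA_real_, n_boot, length(psfst))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(L, L, replace = TRUE)
      bs[b, ] <- rowSums(Dnum[, idx, drop = FALSE], na.rm = TRUE) /
        rowSums(Dden[, idx, drop = FALSE], na.rm = TRUE)
    }
    se <- apply(bs, 2, stats::sd)
  }
  structure(list(psfst = psfst, se = stats::setNames(se, names(psfst)),
                 locus_global_fst = locus_global_fst(t),
                 n_loci = sum(!is.na(MB)), se_method = "bootstrap over loci"),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("fst_result over", x$n_loci, "loci (SE:", x$se_method, ")\n")
  print(round(cbind(psfst = x$psfst, se = x$se), 4))
  invisible(x)
}

#' Locus-wise global FST
#'
#' Matching-based analogue of a global fixation index for one locus:
#' `(mean_i MW_il - MB_l) / (1 - MB_l)`; undefined where `MB_l = 1`
#' (all populations identical and monomorphic).
#'
#' @param t An [allele_freq_table()].
#' @param loci Optional locus ids or indices (default: all).
#' @return Named numeric vector of per-locus global FST (`NA` where
#'   undefined).
#' @export
locus_global_fst <- function(t, loci = NULL) {
  stopifnot(inherits(t, "allele_freq_table"))
  mc <- matching_components(t)
  mw_bar <- colMeans(mc$MW, na.rm = TRUE)
  denom <- 1 - mc$MB
  out <- ifelse(!is.na(mc$MB) & denom > 1e-12, (mw_bar - mc$MB) / denom, NA_real_)
  names(out) <- t$locus_ids
  if (!is.null(loci)) out <- out[loci]
  out
}

#' Select the top-FST SNP of each gene
#'
#' Keeps, for every gene, the locus with the highest locus-wise global
#' FST; ties are broken by locus id order. Genes with no eligible locus
#' (all loci undefined) are dropped with a message.
#'
#' @param t An [allele_freq_table()].
#' @param gene_of Named character vector mapping locus ids to gene ids.
#' @return An [allele_freq_table()] restricted to the selected loci, with
#'   attribute `gene_of` giving the gene of each kept locus.
#' @export
top_snp_per_gene <- function(t, gene_of) {
  stopifnot(inherits(t, "allele_freq_table"))
  if (is.null(names(gene_of))) stop("`gene_of` must be named by locus id")
  gfst <- locus_global_fst(t)
  loci <- intersect(t$locus_ids, names(gene_of))
  keep <- character(0)
  dropped <- 0L
  for (g in unique(gene_of[loci])) {
    cand <- sort(loci[gene_of[loci] == g])
    v <- gfst[cand]
    if (all(is.na(v))) { dropped <- dropped + 1L; next }
    keep <- c(keep, cand[which.max(v)])   # which.max: first max, ids sorted
  }
  if (dropped > 0) message("dropped ", dropped, " gene(s) with no eligible locus")
  sel <- match(keep, t$locus_ids)
  out <- allele_freq_table(t$freq[, sel, drop = FALSE],
                           t$n_alleles[, sel, drop = FALSE],
                           flipped = t$flipped[sel])
  attr(out, "gene_of") <- gene_of[keep]
  out
}
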