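#' Per-trait GWAS scan
#'
#' Ordinary least squares of each trait on per-locus dosage with
#' population-membership indicators as covariates (absorbing population
#' structure), two-sided t tests, and Benjamini-Hochberg q-values. Loci
#' that are monomorphic among the analysed individuals are skipped
#' (`NA` statistics, never significant).
#'
#' @param g A [genotype_matrix()].
#' @param traits Numeric matrix individuals x traits (rownames matching
#'   the genotype individual ids) or a single named vector.
#' @param alpha Significance level on the q-value scale.
#' @return For a single trait, an object of class `gwas_result` (fields
#'   `trait`, `table` with columns locus, beta, se, p, q, significant,
#'   `alpha`, `significant` locus ids); for a trait matrix, a named list
#'   of such objects.
#' @export
gwas_scan <- function(g, traits, alpha = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(dim(traits))) {
    traits <- matrix(traits, ncol = 1,
                     dimnames = list(names(traits), "trait"))
    single <- TRUE
  } else single <- FALSE
  traits <- as.matrix(traits)
  ids <- rownames(traits)
  if (is.null(ids)) {
    if (nrow(traits) != length(g$individual_ids))
      stop("trait rows must match genotype individuals")
    ids <- g$individual_ids
  }
  common <- intersect(g$individual_ids, ids)
  if (length(common) < 10) stop("need at least 10 individuals with genotype and trait data")
  X <- g$dosage[common, , drop = FALSE]
  pop <- factor(g$population[match(common, g$individual_ids)])
  M <- stats::model.matrix(~pop)
  QR <- qr(M)
  has_na <- colSums(is.na(X)) > 0
  RX <- matrix(NA_real_, nrow(X), ncol(X))
  RX[, !has_na] <- qr.resid(QR, X[, !has_na, drop = FALSE])
  cs_all <- colSums(RX^2)

  scan_one <- function(y, trait_name) {
    ok <- !is.na(y)
    L <- ncol(X)
    beta <- se <- p <- rep(NA_real_, L)
    if (all(ok)) {
      ry <- qr.resid(QR, y)
      cs <- cs_all
      use <- !has_na & cs > 1e-10
      b <- colSums(RX[, use, drop = FALSE] * ry) / cs[use]
      df <- length(y) - ncol(M) - 1
      rss <- sum(ry^2) - b^2 * cs[use]
      s2 <- pmax(rss, 0) / df
      sev <- sqrt(s2 / cs[use])
      tv <- b / sev
      beta[use] <- b; se[use] <- sev
      p[use] <- 2 * stats::pt(-abs(tv), df)
      todo <- which(has_na)
    } else todo <- seq_len(L)
    for (l in todo) {
      x <- X[, l]
      keep <- ok & !is.na(x)
      if (sum(keep) < 10) next
      Mk <- stats::model.matrix(~droplevels(pop[keep]))
      Qk <- qr(Mk)
      rx <- qr.resid(Qk, x[keep])
      cs <- sum(rx^2)
      if (cs <= 1e-10) next
      ryk <- qr.resid(Qk, y[keep])
      b <- sum(rx * ryk) / cs
      df <- sum(keep) - ncol(Mk) - 1
      if (df < 1) next
      s2 <- max(sum(ryk^2) - b^2 * cs, 0) / df
      beta[l] <- b; se[l] <- sqrt(s2 / cs)
      p[l] <- 2 * stats::pt(-abs(b / se[l]), df)
    }
    q <- rep(NA_real_, L)
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    sig <- !is.na(q) & q <= alpha
    tab <- data.frame(locus = g$locus_ids, beta = beta, se = se, p = p, q = q,
                      significant = sig, stringsAsFactors = FALSE)
    structure(list(trait = trait_name, table = tab, alpha = alpha,
                   significant = g$locus_ids[sig]),
              class = "gwas_result")
  }
  res <- lapply(seq_len(ncol(traits)), function(j)
    scan_one(traits[match(common, ids), j], colnames(traits)[j]))
  names(res) <- colnames(traits)
  if (single) res[[1]] else res
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("gwas_result for trait '", x$trait, "': ", nrow(x$table), " loci, ",
      length(x$significant), " significant at q <= ", x$alpha, "\n", sep = "")
  invisible(x)
}

#' Gene-environment correlation scan
#'
#' Pearson correlation, across populations, of every locus frequency
#' vector with every environmental variable; t-distributed p-values and
#' Benjamini-Hochberg q-values within each environment. Pairs involving a
#' zero-variance vector are skipped.
#'
#' @param t An [allele_freq_table()] (minor-allele oriented).
#' @param envs Populations x environments matrix.
#' @param alpha Significance level on the q-value scale.
#' @return Object of class `env_cor_result`: a data frame with columns
#'   `locus`, `env`, `r`, `n`, `p`, `q`, `significant`.
#' @export
gene_env_correlations <- function(t, envs, alpha = 0.05) {
  f <- if (inherits(t, "allele_freq_table")) t$freq else as.matrix(t)
  envs <- as.matrix(envs)
  pops <- intersect(rownames(f), rownames(envs))
  if (length(pops) < 4) stop("need at least 4 shared populations")
  f <- f[pops, , drop = FALSE]; envs <- envs[pops, , drop = FALSE]
  out <- list()
  for (e in seq_len(ncol(envs))) {
    ev <- envs[, e]
    r <- suppressWarnings(as.vector(stats::cor(f, ev, use = "pairwise.complete.obs")))
    nn <- colSums(!is.na(f) & !is.na(ev))
    ok <- !is.na(r) & nn >= 4
    tv <- r[ok] * sqrt((nn[ok] - 2) / pmax(1 - r[ok]^2, 1e-12))
    p <- 2 * stats::pt(-abs(tv), nn[ok] - 2)
    q <- stats::p.adjust(p, method = "BH")
    out[[e]] <- data.frame(locus = colnames(f)[ok],
                           env = colnames(envs)[e],
                           r = r[ok], n = nn[ok], p = p, q = q,
                           significant = q <= alpha,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("env_cor_result", class(res))
  res
}

#' Among-population trait-environment correlations
#'
#' Pairwise Pearson correlations over populations between every trait and
#' every environmental variable (pairwise-complete for missing data).
#' These correlations convert trait loadings into environmental loadings
#' in [environment_loadings()].
#'
#' @param traits Populations x traits matrix.
#' @param envs Populations x environments matrix.
#' @return Traits x environments correlation matrix.
#' @export
trait_env_correlations <- function(traits, envs) {
  traits <- as.matrix(traits); envs <- as.matrix(envs)
  if (is.null(rownames(traits)) || is.null(rownames(envs))) {
    if (nrow(traits) != nrow(envs))
      stop("tables without population ids must have matching row counts")
  } else {
    pops <- intersect(rownames(traits), rownames(envs))
    traits <- traits[pops, , drop = FALSE]
    envs <- envs[pops, , drop = FALSE]
  }
  if (nrow(traits) < 3) stop("need at least 3 shared populations")
  suppressWarnings(stats::cor(traits, envs, use = "pairwise.complete.obs"))
}
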