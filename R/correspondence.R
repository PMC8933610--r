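#' Build the composite population x (SNP, trait, environment) table
#'
#' Binds minor-allele SNP frequencies (as-is), min-max-scaled trait means,
#' and min-max-scaled environmental variables into one nonnegative table
#' for correspondence analysis. Every environmental variable contributes
#' two columns: the scaled value (`+NAME`) and its sign-reversed copy
#' (`-NAME`, i.e. `1 -` scaled value), so that positive and negative
#' gene/trait-environment correlations can both be read off the biplot.
#' Missing cells are mean-imputed within column (with a message); constant
#' trait/environment columns are dropped with a warning.
#'
#' @param freqs An [allele_freq_table()] (minor-allele oriented) or a
#'   populations x loci frequency matrix.
#' @param traits Populations x traits matrix of trait means.
#' @param envs Populations x environments matrix.
#' @return An object of class `composite_table`: fields `x` (the K x M
#'   matrix), `col_class` (`snp`/`trait`/`env_plus`/`env_minus`),
#'   `scaling` (per-column original min/max).
#' @export
build_composite_table <- function(freqs, traits, envs) {
  f <- if (inherits(freqs, "allele_freq_table")) freqs$freq else as.matrix(freqs)
  traits <- as.matrix(traits); envs <- as.matrix(envs)
  pops <- rownames(f)
  if (is.null(pops)) stop("frequency table must carry population ids")
  if (!setequal(pops, rownames(traits)) || !setequal(pops, rownames(envs)))
    stop("population ids must match across the three tables")
  traits <- traits[pops, , drop = FALSE]
  envs <- envs[pops, , drop = FALSE]

  impute <- function(m, what) {
    nmiss <- sum(is.na(m))
    if (nmiss > 0) {
      message("mean-imputing ", nmiss, " missing ", what, " cell(s)")
      for (j in seq_len(ncol(m))) {
        mj <- m[, j]
        mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
        m[, j] <- mj
      }
    }
    m
  }
  f <- impute(f, "SNP"); traits <- impute(traits, "trait"); envs <- impute(envs, "environment")

  minmax <- function(m, what) {
    lo <- apply(m, 2, min); hi <- apply(m, 2, max)
    keep <- hi > lo
    if (!all(keep))
      warning("dropping constant ", what, " column(s): ",
              paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
    sc <- sweep(sweep(m, 2, lo[keep], "-"), 2, (hi - lo)[keep], "/")
    list(x = sc, lo = lo[keep], hi = hi[keep])
  }
  tr <- minmax(traits, "trait")
  ev <- minmax(envs, "environment")
  env_plus <- ev$x; colnames(env_plus) <- paste0("+", colnames(ev$x))
  env_minus <- 1 - ev$x; colnames(env_minus) <- paste0("-", colnames(ev$x))
  x <- cbind(f, tr$x, env_plus, env_minus)
  col_class <- c(rep("snp", ncol(f)), rep("trait", ncol(tr$x)),
                 rep("env_plus", ncol(env_plus)), rep("env_minus", ncol(env_minus)))
  structure(list(x = x, col_class = col_class,
                 scaling = list(trait = tr[c("lo", "hi")], env = ev[c("lo", "hi")])),
            class = "composite_table")
}

#' Correspondence analysis
#'
#' Standard CA by SVD of the chi-square standardized residuals: with
#' `P = X / n`, row masses `r` and column masses `c`,
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed as `U D V'`; row
#' and column principal coordinates are `D_r^{-1/2} U D` and
#' `D_c^{-1/2} V D`, and total inertia equals `sum(D^2)` = Pearson
#' chi-square / n. Axis signs are fixed by making the largest-magnitude
#' column coordinate positive on every axis. Zero-mass rows or columns are
#' dropped with a warning.
#'
#' @param x A [build_composite_table()] result or a nonnegative matrix.
#' @param d Number of axes to retain (default: all with positive singular
#'   value).
#' @return Object of class `ca_result`: `row_coords`, `col_coords`
#'   (principal coordinates), `sv` (singular values), `inertia_prop`,
#'   `total_inertia`, `row_mass`, `col_mass`, `col_class`.
#' @export
correspondence_analysis <- function(x, d = NULL) {
  col_class <- NULL
  if (inherits(x, "composite_table")) { col_class <- x$col_class; x <- x$x }
  x <- as.matrix(x)
  if (any(x < 0)) stop("correspondence analysis requires a nonnegative table")
  n <- sum(x)
  if (n <= 0) stop("table total must be positive")
  rkeep <- rowSums(x) > 0; ckeep <- colSums(x) > 0
  if (!all(rkeep) || !all(ckeep)) {
    warning("dropping ", sum(!rkeep), " zero-mass row(s) and ",
            sum(!ckeep), " zero-mass column(s)")
    x <- x[rkeep, ckeep, drop = FALSE]
    if (!is.null(col_class)) col_class <- col_class[ckeep]
  }
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least a 2 x 2 table")
  P <- x / n
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  tol <- max(dim(S)) * max(sv$d) * .Machine$double.eps * 10
  pos <- sv$d > tol
  k <- sum(pos)
  if (k == 0) {
    # independence table: no structure beyond the margins
    k <- 1; sv$d[1] <- 0
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  dvals <- sv$d[seq_len(k)]
  colpc <- sweep(V, 1, sqrt(cc), "/") %*% diag(dvals, k)
  # deterministic axis signs: largest-|column coordinate| positive
  for (j in seq_len(k)) {
    i <- which.max(abs(colpc[, j]))
    if (colpc[i, j] < 0) { colpc[, j] <- -colpc[, j]; U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rowpc <- sweep(U, 1, sqrt(r), "/") %*% diag(dvals, k)
  dimnames(rowpc) <- list(rownames(x), paste0("axis", seq_len(k)))
  dimnames(colpc) <- list(colnames(x), paste0("axis", seq_len(k)))
  total <- sum(sv$d[pos]^2)
  iprop <- if (total > 0) dvals^2 / total else rep(0, k)
  if (!is.null(d)) {
    d <- min(d, k)
    rowpc <- rowpc[, seq_len(d), drop = FALSE]
    colpc <- colpc[, seq_len(d), drop = FALSE]
    dvals <- dvals[seq_len(d)]; iprop <- iprop[seq_len(d)]
  }
  structure(list(row_coords = rowpc, col_coords = colpc, sv = dvals,
                 inertia_prop = iprop, total_inertia = total,
                 row_mass = r, col_mass = cc, col_class = col_class),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("ca_result:", nrow(x$row_coords), "rows x", nrow(x$col_coords),
      "columns; total inertia", signif(x$total_inertia, 4), "\n")
  cat("inertia proportions:", paste(signif(x$inertia_prop[seq_len(min(5, length(x$inertia_prop)))], 3),
                                    collapse = " "), "\n")
  invisible(x)
}

#' Annotate CA populations with psFST-based age colors
#'
#' Attaches each population's population-specific FST and a normalized
#' color scalar in `[0, 1]`: 0 for the smallest psFST (oldest population,
#' conventionally drawn red) and 1 for the largest (youngest, blue). A
#' constant psFST vector maps every population to 0.5.
#'
#' @param ca A `ca_result` whose rows are populations.
#' @param fst An `fst_result` from [population_specific_fst()].
#' @return The `ca_result` with added fields `psfst` and `age_scalar`.
#' @export
annotate_population_ages <- function(ca, fst) {
  stopifnot(inherits(ca, "ca_result"), inherits(fst, "fst_result"))
  pops <- rownames(ca$row_coords)
  if (!all(pops %in% names(fst$psfst)))
    stop("psFST results are missing population(s): ",
         paste(setdiff(pops, names(fst$psfst)), collapse = ", "))
  ps <- fst$psfst[pops]
  rng <- range(ps)
  ca$psfst <- ps
  ca$age_scalar <- if (rng[2] > rng[1]) (ps - rng[1]) / (rng[2] - rng[1]) else
    stats::setNames(rep(0.5, length(ps)), names(ps))
  ca
}
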