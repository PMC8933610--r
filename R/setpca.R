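#' Selection-on-edge-by-trait (SET) matrix
#'
#' Binds per-trait edge-selection vectors column-wise into the central
#' object of the analysis: rows are admixture-graph tree edges, columns
#' are traits, entries are the standardized positive-selection parameters
#' `alpha`. All vectors must come from the same graph (identical edge
#' sets); column order follows the input order.
#'
#' @param vectors Named list of `edge_selection` objects (or of numeric
#'   vectors named by edge), or an edges x traits matrix.
#' @return Object of class `set_matrix`: fields `alpha` (matrix),
#'   `edge_ids`, `trait_ids`.
#' @export
build_set_matrix <- function(vectors) {
  if (is.matrix(vectors)) {
    m <- vectors
  } else {
    if (length(vectors) == 0) stop("no edge-selection vectors supplied")
    get_alpha <- function(v) if (inherits(v, "edge_selection")) v$alpha else v
    ref <- names(get_alpha(vectors[[1]]))
    cols <- lapply(vectors, function(v) {
      a <- get_alpha(v)
      if (!identical(sort(names(a)), sort(ref)))
        stop("edge sets differ across traits; all vectors must share one graph")
      a[ref]
    })
    m <- do.call(cbind, cols)
    rownames(m) <- ref
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("SET matrix needs edge and trait names")
  m[is.na(m)] <- 0
  structure(list(alpha = m, edge_ids = rownames(m), trait_ids = colnames(m)),
            class = "set_matrix")
}

#' @export
print.set_matrix <- function(x, ...) {
  cat("set_matrix:", length(x$edge_ids), "edges x", length(x$trait_ids), "traits\n")
  invisible(x)
}

#' PCA of the SET matrix
#'
#' Columns are centered (and scaled to unit variance when `standardize`,
#' the default) and decomposed by SVD. Edge scores are the projections of
#' the edges onto the components; trait loadings are the right singular
#' vectors (orthonormal columns). Component signs are fixed by making the
#' largest-magnitude trait loading positive. Zero-variance columns are
#' dropped with a warning under standardization.
#'
#' @param m A [build_set_matrix()] result (or edges x traits matrix).
#' @param standardize Scale trait columns to unit variance.
#' @param components Optional cap on the number of components returned.
#' @return Object of class `set_pca`: `scores` (edges x components),
#'   `loadings` (traits x components), `var_prop`
#'   (variance-explained proportions over all components), `center`,
#'   `scale`, `trait_ids`, `edge_ids`, `dropped` (trait columns dropped).
#' @export
set_pca <- function(m, standardize = TRUE, components = NULL) {
  if (!inherits(m, "set_matrix")) m <- build_set_matrix(m)
  x <- m$alpha
  if (nrow(x) < 2 || ncol(x) < 2) stop("need at least 2 edges and 2 traits")
  dropped <- character(0)
  if (standardize) {
    v <- apply(x, 2, stats::var)
    if (any(v <= 1e-300)) {
      dropped <- colnames(x)[v <= 1e-300]
      warning("dropping zero-variance trait column(s): ",
              paste(dropped, collapse = ", "))
      x <- x[, v > 1e-300, drop = FALSE]
    }
  }
  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  xc <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  sv <- svd(xc)
  k <- min(dim(xc))
  var_all <- sv$d^2 / sum(sv$d^2)
  if (!is.null(components)) k <- min(k, components)
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  dk <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(dk, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(V) <- list(colnames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = V,
                 var_prop = var_all[seq_len(k)], var_prop_all = var_all,
                 center = ctr, scale = scl,
                 trait_ids = colnames(x), edge_ids = rownames(x),
                 dropped = dropped, standardize = standardize),
            class = "set_pca")
}

#' @export
print.set_pca <- function(x, ...) {
  cat("set_pca:", length(x$edge_ids), "edges,", length(x$trait_ids),
      "traits; variance explained:",
      paste0(round(100 * x$var_prop[seq_len(min(4, length(x$var_prop)))], 1),
             "%", collapse = " "), "\n")
  invisible(x)
}

#' Factor loadings of environmental variables
#'
#' The conditional loading of an environment via one trait is the product
#' of that trait's component loading and the among-population correlation
#' between trait and environment; summing the conditional loadings over
#' all traits gives the unconditioned environmental loading:
#' `load(E, k) = sum_t load(t, k) * r(t, E)`. Missing correlations count
#' as 0 (their number is attached as attribute `n_missing_r`). The
#' loading of a sign-reversed environment is minus the loading of the
#' original, so reversed copies are not duplicated here.
#'
#' @param trait_loadings A `set_pca` object or traits x components
#'   loading matrix.
#' @param trait_env_r Traits x environments correlation matrix from
#'   [trait_env_correlations()].
#' @return Environments x components loading matrix.
#' @export
environment_loadings <- function(trait_loadings, trait_env_r) {
  L <- if (inherits(trait_loadings, "set_pca")) trait_loadings$loadings
       else as.matrix(trait_loadings)
  r <- as.matrix(trait_env_r)
  shared <- intersect(rownames(L), rownames(r))
  if (length(shared) == 0) stop("no shared traits between loadings and correlations")
  L <- L[shared, , drop = FALSE]
  r <- r[shared, , drop = FALSE]
  nmiss <- sum(is.na(r))
  r[is.na(r)] <- 0
  out <- crossprod(r, L)               # envs x components
  attr(out, "n_missing_r") <- nmiss
  out
}

#' Signed edge scores of one principal component
#'
#' `score_e = sum_t alpha_{e,t} * load(t, k)` on the same
#' centering/scaling as the PCA, i.e. exactly the PCA edge score for
#' component `k`. Positive/negative scores mark edges with selection
#' toward increased/decreased values of the component's trait combination
#' (the red/blue coloring of the admixture graph).
#'
#' @param m The [build_set_matrix()] the PCA was run on.
#' @param pca The corresponding `set_pca`.
#' @param k Component index.
#' @return Data frame with columns `edge`, `score`, `sign`.
#' @export
pc_edge_scores <- function(m, pca, k) {
  if (!inherits(m, "set_matrix")) m <- build_set_matrix(m)
  if (k > ncol(pca$loadings)) stop("component ", k, " not available")
  x <- m$alpha[, pca$trait_ids, drop = FALSE]
  xc <- sweep(sweep(x, 2, pca$center, "-"), 2, pca$scale, "/")
  sc <- as.vector(xc %*% pca$loadings[, k])
  data.frame(edge = rownames(x), score = sc,
             sign = ifelse(sc >= 0, "increase", "decrease"),
             stringsAsFactors = FALSE)
}
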