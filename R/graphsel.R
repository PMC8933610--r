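#' Drift covariance of population allele frequencies
#'
#' TreeMix-style estimator: with `qbar_l` the unweighted across-population
#' mean frequency at locus `l`,
#' `W_ij = mean_l (q_il - qbar_l)(q_jl - qbar_l) / (qbar_l (1 - qbar_l))`.
#' Loci that are fixed on average (`qbar` 0 or 1) or carry missing cells
#' are skipped.
#'
#' @param t An [allele_freq_table()] or frequency matrix.
#' @return Object of class `drift_cov`: fields `W` (K x K symmetric
#'   matrix), `n_loci`.
#' @export
drift_covariance <- function(t) {
  f <- if (inherits(t, "allele_freq_table")) t$freq else as.matrix(t)
  complete <- colSums(is.na(f)) == 0
  f <- f[, complete, drop = FALSE]
  qbar <- colMeans(f)
  keep <- qbar > 0 & qbar < 1
  f <- f[, keep, drop = FALSE]
  qbar <- qbar[keep]
  if (ncol(f) == 0) stop("no usable loci for the drift covariance")
  if (ncol(f) < 50)
    warning("drift covariance estimated from only ", ncol(f), " loci")
  X <- sweep(f, 2, qbar, "-")
  X <- sweep(X, 2, sqrt(qbar * (1 - qbar)), "/")
  W <- tcrossprod(X) / ncol(f)
  structure(list(W = W, n_loci = ncol(f)), class = "drift_cov")
}

#' Fit a population tree to a drift covariance
#'
#' Pairwise drift distances `d_ij = W_ii + W_jj - 2 W_ij` are turned into
#' a neighbor-joining topology whose branch lengths are then refitted by
#' nonnegative least squares of path distances against `d`. The tree is
#' rooted at the attachment of the user-specified root population and
#' internal nodes are relabelled `a1, a2, ...` in preorder.
#'
#' @param w A `drift_cov` from [drift_covariance()] (or a covariance
#'   matrix with dimnames).
#' @param root Population id to root at (no automatic rooting).
#' @return An [admixture_graph()] (tree; no admixture edges). The residual
#'   sum of squares of path distances is attached as attribute `rss`.
#' @export
fit_tree <- function(w, root) {
  W <- if (inherits(w, "drift_cov")) w$W else as.matrix(w)
  if (!all(is.finite(W))) stop("drift covariance contains non-finite values")
  pops <- rownames(W)
  if (is.null(pops)) stop("covariance matrix must carry population ids")
  if (!root %in% pops) stop("root '", root, "' is not a population")
  K <- nrow(W)
  D <- outer(diag(W), diag(W), "+") - 2 * W
  D[D < 0] <- 0
  dimnames(D) <- dimnames(W)
  if (!all(is.finite(D))) stop("non-finite drift distances")
  if (K == 2) {
    h <- D[1, 2] / 2
    par <- stats::setNames(c("a1", "a1"), pops)
    return(admixture_graph(par, stats::setNames(c(h, h), pops), root = "a1"))
  }
  phy <- ape::nj(stats::as.dist(D))
  # refit branch lengths: NNLS of edge-path incidence against distances
  pairs <- utils::combn(K, 2)
  tipidx <- match(phy$tip.label, phy$tip.label) # identity; tips are 1..K
  nedge <- nrow(phy$edge)
  edge_key <- paste(phy$edge[, 1], phy$edge[, 2])
  A <- matrix(0, ncol(pairs), nedge)
  b <- numeric(ncol(pairs))
  for (pr in seq_len(ncol(pairs))) {
    i <- match(phy$tip.label[pairs[1, pr]], phy$tip.label)
    j <- match(phy$tip.label[pairs[2, pr]], phy$tip.label)
    np <- ape::nodepath(phy, i, j)
    for (s in seq_len(length(np) - 1)) {
      e <- match(paste(np[s], np[s + 1]), edge_key)
      if (is.na(e)) e <- match(paste(np[s + 1], np[s]), edge_key)
      A[pr, e] <- 1
    }
    b[pr] <- D[phy$tip.label[pairs[1, pr]], phy$tip.label[pairs[2, pr]]]
  }
  fit <- pracma::lsqnonneg(A, b)
  phy$edge.length <- fit$x
  rooted <- ape::root(phy, outgroup = root, resolve.root = TRUE)
  g <- phylo_to_graph(rooted)
  attr(g, "rss") <- sum((A %*% fit$x - b)^2)
  g
}

## internal: linear-mixture edge usage and implied leaf covariance ---------

# mass of each tree edge's drift in each leaf's ancestry
# (admixture mixes at the top of the child edge: x_c = (1-w) x_p + w x_s + d_c)
graph_edge_mass <- function(g) {
  ed <- graph_edges(g)
  U <- matrix(0, nrow(ed), length(g$leaves),
              dimnames = list(ed$edge, g$leaves))
  aw <- ap <- NULL
  if (!is.null(g$admix) && nrow(g$admix) > 0) {
    aw <- stats::setNames(g$admix$weight, g$admix$child)
    ap <- stats::setNames(g$admix$parent, g$admix$child)
  }
  eidx <- stats::setNames(seq_len(nrow(ed)), ed$child)
  for (lf in g$leaves) {
    climb <- function(node, mass) {
      if (node == g$root || mass < 1e-10) return(invisible())
      U[eidx[[node]], lf] <<- U[eidx[[node]], lf] + mass
      w <- if (!is.null(aw) && node %in% names(aw)) aw[[node]] else 0
      climb(g$parent[[node]], mass * (1 - w))
      if (w > 0) climb(ap[[node]], mass * w)
    }
    climb(lf, 1)
  }
  U
}

# leaf covariance implied by the graph under the Brownian drift model
graph_leaf_cov <- function(g) {
  U <- graph_edge_mass(g)
  ed <- graph_edges(g)
  crossprod(U * sqrt(ed$length), U * sqrt(ed$length))
}

#' Greedily add admixture edges to a fitted tree
#'
#' For each of `n_mig` rounds, every candidate admixture edge
#' (source node into a non-root node, weight fitted by least squares of
#' the graph-implied, doubly centered covariance against the observed
#' drift covariance) is scored, and the one that maximally reduces the
#' residual sum of squares is added.
#'
#' @param g An [admixture_graph()] from [fit_tree()].
#' @param w A `drift_cov` (the same data the tree was fitted to).
#' @param n_mig Number of admixture edges to add (default 0 = identity).
#' @return The graph with admixture edges and attribute `rss_path`
#'   (residual sum of squares after each round, starting with the tree).
#' @export
add_migration_edges <- function(g, w, n_mig = 0) {
  W <- if (inherits(w, "drift_cov")) w$W else as.matrix(w)
  pops <- g$leaves
  W <- W[pops, pops]
  K <- length(pops)
  C <- diag(K) - 1 / K
  center <- function(m) C %*% m %*% C
  Wc <- center(W)
  rss_of <- function(graph) sum((center(graph_leaf_cov(graph)[pops, pops]) - Wc)^2)
  rss_path <- rss_of(g)
  if (n_mig == 0) { attr(g, "rss_path") <- rss_path; return(g) }
  for (round in seq_len(n_mig)) {
    best <- NULL
    base_admixed <- if (is.null(g$admix)) character(0) else g$admix$child
    for (child in setdiff(g$nodes, g$root)) {
      if (child %in% base_admixed) next
      desc <- c(child, graph_descendants(g, child))
      for (src in setdiff(g$nodes, c(desc, g$parent[[child]]))) {
        obj <- function(wt) {
          cand <- g
          cand$admix <- rbind(g$admix,
                              data.frame(child = child, parent = src, weight = wt,
                                         stringsAsFactors = FALSE))
          rss_of(cand)
        }
        opt <- stats::optimize(obj, c(0.001, 0.499))
        if (is.null(best) || opt$objective < best$rss)
          best <- list(child = child, parent = src, weight = opt$minimum,
                       rss = opt$objective)
      }
    }
    if (is.null(best) || best$rss >= rss_path[length(rss_path)]) break
    g$admix <- rbind(g$admix,
                     data.frame(child = best$child, parent = best$parent,
                                weight = best$weight, stringsAsFactors = FALSE))
    rss_path <- c(rss_path, best$rss)
  }
  attr(g, "rss_path") <- rss_path
  g
}

#' Polygenic scores of the populations
#'
#' `Z_i = 2 sum_j beta_j q_ij` over the trait's significant GWAS loci.
#'
#' @param freqs An [allele_freq_table()].
#' @param gwas A `gwas_result` from [gwas_scan()] (its significant-locus
#'   set must be nonempty), or a named vector of effect sizes to use
#'   directly.
#' @return Named numeric vector of per-population scores.
#' @export
polygenic_scores <- function(freqs, gwas) {
  beta <- gwas_betas(gwas)
  q <- freqs$freq[, names(beta), drop = FALSE]
  if (anyNA(q)) stop("missing frequencies at score loci")
  stats::setNames(2 * as.vector(q %*% beta), rownames(q))
}

gwas_betas <- function(gwas) {
  if (inherits(gwas, "gwas_result")) {
    sig <- gwas$significant
    if (length(sig) == 0)
      stop("no significant loci for trait '", gwas$trait, "'")
    tab <- gwas$table
    stats::setNames(tab$beta[match(sig, tab$locus)], sig)
  } else {
    if (is.null(names(gwas))) stop("effect sizes must be named by locus")
    gwas
  }
}

#' Additive genic variance implied by effect sizes
#'
#' `V_A = 4 sum_j beta_j^2 qbar_j (1 - qbar_j)` with `qbar` the pooled
#' (unweighted across-population) mean frequency; this sets the scale of
#' one unit of drift for the polygenic score.
#'
#' @param freqs An [allele_freq_table()].
#' @param gwas A `gwas_result` or named effect-size vector.
#' @return The additive variance (scalar).
#' @export
additive_variance <- function(freqs, gwas) {
  beta <- gwas_betas(gwas)
  qbar <- colMeans(freqs$freq[, names(beta), drop = FALSE], na.rm = TRUE)
  4 * sum(beta^2 * qbar * (1 - qbar))
}

#' Standardized per-edge polygenic selection parameters
#'
#' Reconstructs ancestral polygenic scores by generalized least squares
#' under a Brownian drift model on the graph (per-edge variance
#' `V_A * c_e`; admixture children are tied to
#' `w * parent_admix + (1 - w) * parent_tree`), then standardizes every
#' tree-edge contrast by its exact sampling SD under the neutral model:
#' `alpha_e = (zhat_child - zhat_parent) / sqrt(V_A * v_e)`, where `v_e`
#' is the null variance of the GLS contrast implied by the fitted graph.
#' Under pure drift each `alpha_e` is standard normal, so `|alpha|`
#' measures allele-frequency change of trait-associated SNPs beyond
#' drift; the sign gives the direction of change of the trait value
#' along the edge. Edges with (near-)zero drift length get `alpha = 0`.
#'
#' @param g An [admixture_graph()].
#' @param z Named leaf polygenic scores from [polygenic_scores()].
#' @param v_a Additive variance from [additive_variance()].
#' @param trait Optional trait id carried through to the result.
#' @return Object of class `edge_selection`: fields `alpha` (named by
#'   `"parent-child"` edge), `c` (drift lengths), `v_null` (contrast null
#'   variances, on the `V_A = 1` scale), `zhat` (scores at every node),
#'   `trait`, `v_a`.
#' @export
estimate_edge_selection <- function(g, z, v_a, trait = NULL) {
  stopifnot(inherits(g, "admixture_graph"))
  if (!all(g$leaves %in% names(z)))
    stop("scores missing for leaves: ",
         paste(setdiff(g$leaves, names(z)), collapse = ", "))
  if (!is.finite(v_a) || v_a <= 0) stop("additive variance must be positive")
  ed <- graph_edges(g)
  if (sum(ed$length) <= 0) stop("tree has no positive drift length")
  nodes <- g$nodes
  leaves <- g$leaves
  internals <- setdiff(nodes, leaves)
  eps <- 1e-8 * max(ed$length)
  wgt <- 1 / pmax(ed$length, eps)
  aw <- ap <- NULL
  if (!is.null(g$admix) && nrow(g$admix) > 0) {
    aw <- stats::setNames(g$admix$weight, g$admix$child)
    ap <- stats::setNames(g$admix$parent, g$admix$child)
  }
  B <- matrix(0, nrow(ed), length(nodes), dimnames = list(ed$edge, nodes))
  for (e in seq_len(nrow(ed))) {
    ch <- ed$child[e]
    w <- if (!is.null(aw) && ch %in% names(aw)) aw[[ch]] else 0
    B[e, ch] <- 1
    B[e, ed$parent[e]] <- -(1 - w)
    if (w > 0) B[e, ap[[ch]]] <- B[e, ap[[ch]]] - w
  }
  M <- t(B) %*% (wgt * B)
  Mff <- M[internals, internals, drop = FALSE]
  Mfl <- M[internals, leaves, drop = FALSE]
  G <- tryCatch(solve(Mff, -Mfl), error = function(e)
    stop("singular GLS system (", conditionMessage(e), "); graph: ",
         length(leaves), " leaves, ", nrow(ed), " edges, root ", g$root))
  A <- matrix(0, length(nodes), length(leaves), dimnames = list(nodes, leaves))
  A[internals, ] <- G
  A[leaves, ] <- diag(length(leaves))
  zl <- z[leaves]
  zhat <- stats::setNames(as.vector(A %*% zl), nodes)
  Acon <- A[ed$child, , drop = FALSE] - A[ed$parent, , drop = FALSE]
  Tm <- graph_leaf_cov(g)[leaves, leaves]
  v_null <- rowSums((Acon %*% Tm) * Acon)
  contrast <- zhat[ed$child] - zhat[ed$parent]
  tol <- 1e-10 * max(v_null, 1e-300)
  alpha <- ifelse(v_null > tol & ed$length > eps,
                  contrast / sqrt(v_a * v_null), 0)
  structure(list(alpha = stats::setNames(alpha, ed$edge),
                 c = stats::setNames(ed$length, ed$edge),
                 v_null = stats::setNames(v_null, ed$edge),
                 zhat = zhat, trait = trait, v_a = v_a),
            class = "edge_selection")
}

#' @export
print.edge_selection <- function(x, ...) {
  cat("edge_selection", if (!is.null(x$trait)) paste0("for trait '", x$trait, "'"),
      ":", length(x$alpha), "edges, V_A =", signif(x$v_a, 4), "\n")
  invisible(x)
}

#' Per-trait edge-selection scan over a GWAS collection
#'
#' Runs [polygenic_scores()], [additive_variance()] and
#' [estimate_edge_selection()] for every trait whose GWAS has at least one
#' significant locus, and binds the results into a SET matrix. Traits
#' without significant loci are omitted and reported.
#'
#' @param g An [admixture_graph()].
#' @param freqs An [allele_freq_table()].
#' @param gwas_list Named list of `gwas_result` objects (one per trait).
#' @return A [build_set_matrix()] result (attribute `omitted` lists
#'   skipped traits).
#' @export
edge_selection_scan <- function(g, freqs, gwas_list) {
  vecs <- list()
  omitted <- character(0)
  for (nm in names(gwas_list)) {
    gw <- gwas_list[[nm]]
    if (inherits(gw, "gwas_result") && length(gw$significant) == 0) {
      omitted <- c(omitted, nm)
      next
    }
    z <- polygenic_scores(freqs, gw)
    va <- additive_variance(freqs, gw)
    vecs[[nm]] <- estimate_edge_selection(g, z, va, trait = nm)
  }
  if (length(omitted))
    message("omitting ", length(omitted), " trait(s) with no significant loci: ",
            paste(omitted, collapse = ", "))
  m <- build_set_matrix(vecs)
  attr(m, "omitted") <- omitted
  m
}
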