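#' Admixture graph
#'
#' Rooted graph of population splits. Tree edges `parent -> child` carry
#' nonnegative drift lengths; optional admixture edges add a second,
#' weighted parent to a node. Leaves are the populations; internal nodes
#' are conventionally labelled `a1, a2, ...`.
#'
#' @param parent Named character vector: for each non-root node (name),
#'   its tree parent (value).
#' @param length Named numeric vector of drift lengths `c_e >= 0`, named by
#'   child node, one per tree edge.
#' @param root Root node id (the single node without a tree parent).
#' @param admix Optional data frame with columns `child`, `parent`,
#'   `weight` (in (0, 1)): admixture edges. The child must also have a tree
#'   parent; the admixture parent contributes fraction `weight` of the
#'   child's ancestry.
#' @return An object of class `admixture_graph`.
#' @export
admixture_graph <- function(parent, length, root, admix = NULL) {
  if (is.null(names(parent)) || is.null(names(length)))
    stop("`parent` and `length` must be named by child node")
  length <- length[names(parent)]
  if (anyNA(length)) stop("every tree edge needs a drift length")
  if (any(length < 0)) stop("drift lengths must be nonnegative")
  if (root %in% names(parent)) stop("root must not have a tree parent")
  nodes <- unique(c(root, names(parent), parent))
  if (!all(parent %in% nodes)) stop("dangling parent reference")
  # acyclicity / single root: every node must reach the root
  for (n in names(parent)) {
    seen <- character(0); cur <- n
    while (cur != root) {
      if (cur %in% seen) stop("cycle detected through node '", cur, "'")
      seen <- c(seen, cur)
      if (!cur %in% names(parent)) stop("node '", cur, "' has no path to the root")
      cur <- parent[[cur]]
    }
  }
  if (!is.null(admix)) {
    admix <- as.data.frame(admix)
    stopifnot(all(c("child", "parent", "weight") %in% names(admix)))
    if (any(admix$weight <= 0 | admix$weight >= 1))
      stop("admixture weights must lie in (0, 1)")
    if (!all(admix$child %in% names(parent)))
      stop("admixture children must also have a tree parent")
    if (!all(admix$parent %in% nodes)) stop("dangling admixture parent")
    if (anyDuplicated(admix$child)) stop("at most one admixture parent per node")
    for (i in seq_len(nrow(admix)))
      if (admix$parent[i] %in% graph_descendants(list(parent = parent, root = root), admix$child[i]))
        stop("admixture parent must not descend from its child")
  }
  leaves <- setdiff(nodes, parent)
  structure(list(parent = parent, length = length, root = root,
                 admix = admix, nodes = nodes, leaves = leaves),
            class = "admixture_graph")
}

#' @export
print.admixture_graph <- function(x, ...) {
  cat("admixture_graph:", length(x$leaves), "leaves,",
      length(x$parent), "tree edges,",
      if (is.null(x$admix)) 0 else nrow(x$admix), "admixture edges; root =",
      x$root, "\n")
  invisible(x)
}

#' Tree edges of an admixture graph
#'
#' @param g An [admixture_graph()].
#' @return Data frame with columns `edge` (`"parent-child"`), `parent`,
#'   `child`, `length`, in a stable order (preorder of children).
#' @export
graph_edges <- function(g) {
  ord <- graph_preorder(g)
  ch <- ord[ord %in% names(g$parent)]
  data.frame(edge = paste0(g$parent[ch], "-", ch),
             parent = unname(g$parent[ch]), child = ch,
             length = unname(g$length[ch]), stringsAsFactors = FALSE)
}

graph_children <- function(g, node) names(g$parent)[g$parent == node]

graph_preorder <- function(g) {
  out <- character(0)
  visit <- function(n) {
    out <<- c(out, n)
    for (c in graph_children(g, n)) visit(c)
  }
  visit(g$root)
  out
}

graph_descendants <- function(g, node) {
  kids <- names(g$parent)[g$parent == node]
  out <- kids
  for (k in kids) out <- c(out, graph_descendants(g, k))
  out
}

#' Write an admixture graph as Newick
#'
#' Only the tree part of the graph can be serialized; admixture edges must
#' be absent or explicitly stripped.
#'
#' @param g An [admixture_graph()].
#' @param path Optional output path; if `NULL` the Newick string is
#'   returned.
#' @param strip_admixture Drop admixture edges before writing.
#' @return The Newick string, invisibly if written to `path`.
#' @export
write_newick <- function(g, path = NULL, strip_admixture = FALSE) {
  stopifnot(inherits(g, "admixture_graph"))
  if (!is.null(g$admix) && nrow(g$admix) > 0) {
    if (!strip_admixture)
      stop("graph has admixture edges; use strip_admixture = TRUE")
    g$admix <- NULL
  }
  build <- function(n) {
    kids <- graph_children(g, n)
    lab <- if (length(kids) == 0) n else
      paste0("(", paste(vapply(kids, build, ""), collapse = ","), ")", n)
    if (n == g$root) lab else paste0(lab, ":", format(g$length[[n]], digits = 12))
  }
  nwk <- paste0(build(g$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' Convert an ape phylo tree to an admixture graph
#'
#' Internal nodes are relabelled `a1, a2, ...` in preorder from the root.
#'
#' @param phy A rooted `phylo` object with edge lengths.
#' @return An [admixture_graph()].
#' @export
phylo_to_graph <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  ntip <- length(phy$tip.label)
  rootnum <- ntip + 1L
  # preorder internal numbering -> a1..
  pre <- integer(0)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  visit <- function(v) {
    pre <<- c(pre, v)
    for (k in kids[[as.character(v)]]) if (k > ntip) visit(k)
  }
  visit(rootnum)
  lab <- character(ntip + phy$Nnode)
  lab[seq_len(ntip)] <- phy$tip.label
  lab[pre] <- paste0("a", seq_along(pre))
  parent <- stats::setNames(lab[phy$edge[, 1]], lab[phy$edge[, 2]])
  len <- stats::setNames(phy$edge.length, lab[phy$edge[, 2]])
  admixture_graph(parent, len, root = lab[rootnum])
}

#' Read a TreeMix-style graph (vertices + edges files)
#'
#' Reads the whitespace-separated vertices/edges dialect: the vertices
#' file has columns `id`, `name` (`NA` for internal nodes),
#' `ROOT|NOT_ROOT`, `MIG|NOT_MIG`, `TIP|NOT_TIP`; the edges file has
#' columns `from`, `to`, `value`, `MIG|NOT_MIG`, where `value` is the
#' drift length for tree edges and the admixture weight for `MIG` edges.
#' Files may be gzip-compressed (`.gz`).
#'
#' @param vertices_file,edges_file Paths.
#' @return An [admixture_graph()].
#' @export
read_treemix_output <- function(vertices_file, edges_file) {
  vt <- utils::read.table(vertices_file, header = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  ed <- tryCatch(utils::read.table(edges_file, header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop("edges file is empty or unreadable"))
  if (nrow(ed) == 0) stop("edges file contains no edges")
  ids <- as.character(vt[[1]])
  name <- as.character(vt[[2]])
  is_tip <- vt[[5]] == "TIP"
  is_root <- vt[[3]] == "ROOT"
  if (sum(is_root) != 1) stop("vertices file must mark exactly one ROOT")
  lab <- ifelse(is_tip & !is.na(name), name, NA_character_)
  nint <- sum(is.na(lab))
  lab[is.na(lab)] <- paste0("a", seq_len(nint))
  names(lab) <- ids
  from <- as.character(ed[[1]]); to <- as.character(ed[[2]])
  if (!all(c(from, to) %in% ids)) stop("edge references a node absent from the vertices file")
  mig <- ed[[4]] == "MIG"
  parent <- stats::setNames(lab[from[!mig]], lab[to[!mig]])
  len <- stats::setNames(as.numeric(ed[[3]][!mig]), lab[to[!mig]])
  admix <- NULL
  if (any(mig)) {
    admix <- data.frame(child = unname(lab[to[mig]]),
                        parent = unname(lab[from[mig]]),
                        weight = as.numeric(ed[[3]][mig]),
                        stringsAsFactors = FALSE)
  }
  admixture_graph(parent, len, root = unname(lab[ids[is_root]]), admix = admix)
}
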