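#' Disconnectivity tree of an energy landscape
#'
#' Builds the hierarchical barrier structure of the local minima: leaves are
#' the local minima at their own energies, and each internal node joins two
#' groups of minima at the lowest energy level at which they become mutually
#' reachable — the minimax barrier (see [minimax_barrier()]).
#'
#' The tree is built by a threshold sweep: states are activated in order of
#' ascending energy (ties broken by ascending state index) and
#' Hamming-adjacent active states are merged with a union-find structure;
#' whenever two components that each contain a local minimum join, an
#' internal node is recorded at the energy of the state whose activation
#' connected them. This is equivalent to running a Dijkstra-type minimax-path
#' search between every pair of minima: the barrier at the lowest common
#' ancestor of two leaves equals their pairwise minimax barrier, and the
#' barrier heights are ultrametric (non-decreasing from leaves to root).
#'
#' @param landscape an [energy_landscape()] object, or a [pmem]/[pmem_params]
#'   object (converted via [energy_landscape()]).
#' @return an object of class `disconnectivity_tree`: list with
#'   \describe{
#'     \item{leaves}{state indices of the local minima (ascending).}
#'     \item{leaf_energies}{their energies.}
#'     \item{merge}{(M-1) x 2 matrix in [stats::hclust()] convention
#'       (negative = leaf number, positive = earlier merge row).}
#'     \item{height}{barrier energy of each merge, non-decreasing.}
#'     \item{n_regions}{N.}
#'   }
#' @seealso [to_newick()], [plot.disconnectivity_tree()], [lca_barrier()]
#' @export
disconnectivity_tree <- function(landscape) {
  if (!inherits(landscape, "energy_landscape")) {
    landscape <- energy_landscape(landscape)
  }
  e <- landscape$energies
  n <- landscape$n_regions
  mins <- landscape$local_minima
  m <- length(mins)
  if (m < 1L) stop("landscape has no local minima", call. = FALSE)
  n_states <- length(e)
  nb <- neighbor_index_matrix(n)

  parent <- seq_len(n_states)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  token <- integer(n_states)       # per root: 0, -leaf number, +merge row
  leaf_of_state <- integer(n_states)
  leaf_of_state[mins] <- seq_len(m)
  active <- logical(n_states)

  merge <- matrix(0L, max(m - 1L, 0L), 2L)
  height <- numeric(max(m - 1L, 0L))
  n_merges <- 0L

  for (s in order(e, seq_len(n_states))) {
    active[s] <- TRUE
    token[s] <- -leaf_of_state[s]   # 0 if not a minimum
    for (v in nb[s, ]) {
      if (!active[v]) next
      ra <- find(s)
      rb <- find(v)
      if (ra == rb) next
      ta <- token[ra]
      tb <- token[rb]
      parent[ra] <- rb
      if (ta != 0L && tb != 0L) {
        n_merges <- n_merges + 1L
        merge[n_merges, ] <- c(ta, tb)
        height[n_merges] <- e[s]
        token[rb] <- n_merges
      } else {
        token[rb] <- ta + tb
      }
    }
  }
  stopifnot(n_merges == m - 1L)

  structure(list(
    leaves = mins,
    leaf_energies = e[mins],
    merge = merge,
    height = height,
    n_regions = n
  ), class = "disconnectivity_tree")
}

# leaf numbers (1..M) in left-to-right display order
tree_leaf_order <- function(tree) {
  m <- length(tree$leaves)
  if (m == 1L) return(1L)
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(tree$merge[node, 1]), walk(tree$merge[node, 2]))
  }
  walk(nrow(tree$merge))
}

#' Barrier energy at the lowest common ancestor of two leaves
#'
#' @param tree a [disconnectivity_tree()].
#' @param a,b state indices of two local minima (leaves of the tree).
#' @return the barrier energy of the lowest internal node above both leaves;
#'   equals the leaf energy when `a == b`.
#' @export
lca_barrier <- function(tree, a, b) {
  la <- match(a, tree$leaves)
  lb <- match(b, tree$leaves)
  if (is.na(la) || is.na(lb)) {
    stop("a and b must be local-minimum states (tree leaves)", call. = FALSE)
  }
  if (la == lb) return(tree$leaf_energies[la])
  cluster <- -seq_along(tree$leaves)  # current cluster token per leaf
  for (k in seq_along(tree$height)) {
    hit <- cluster %in% tree$merge[k, ]
    cluster[hit] <- k
    if (cluster[la] == cluster[lb]) return(tree$height[k])
  }
  stop("leaves never merge; malformed tree", call. = FALSE)
}

#' Newick export of a disconnectivity tree
#'
#' Writes the tree as a Newick-like string: leaves are named `s<state
#' index>`, internal nodes are labelled with their barrier energy, and
#' branch lengths are the energy drops from a node to its parent barrier.
#'
#' @param tree a [disconnectivity_tree()].
#' @param digits number of significant digits for energies.
#' @return a single Newick string (terminated by `;`).
#' @export
to_newick <- function(tree, digits = 6) {
  fmt <- function(x) format(x, digits = digits, trim = TRUE)
  node_height <- function(node) {
    if (node < 0L) tree$leaf_energies[-node] else tree$height[node]
  }
  build <- function(node, parent_height) {
    bl <- if (is.na(parent_height)) "" else
      paste0(":", fmt(parent_height - node_height(node)))
    if (node < 0L) {
      paste0("s", tree$leaves[-node], bl)
    } else {
      paste0("(",
             build(tree$merge[node, 1], tree$height[node]), ",",
             build(tree$merge[node, 2], tree$height[node]),
             ")", fmt(tree$height[node]), bl)
    }
  }
  m <- length(tree$leaves)
  if (m == 1L) return(paste0("s", tree$leaves[1], ";"))
  paste0(build(nrow(tree$merge), NA_real_), ";")
}

#' @export
print.disconnectivity_tree <- function(x, digits = 4, ...) {
  cat(sprintf("Disconnectivity tree: %d local minima\n", length(x$leaves)))
  fmt <- function(v) format(v, digits = digits, trim = TRUE)
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node < 0L) {
      cat(sprintf("%sleaf s%d (E = %s)\n", pad, x$leaves[-node],
                  fmt(x$leaf_energies[-node])))
    } else {
      cat(sprintf("%sbarrier %s\n", pad, fmt(x$height[node])))
      show(x$merge[node, 1], indent + 1L)
      show(x$merge[node, 2], indent + 1L)
    }
  }
  if (length(x$leaves) == 1L) {
    show(-1L, 1L)
  } else {
    show(nrow(x$merge), 1L)
  }
  invisible(x)
}

#' @export
as.hclust.disconnectivity_tree <- function(x, ...) {
  if (length(x$leaves) < 2L) {
    stop("need at least two leaves to form an hclust object", call. = FALSE)
  }
  structure(list(
    merge = x$merge,
    height = x$height,
    order = tree_leaf_order(x),
    labels = paste0("s", x$leaves),
    method = "minimax barrier",
    call = match.call(),
    dist.method = "energy"
  ), class = "hclust")
}

#' Plot a disconnectivity tree
#'
#' Classic disconnectivity-graph rendering: each leaf hangs at its own
#' energy, vertical branches rise to the barrier at which two groups of
#' minima merge.
#'
#' @param x a [disconnectivity_tree()].
#' @param ylab y-axis label.
#' @param leaf_labels logical; annotate leaves with their state indices.
#' @param ... passed to [graphics::plot()].
#' @export
plot.disconnectivity_tree <- function(x, ylab = "energy",
                                      leaf_labels = TRUE, ...) {
  m <- length(x$leaves)
  ord <- tree_leaf_order(x)
  xpos_leaf <- numeric(m)
  xpos_leaf[ord] <- seq_len(m)
  node_x <- function(node) {
    if (node < 0L) xpos_leaf[-node]
    else mean(c(node_x(x$merge[node, 1]), node_x(x$merge[node, 2])))
  }
  node_h <- function(node) {
    if (node < 0L) x$leaf_energies[-node] else x$height[node]
  }
  top <- if (m == 1L) x$leaf_energies[1] else max(x$height)
  ylim <- range(c(x$leaf_energies, top))
  ylim[2] <- ylim[2] + 0.05 * diff(range(ylim, finite = TRUE), na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.5, m + 0.5), ylim = ylim,
                 xlab = "local minimum", ylab = ylab, xaxt = "n", ...)
  if (m > 1L) {
    for (k in seq_len(nrow(x$merge))) {
      ch <- x$merge[k, ]
      xs <- vapply(ch, node_x, numeric(1))
      hs <- vapply(ch, node_h, numeric(1))
      graphics::segments(xs, hs, xs, x$height[k])
      graphics::segments(xs[1], x$height[k], xs[2], x$height[k])
    }
  }
  graphics::points(xpos_leaf, x$leaf_energies, pch = 19, cex = 0.6)
  if (leaf_labels) {
    graphics::axis(1, at = seq_len(m), labels = x$leaves[ord], las = 2,
                   cex.axis = 0.8)
  }
  invisible(x)
}
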