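#' Local minima of an energy landscape
#'
#' A state is a local minimum when its energy is strictly lower than that of
#' each of its N single-bit-flip (Hamming-1) neighbors. Equal-energy
#' neighbors disqualify both states (plateaus are not minima).
#'
#' @param energies numeric vector of length `2^N`, state-index order.
#' @param n_regions N.
#' @return sorted integer vector of local-minimum state indices.
#' @export
find_local_minima <- function(energies, n_regions) {
  check_landscape_args(energies, n_regions)
  nb <- neighbor_index_matrix(n_regions)
  is_min <- rep(TRUE, length(energies))
  for (i in seq_len(n_regions)) {
    is_min <- is_min & (energies < energies[nb[, i]])
  }
  which(is_min)
}

#' Basin of attraction of every state
#'
#' Steepest-descent dynamics: from each state, repeatedly move to the
#' lowest-energy Hamming-1 neighbor while one is strictly lower than the
#' current state; ties among equally lowest neighbors are resolved to the
#' lowest state index. The terminal state (a local minimum) labels the basin.
#'
#' @inheritParams find_local_minima
#' @return integer vector of length `2^N`; entry `s` is the local-minimum
#'   state index that state `s` descends to.
#' @export
assign_basins <- function(energies, n_regions) {
  check_landscape_args(energies, n_regions)
  n_states <- length(energies)
  nb <- neighbor_index_matrix(n_regions)
  basin <- integer(n_states)
  # process states by ascending energy (ties: ascending index) so each
  # strictly-downhill move lands on an already-labelled state
  for (s in order(energies, seq_len(n_states))) {
    nbs <- nb[s, ]
    e_nb <- energies[nbs]
    best <- min(e_nb)
    if (best >= energies[s]) {
      basin[s] <- s
    } else {
      cand <- nbs[e_nb == best]
      basin[s] <- basin[min(cand)]
    }
  }
  basin
}

#' Minimax energy barrier between two states
#'
#' Over all paths on the N-dimensional hypercube between states `a` and `b`,
#' the smallest achievable value of the path's maximum energy (endpoints
#' included). Computed with a Dijkstra variant in which the cost of a path is
#' its running maximum energy rather than a sum. Symmetric in `a` and `b`;
#' equals `energies[a]` when `a == b`.
#'
#' @inheritParams find_local_minima
#' @param a,b state indices in `[1, 2^N]`.
#' @return scalar barrier energy.
#' @export
minimax_barrier <- function(energies, n_regions, a, b) {
  check_landscape_args(energies, n_regions)
  n_states <- length(energies)
  a <- as.integer(a); b <- as.integer(b)
  if (any(c(a, b) < 1L) || any(c(a, b) > n_states)) {
    stop(sprintf("state index out of range [1, %d]", n_states), call. = FALSE)
  }
  if (a == b) return(energies[a])
  nb <- neighbor_index_matrix(n_regions)
  dist <- rep(Inf, n_states)
  done <- rep(FALSE, n_states)
  dist[a] <- energies[a]
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) stop("hypercube unexpectedly disconnected")
    if (u == b) return(dist[b])
    done[u] <- TRUE
    vs <- nb[u, ]
    relax <- pmax(dist[u], energies[vs])
    upd <- !done[vs] & relax < dist[vs]
    dist[vs[upd]] <- relax[upd]
  }
}

check_landscape_args <- function(energies, n_regions) {
  check_capacity(n_regions)
  if (length(energies) != 2^n_regions) {
    stop(sprintf("energies must have length 2^%d = %d (got %d)",
                 n_regions, 2^n_regions, length(energies)), call. = FALSE)
  }
  if (any(!is.finite(energies))) {
    stop("energies must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Exhaustive energy landscape of a pairwise maximum entropy model
#'
#' Enumerates the energy of all `2^N` activity patterns under the model,
#' identifies local minima (states below all N Hamming-1 neighbors) and the
#' basin of attraction of every state under steepest descent. Local minima
#' are the model's stable connectivity states: the lower a minimum's energy,
#' the more often the pattern is visited.
#'
#' @param object a fitted [pmem] model or a [pmem_params] object.
#' @return an object of class `energy_landscape`: list with `energies`
#'   (length `2^N`), `probabilities`, `local_minima` (sorted state indices),
#'   `basins` (length `2^N`), `params`, `n_regions`, `roi_names`.
#' @seealso [disconnectivity_tree()], [minima_table()], [activity_patterns()]
#' @export
#' @examples
#' p <- pmem_params(rep(0, 3), matrix(0.5, 3, 3) - diag(0.5, 3))
#' el <- energy_landscape(p)
#' el$local_minima   # states 1 and 8: all-inactive and all-active
energy_landscape <- function(object) {
  params <- as_pmem_params(object)
  n <- params$n_regions
  e <- energies_all_states(params)
  structure(list(
    energies = e,
    probabilities = {
      w <- exp(-(e - min(e)))
      w / sum(w)
    },
    local_minima = find_local_minima(e, n),
    basins = assign_basins(e, n),
    params = params,
    n_regions = n,
    roi_names = params$roi_names
  ), class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("Energy landscape: %d regions, %d states, %d local minima\n",
              x$n_regions, length(x$energies), length(x$local_minima)))
  cat(sprintf("  energy range [%.4f, %.4f]\n",
              min(x$energies), max(x$energies)))
  invisible(x)
}

#' @export
summary.energy_landscape <- function(object, ...) {
  tab <- minima_table(object)
  cat(sprintf("Energy landscape over %d states (%d regions)\n",
              length(object$energies), object$n_regions))
  cat("\nLocal minima:\n")
  print(tab, row.names = FALSE)
  invisible(tab)
}

#' Table of local minima
#'
#' @param landscape an [energy_landscape()] object.
#' @return data frame with one row per local minimum: `state` (index),
#'   `energy`, `probability`, `basin_size` (number of states draining to it),
#'   and `pattern` (the -1/+1 pattern as a compact +/- string, region 1
#'   first).
#' @export
minima_table <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  mins <- landscape$local_minima
  pats <- vapply(mins, function(s) {
    p <- decode_state(s, landscape$n_regions)
    paste(ifelse(p > 0, "+", "-"), collapse = "")
  }, character(1))
  data.frame(
    state = mins,
    energy = landscape$energies[mins],
    probability = landscape$probabilities[mins],
    basin_size = as.integer(tabulate(match(landscape$basins, mins),
                                     nbins = length(mins))),
    pattern = pats,
    stringsAsFactors = FALSE
  )
}

#' Activity-pattern matrix of the local minima
#'
#' The regions x minima matrix of -1/+1 values showing which regions are
#' active in each local-minimum connectivity state, as displayed alongside
#' disconnectivity graphs.
#'
#' @param landscape an [energy_landscape()] object.
#' @return integer matrix, N regions x number of minima; columns named by
#'   state index.
#' @export
activity_patterns <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  mins <- landscape$local_minima
  out <- vapply(mins, function(s) decode_state(s, landscape$n_regions),
                integer(landscape$n_regions))
  out <- matrix(out, nrow = landscape$n_regions)
  dimnames(out) <- list(landscape$roi_names, as.character(mins))
  out
}

#' Plot an energy landscape
#'
#' Draws the disconnectivity tree of the landscape's local minima (left) and
#' the corresponding activity-pattern matrix (right): dark cells are active
#' regions.
#'
#' @param x an [energy_landscape()] object.
#' @param ... passed to [plot.disconnectivity_tree()].
#' @export
plot.energy_landscape <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  plot(disconnectivity_tree(x), ...)
  ap <- activity_patterns(x)
  graphics::image(seq_len(ncol(ap)), seq_len(nrow(ap)),
                  t(ap[rev(seq_len(nrow(ap))), , drop = FALSE]),
                  col = c("white", "grey20"), axes = FALSE,
                  xlab = "local minimum", ylab = "")
  graphics::axis(1, at = seq_len(ncol(ap)), labels = colnames(ap), las = 2)
  graphics::axis(2, at = seq_len(nrow(ap)), labels = rev(rownames(ap)),
                 las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}
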