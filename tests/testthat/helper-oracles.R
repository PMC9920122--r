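# Independent brute-force oracles for the landscape machinery. These use
# bitwXor index arithmetic for adjacency, deliberately distinct from the
# package's neighbor bookkeeping.

flip_neighbors <- function(s, n) {
  vapply(0:(n - 1), function(k) bitwXor(s - 1L, bitwShiftL(1L, k)) + 1L, 1L)
}

# local minima by direct double-loop neighbor comparison
brute_minima <- function(e, n) {
  which(vapply(seq_along(e), function(s) {
    all(e[s] < e[flip_neighbors(s, n)])
  }, logical(1)))
}

# minimax barrier by exhaustive DFS over all simple paths (with the safe
# running-max prune); use at small n only
brute_minimax_dfs <- function(e, n, a, b) {
  best <- Inf
  rec <- function(v, visited, curmax) {
    curmax <- max(curmax, e[v])
    if (curmax >= best && v != b) return(invisible())
    if (v == b) {
      best <<- min(best, curmax)
      return(invisible())
    }
    for (w in flip_neighbors(v, n)) {
      if (!visited[w]) {
        vis <- visited
        vis[w] <- TRUE
        rec(w, vis, curmax)
      }
    }
  }
  visited <- logical(length(e))
  visited[a] <- TRUE
  rec(a, visited, -Inf)
  best
}

# minimax barrier as the smallest threshold at which a and b are connected in
# the subgraph of states with energy <= threshold (BFS connectivity)
brute_minimax_threshold <- function(e, n, a, b) {
  for (theta in sort(unique(e))) {
    if (theta < max(e[a], e[b])) next
    keep <- e <= theta
    seen <- logical(length(e))
    seen[a] <- TRUE
    frontier <- a
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in flip_neighbors(v, n)) {
          if (keep[w] && !seen[w]) {
            seen[w] <- TRUE
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    if (seen[b]) return(theta)
  }
  stop("unreachable")
}

# random model parameters with given spread
rand_params <- function(n, h_sd = 0.3, j_sd = 0.3) {
  J <- matrix(stats::rnorm(n * n, 0, j_sd), n, n)
  J <- (J + t(J)) / 2
  diag(J) <- 0
  pmem_params(stats::rnorm(n, 0, h_sd), J)
}

# random binary series drawn from a random model
rand_series <- function(n, t, h_sd = 0.3, j_sd = 0.3) {
  sample_patterns(rand_params(n, h_sd, j_sd), t)
}

# fake landscape object around an arbitrary energy vector
manual_landscape <- function(e, n) {
  structure(list(energies = e,
                 probabilities = exp(-(e - min(e))) / sum(exp(-(e - min(e)))),
                 local_minima = find_local_minima(e, n),
                 basins = assign_basins(e, n),
                 n_regions = n,
                 roi_names = paste0("R", seq_len(n))),
            class = "energy_landscape")
}
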