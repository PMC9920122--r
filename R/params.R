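#' Pairwise maximum entropy model parameters
#'
#' Container for the parameters of a pairwise maximum entropy (Ising) model:
#' a bias `h[i]` per region, encoding its baseline tendency to be active, and
#' a symmetric coupling `J[i, j]` per region pair, encoding how strongly the
#' two regions tend to be in the same state. The diagonal of `J` is zero by
#' definition.
#'
#' @param h numeric vector of N biases.
#' @param J symmetric N x N numeric coupling matrix with zero diagonal.
#' @param roi_names optional character vector of N region labels; defaults to
#'   names of `h`, then dimnames of `J`, then `R1..RN`.
#' @return an object of class `pmem_params` (a list with elements `h`, `J`,
#'   `roi_names`).
#' @seealso [pmem()], [state_energy()], [boltzmann_distribution()]
#' @export
#' @examples
#' p <- pmem_params(h = c(1, -1), J = matrix(c(0, 0.5, 0.5, 0), 2))
#' state_energy(c(1, 1), p)
pmem_params <- function(h, J, roi_names = NULL) {
  h <- as.numeric(h)
  n <- length(h)
  J <- as.matrix(J)
  if (!is.numeric(J) || nrow(J) != n || ncol(J) != n) {
    stop("J must be a numeric N x N matrix matching length(h)", call. = FALSE)
  }
  if (any(!is.finite(h)) || any(!is.finite(J))) {
    stop("parameters must be finite", call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-8) {
    stop("J must be symmetric (J[i,j] == J[j,i])", call. = FALSE)
  }
  if (any(diag(J) != 0)) {
    stop("J must have a zero diagonal (no self-coupling)", call. = FALSE)
  }
  J <- (J + t(J)) / 2
  if (is.null(roi_names)) {
    roi_names <- names(h)
    if (is.null(roi_names)) roi_names <- rownames(J)
    if (is.null(roi_names)) roi_names <- paste0("R", seq_len(n))
  }
  if (length(roi_names) != n || anyDuplicated(roi_names)) {
    stop("roi_names must be ", n, " unique labels", call. = FALSE)
  }
  names(h) <- roi_names
  dimnames(J) <- list(roi_names, roi_names)
  structure(list(h = h, J = J, roi_names = roi_names, n_regions = n),
            class = "pmem_params")
}

#' @export
print.pmem_params <- function(x, ...) {
  cat(sprintf("Pairwise MEM parameters: %d regions\n", x$n_regions))
  cat("  h range: [", format(min(x$h), digits = 4), ",",
      format(max(x$h), digits = 4), "]\n")
  off <- x$J[upper.tri(x$J)]
  if (length(off)) {
    cat("  J range: [", format(min(off), digits = 4), ",",
        format(max(off), digits = 4), "]\n")
  }
  invisible(x)
}

# accept a pmem fit, pmem_params, or list(h, J)
as_pmem_params <- function(object) {
  if (inherits(object, "pmem_params")) return(object)
  if (inherits(object, "pmem")) return(object$params)
  if (is.list(object) && all(c("h", "J") %in% names(object))) {
    return(pmem_params(object$h, object$J, object$roi_names))
  }
  stop("cannot interpret object as pairwise MEM parameters", call. = FALSE)
}

#' Energy of binary activity patterns
#'
#' Computes `E(sigma | h, J) = -sum_i h_i sigma_i - (1/2) sum_{i != j} J_ij
#' sigma_i sigma_j`, the energy of an activity pattern under a pairwise
#' maximum entropy model. Each unordered region pair contributes
#' `J_ij sigma_i sigma_j` once. Lower energy corresponds to higher model
#' probability; with `h = 0` the energy is invariant under a global sign flip
#' of the pattern.
#'
#' @param pattern a -1/+1 vector of length N or an N x k matrix of patterns in
#'   columns.
#' @param params a [pmem_params] object (or a fitted [pmem] model).
#' @return numeric vector of energies, one per pattern.
#' @export
state_energy <- function(pattern, params) {
  params <- as_pmem_params(params)
  if (is.vector(pattern)) pattern <- matrix(pattern, ncol = 1L)
  if (nrow(pattern) != params$n_regions) {
    stop(sprintf("pattern has %d regions but params have %d",
                 nrow(pattern), params$n_regions), call. = FALSE)
  }
  if (!isTRUE(all(pattern == 1 | pattern == -1))) {
    stop("invalid pattern: entries must be -1 or +1", call. = FALSE)
  }
  e <- -as.vector(crossprod(pattern, params$h)) -
    0.5 * colSums(pattern * (params$J %*% pattern))
  as.numeric(e)
}

# energies of all 2^N states, in state-index order; `states` may be passed to
# reuse an existing all_states(N) matrix.
energies_all_states <- function(params, states = NULL) {
  params <- as_pmem_params(params)
  if (is.null(states)) states <- all_states(params$n_regions)
  as.vector(-(states %*% params$h)) -
    0.5 * rowSums((states %*% params$J) * states)
}

#' Enumerate state energies over the full state space
#'
#' Evaluates the model energy of every one of the `2^N` activity patterns, in
#' state-index order (see [encode_state()]).
#'
#' @inheritParams state_energy
#' @return numeric vector of length `2^N`; entry `s` is the energy of the
#'   pattern `decode_state(s, N)`.
#' @export
enumerate_energies <- function(params) {
  params <- as_pmem_params(params)
  energies_all_states(params)
}

#' Boltzmann distribution over all activity patterns
#'
#' Probabilities `P(sigma) = exp(-E(sigma)) / Z` over the full `2^N` state
#' space, in state-index order. Probabilities are strictly positive, sum to
#' one, and are strictly decreasing in energy.
#'
#' @inheritParams state_energy
#' @return numeric probability vector of length `2^N`.
#' @export
#' @examples
#' boltzmann_distribution(pmem_params(0, matrix(0, 1, 1)))  # c(0.5, 0.5)
boltzmann_distribution <- function(params) {
  params <- as_pmem_params(params)
  e <- energies_all_states(params)
  w <- exp(-(e - min(e)))
  w / sum(w)
}

#' Exact first and second moments of the model distribution
#'
#' Expectations `<sigma_i>` and `<sigma_i sigma_j>` under the Boltzmann
#' distribution, computed by exact summation over all `2^N` states. The
#' diagonal of the second-moment matrix is identically 1.
#'
#' @inheritParams state_energy
#' @return list with `mean_activity` (length-N vector) and
#'   `pairwise_products` (N x N symmetric matrix with unit diagonal).
#' @export
#' @examples
#' model_moments(pmem_params(0.5, matrix(0, 1, 1)))$mean_activity  # tanh(0.5)
model_moments <- function(params) {
  params <- as_pmem_params(params)
  states <- all_states(params$n_regions)
  p <- boltzmann_distribution(params)
  m1 <- as.vector(crossprod(states, p))
  m2 <- crossprod(states, p * states)
  names(m1) <- params$roi_names
  dimnames(m2) <- list(params$roi_names, params$roi_names)
  list(mean_activity = m1, pairwise_products = m2)
}
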