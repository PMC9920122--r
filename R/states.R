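#' Enumerate all binary activity patterns
#'
#' Returns the full state space of an `n_regions`-node network as a
#' `2^n_regions x n_regions` matrix of -1/+1 entries, with row `s` holding the
#' pattern of state index `s` (see [encode_state()] for the indexing
#' convention).
#'
#' @param n_regions number of regions (N); must satisfy `1 <= N <= 20`.
#' @return integer matrix of -1/+1 values, `2^N` rows by `N` columns.
#' @seealso [encode_state()], [decode_state()]
#' @export
#' @examples
#' all_states(2)
all_states <- function(n_regions) {
  check_capacity(n_regions)
  n_states <- 2L^n_regions
  s <- matrix(0L, n_states, n_regions)
  for (i in seq_len(n_regions)) {
    block <- 2L^(n_regions - i)
    s[, i] <- rep(rep(c(-1L, 1L), each = block), times = 2L^(i - 1L))
  }
  s
}

#' Map binary activity patterns to state indices
#'
#' States are numbered 1-based: region 1 is the most significant bit, an
#' inactive region (-1) is bit 0 and an active region (+1) is bit 1, so the
#' all-inactive pattern is state 1 and the all-active pattern is state `2^N`.
#' For a 10-region network these are states 1 and 1024.
#'
#' @param pattern a -1/+1 vector of length N, or an N x k matrix whose columns
#'   are patterns.
#' @return integer state index (or vector of k indices) in `[1, 2^N]`.
#' @export
#' @examples
#' encode_state(c(1, -1))          # 3
#' encode_state(rep(-1, 10))       # 1
#' encode_state(rep(1, 10))        # 1024
encode_state <- function(pattern) {
  if (is.vector(pattern)) pattern <- matrix(pattern, ncol = 1L)
  if (!isTRUE(all(pattern == 1 | pattern == -1))) {
    stop("invalid pattern: entries must be -1 or +1", call. = FALSE)
  }
  n <- nrow(pattern)
  check_capacity(n)
  bits <- (pattern + 1) / 2
  as.integer(1 + colSums(bits * 2^((n - 1):0)))
}

#' Reconstruct the activity pattern of a state index
#'
#' Inverse of [encode_state()]: `decode_state(encode_state(x), length(x))`
#' returns `x` for every valid pattern.
#'
#' @param index state index (or vector of indices) in `[1, 2^N]`.
#' @param n_regions number of regions N.
#' @return a -1/+1 integer vector of length N, or an N x k matrix when `index`
#'   has length k > 1.
#' @export
#' @examples
#' decode_state(1, 3)   # c(-1, -1, -1)
#' decode_state(8, 3)   # c(1, 1, 1)
decode_state <- function(index, n_regions) {
  check_capacity(n_regions)
  index <- as.integer(index)
  if (any(is.na(index)) || any(index < 1L) || any(index > 2L^n_regions)) {
    stop(sprintf("state index out of range [1, %d]", 2L^n_regions),
         call. = FALSE)
  }
  out <- vapply(index, function(s) {
    bits <- as.integer(intToBits(s - 1L))[n_regions:1]
    as.integer(2L * bits - 1L)
  }, integer(n_regions))
  if (length(index) == 1L) as.vector(out) else out
}

# All enumerating operations scale as 2^N; refuse above N = 20.
check_capacity <- function(n_regions) {
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 1) {
    stop("n_regions must be a single integer >= 1", call. = FALSE)
  }
  if (n_regions > 20) {
    stop(sprintf(
      "capacity exceeded: n_regions = %d requires enumerating 2^%d states (limit N = 20)",
      n_regions, n_regions), call. = FALSE)
  }
  invisible(n_regions)
}

# indices of the N Hamming-1 neighbors of every state: row s, column i is the
# state reached from s by flipping region i.
neighbor_index_matrix <- function(n_regions, states = all_states(n_regions)) {
  n_states <- nrow(states)
  idx <- seq_len(n_states)
  nb <- matrix(0L, n_states, n_regions)
  for (i in seq_len(n_regions)) {
    step <- 2L^(n_regions - i)
    nb[, i] <- ifelse(states[, i] == 1L, idx - step, idx + step)
  }
  nb
}
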