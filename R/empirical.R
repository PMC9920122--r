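# Binary activity series are plain numeric/integer matrices with regions in
# rows (rownames = ROI labels) and time points in columns, entries -1/+1.

check_binary_series <- function(x, what = "series") {
  if (!is.matrix(x)) stop(what, " must be a matrix (regions x time)",
                          call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("empty ", what, ": need at least one region and one time point",
         call. = FALSE)
  }
  if (!isTRUE(all(x == 1 | x == -1))) {
    stop(what, " entries must all be -1 or +1", call. = FALSE)
  }
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    stop("duplicated region names in ", what, call. = FALSE)
  }
  invisible(x)
}

roi_labels <- function(x) {
  if (is.null(rownames(x))) paste0("R", seq_len(nrow(x))) else rownames(x)
}

#' Empirical statistics of a binary activity series
#'
#' Time-averaged first moments `<sigma_i>`, second moments
#' `<sigma_i sigma_j>`, and the relative frequency of each observed activity
#' pattern — the sufficient statistics that the pairwise maximum entropy model
#' is fitted to.
#'
#' @param x a -1/+1 matrix, regions in rows, time points in columns.
#' @return list with elements
#'   \describe{
#'     \item{mean_activity}{length-N vector, `mean_t sigma_i(t)`.}
#'     \item{pairwise_products}{N x N symmetric matrix with unit diagonal,
#'       `mean_t sigma_i(t) sigma_j(t)`.}
#'     \item{frequencies}{named numeric vector of relative frequencies over
#'       the observed state indices (names are state indices as in
#'       [encode_state()]); sums to 1.}
#'     \item{t_max}{number of time points.}
#'   }
#' @export
empirical_stats <- function(x) {
  check_binary_series(x)
  n <- nrow(x)
  t_max <- ncol(x)
  m1 <- rowMeans(x)
  m2 <- tcrossprod(x) / t_max
  names(m1) <- roi_labels(x)
  dimnames(m2) <- list(roi_labels(x), roi_labels(x))
  idx <- encode_state(x)
  tab <- table(idx)
  freq <- as.numeric(tab) / t_max
  names(freq) <- names(tab)
  list(mean_activity = m1, pairwise_products = m2,
       frequencies = freq, t_max = t_max)
}
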