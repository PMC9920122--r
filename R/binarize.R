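#' Binarize continuous region time series at the per-region time mean
#'
#' Each region's continuous signal is thresholded at its own time average:
#' `sigma_i(t) = +1` when the signal strictly exceeds the region's mean and
#' `-1` otherwise (values exactly equal to the mean map to `-1`, a
#' deterministic tie rule that only matters for integer-valued test signals).
#' A region with zero variance has no meaningful threshold and is an error.
#'
#' @param x numeric matrix, N regions in rows and `t_max` time points in
#'   columns; rownames are region labels.
#' @return a -1/+1 integer matrix of the same dimensions and dimnames.
#' @export
#' @examples
#' binarize(matrix(c(1, 2, 3), 1, dimnames = list("ROI1", NULL)))
binarize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("x must be a numeric matrix (regions x time)", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) stop("empty series", call. = FALSE)
  if (anyNA(x)) stop("series contains missing values", call. = FALSE)
  rng <- apply(x, 1L, function(r) max(r) - min(r))
  if (any(rng == 0)) {
    bad <- roi_labels(x)[rng == 0]
    stop("degenerate region(s) with zero variance: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- ifelse(x > rowMeans(x), 1L, -1L)
  dimnames(out) <- dimnames(x)
  out
}

#' Average homologous left/right regions
#'
#' Replaces each configured left/right pair of regions by the pointwise
#' arithmetic mean of their continuous signals, under the pair's merged
#' label. Averaging is done on the continuous signals before binarization;
#' this is how networks whose region count exceeds the enumeration limit
#' (e.g. an 18-region default-mode set reduced to 9, or a 14-region visual
#' set reduced to 7) are brought within reach of the exact model fit.
#' The merged region takes the position of the pair's left member; unpaired
#' regions pass through unchanged.
#'
#' @param x numeric matrix, regions in rows (rownames required).
#' @param pairs a data frame (or list of length-3 character vectors) with
#'   columns/elements `left`, `right`, `merged`: the two region labels to
#'   average and the label of the result.
#' @return numeric matrix with `nrow(x) - nrow(pairs)` rows.
#' @export
reduce_bilateral <- function(x, pairs) {
  if (!is.matrix(x) || is.null(rownames(x))) {
    stop("x must be a matrix with region rownames", call. = FALSE)
  }
  pairs <- as_bilateral_pairs(pairs)
  members <- c(pairs$left, pairs$right)
  if (anyDuplicated(members)) {
    stop("bilateral pairs must be disjoint: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(members, rownames(x))
  if (length(missing)) {
    stop("bilateral map names region(s) absent from the series: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- x
  rownames(out) <- rownames(x)
  for (k in seq_len(nrow(pairs))) {
    li <- match(pairs$left[k], rownames(out))
    out[li, ] <- (x[pairs$left[k], ] + x[pairs$right[k], ]) / 2
    rownames(out)[li] <- pairs$merged[k]
  }
  out[!(rownames(out) %in% pairs$right), , drop = FALSE]
}

as_bilateral_pairs <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs) &&
      all(vapply(pairs, length, 1L) == 3L)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(left = p[[1]], right = p[[2]], merged = p[[3]],
                 stringsAsFactors = FALSE)
    }))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("left", "right", "merged") %in% names(pairs))) {
    stop("pairs must have elements/columns left, right, merged",
         call. = FALSE)
  }
  pairs
}

#' Concatenate per-subject binary series into a group series
#'
#' Joins already-binarized subject series along the time axis, preserving
#' subject order. Binarization is per subject (each subject thresholded at
#' its own means) and is not re-applied after concatenation; group-level
#' statistics are therefore duration-weighted averages of the per-subject
#' statistics.
#'
#' @param series_list list of -1/+1 matrices with identical region rownames
#'   in identical order.
#' @return a -1/+1 matrix whose column count is the sum of the subjects'.
#' @export
concatenate_group <- function(series_list) {
  if (!is.list(series_list) || length(series_list) < 1L) {
    stop("series_list must be a non-empty list", call. = FALSE)
  }
  ref <- rownames(series_list[[1]])
  for (i in seq_along(series_list)) {
    check_binary_series(series_list[[i]],
                        what = sprintf("series %d", i))
    if (!identical(rownames(series_list[[i]]), ref)) {
      stop(sprintf("region names of series %d do not match series 1", i),
           call. = FALSE)
    }
  }
  do.call(cbind, series_list)
}
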