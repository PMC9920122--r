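#' Energy of specified states under a subject's own fitted model
#'
#' Fits a pairwise maximum entropy model to one subject's binarized series
#' and evaluates the energy of the requested connectivity states under the
#' subject's fitted parameters. These per-subject energies are the samples
#' that group comparisons are run on.
#'
#' @param x the subject's -1/+1 series (regions x time).
#' @param states integer vector of state indices.
#' @param subject_id optional label used in error messages.
#' @param ... fit options passed to [pmem()].
#' @return numeric vector of energies, one per requested state, named by
#'   state index.
#' @export
subject_state_energy <- function(x, states, subject_id = NULL, ...) {
  fit <- tryCatch(pmem(x, ...), error = function(e) {
    stop(sprintf("fit failed%s: %s",
                 if (is.null(subject_id)) "" else
                   paste0(" for subject ", subject_id),
                 conditionMessage(e)), call. = FALSE)
  })
  e <- energies_all_states(fit$params)
  states <- as.integer(states)
  if (any(states < 1L) || any(states > length(e))) {
    stop("state index out of range", call. = FALSE)
  }
  stats::setNames(e[states], as.character(states))
}

#' Two-sample t-test on energy samples
#'
#' Thin wrapper around [stats::t.test()] returning the statistic, degrees of
#' freedom and two-sided p-value. The pooled flavor assumes equal group
#' variances (Student); the `welch` flavor uses the Welch–Satterthwaite
#' approximation.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @param flavor `"pooled"` (default) or `"welch"`.
#' @return list with elements `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  if (length(a) < 2L || length(b) < 2L) {
    stop("degenerate sample: each group needs at least 2 observations",
         call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      # identical constant samples: no evidence of a difference
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    stop("degenerate sample: zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = (flavor == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise level `alpha` divided by the number of comparisons `m`; a test
#' is significant when its p-value falls below this threshold.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param m number of comparisons (here: the total number of local minima
#'   pooled over all networks and both groups).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 125)  # 4e-04
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("m must be a positive integer", call. = FALSE)
  }
  alpha / m
}

#' Screen candidate states for group-discriminating signatures
#'
#' Runs a two-sample t-test on the per-subject energies of each candidate
#' connectivity state and flags the states that survive Bonferroni
#' correction at level `alpha / m` as connectivity signatures.
#'
#' @param energies matrix of per-subject state energies: one row per subject,
#'   one column per candidate state, with column names the state indices (as
#'   returned by stacking [subject_state_energy()] calls).
#' @param groups factor or character vector of group labels, one per subject
#'   (exactly two levels).
#' @param m total number of comparisons M for the Bonferroni correction.
#'   Duplicate minima appearing in both groups' landscapes are tested once
#'   but counted per group in M.
#' @param alpha family-wise significance level.
#' @param flavor t-test flavor, see [two_sample_t()].
#' @param n_regions if supplied, a -1/+1 pattern string is added per state.
#' @param network optional network label carried into the result.
#' @return data frame sorted by ascending p-value, one row per candidate
#'   state: `state`, `pattern` (if `n_regions` given), group mean energies
#'   (`mean_<level>`), `t`, `df`, `p`, `corrected_alpha`, `significant`.
#' @export
extract_signatures <- function(energies, groups, m, alpha = 0.05,
                               flavor = c("pooled", "welch"),
                               n_regions = NULL, network = NULL) {
  flavor <- match.arg(flavor)
  energies <- as.matrix(energies)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) {
    stop("groups must have exactly two levels", call. = FALSE)
  }
  if (length(groups) != nrow(energies)) {
    stop("one group label per subject (row of energies) required",
         call. = FALSE)
  }
  if (is.null(colnames(energies))) {
    stop("energies must have state indices as column names", call. = FALSE)
  }
  lev <- levels(groups)
  thr <- bonferroni_threshold(alpha, m)
  rows <- lapply(seq_len(ncol(energies)), function(j) {
    a <- energies[groups == lev[1], j]
    b <- energies[groups == lev[2], j]
    tt <- two_sample_t(a, b, flavor)
    out <- data.frame(state = as.integer(colnames(energies)[j]),
                      mean_a = mean(a), mean_b = mean(b),
                      t = tt$t, df = tt$df, p = tt$p,
                      corrected_alpha = thr,
                      significant = tt$p < thr,
                      stringsAsFactors = FALSE)
    names(out)[names(out) == "mean_a"] <- paste0("mean_", lev[1])
    names(out)[names(out) == "mean_b"] <- paste0("mean_", lev[2])
    out
  })
  res <- do.call(rbind, rows)
  if (!is.null(n_regions)) {
    res$pattern <- vapply(res$state, function(s) {
      paste(ifelse(decode_state(s, n_regions) > 0, "+", "-"), collapse = "")
    }, character(1))
  }
  if (!is.null(network)) res$network <- network
  res[order(res$p, res$state), , drop = FALSE]
}
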