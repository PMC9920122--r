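#' Draw activity patterns exactly from a pairwise MEM distribution
#'
#' Samples `t` i.i.d. time points from the full `2^N`-state Boltzmann
#' distribution of the model by enumerating the distribution and drawing
#' state indices from it directly. Exact sampling (as opposed to MCMC) is
#' possible because the state space is enumerable at these scales, so there
#' are no mixing-time concerns.
#'
#' @param params a [pmem_params] object or fitted [pmem] model.
#' @param t number of time points to draw.
#' @param seed optional integer seed for reproducibility.
#' @return a -1/+1 integer matrix, N regions x `t` time points, with region
#'   labels from `params`.
#' @export
#' @examples
#' p <- pmem_params(c(0, 0), matrix(c(0, 1, 1, 0), 2))
#' x <- sample_patterns(p, 100, seed = 1)
sample_patterns <- function(params, t, seed = NULL) {
  params <- as_pmem_params(params)
  stopifnot(t >= 1)
  if (!is.null(seed)) set.seed(seed)
  prob <- boltzmann_distribution(params)
  idx <- sample.int(length(prob), size = t, replace = TRUE, prob = prob)
  states <- all_states(params$n_regions)
  out <- t(states[idx, , drop = FALSE])
  rownames(out) <- params$roi_names
  out
}

#' Continuous surrogate signals from a binary series
#'
#' Maps a -1/+1 series to continuous signals by adding Gaussian noise, so the
#' binarization stage can be exercised end-to-end on synthetic data. When the
#' noise scale is well below the +/-1 gap and each region's series is
#' balanced enough, re-binarizing the surrogate at the per-region time mean
#' recovers the original binary series exactly; a warning is raised if it
#' does not.
#'
#' @param x a -1/+1 matrix (regions x time).
#' @param noise_scale standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @param seed optional integer seed.
#' @return numeric matrix of the same dimensions and dimnames.
#' @export
make_continuous_surrogate <- function(x, noise_scale = 0.1, seed = NULL) {
  check_binary_series(x)
  stopifnot(noise_scale >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- x + matrix(stats::rnorm(length(x), sd = noise_scale),
                    nrow(x), ncol(x))
  dimnames(out) <- dimnames(x)
  recovered <- tryCatch(identical(unname(binarize(out)),
                                  unname(ifelse(x > 0, 1L, -1L))),
                        error = function(e) FALSE)
  if (!recovered) {
    warning("re-binarization does not recover the input series ",
            "(unbalanced regions or noise too large)", call. = FALSE)
  }
  out
}

#' Ferromagnetic example parameters
#'
#' A uniform positive coupling between every region pair plus small random
#' per-region bias jitter — the generator's default model of a cooperative
#' resting-state network, whose landscape has deep all-active/all-inactive
#' minima.
#'
#' @param n_regions number of regions (default 10, an attention-network-sized
#'   system).
#' @param coupling uniform coupling strength `J_ij` (default 0.1).
#' @param bias_sd standard deviation of the Gaussian bias jitter
#'   (default 0.05).
#' @param seed optional seed for the jitter.
#' @return a [pmem_params] object.
#' @export
ferromagnetic_params <- function(n_regions = 10, coupling = 0.1,
                                 bias_sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- matrix(coupling, n_regions, n_regions)
  diag(J) <- 0
  h <- stats::rnorm(n_regions, 0, bias_sd)
  pmem_params(h, J)
}

#' Scale the couplings of a model
#'
#' Multiplies every pairwise coupling by a factor while leaving the biases
#' untouched — the generator's device for a group with uniformly weaker (or
#' stronger) within-network interactions.
#'
#' @param params a [pmem_params] object.
#' @param factor scalar multiplier applied to `J`.
#' @return a [pmem_params] object.
#' @export
scale_couplings <- function(params, factor) {
  params <- as_pmem_params(params)
  pmem_params(params$h, params$J * factor, params$roi_names)
}

#' Generate a synthetic two-group study
#'
#' Draws independent per-subject binary series from group-specific pairwise
#' MEM distributions, emulating a two-group resting-state design (the
#' default sizes, 23 and 47 subjects, mirror a young/old comparison of 70
#' participants). Each subject gets a seed derived deterministically from
#' the study seed, the group and the subject index, so the whole dataset is
#' reproducible and subjects are mutually independent.
#'
#' @param params_by_group named list of two [pmem_params] objects (same
#'   region count), one per group; names are the group labels.
#' @param subjects_per_group integer vector of two group sizes, in the order
#'   of `params_by_group` (default `c(23, 47)`).
#' @param t_max time points per subject (default 500).
#' @param seed study seed.
#' @param continuous if `TRUE`, each subject's series is returned as a
#'   continuous surrogate (see [make_continuous_surrogate()]) so that the
#'   binarization stage runs on it; otherwise the -1/+1 series itself.
#' @param noise_scale noise scale of the surrogate.
#' @return list with
#'   \describe{
#'     \item{series}{named list of per-subject matrices (regions x time).}
#'     \item{manifest}{data frame with columns `subject_id`, `group`.}
#'     \item{params_by_group}{the generating parameters.}
#'   }
#' @export
make_two_group_dataset <- function(params_by_group,
                                   subjects_per_group = c(23, 47),
                                   t_max = 500, seed = 1,
                                   continuous = FALSE, noise_scale = 0.1) {
  stopifnot(is.list(params_by_group), length(params_by_group) == 2L,
            !is.null(names(params_by_group)),
            length(subjects_per_group) == 2L, all(subjects_per_group >= 1),
            t_max >= 1)
  params_by_group <- lapply(params_by_group, as_pmem_params)
  ns <- vapply(params_by_group, function(p) p$n_regions, 1L)
  if (ns[1] != ns[2]) stop("group params must share n_regions", call. = FALSE)
  series <- list()
  manifest <- data.frame(subject_id = character(), group = character(),
                         stringsAsFactors = FALSE)
  for (g in seq_along(params_by_group)) {
    glab <- names(params_by_group)[g]
    for (s in seq_len(subjects_per_group[g])) {
      sid <- sprintf("%s_%02d", glab, s)
      sseed <- derive_seed(seed, g, s)
      x <- sample_patterns(params_by_group[[g]], t = t_max, seed = sseed)
      if (continuous) {
        x <- make_continuous_surrogate(x, noise_scale = noise_scale,
                                       seed = derive_seed(seed, g, s + 10000L))
      }
      series[[sid]] <- x
      manifest <- rbind(manifest,
                        data.frame(subject_id = sid, group = glab,
                                   stringsAsFactors = FALSE))
    }
  }
  list(series = series, manifest = manifest,
       params_by_group = params_by_group)
}

# deterministic per-subject seed in [0, 2^31 - 2]
derive_seed <- function(seed, group_index, subject_index) {
  base <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((base * 31 + group_index * 1009 + subject_index * 9973) %%
               2147483647)
}
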