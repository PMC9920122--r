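#' Fit a pairwise maximum entropy model by maximum likelihood
#'
#' Fits the pairwise maximum entropy (Ising) model
#' `P(sigma | h, J) = exp(-E(sigma | h, J)) / Z` to a binarized multivariate
#' time series by gradient ascent on the i.i.d. log-likelihood
#' `sum_t log P(sigma(t) | h, J)`. The gradient of the log-likelihood per
#' time point is the difference between empirical and model moments, so each
#' update is
#' \deqn{h_i \leftarrow h_i + \epsilon (\langle\sigma_i\rangle_{emp} -
#'   \langle\sigma_i\rangle_{model}),\quad
#'   J_{ij} \leftarrow J_{ij} + \epsilon (\langle\sigma_i\sigma_j\rangle_{emp}
#'   - \langle\sigma_i\sigma_j\rangle_{model})}
#' and the fit has converged when the maximum absolute moment mismatch falls
#' below `tolerance` — the maximum-entropy stationarity condition that model
#' moments match empirical moments. The log-likelihood is concave in (h, J),
#' so the optimum is unique and the zero initialization (uniform model)
#' affects only speed. Model moments are exact sums over all `2^N` states at
#' every step, which is what limits N in practice.
#'
#' @param x a -1/+1 matrix, N regions in rows and `t_max` time points in
#'   columns (see [binarize()]); rownames are used as region labels.
#' @param learning_rate positive gradient step `epsilon`.
#' @param tolerance convergence threshold on the maximum absolute difference
#'   between empirical and model moments.
#' @param max_iter maximum number of accepted gradient updates.
#' @param adapt if `TRUE` (default), a step that would decrease the
#'   log-likelihood is rejected and the learning rate halved; if `FALSE`, raw
#'   fixed-step gradient ascent.
#' @param trace if `TRUE`, record per-iteration mismatch and log-likelihood in
#'   the returned object (`$trace`).
#' @return an object of class `pmem`: a list with components `params`
#'   ([pmem_params]), `converged`, `iterations`, `final_mismatch`,
#'   `log_likelihood`, `empirical` (see [empirical_stats()]), `t_max`,
#'   `n_regions`, `control`, and optionally `trace`.
#' @references Ezaki T, Watanabe T, Ohzeki M, Masuda N (2017) Energy
#'   landscape analysis of neuroimaging data. Phil Trans R Soc A 375:20160287.
#' @seealso [energy_landscape()], [simulate.pmem()], [predict.pmem()]
#' @export
#' @examples
#' set.seed(1)
#' x <- sample_patterns(pmem_params(c(0.3, -0.2), matrix(c(0, 0.4, 0.4, 0), 2)),
#'                      t = 2000)
#' fit <- pmem(x)
#' fit
#' coef(fit)
pmem <- function(x, learning_rate = 0.1, tolerance = 1e-5, max_iter = 50000,
                 adapt = TRUE, trace = FALSE) {
  check_binary_series(x)
  stopifnot(learning_rate > 0, tolerance > 0, max_iter >= 1)
  n <- nrow(x)
  check_capacity(n)
  t_max <- ncol(x)
  labels <- roi_labels(x)

  emp <- empirical_stats(x)
  m1_emp <- unname(emp$mean_activity)
  m2_emp <- unname(emp$pairwise_products)
  obs_idx <- as.integer(names(emp$frequencies))
  obs_freq <- unname(emp$frequencies)

  states <- all_states(n)
  eps <- learning_rate

  # energies, probabilities, moments and per-observation log-likelihood for a
  # candidate (h, J)
  eval_point <- function(h, J) {
    e <- as.vector(-(states %*% h)) - 0.5 * rowSums((states %*% J) * states)
    if (any(!is.finite(e))) {
      stop("divergence during fit (non-finite energies); ",
           "try a smaller learning_rate", call. = FALSE)
    }
    emin <- min(e)
    w <- exp(-(e - emin))
    z <- sum(w)
    p <- w / z
    m1 <- as.vector(crossprod(states, p))
    m2 <- crossprod(states, p * states)
    ll <- t_max * sum(obs_freq * (-(e[obs_idx] - emin) - log(z)))
    list(e = e, p = p, m1 = m1, m2 = m2, ll = ll)
  }

  h <- numeric(n)
  J <- matrix(0, n, n)
  cur <- eval_point(h, J)
  mismatch <- function(pt) {
    d2 <- m2_emp - pt$m2
    diag(d2) <- 0
    max(abs(m1_emp - pt$m1), abs(d2))
  }
  mis <- mismatch(cur)
  iter <- 0L
  tr <- if (trace) list(iteration = integer(), mismatch = numeric(),
                        log_likelihood = numeric()) else NULL
  converged <- mis <= tolerance

  while (!converged && iter < max_iter) {
    g1 <- m1_emp - cur$m1
    g2 <- m2_emp - cur$m2
    diag(g2) <- 0
    repeat {
      h_new <- h + eps * g1
      J_new <- J + eps * g2
      cand <- eval_point(h_new, J_new)
      # tolerate float noise in the likelihood when judging a decrease
      if (!adapt || cand$ll >= cur$ll - 1e-12 * (abs(cur$ll) + 1) ||
          eps < 1e-12) {
        break
      }
      eps <- eps / 2
    }
    h <- h_new
    J <- J_new
    cur <- cand
    if (adapt) eps <- min(eps * 1.05, learning_rate)
    iter <- iter + 1L
    mis <- mismatch(cur)
    if (trace) {
      tr$iteration <- c(tr$iteration, iter)
      tr$mismatch <- c(tr$mismatch, mis)
      tr$log_likelihood <- c(tr$log_likelihood, cur$ll)
    }
    converged <- mis <= tolerance
  }
  if (any(!is.finite(h)) || any(!is.finite(J))) {
    stop("divergence during fit (non-finite parameters); ",
         "try a smaller learning_rate", call. = FALSE)
  }

  structure(list(
    params = pmem_params(h, J, labels),
    converged = converged,
    iterations = iter,
    final_mismatch = mis,
    log_likelihood = cur$ll,
    empirical = emp,
    t_max = t_max,
    n_regions = n,
    control = list(learning_rate = learning_rate, tolerance = tolerance,
                   max_iter = max_iter, adapt = adapt),
    trace = if (trace) as.data.frame(tr) else NULL,
    call = match.call()
  ), class = "pmem")
}

#' Log-likelihood of a binary series under given model parameters
#'
#' The i.i.d. log-likelihood `sum_t log P(sigma(t) | h, J)`; always `<= 0`.
#'
#' @param x a -1/+1 matrix, regions in rows, time points in columns.
#' @param params a [pmem_params] object or fitted [pmem] model.
#' @return scalar log-likelihood (natural log).
#' @export
log_likelihood <- function(x, params) {
  check_binary_series(x)
  params <- as_pmem_params(params)
  if (nrow(x) != params$n_regions) {
    stop(sprintf("series has %d regions but params have %d",
                 nrow(x), params$n_regions), call. = FALSE)
  }
  e_all <- energies_all_states(params)
  emin <- min(e_all)
  logz <- log(sum(exp(-(e_all - emin))))
  idx <- encode_state(x)
  sum(-(e_all[idx] - emin) - logz)
}

#' @export
print.pmem <- function(x, ...) {
  cat(sprintf("Pairwise maximum entropy model: %d regions, %d time points\n",
              x$n_regions, x$t_max))
  cat(sprintf("  %s after %d iterations (max moment mismatch %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$final_mismatch))
  cat(sprintf("  log-likelihood: %.4f\n", x$log_likelihood))
  invisible(x)
}

#' @export
summary.pmem <- function(object, ...) {
  mm <- model_moments(object$params)
  structure(list(fit = object,
                 model_moments = mm,
                 h = object$params$h,
                 J = object$params$J),
            class = "summary.pmem")
}

#' @export
print.summary.pmem <- function(x, ...) {
  print(x$fit)
  cat("\nBiases (h):\n")
  print(round(x$h, 4))
  cat("\nCouplings (J, upper triangle summary):\n")
  off <- x$J[upper.tri(x$J)]
  if (length(off)) print(summary(off)) else cat("  (single region)\n")
  d1 <- x$fit$empirical$mean_activity - x$model_moments$mean_activity
  cat(sprintf("\nMoment mismatch: first %.3g, second %.3g\n",
              max(abs(d1)),
              {
                d2 <- x$fit$empirical$pairwise_products -
                  x$model_moments$pairwise_products
                diag(d2) <- 0
                max(abs(d2))
              }))
  invisible(x)
}

#' Extract fitted parameters
#'
#' @param object a fitted [pmem] model.
#' @param ... unused.
#' @return the fitted [pmem_params] (list with `h` and `J`).
#' @export
coef.pmem <- function(object, ...) object$params

#' @export
logLik.pmem <- function(object, ...) {
  n <- object$n_regions
  structure(object$log_likelihood,
            df = n + n * (n - 1) / 2,
            nobs = object$t_max,
            class = "logLik")
}

#' Moment-mismatch residuals of a fitted model
#'
#' Differences between empirical and model moments — zero (to within the fit
#' tolerance) at the maximum-likelihood solution.
#'
#' @param object a fitted [pmem] model.
#' @param ... unused.
#' @return list with `mean_activity` (length-N vector of first-moment
#'   differences) and `pairwise_products` (N x N matrix of second-moment
#'   differences, zero diagonal).
#' @export
residuals.pmem <- function(object, ...) {
  mm <- model_moments(object$params)
  d2 <- object$empirical$pairwise_products - mm$pairwise_products
  diag(d2) <- 0
  list(mean_activity = object$empirical$mean_activity - mm$mean_activity,
       pairwise_products = d2)
}

#' Model energies and probabilities of activity patterns
#'
#' @param object a fitted [pmem] model.
#' @param newdata a -1/+1 pattern vector, an N x k matrix of patterns in
#'   columns, or `NULL` (default) for all `2^N` states in state-index order.
#' @param type `"energy"`, `"probability"` or `"log_probability"`.
#' @param ... unused.
#' @return numeric vector, one value per requested pattern.
#' @export
predict.pmem <- function(object, newdata = NULL,
                         type = c("energy", "probability", "log_probability"),
                         ...) {
  type <- match.arg(type)
  params <- object$params
  e_all <- energies_all_states(params)
  if (is.null(newdata)) {
    e <- e_all
  } else {
    e <- state_energy(newdata, params)
  }
  if (type == "energy") return(e)
  emin <- min(e_all)
  logz <- log(sum(exp(-(e_all - emin))))
  lp <- -(e - emin) - logz
  if (type == "log_probability") lp else exp(lp)
}

#' Simulate a binary series from a fitted model
#'
#' Draws `nsim` i.i.d. time points exactly from the model's Boltzmann
#' distribution (see [sample_patterns()]).
#'
#' @param object a fitted [pmem] model.
#' @param nsim number of time points to draw.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a -1/+1 matrix, N regions x `nsim` time points.
#' @export
simulate.pmem <- function(object, nsim = 1, seed = NULL, ...) {
  sample_patterns(object$params, t = nsim, seed = seed)
}

#' Diagnostic plot of a fitted model
#'
#' Plots empirical versus model moments: at convergence all points lie on the
#' identity line.
#'
#' @param x a fitted [pmem] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pmem <- function(x, ...) {
  mm <- model_moments(x$params)
  emp1 <- x$empirical$mean_activity
  emp2 <- x$empirical$pairwise_products[upper.tri(x$params$J)]
  mod1 <- mm$mean_activity
  mod2 <- mm$pairwise_products[upper.tri(x$params$J)]
  graphics::plot(c(emp1, emp2), c(mod1, mod2),
                 xlab = "empirical moment", ylab = "model moment",
                 pch = c(rep(19, length(emp1)), rep(1, length(emp2))), ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", pch = c(19, 1), bty = "n",
                   legend = c("first moments", "second moments"))
  invisible(x)
}
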