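#' Gaussian log-likelihood of a parameter pair
#'
#' Up to an additive constant, the log-likelihood of
#' \eqn{\theta = (\alpha, IC)} given observations
#' \eqn{D = (y_1, \dots, y_M)} under i.i.d. Gaussian measurement noise is
#' \deqn{\ln L(\theta \mid D) = -\tfrac12 \sum_{i=1}^{M}
#'       (y_i - \mu_i(\theta))^2,}
#' where \eqn{\mu(\theta)} is the RK4 solution of the model at the
#' observation times. The proportionality constant is fixed to 0 and no
#' \eqn{1/\sigma^2} weighting is applied; neither changes the location of
#' the maximum. If the candidate trajectory diverges before the last
#' observation time, the value is \eqn{-\infty}: such \eqn{\theta} are
#' treated as non-inferable and excluded, which keeps grid argmax
#' operations well defined.
#'
#' @param theta Candidate parameter pair.
#' @param obs A [generate_observation()] result with status `"ok"`.
#' @param cfg A [solver_config()].
#' @param grid Optional [time_grid()]; when supplied it must match the
#'   observation's times exactly. Defaults to the grid the observation was
#'   generated on.
#' @return A single number, `-Inf` when the candidate diverges.
#' @export
#' @examples
#' g <- time_grid(10)
#' obs <- generate_observation("saddle_node", theta(1, 1), g,
#'                             noise_spec(sigma = 0), seed = 1)
#' log_likelihood(theta(1, 1), obs)   # 0: zero residuals
#' log_likelihood(theta(4, 2), obs)   # -5: constant residual 1 at 10 points
log_likelihood <- function(theta, obs, cfg = solver_config(), grid = NULL) {
  th <- as_theta(theta)
  if (!inherits(obs, "bif_observation")) {
    stop_invalid("`obs` must be created by generate_observation()")
  }
  if (obs$status != "ok") {
    stop_invalid("`obs` has status %s; a log-likelihood needs observed values",
                 obs$status)
  }
  obs_grid <- attr(obs, "grid")
  if (!is.null(grid)) {
    if (!inherits(grid, "bif_time_grid")) {
      stop_invalid("`grid` must be created by time_grid()")
    }
    if (length(grid$obs_times) != length(obs$times) ||
        !isTRUE(all.equal(grid$obs_times, obs$times, tolerance = 1e-12))) {
      stop_invalid("`grid` does not match the observation's time grid")
    }
    obs_grid <- grid
  }
  cfg <- as_solver_config(cfg)
  nsub <- n_substeps(obs_grid, cfg)
  rk4_loglik_cpp(model_code(obs$model), th[["alpha"]], th[["ic"]],
                 obs_grid$obs_times, nsub, cfg$divergence_threshold,
                 obs$values)
}

# Argmax over a loglik matrix (rows = ic, cols = alpha) with deterministic
# tie-breaking: smallest alpha, then smallest ic.
surface_argmax <- function(ll, alpha_axis, ic_axis) {
  best <- max(ll[is.finite(ll)])
  hits <- which(ll == best, arr.ind = TRUE)
  # column (alpha) first, then row (ic)
  ord <- order(hits[, "col"], hits[, "row"])
  top <- hits[ord[1L], ]
  theta(alpha_axis[top[["col"]]], ic_axis[top[["row"]]])
}

#' Log-likelihood surface over the (alpha, IC) plane
#'
#' Evaluates [log_likelihood()] at every cell of the grid spanned by
#' `alpha_axis` and `ic_axis` and records the argmax cell (ties broken by
#' smallest alpha, then smallest IC).
#'
#' @inheritParams log_likelihood
#' @param model Candidate model; defaults to the observation's model.
#' @param alpha_axis,ic_axis Strictly increasing numeric axes.
#' @return A list of class `bif_surface` with fields `alpha_axis`,
#'   `ic_axis`, `loglik` (matrix, rows indexed by IC, columns by alpha;
#'   `-Inf` marks divergent candidates), `argmax` and `model`.
#' @export
likelihood_surface <- function(model = obs$model, obs, alpha_axis, ic_axis,
                               cfg = solver_config()) {
  model <- as_bif_model(model)
  check_axis(alpha_axis, "alpha_axis")
  check_axis(ic_axis, "ic_axis")
  cfg <- as_solver_config(cfg)
  obs_grid <- attr(obs, "grid")
  if (!inherits(obs, "bif_observation") || obs$status != "ok") {
    stop_invalid("`obs` must be an observation with status ok")
  }
  nsub <- n_substeps(obs_grid, cfg)
  mc <- model_code(model)
  ll <- matrix(-Inf, nrow = length(ic_axis), ncol = length(alpha_axis),
               dimnames = NULL)
  for (j in seq_along(alpha_axis)) {
    for (i in seq_along(ic_axis)) {
      ll[i, j] <- rk4_loglik_cpp(mc, alpha_axis[j], ic_axis[i],
                                 obs_grid$obs_times, nsub,
                                 cfg$divergence_threshold, obs$values)
    }
  }
  if (!any(is.finite(ll))) {
    stop_no_finite_likelihood(
      "every grid cell has log-likelihood -Inf (all candidates diverge)")
  }
  structure(
    list(alpha_axis = alpha_axis, ic_axis = ic_axis, loglik = ll,
         argmax = surface_argmax(ll, alpha_axis, ic_axis), model = model),
    class = "bif_surface", cfg = cfg, grid = obs_grid
  )
}

#' @export
print.bif_surface <- function(x, ...) {
  cat(sprintf(
    "log-likelihood surface: %s, %d x %d cells, %d divergent, argmax (%g, %g)\n",
    x$model, length(x$ic_axis), length(x$alpha_axis),
    sum(!is.finite(x$loglik)), x$argmax[["alpha"]], x$argmax[["ic"]]))
  invisible(x)
}

check_axis <- function(axis, name) {
  if (!is.numeric(axis) || length(axis) < 1L || any(!is.finite(axis)) ||
      (length(axis) > 1L && any(diff(axis) <= 0))) {
    stop_invalid("`%s` must be non-empty, finite, strictly increasing", name)
  }
  invisible(axis)
}

#' Maximum-likelihood estimate of (alpha, IC)
#'
#' Two-stage search: a coarse grid (default 41 x 41) over the bounds
#' locates the best cell, then derivative-free Nelder-Mead refinement
#' (function evaluations only — the likelihood is non-smooth at divergence
#' boundaries) polishes it. Candidates outside the bounds or with divergent
#' trajectories are rejected through a finite penalty so the simplex
#' contracts back; the returned estimate never falls below the best coarse
#' cell.
#'
#' @inheritParams likelihood_surface
#' @param alpha_bounds,ic_bounds Length-2 finite, strictly increasing
#'   bounds.
#' @param coarse_n Coarse grid resolution per axis (default 41).
#' @return A list of class `bif_mle` with fields `theta_hat`,
#'   `loglik_at_hat` and `n_evaluations`.
#' @export
find_mle <- function(model = obs$model, obs, alpha_bounds, ic_bounds,
                     cfg = solver_config(), coarse_n = 41L) {
  model <- as_bif_model(model)
  check_bounds(alpha_bounds, "alpha_bounds")
  check_bounds(ic_bounds, "ic_bounds")
  cfg <- as_solver_config(cfg)
  if (!inherits(obs, "bif_observation") || obs$status != "ok") {
    stop_invalid("`obs` must be an observation with status ok")
  }
  obs_grid <- attr(obs, "grid")
  nsub <- n_substeps(obs_grid, cfg)
  mc <- model_code(model)
  n_eval <- 0L
  ll_fun <- function(a, ic) {
    n_eval <<- n_eval + 1L
    rk4_loglik_cpp(mc, a, ic, obs_grid$obs_times, nsub,
                   cfg$divergence_threshold, obs$values)
  }

  alpha_axis <- seq(alpha_bounds[1L], alpha_bounds[2L],
                    length.out = coarse_n)
  ic_axis <- seq(ic_bounds[1L], ic_bounds[2L], length.out = coarse_n)
  ll <- matrix(-Inf, nrow = length(ic_axis), ncol = length(alpha_axis))
  for (j in seq_along(alpha_axis)) {
    for (i in seq_along(ic_axis)) {
      ll[i, j] <- ll_fun(alpha_axis[j], ic_axis[i])
    }
  }
  if (!any(is.finite(ll))) {
    stop_no_finite_likelihood(
      "no finite log-likelihood anywhere on the coarse grid")
  }
  start <- surface_argmax(ll, alpha_axis, ic_axis)
  best_coarse <- max(ll[is.finite(ll)])

  penalty <- 1e10
  neg_obj <- function(p) {
    if (p[1L] < alpha_bounds[1L] || p[1L] > alpha_bounds[2L] ||
        p[2L] < ic_bounds[1L] || p[2L] > ic_bounds[2L]) {
      return(penalty)
    }
    v <- ll_fun(p[1L], p[2L])
    if (!is.finite(v)) penalty else -v
  }
  fit <- optim(c(start[["alpha"]], start[["ic"]]), neg_obj,
               method = "Nelder-Mead",
               control = list(maxit = 1000L, reltol = 1e-12))
  if (-fit$value >= best_coarse) {
    th_hat <- theta(fit$par[1L], fit$par[2L])
    ll_hat <- -fit$value
  } else {
    th_hat <- start
    ll_hat <- best_coarse
  }
  structure(list(theta_hat = th_hat, loglik_at_hat = ll_hat,
                 n_evaluations = n_eval),
            class = "bif_mle", model = model, bounds = list(
              alpha = alpha_bounds, ic = ic_bounds))
}

#' @export
print.bif_mle <- function(x, ...) {
  cat(sprintf(
    "MLE: alpha_hat = %.6g, ic_hat = %.6g, loglik = %.6g (%d evaluations)\n",
    x$theta_hat[["alpha"]], x$theta_hat[["ic"]], x$loglik_at_hat,
    x$n_evaluations))
  invisible(x)
}

check_bounds <- function(b, name) {
  if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)) ||
      b[2L] <= b[1L]) {
    stop_invalid("`%s` must be two finite, strictly increasing values", name)
  }
  invisible(b)
}
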