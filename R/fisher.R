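#' Central finite-difference Hessian of a bivariate function
#'
#' Second derivatives of `f(alpha, ic)` by central differences: 3-point
#' stencils for the diagonal entries and the 4-point cross stencil for the
#' mixed entry. The Hessian is symmetric by construction (a single mixed
#' entry is stored). The estimate is flagged invalid if any of the nine
#' stencil evaluations is non-finite (e.g. a divergent candidate with
#' log-likelihood \eqn{-\infty}).
#'
#' @param f Function of two scalars `(alpha, ic)` returning a scalar,
#'   possibly `-Inf`.
#' @param theta Expansion point.
#' @param step_alpha,step_ic Positive step sizes. The default `1e-3`
#'   balances truncation against cancellation for log-likelihoods built
#'   from \eqn{\sim 10^3} squared residuals.
#' @return A list of class `bif_hessian` with fields `h_aa`, `h_ai`,
#'   `h_ii`, `step_alpha`, `step_ic`, `valid`.
#' @export
#' @examples
#' # exact quadratic: FD is exact up to rounding
#' f <- function(a, ic) -((a - 1)^2 + ic^2) / 2
#' fd_hessian(f, theta(1, 0))   # h_aa = h_ii = -1, h_ai = 0
fd_hessian <- function(f, theta, step_alpha = 1e-3, step_ic = 1e-3) {
  th <- as_theta(theta)
  ha <- check_finite_scalar(step_alpha, "step_alpha")
  hi <- check_finite_scalar(step_ic, "step_ic")
  if (ha <= 0 || hi <= 0) stop_invalid("finite-difference steps must be > 0")
  a <- th[["alpha"]]
  ic <- th[["ic"]]
  v00 <- f(a, ic)
  vp0 <- f(a + ha, ic)
  vm0 <- f(a - ha, ic)
  v0p <- f(a, ic + hi)
  v0m <- f(a, ic - hi)
  vpp <- f(a + ha, ic + hi)
  vpm <- f(a + ha, ic - hi)
  vmp <- f(a - ha, ic + hi)
  vmm <- f(a - ha, ic - hi)
  vals <- c(v00, vp0, vm0, v0p, v0m, vpp, vpm, vmp, vmm)
  valid <- all(is.finite(vals))
  structure(
    list(h_aa = if (valid) (vp0 - 2 * v00 + vm0) / ha^2 else NA_real_,
         h_ai = if (valid) (vpp - vpm - vmp + vmm) / (4 * ha * hi)
                else NA_real_,
         h_ii = if (valid) (v0p - 2 * v00 + v0m) / hi^2 else NA_real_,
         step_alpha = ha, step_ic = hi, valid = valid),
    class = "bif_hessian"
  )
}

#' Finite-difference Hessian of the log-likelihood
#'
#' [fd_hessian()] applied to `log_likelihood(theta, obs)` as a function of
#' \eqn{(\alpha, IC)}.
#'
#' @inheritParams log_likelihood
#' @inheritParams fd_hessian
#' @return A `bif_hessian`; `valid = FALSE` if any stencil point has a
#'   divergent trajectory.
#' @export
hessian_loglik <- function(theta, obs, step_alpha = 1e-3, step_ic = 1e-3,
                           cfg = solver_config()) {
  fd_hessian(function(a, ic) log_likelihood(c(alpha = a, ic = ic), obs, cfg),
             theta, step_alpha, step_ic)
}

#' @export
print.bif_hessian <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("FD Hessian: h_aa = %.6g, h_ai = %.6g, h_ii = %.6g\n",
                x$h_aa, x$h_ai, x$h_ii))
  } else {
    cat("FD Hessian: invalid (stencil touched a divergent candidate)\n")
  }
  invisible(x)
}

fisher_value <- function(trace_fi, status) {
  structure(list(trace_fi = trace_fi, status = status),
            class = "bif_fisher_value")
}

#' @export
print.bif_fisher_value <- function(x, ...) {
  cat(sprintf("observed FI trace: %.6g (%s)\n", x$trace_fi, x$status))
  invisible(x)
}

#' Observed Fisher information trace at a parameter point
#'
#' The observed Fisher information is the negative Hessian of the
#' log-likelihood; it is summarized by its trace,
#' \eqn{FI_{obs}(\theta) = -\mathrm{tr}\, H = -(H_{\alpha\alpha} + H_{IC\,IC})},
#' as a scalar measure of how sharply the likelihood is curved around
#' \eqn{\theta}. For whole-plane maps each point is evaluated against the
#' noiseless observation generated at \eqn{\theta} itself, so \eqn{\theta}
#' is the exact MLE of its own data and the curvature is measured at the
#' maximum. If the trajectory at \eqn{\theta} diverges, or any
#' finite-difference stencil point does, the value is set to 0 with status
#' `"divergent_set_zero"`; the raw (possibly slightly negative, at the
#' level of finite-difference error) trace is kept otherwise.
#'
#' @inheritParams integrate_model
#' @inheritParams fd_hessian
#' @return A list of class `bif_fisher_value` with fields `trace_fi` and
#'   `status` (`"ok"` or `"divergent_set_zero"`).
#' @export
#' @examples
#' fisher_trace("saddle_node", theta(-0.5, 0), time_grid(50))  # set to 0
fisher_trace <- function(model, theta, grid, cfg = solver_config(),
                         step_alpha = 1e-3, step_ic = 1e-3) {
  model <- as_bif_model(model)
  th <- as_theta(theta)
  traj <- integrate_model(model, th, grid, cfg)
  if (traj$status == "diverged") {
    return(fisher_value(0, "divergent_set_zero"))
  }
  nsub <- n_substeps(grid, cfg)
  mc <- model_code(model)
  y <- traj$states
  h <- fd_hessian(function(a, ic) {
    rk4_loglik_cpp(mc, a, ic, grid$obs_times, nsub,
                   cfg$divergence_threshold, y)
  }, th, step_alpha, step_ic)
  if (!h$valid) return(fisher_value(0, "divergent_set_zero"))
  fisher_value(-(h$h_aa + h$h_ii), "ok")
}

#' Observed Fisher information map over the (alpha, IC) plane
#'
#' [fisher_trace()] at every cell of the grid spanned by the axes. Cells
#' are independent of one another and of evaluation order. Divergent cells
#' (including cells whose finite-difference stencil touches a divergent
#' neighbour, a margin of at most one FD step around basin boundaries) are
#' 0 with status `"divergent_set_zero"`.
#'
#' @inheritParams fisher_trace
#' @param alpha_axis,ic_axis Strictly increasing numeric axes.
#' @return A list of class `bif_fisher_map` with fields `alpha_axis`,
#'   `ic_axis`, `fi` (matrix of raw traces, rows indexed by IC, columns by
#'   alpha), `status` (matching character matrix) and `model`, plus a
#'   `settings` attribute recording every numerical setting.
#' @seealso [fisher_map_values()] for the clamped-at-zero view used in
#'   exports.
#' @export
fisher_map <- function(model, alpha_axis, ic_axis, grid,
                       cfg = solver_config(), step_alpha = 1e-3,
                       step_ic = 1e-3) {
  model <- as_bif_model(model)
  check_axis(alpha_axis, "alpha_axis")
  check_axis(ic_axis, "ic_axis")
  fi <- matrix(0, nrow = length(ic_axis), ncol = length(alpha_axis))
  status <- matrix("divergent_set_zero", nrow = length(ic_axis),
                   ncol = length(alpha_axis))
  for (j in seq_along(alpha_axis)) {
    for (i in seq_along(ic_axis)) {
      fv <- fisher_trace(model, theta(alpha_axis[j], ic_axis[i]), grid,
                         cfg, step_alpha, step_ic)
      fi[i, j] <- fv$trace_fi
      status[i, j] <- fv$status
    }
  }
  structure(
    list(alpha_axis = alpha_axis, ic_axis = ic_axis, fi = fi,
         status = status, model = model),
    class = "bif_fisher_map",
    settings = list(grid = grid, cfg = cfg, step_alpha = step_alpha,
                    step_ic = step_ic)
  )
}

#' Fisher map values, optionally clamped at zero
#'
#' The map stores raw finite-difference traces, which can dip marginally
#' below zero at the level of FD error even though the curvature at an MLE
#' is non-negative. For display and export a clamped view is conventional.
#'
#' @param map A [fisher_map()] result.
#' @param clamp Replace negative traces by 0 (default `TRUE`).
#' @return Numeric matrix of FI values.
#' @export
fisher_map_values <- function(map, clamp = TRUE) {
  if (!inherits(map, "bif_fisher_map")) {
    stop_invalid("`map` must be created by fisher_map()")
  }
  if (clamp) pmax(map$fi, 0) else map$fi
}

#' @export
print.bif_fisher_map <- function(x, ...) {
  cat(sprintf(
    "observed FI map: %s, %d x %d cells, %d divergent, max FI = %.4g\n",
    x$model, length(x$ic_axis), length(x$alpha_axis),
    sum(x$status == "divergent_set_zero"), max(x$fi)))
  invisible(x)
}

#' Marginal Fisher information along alpha at fixed IC
#'
#' The fixed-IC row of the Fisher map: observed FI as a function of the
#' bifurcation parameter for a known initial condition. By default this is
#' the full 2x2-trace convention (the same quantity as [fisher_map()]
#' cells); `component = "alpha"` instead reports only the
#' \eqn{-H_{\alpha\alpha}} curvature, for the reading in which the initial
#' condition is treated as known rather than co-estimated. The convention
#' used is recorded on the result.
#'
#' @inheritParams fisher_map
#' @param ic Fixed initial condition.
#' @param component `"trace"` (default) or `"alpha"`.
#' @return A data frame with columns `alpha`, `fi`, `status`, and
#'   attributes `ic`, `component`, `model`.
#' @export
fisher_slice <- function(model, ic, alpha_axis, grid,
                         cfg = solver_config(), step_alpha = 1e-3,
                         step_ic = 1e-3, component = c("trace", "alpha")) {
  model <- as_bif_model(model)
  ic <- check_finite_scalar(ic, "ic")
  check_axis(alpha_axis, "alpha_axis")
  component <- match.arg(component)
  fi <- numeric(length(alpha_axis))
  status <- character(length(alpha_axis))
  nsub <- n_substeps(grid, as_solver_config(cfg))
  mc <- model_code(model)
  for (j in seq_along(alpha_axis)) {
    th <- theta(alpha_axis[j], ic)
    if (component == "trace") {
      fv <- fisher_trace(model, th, grid, cfg, step_alpha, step_ic)
      fi[j] <- fv$trace_fi
      status[j] <- fv$status
    } else {
      traj <- integrate_model(model, th, grid, cfg)
      if (traj$status == "diverged") {
        fi[j] <- 0
        status[j] <- "divergent_set_zero"
        next
      }
      y <- traj$states
      h <- fd_hessian(function(a, i_) {
        rk4_loglik_cpp(mc, a, i_, grid$obs_times, nsub,
                       cfg$divergence_threshold, y)
      }, th, step_alpha, step_ic)
      if (!h$valid) {
        fi[j] <- 0
        status[j] <- "divergent_set_zero"
      } else {
        fi[j] <- -h$h_aa
        status[j] <- "ok"
      }
    }
  }
  structure(
    data.frame(alpha = alpha_axis, fi = fi, status = status,
               stringsAsFactors = FALSE),
    ic = ic, component = component, model = model,
    class = c("bif_fisher_slice", "data.frame")
  )
}
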