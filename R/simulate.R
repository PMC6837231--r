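#' Observation time grid
#'
#' `n_obs` evenly spaced observation times spanning `[t_start, t_end]`.
#' The default window `[0, 10]` is long enough that, over the parameter
#' ranges studied (\eqn{|\alpha|, |IC| \le 2}), every converging trajectory
#' reaches its fixed point to well within the noise floors considered.
#'
#' @param n_obs Number of observation times M (integer \eqn{\ge 2}).
#' @param t_start Start time (default 0).
#' @param t_end End time (default 10), strictly greater than `t_start`.
#' @return A list of class `bif_time_grid` with fields `t_start`, `t_end`,
#'   `n_obs` and `obs_times`.
#' @export
#' @examples
#' time_grid(10)
time_grid <- function(n_obs, t_start = 0, t_end = 10) {
  t_start <- check_finite_scalar(t_start, "t_start")
  t_end <- check_finite_scalar(t_end, "t_end")
  if (!is.numeric(n_obs) || length(n_obs) != 1L || !is.finite(n_obs) ||
      n_obs < 2 || n_obs != round(n_obs)) {
    stop_invalid("`n_obs` must be an integer >= 2")
  }
  if (t_end <= t_start) stop_invalid("`t_end` must exceed `t_start`")
  structure(
    list(t_start = t_start, t_end = t_end, n_obs = as.integer(n_obs),
         obs_times = seq(t_start, t_end, length.out = as.integer(n_obs))),
    class = "bif_time_grid"
  )
}

#' @export
print.bif_time_grid <- function(x, ...) {
  cat(sprintf("time grid: %d observations on [%g, %g]\n",
              x$n_obs, x$t_start, x$t_end))
  invisible(x)
}

#' Integrator settings
#'
#' @param step Requested internal RK4 step (default `1e-3`). The actual step
#'   subdivides each observation interval evenly so observation times are hit
#'   exactly; it is never larger than `step`. Must not exceed the observation
#'   spacing.
#' @param divergence_threshold Absolute state bound beyond which the
#'   trajectory is declared diverged (default `1e6`). All four drifts blow up
#'   in finite time once diverging, so the classification is insensitive to
#'   this constant over many orders of magnitude.
#' @return A list of class `bif_solver_config`.
#' @export
solver_config <- function(step = 1e-3, divergence_threshold = 1e6) {
  step <- check_finite_scalar(step, "step")
  divergence_threshold <- check_finite_scalar(divergence_threshold,
                                              "divergence_threshold")
  if (step <= 0) stop_config("`step` must be positive")
  if (divergence_threshold <= 0) {
    stop_config("`divergence_threshold` must be positive")
  }
  structure(list(step = step, divergence_threshold = divergence_threshold),
            class = "bif_solver_config")
}

as_solver_config <- function(cfg) {
  if (!inherits(cfg, "bif_solver_config")) {
    stop_config("`cfg` must be created by solver_config()")
  }
  cfg
}

# Number of internal RK4 substeps per observation interval so the actual
# step is <= the requested step and observation times are hit exactly.
n_substeps <- function(grid, cfg) {
  spacing <- (grid$t_end - grid$t_start) / (grid$n_obs - 1L)
  if (cfg$step > spacing * (1 + 1e-12)) {
    stop_config("solver step (%g) exceeds observation spacing (%g)",
                cfg$step, spacing)
  }
  max(1L, as.integer(ceiling(spacing / cfg$step - 1e-9)))
}

#' Integrate a normal form with fixed-step RK4
#'
#' Classic fourth-order Runge-Kutta from the initial condition at
#' `grid$t_start`, recording the state at every observation time. Each
#' observation interval is subdivided evenly so observation times are hit
#' exactly. Integration halts — with status `"diverged"` rather than an
#' error — the first time the state exceeds the divergence threshold or
#' becomes non-finite, on internal steps as well as observation times, so
#' blow-up between sparse observations is still caught.
#'
#' @inheritParams blow_up_time
#' @param grid A [time_grid()].
#' @param cfg A [solver_config()].
#' @return A list of class `bif_trajectory` with fields `times`, `states`
#'   (only times strictly before any divergence), `status` (`"ok"` or
#'   `"diverged"`) and `divergence_time` (`NA` when `status = "ok"`), plus
#'   attributes recording `model`, `theta`, `grid` and `cfg`.
#' @export
#' @examples
#' tr <- integrate_model("saddle_node", theta(1, 1.5), time_grid(100))
#' tr$status
#' tail(tr$states, 1)  # ~ sqrt(alpha) = 1
integrate_model <- function(model, theta, grid, cfg = solver_config()) {
  model <- as_bif_model(model)
  th <- as_theta(theta)
  if (!inherits(grid, "bif_time_grid")) {
    stop_invalid("`grid` must be created by time_grid()")
  }
  cfg <- as_solver_config(cfg)
  nsub <- n_substeps(grid, cfg)
  res <- rk4_path_cpp(model_code(model), th[["alpha"]], th[["ic"]],
                      grid$obs_times, nsub, cfg$divergence_threshold)
  keep <- !is.na(res$states)
  structure(
    list(times = grid$obs_times[keep],
         states = res$states[keep],
         status = if (res$diverged) "diverged" else "ok",
         divergence_time = res$divergence_time),
    class = "bif_trajectory",
    model = model, theta = th, grid = grid, cfg = cfg
  )
}

#' @export
print.bif_trajectory <- function(x, ...) {
  th <- attr(x, "theta")
  cat(sprintf("trajectory: %s, alpha = %g, ic = %g, %d states, status %s",
              attr(x, "model"), th[["alpha"]], th[["ic"]],
              length(x$states), x$status))
  if (x$status == "diverged") {
    cat(sprintf(" (blow-up detected at t = %g)", x$divergence_time))
  }
  cat("\n")
  invisible(x)
}
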