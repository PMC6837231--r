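.NOISE_LEVELS <- c(low = 0, moderate = 0.1, heavy = 1.0)

#' Measurement-noise specification
#'
#' Observation noise is i.i.d. zero-mean Gaussian with standard deviation
#' `sigma`, added per time point after solving the ODE. The three named
#' study levels are `low` (\eqn{\sigma = 0}), `moderate`
#' (\eqn{\sigma = 0.1}) and `heavy` (\eqn{\sigma = 1.0}). Other noise
#' models (e.g. log-normal) are a possible extension point but are not
#' implemented.
#'
#' @param sigma Noise standard deviation (\eqn{\ge 0}). Exactly one of
#'   `sigma` and `level` must be given.
#' @param level One of `"low"`, `"moderate"`, `"heavy"`.
#' @return A list of class `bif_noise_spec` with fields `sigma` and
#'   `level` (`NA` when constructed from a bare `sigma` that matches no
#'   named level).
#' @export
#' @examples
#' noise_spec(level = "heavy")   # sigma = 1.0
#' noise_spec(sigma = 0.25)
noise_spec <- function(sigma = NULL, level = NULL) {
  if (is.null(sigma) == is.null(level)) {
    stop_invalid("give exactly one of `sigma` and `level`")
  }
  if (!is.null(level)) {
    if (!is.character(level) || length(level) != 1L ||
        !level %in% names(.NOISE_LEVELS)) {
      stop_invalid("`level` must be one of: %s",
                   paste(names(.NOISE_LEVELS), collapse = ", "))
    }
    sigma <- unname(.NOISE_LEVELS[[level]])
  } else {
    sigma <- check_finite_scalar(sigma, "sigma")
    if (sigma < 0) stop_invalid("`sigma` must be >= 0")
    hit <- names(.NOISE_LEVELS)[.NOISE_LEVELS == sigma]
    level <- if (length(hit) == 1L) hit else NA_character_
  }
  structure(list(sigma = sigma, level = level), class = "bif_noise_spec")
}

#' Sampling-density presets
#'
#' The observation counts studied: very high (M = 1000), high (M = 500) and
#' low (M = 10) sampling rates.
#'
#' @return Integer vector `c(1000, 500, 10)`.
#' @export
sampling_presets <- function() c(1000L, 500L, 10L)

# Draw from a dedicated, restorable RNG stream so a single integer seed
# fully determines the Observation without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic observation
#'
#' Solves the model at `theta_true` with RK4, then adds one independent
#' \eqn{N(0, \sigma^2)} draw per observation time. Fully reproducible from
#' `(model, theta_true, grid, noise, seed)`; the caller's RNG state is left
#' untouched. A diverging `theta_true` yields a value-less observation with
#' status `"diverged"` rather than an error, so parameter-plane scans can
#' traverse divergent regions without aborting.
#'
#' @inheritParams integrate_model
#' @param theta_true The generating parameter pair.
#' @param noise A [noise_spec()].
#' @param seed Single integer seed for the noise draws.
#' @return A list of class `bif_observation` with fields `times`, `values`
#'   (`NULL` when diverged), `n_obs`, `noise`, `seed`, `model`,
#'   `theta_true`, `status`, and `noiseless` (the underlying trajectory
#'   states).
#' @export
#' @examples
#' obs <- generate_observation("saddle_node", theta(1, 1.5), time_grid(100),
#'                             noise_spec(level = "moderate"), seed = 1)
#' obs$status
generate_observation <- function(model, theta_true, grid, noise, seed) {
  model <- as_bif_model(model)
  th <- as_theta(theta_true)
  if (!inherits(noise, "bif_noise_spec")) {
    stop_invalid("`noise` must be created by noise_spec()")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  traj <- integrate_model(model, th, grid)
  if (traj$status == "diverged") {
    out <- list(times = grid$obs_times, values = NULL, n_obs = grid$n_obs,
                noise = noise, seed = as.integer(seed), model = model,
                theta_true = th, status = "diverged", noiseless = NULL)
    return(structure(out, class = "bif_observation", grid = grid))
  }
  eps <- with_local_seed(as.integer(seed),
                         rnorm(grid$n_obs, mean = 0, sd = noise$sigma))
  structure(
    list(times = traj$times, values = traj$states + eps, n_obs = grid$n_obs,
         noise = noise, seed = as.integer(seed), model = model,
         theta_true = th, status = "ok", noiseless = traj$states),
    class = "bif_observation", grid = grid
  )
}

#' @export
print.bif_observation <- function(x, ...) {
  th <- x$theta_true
  cat(sprintf(
    "observation: %s, alpha = %g, ic = %g, M = %d, sigma = %g, seed = %d, status %s\n",
    x$model, th[["alpha"]], th[["ic"]], x$n_obs, x$noise$sigma, x$seed,
    x$status))
  invisible(x)
}
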