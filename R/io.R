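# File round-tripping: long-format CSV for the numbers, a JSON sidecar for
# the metadata. Numeric columns are rendered with %.17g (17 significant
# digits always round-trip a double exactly), so CSV read-back is bit-exact.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_num_csv <- function(dt, path) {
  out <- data.table::as.data.table(lapply(dt, function(col) {
    if (is.double(col)) fmt_num(col) else col
  }))
  data.table::fwrite(out, path, quote = FALSE)
}

write_json_meta <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_json_meta <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

csv_sidecar <- function(csv_path) sub("\\.csv$", ".json", csv_path)

#' Write / read a trajectory
#'
#' CSV columns `(time, state)` plus a JSON sidecar recording the model,
#' parameters, status, divergence time and solver settings.
#'
#' @param traj An [integrate_model()] result.
#' @param path Output CSV path; the sidecar goes to the same path with
#'   extension `.json`.
#' @return `write_trajectory()` returns the paths written (invisibly);
#'   `read_trajectory()` returns a `bif_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "bif_trajectory")) {
    stop_invalid("`traj` must be created by integrate_model()")
  }
  th <- attr(traj, "theta")
  grid <- attr(traj, "grid")
  cfg <- attr(traj, "cfg")
  write_num_csv(data.table::data.table(time = traj$times,
                                       state = traj$states), path)
  meta <- list(kind = "trajectory", model = attr(traj, "model"),
               alpha = th[["alpha"]], ic = th[["ic"]],
               status = traj$status,
               divergence_time = if (is.na(traj$divergence_time)) NULL
                                 else traj$divergence_time,
               t_start = grid$t_start, t_end = grid$t_end,
               n_obs = grid$n_obs, step = cfg$step,
               divergence_threshold = cfg$divergence_threshold)
  write_json_meta(meta, csv_sidecar(path))
  invisible(c(path, csv_sidecar(path)))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- data.table::fread(path)
  meta <- read_json_meta(csv_sidecar(path))
  structure(
    list(times = d$time, states = d$state, status = meta$status,
         divergence_time = if (is.null(meta$divergence_time)) NA_real_
                           else meta$divergence_time),
    class = "bif_trajectory",
    model = meta$model, theta = theta(meta$alpha, meta$ic),
    grid = time_grid(meta$n_obs, meta$t_start, meta$t_end),
    cfg = solver_config(meta$step, meta$divergence_threshold)
  )
}

#' Write / read an observation
#'
#' CSV columns `(time, value)` plus JSON metadata (model, alpha, ic, sigma,
#' M, seed, status). The round trip is bit-exact.
#'
#' @param obs A [generate_observation()] result.
#' @param path Output CSV path.
#' @return `write_observation()` returns the paths written (invisibly);
#'   `read_observation()` returns a `bif_observation` (without the cached
#'   noiseless states, which are recomputed on demand by regenerating).
#' @export
write_observation <- function(obs, path) {
  if (!inherits(obs, "bif_observation")) {
    stop_invalid("`obs` must be created by generate_observation()")
  }
  grid <- attr(obs, "grid")
  d <- if (obs$status == "ok") {
    data.table::data.table(time = obs$times, value = obs$values)
  } else {
    data.table::data.table(time = numeric(0), value = numeric(0))
  }
  write_num_csv(d, path)
  meta <- list(kind = "observation", model = obs$model,
               alpha = obs$theta_true[["alpha"]],
               ic = obs$theta_true[["ic"]],
               sigma = obs$noise$sigma,
               level = if (is.na(obs$noise$level)) NULL else obs$noise$level,
               n_obs = obs$n_obs, seed = obs$seed, status = obs$status,
               t_start = grid$t_start, t_end = grid$t_end)
  write_json_meta(meta, csv_sidecar(path))
  invisible(c(path, csv_sidecar(path)))
}

#' @rdname write_observation
#' @export
read_observation <- function(path) {
  d <- data.table::fread(path)
  meta <- read_json_meta(csv_sidecar(path))
  grid <- time_grid(meta$n_obs, meta$t_start, meta$t_end)
  structure(
    list(times = if (meta$status == "ok") d$time else grid$obs_times,
         values = if (meta$status == "ok") d$value else NULL,
         n_obs = meta$n_obs,
         noise = noise_spec(sigma = meta$sigma),
         seed = meta$seed, model = meta$model,
         theta_true = theta(meta$alpha, meta$ic),
         status = meta$status,
         noiseless = NULL),
    class = "bif_observation", grid = grid
  )
}

#' Write a log-likelihood surface
#'
#' Long-format CSV `(alpha, ic, loglik, diverged)` plus JSON metadata.
#' Divergent cells are written with an empty `loglik` field and
#' `diverged = TRUE`.
#'
#' @param surface A [likelihood_surface()] result.
#' @param path Output CSV path.
#' @return The paths written, invisibly.
#' @export
write_surface <- function(surface, path) {
  if (!inherits(surface, "bif_surface")) {
    stop_invalid("`surface` must be created by likelihood_surface()")
  }
  long <- data.table::data.table(
    alpha = rep(surface$alpha_axis, each = length(surface$ic_axis)),
    ic = rep(surface$ic_axis, times = length(surface$alpha_axis)),
    loglik = as.vector(surface$loglik),
    diverged = !is.finite(as.vector(surface$loglik))
  )
  long$loglik[!is.finite(long$loglik)] <- NA_real_
  write_num_csv(long, path)
  grid <- attr(surface, "grid")
  cfg <- attr(surface, "cfg")
  meta <- list(kind = "loglik_surface", model = surface$model,
               argmax_alpha = surface$argmax[["alpha"]],
               argmax_ic = surface$argmax[["ic"]],
               n_alpha = length(surface$alpha_axis),
               n_ic = length(surface$ic_axis),
               t_start = grid$t_start, t_end = grid$t_end,
               n_obs = grid$n_obs, step = cfg$step,
               divergence_threshold = cfg$divergence_threshold)
  write_json_meta(meta, csv_sidecar(path))
  invisible(c(path, csv_sidecar(path)))
}

#' Write a Fisher information map
#'
#' Long-format CSV `(alpha, ic, fi, status)` plus JSON metadata recording
#' every numerical setting (grid, window, FD steps, solver step, divergence
#' threshold) for provenance.
#'
#' @param map A [fisher_map()] result.
#' @param path Output CSV path.
#' @param clamp Write the clamped-at-zero view (default `TRUE`); recorded
#'   in the metadata.
#' @return The paths written, invisibly.
#' @export
write_fisher_map <- function(map, path, clamp = TRUE) {
  if (!inherits(map, "bif_fisher_map")) {
    stop_invalid("`map` must be created by fisher_map()")
  }
  vals <- fisher_map_values(map, clamp = clamp)
  long <- data.table::data.table(
    alpha = rep(map$alpha_axis, each = length(map$ic_axis)),
    ic = rep(map$ic_axis, times = length(map$alpha_axis)),
    fi = as.vector(vals),
    status = as.vector(map$status)
  )
  write_num_csv(long, path)
  s <- attr(map, "settings")
  meta <- list(kind = "fisher_map", model = map$model,
               n_alpha = length(map$alpha_axis),
               n_ic = length(map$ic_axis),
               alpha_min = map$alpha_axis[1L],
               alpha_max = map$alpha_axis[length(map$alpha_axis)],
               ic_min = map$ic_axis[1L],
               ic_max = map$ic_axis[length(map$ic_axis)],
               clamped = clamp,
               t_start = s$grid$t_start, t_end = s$grid$t_end,
               n_obs = s$grid$n_obs, step = s$cfg$step,
               divergence_threshold = s$cfg$divergence_threshold,
               fd_step_alpha = s$step_alpha, fd_step_ic = s$step_ic)
  write_json_meta(meta, csv_sidecar(path))
  invisible(c(path, csv_sidecar(path)))
}
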