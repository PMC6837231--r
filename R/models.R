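.BIF_MODELS <- c("saddle_node", "transcritical",
                 "pitchfork_supercritical", "pitchfork_subcritical")

#' The four co-dimension 1 normal forms
#'
#' Returns the admissible model names. Each names a scalar autonomous ODE
#' \eqn{dX/dt = f(X; \alpha)} in its normal form:
#' \describe{
#'   \item{`saddle_node`}{\eqn{f = \alpha - X^2}}
#'   \item{`transcritical`}{\eqn{f = \alpha X - X^2}}
#'   \item{`pitchfork_supercritical`}{\eqn{f = \alpha X - X^3}}
#'   \item{`pitchfork_subcritical`}{\eqn{f = \alpha X + X^3}}
#' }
#'
#' @return Character vector of the four model names.
#' @export
#' @examples
#' bif_models()
bif_models <- function() .BIF_MODELS

as_bif_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% .BIF_MODELS) {
    stop_invalid("`model` must be one of: %s",
                 paste(.BIF_MODELS, collapse = ", "))
  }
  model
}

model_code <- function(model) match(as_bif_model(model), .BIF_MODELS)

#' Parameter pair (bifurcation parameter, initial condition)
#'
#' The inferred quantity throughout the package is the pair
#' \eqn{\theta = (\alpha, IC)}: the bifurcation parameter of the normal form
#' and the initial condition of the trajectory.
#'
#' @param alpha Bifurcation parameter (finite).
#' @param ic Initial condition, in state units (finite).
#' @return A named numeric vector of class `bif_theta`.
#' @export
#' @examples
#' theta(1, 1.5)
theta <- function(alpha, ic) {
  structure(c(alpha = check_finite_scalar(alpha, "alpha"),
              ic = check_finite_scalar(ic, "ic")),
            class = "bif_theta")
}

as_theta <- function(x) {
  if (inherits(x, "bif_theta")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    if (!is.null(names(x)) && all(c("alpha", "ic") %in% names(x))) {
      return(theta(x[["alpha"]], x[["ic"]]))
    }
    return(theta(x[[1L]], x[[2L]]))
  }
  stop_invalid("`theta` must be a bif_theta or a numeric vector of length 2")
}

#' @export
print.bif_theta <- function(x, ...) {
  cat(sprintf("theta: alpha = %g, ic = %g\n", x[["alpha"]], x[["ic"]]))
  invisible(x)
}

#' Drift of a normal form
#'
#' Evaluates \eqn{f(X; \alpha)} for one of the four normal forms.
#' Vectorized over `x`.
#'
#' @param model One of [bif_models()].
#' @param x State value(s); must be finite.
#' @param alpha Bifurcation parameter; must be finite.
#' @return Numeric vector of drift values.
#' @export
#' @examples
#' drift("saddle_node", 0, 1)      # 1
#' drift("transcritical", 0, 7)    # 0
drift <- function(model, x, alpha) {
  model <- as_bif_model(model)
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop_invalid("`x` must be finite")
  }
  alpha <- check_finite_scalar(alpha, "alpha")
  switch(model,
    saddle_node = alpha - x^2,
    transcritical = alpha * x - x^2,
    pitchfork_supercritical = alpha * x - x^3,
    pitchfork_subcritical = alpha * x + x^3
  )
}

#' Derivative of the drift with respect to the state
#'
#' \eqn{\partial f/\partial X} at `x`; the linearization used to classify
#' fixed-point stability.
#'
#' @inheritParams drift
#' @return Numeric vector of derivative values.
#' @export
drift_deriv <- function(model, x, alpha) {
  model <- as_bif_model(model)
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop_invalid("`x` must be finite")
  }
  alpha <- check_finite_scalar(alpha, "alpha")
  switch(model,
    saddle_node = -2 * x,
    transcritical = alpha - 2 * x,
    pitchfork_supercritical = alpha - 3 * x^2,
    pitchfork_subcritical = alpha + 3 * x^2
  )
}

classify_stability <- function(fprime, tol = 1e-10) {
  ifelse(fprime < -tol, "stable",
         ifelse(fprime > tol, "unstable", "marginal"))
}

#' Fixed points of a normal form
#'
#' All real equilibria of \eqn{f(X;\alpha) = 0}, found analytically (the four
#' drifts are fixed quadratic/cubic polynomials), with stability from the
#' sign of \eqn{f'(X^*)}: stable if \eqn{f' < -tol}, unstable if
#' \eqn{f' > tol}, marginal otherwise. Marginal points occur exactly at the
#' bifurcation (\eqn{\alpha = 0} for all four forms).
#'
#' @inheritParams drift
#' @param tol Threshold on \eqn{|f'|} below which a point is classified
#'   marginal. Default `1e-10`, tight enough to flag only the exact
#'   bifurcation points.
#' @return A data frame of class `bif_fixed_points` with columns `location`
#'   (ascending) and `stability` (`"stable"`, `"unstable"` or `"marginal"`),
#'   and attributes `model` and `alpha`. Zero rows when no equilibrium
#'   exists (saddle-node with \eqn{\alpha < 0}).
#' @export
#' @examples
#' fixed_points("saddle_node", 4)        # -2 unstable, 2 stable
#' fixed_points("transcritical", 1)      # 0 unstable, 1 stable
#' fixed_points("saddle_node", -1)       # none
fixed_points <- function(model, alpha, tol = 1e-10) {
  model <- as_bif_model(model)
  alpha <- check_finite_scalar(alpha, "alpha")
  locs <- switch(model,
    saddle_node = if (alpha > 0) c(-sqrt(alpha), sqrt(alpha))
                  else if (alpha == 0) 0 else numeric(0),
    transcritical = if (alpha == 0) 0 else sort(c(0, alpha)),
    pitchfork_supercritical = if (alpha > 0) c(-sqrt(alpha), 0, sqrt(alpha))
                              else 0,
    pitchfork_subcritical = if (alpha < 0) c(-sqrt(-alpha), 0, sqrt(-alpha))
                            else 0
  )
  stab <- if (length(locs)) {
    classify_stability(drift_deriv(model, locs, alpha), tol)
  } else {
    character(0)
  }
  structure(
    data.frame(location = locs, stability = stab,
               stringsAsFactors = FALSE),
    class = c("bif_fixed_points", "data.frame"),
    model = model, alpha = alpha
  )
}

#' @export
print.bif_fixed_points <- function(x, ...) {
  cat(sprintf("Fixed points of %s at alpha = %g:\n",
              attr(x, "model"), attr(x, "alpha")))
  if (nrow(x) == 0L) {
    cat("  (none)\n")
  } else {
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
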