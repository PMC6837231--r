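#' Finite-time blow-up time of a normal-form trajectory
#'
#' The exact time at which the solution of the normal form started at
#' `theta` escapes to infinity, or `Inf` if the trajectory exists for all
#' \eqn{t \ge 0}. Derived from the closed-form solutions documented in
#' [closed_form_solution()].
#'
#' @inheritParams drift
#' @param theta A [theta()] pair (alpha, ic).
#' @return A single positive number (possibly `Inf`).
#' @export
blow_up_time <- function(model, theta) {
  model <- as_bif_model(model)
  th <- as_theta(theta)
  a <- th[["alpha"]]
  x0 <- th[["ic"]]
  switch(model,
    saddle_node = {
      if (a > 0) {
        s <- sqrt(a)
        if (x0 < -s) atanh(s / (-x0)) / s else Inf
      } else if (a == 0) {
        if (x0 < 0) -1 / x0 else Inf
      } else {
        b <- sqrt(-a)
        (atan(x0 / b) + pi / 2) / b
      }
    },
    transcritical = {
      if (a == 0) {
        if (x0 < 0) -1 / x0 else Inf
      } else if ((a > 0 && x0 < 0) || (a < 0 && x0 < a)) {
        -log(x0 / (x0 - a)) / a
      } else {
        Inf
      }
    },
    pitchfork_supercritical = Inf,
    pitchfork_subcritical = {
      if (x0 == 0) return(Inf)
      u0 <- 1 / x0^2
      if (a == 0) {
        u0 / 2
      } else if (a > 0 || u0 < -1 / a) {
        log(a * u0 + 1) / (2 * a)
      } else {
        Inf
      }
    }
  )
}

#' Exact solution of a normal form
#'
#' Closed-form solution \eqn{X(t)} of \eqn{dX/dt = f(X;\alpha)},
#' \eqn{X(0) = IC}, used as the analytic oracle for the numerical
#' integrator. The derivations, by branch:
#'
#' \describe{
#'   \item{saddle-node, \eqn{\alpha > 0}}{With \eqn{s = \sqrt\alpha}, the
#'     tanh addition identity gives
#'     \eqn{X(t) = s\,(X_0 + s\tanh(st)) / (s + X_0\tanh(st))}. The
#'     denominator vanishes in finite time iff \eqn{X_0 < -s} (below the
#'     unstable point).}
#'   \item{saddle-node, \eqn{\alpha = 0}; transcritical, \eqn{\alpha = 0}}{
#'     \eqn{dX/dt = -X^2} integrates to \eqn{X(t) = X_0/(1 + X_0 t)};
#'     blow-up at \eqn{t = -1/X_0} for \eqn{X_0 < 0}.}
#'   \item{saddle-node, \eqn{\alpha < 0}}{With \eqn{b = \sqrt{-\alpha}},
#'     \eqn{X(t) = b\tan(\arctan(X_0/b) - bt)}; every trajectory reaches
#'     \eqn{-\infty} at \eqn{t = (\arctan(X_0/b) + \pi/2)/b}.}
#'   \item{transcritical, \eqn{\alpha \ne 0}}{The logistic solution
#'     \eqn{X(t) = \alpha X_0 / (X_0 + (\alpha - X_0)e^{-\alpha t})}
#'     (Bernoulli substitution \eqn{u = 1/X}); blow-up iff
#'     \eqn{\alpha > 0, X_0 < 0} or \eqn{\alpha < 0, X_0 < \alpha}.}
#'   \item{pitchforks}{Bernoulli substitution \eqn{u = X^{-2}} gives
#'     \eqn{u' = -2\alpha u \pm 2} with solution
#'     \eqn{u(t) = (u_0 \mp 1/\alpha)e^{-2\alpha t} \pm 1/\alpha} (upper
#'     signs supercritical), and \eqn{X = \mathrm{sign}(X_0)/\sqrt{u}}.
#'     At \eqn{\alpha = 0}: \eqn{u = u_0 + 2t} (supercritical, never 0) or
#'     \eqn{u = u_0 - 2t} (subcritical, blow-up at \eqn{u_0/2}). The
#'     supercritical form never blows up; the subcritical form blows up for
#'     any \eqn{X_0 \ne 0} when \eqn{\alpha > 0}, and when
#'     \eqn{|X_0| > \sqrt{-\alpha}} for \eqn{\alpha < 0}.}
#' }
#'
#' @inheritParams blow_up_time
#' @param t Time(s), each \eqn{\ge 0} and strictly before the blow-up time.
#' @return Numeric vector of solution values, one per element of `t`.
#' @seealso [blow_up_time()], [integrate_model()]
#' @export
#' @examples
#' closed_form_solution("transcritical", theta(1, 1), 5)   # stays at 1
#' closed_form_solution("saddle_node", theta(4, 0), c(0, 1, 10))
closed_form_solution <- function(model, theta, t) {
  model <- as_bif_model(model)
  th <- as_theta(theta)
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t)) || any(t < 0)) {
    stop_invalid("`t` must be finite and non-negative")
  }
  a <- th[["alpha"]]
  x0 <- th[["ic"]]
  tb <- blow_up_time(model, th)
  if (any(t >= tb)) {
    stop_blowup(tb, "solution blows up at t = %g, before requested t = %g",
                tb, max(t))
  }
  switch(model,
    saddle_node = {
      if (a > 0) {
        s <- sqrt(a)
        th_t <- tanh(s * t)
        s * (x0 + s * th_t) / (s + x0 * th_t)
      } else if (a == 0) {
        x0 / (1 + x0 * t)
      } else {
        b <- sqrt(-a)
        b * tan(atan(x0 / b) - b * t)
      }
    },
    transcritical = {
      if (a == 0) {
        x0 / (1 + x0 * t)
      } else {
        a * x0 / (x0 + (a - x0) * exp(-a * t))
      }
    },
    pitchfork_supercritical = {
      if (x0 == 0) {
        rep(0, length(t))
      } else {
        u0 <- 1 / x0^2
        u <- if (a == 0) u0 + 2 * t else (u0 - 1 / a) * exp(-2 * a * t) + 1 / a
        sign(x0) / sqrt(u)
      }
    },
    pitchfork_subcritical = {
      if (x0 == 0) {
        rep(0, length(t))
      } else {
        u0 <- 1 / x0^2
        u <- if (a == 0) u0 - 2 * t else (u0 + 1 / a) * exp(-2 * a * t) - 1 / a
        sign(x0) / sqrt(u)
      }
    }
  )
}
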