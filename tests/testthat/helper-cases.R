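# Shared fixtures: parameter pairs whose trajectories converge (no
# finite-time blow-up on [0, 10]) for each normal form, chosen across the
# qualitative regimes (above/below fixed points, both signs of alpha where
# admissible).
convergent_cases <- list(
  saddle_node = list(c(1, 0), c(4, 3), c(0.5, 1.2), c(2, -1), c(1, 1.5)),
  transcritical = list(c(1, 0.5), c(-1, -0.5), c(2, 3), c(-0.5, 0.3),
                       c(1, 2)),
  pitchfork_supercritical = list(c(1, 0.5), c(-1, 1), c(2, -0.7),
                                 c(1.5, 2), c(-2, -1)),
  pitchfork_subcritical = list(c(-1, 0.5), c(-2, 1), c(-1, -0.9),
                               c(-0.5, 0.2), c(-1.5, -1))
)

# Parameter pairs with finite-time blow-up on [0, 10].
divergent_cases <- list(
  saddle_node = list(c(-1, 0), c(-0.5, 1), c(1, -1.5)),
  transcritical = list(c(1, -0.5), c(-1, -1.5)),
  pitchfork_subcritical = list(c(-1, 1.5), c(1, 0.5), c(0.5, -0.2))
)

# Count sign changes of the drift on a fine state grid; the brute-force
# root-counting oracle (all roots of the four drifts are simple away from
# alpha = 0, so each root is one sign change).
brute_force_root_count <- function(model, alpha, x_max = 10, res = 1e-4) {
  x <- seq(-x_max, x_max, by = res)
  s <- sign(drift(model, x, alpha))
  # a grid-exact zero is one root; otherwise a root is a strict sign flip
  sum(s == 0) + sum(s[-length(s)] * s[-1] < 0)
}

# Richardson-extrapolated central second differences of a bivariate
# function: an FD oracle independent of fd_hessian's single-step stencil.
richardson_hessian <- function(f, a, ic, h = 1e-2) {
  d2 <- function(h_) {
    list(
      aa = (f(a + h_, ic) - 2 * f(a, ic) + f(a - h_, ic)) / h_^2,
      ii = (f(a, ic + h_) - 2 * f(a, ic) + f(a, ic - h_)) / h_^2,
      ai = (f(a + h_, ic + h_) - f(a + h_, ic - h_) -
            f(a - h_, ic + h_) + f(a - h_, ic - h_)) / (4 * h_^2)
    )
  }
  c1 <- d2(h)
  c2 <- d2(h / 2)
  # central differences have O(h^2) leading error
  list(aa = (4 * c2$aa - c1$aa) / 3,
       ii = (4 * c2$ii - c1$ii) / 3,
       ai = (4 * c2$ai - c1$ai) / 3)
}

# Per-test scratch directory, cleaned up when the calling test finishes.
local_out_dir <- function(env = parent.frame()) {
  d <- tempfile("bifinfer-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
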