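test_that("the FD Hessian is exact on a quadratic surrogate", {
  f <- function(a, ic) -((a - 1)^2 + ic^2) / 2
  h <- fd_hessian(f, theta(1, 0))
  expect_true(h$valid)
  expect_lt(abs(h$h_aa - (-1)), 1e-6)
  expect_lt(abs(h$h_ii - (-1)), 1e-6)
  expect_lt(abs(h$h_ai), 1e-6)
  # trace of the observed information: -tr(H) = 2
  expect_lt(abs(-(h$h_aa + h$h_ii) - 2), 1e-6)

  # correlated quadratic: mixed entry recovered
  g2 <- function(a, ic) -(a^2 + ic^2 + a * ic)
  h2 <- fd_hessian(g2, theta(0.3, -0.2))
  expect_lt(abs(h2$h_ai - (-1)), 1e-5)
})

test_that("a stencil touching -Inf invalidates the estimate", {
  f <- function(a, ic) if (a > 1) -Inf else -(a^2 + ic^2)
  h <- fd_hessian(f, theta(1, 0))  # a + step crosses the -Inf region
  expect_false(h$valid)
  expect_true(is.na(h$h_aa))
  h_ok <- fd_hessian(f, theta(0, 0))
  expect_true(h_ok$valid)
})

test_that("hessian_loglik matches a Richardson-extrapolated oracle", {
  g <- time_grid(200)
  pts <- list(c(1, 1.5), c(1, 0.5), c(0.5, 1), c(1.5, 1.5), c(2, 1))
  for (p in pts) {
    obs <- generate_observation("saddle_node", theta(p[1], p[2]), g,
                                noise_spec(sigma = 0), 1)
    f <- function(a, ic) log_likelihood(c(alpha = a, ic = ic), obs)
    h <- hessian_loglik(theta(p[1], p[2]), obs)
    oracle <- richardson_hessian(f, p[1], p[2])
    expect_true(h$valid)
    expect_lt(abs(h$h_aa - oracle$aa) / abs(oracle$aa), 1e-3)
    expect_lt(abs(h$h_ii - oracle$ii) / abs(oracle$ii), 1e-3)
  }
})

test_that("fisher_trace zeroes divergent parameter combinations", {
  g <- time_grid(100)
  fv <- fisher_trace("saddle_node", theta(-0.5, 0), g)
  expect_identical(fv$status, "divergent_set_zero")
  expect_identical(fv$trace_fi, 0)
  # a point whose own trajectory converges but whose stencil touches the
  # basin boundary is zeroed too (margin of one FD step)
  fv2 <- fisher_trace("pitchfork_subcritical", theta(-1, 1 - 5e-4), g)
  expect_identical(fv2$status, "divergent_set_zero")
  fv3 <- fisher_trace("saddle_node", theta(1, 1.5), g)
  expect_identical(fv3$status, "ok")
  expect_true(is.finite(fv3$trace_fi))
  expect_gt(fv3$trace_fi, 0)
})

test_that("noiseless self-data curvature is non-negative up to FD error", {
  g <- time_grid(100)
  for (model in names(convergent_cases)) {
    for (th in convergent_cases[[model]]) {
      fv <- fisher_trace(model, theta(th[1], th[2]), g)
      if (fv$status == "ok") {
        expect_gte(fv$trace_fi, -1e-6 * max(1, abs(fv$trace_fi)))
      }
    }
  }
})

test_that("pitchfork Fisher information is symmetric under IC mirroring", {
  g <- time_grid(200)
  for (model in c("pitchfork_supercritical", "pitchfork_subcritical")) {
    for (p in list(c(1, 0.6), c(-0.5, 0.4), c(0.8, 1.2))) {
      up <- fisher_trace(model, theta(p[1], p[2]), g)
      down <- fisher_trace(model, theta(p[1], -p[2]), g)
      expect_identical(up$status, down$status)
      if (up$status == "ok" && up$trace_fi != 0) {
        expect_lt(abs(up$trace_fi - down$trace_fi) / abs(up$trace_fi), 1e-6)
      }
    }
  }
})

test_that("map cells are independent of evaluation order and status-consistent", {
  g <- time_grid(50)
  ax <- seq(-1, 2, by = 0.5)
  ix <- seq(-0.5, 2, by = 0.5)
  m <- fisher_map("saddle_node", ax, ix, g)
  expect_equal(dim(m$fi), c(length(ix), length(ax)))
  # recompute a scattered subset individually: identical values
  for (cell in list(c(2, 3), c(1, 7), c(5, 4))) {
    fv <- fisher_trace("saddle_node", theta(ax[cell[2]], ix[cell[1]]), g)
    expect_identical(fv$trace_fi, m$fi[cell[1], cell[2]])
    expect_identical(fv$status, m$status[cell[1], cell[2]])
  }
  # divergent cells are exactly zero; ok cells finite
  expect_true(all(m$fi[m$status == "divergent_set_zero"] == 0))
  expect_true(all(is.finite(m$fi)))
  # clamped view never negative, raw view preserved
  expect_true(all(fisher_map_values(m) >= 0))
  expect_identical(fisher_map_values(m, clamp = FALSE), m$fi)
})

test_that("marginal FI slices reproduce the saddle-node peak structure", {
  g <- time_grid(500)
  ax <- seq(-0.5, 2, by = 0.1)
  sl <- fisher_slice("saddle_node", 1.5, ax, g)
  expect_identical(attr(sl, "component"), "trace")
  # peak at the bifurcation point alpha = 0, within one grid step
  expect_lte(abs(sl$alpha[which.max(sl$fi)]), 0.1 + 1e-9)
  # FI decreases moving away from the bifurcation
  expect_lt(sl$fi[sl$alpha == 2], max(sl$fi))
  # for IC = -1 the peak sits at the unstable fixed point alpha = IC^2 = 1
  sl2 <- fisher_slice("saddle_node", -1, seq(0, 2, by = 0.05), g)
  expect_lte(abs(sl2$alpha[which.max(sl2$fi)] - 1), 0.1 + 1e-9)

  # the alpha-curvature-only convention is available and differs
  sl3 <- fisher_slice("saddle_node", 1.5, ax, g, component = "alpha")
  expect_identical(attr(sl3, "component"), "alpha")
  ok <- sl$status == "ok"
  expect_true(all(sl3$fi[ok] <= sl$fi[ok] + 1e-9))
})
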