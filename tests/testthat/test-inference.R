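noiseless_obs <- function(model, alpha, ic, n = 100) {
  generate_observation(model, theta(alpha, ic), time_grid(n),
                       noise_spec(sigma = 0), 1)
}

test_that("log-likelihood is exact on worked cases", {
  # zero residuals at the truth
  obs <- noiseless_obs("saddle_node", 1, 1.5)
  expect_identical(log_likelihood(theta(1, 1.5), obs), 0)
  # constant-1 data vs constant-2 candidate at M = 10: -10/2
  obs10 <- noiseless_obs("saddle_node", 1, 1, n = 10)
  expect_identical(log_likelihood(theta(4, 2), obs10), -5.0)
  # divergent candidates map to -Inf
  expect_identical(log_likelihood(theta(-1, 0), obs), -Inf)
})

test_that("log-likelihood is never positive and zero only at zero residuals", {
  set.seed(12)
  obs <- generate_observation("saddle_node", theta(1, 1.5), time_grid(200),
                              noise_spec(sigma = 0.1), 5)
  for (k in 1:20) {
    th <- theta(runif(1, -2, 2), runif(1, -2, 2))
    ll <- log_likelihood(th, obs)
    expect_lte(ll, 0)
    if (ll == 0) {
      # only possible when candidate reproduces the data exactly
      tr <- integrate_model("saddle_node", th, time_grid(200))
      expect_identical(tr$states, obs$values)
    }
  }
})

test_that("noise strictly lowers the self-likelihood (paired seeds)", {
  g <- time_grid(100)
  failures <- 0L
  for (seed in 1:20) {
    o0 <- generate_observation("saddle_node", theta(1, 1.5), g,
                               noise_spec(sigma = 0), seed)
    o1 <- generate_observation("saddle_node", theta(1, 1.5), g,
                               noise_spec(sigma = 0.1), seed)
    if (log_likelihood(theta(1, 1.5), o0) <=
        log_likelihood(theta(1, 1.5), o1)) {
      failures <- failures + 1L
    }
  }
  expect_lte(failures, 1L)
})

test_that("mismatched time grids are rejected", {
  obs <- noiseless_obs("saddle_node", 1, 1.5)
  expect_error(log_likelihood(theta(1, 1.5), obs, grid = time_grid(50)),
               class = "bif_invalid_argument")
  expect_silent(log_likelihood(theta(1, 1.5), obs, grid = time_grid(100)))
})

test_that("surfaces locate the truth and flag divergent regions", {
  obs <- noiseless_obs("saddle_node", 1, 1.5, n = 50)
  ax <- seq(0, 2, by = 0.25)     # contains alpha = 1
  ix <- seq(0.5, 2, by = 0.25)   # contains ic = 1.5
  s <- likelihood_surface(obs = obs, alpha_axis = ax, ic_axis = ix)
  expect_equal(s$argmax[["alpha"]], 1)
  expect_equal(s$argmax[["ic"]], 1.5)
  expect_equal(dim(s$loglik), c(length(ix), length(ax)))
  expect_equal(max(s$loglik), 0)
  # a sub-grid entirely in the diverging half-plane has no finite value
  expect_error(
    likelihood_surface(obs = obs, alpha_axis = seq(-2, -0.5, by = 0.5),
                       ic_axis = seq(-2, 2, by = 1)),
    class = "bif_no_finite_likelihood")
})

test_that("surface argmax tie-breaking picks smallest alpha then smallest ic", {
  # constant-zero data: any theta whose trajectory is constant zero ties
  obs <- noiseless_obs("pitchfork_supercritical", -1, 0, n = 20)
  s <- likelihood_surface(obs = obs, alpha_axis = c(-1.5, -1, -0.5),
                          ic_axis = c(0, 0.5))
  # every alpha with ic = 0 gives exactly zero residuals: ties
  expect_equal(sum(s$loglik == 0), 3L)
  expect_equal(s$argmax[["alpha"]], -1.5)
  expect_equal(s$argmax[["ic"]], 0)
})

test_that("the supercritical surface is equivariant under IC mirroring", {
  g <- time_grid(60)
  ax <- seq(-1.5, 1.5, by = 0.5)
  ix <- seq(-1.5, 1.5, by = 0.5)
  o_plus <- generate_observation("pitchfork_supercritical", theta(1, 0.8),
                                 g, noise_spec(sigma = 0), 1)
  o_minus <- generate_observation("pitchfork_supercritical", theta(1, -0.8),
                                  g, noise_spec(sigma = 0), 1)
  s_plus <- likelihood_surface(obs = o_plus, alpha_axis = ax, ic_axis = ix)
  s_minus <- likelihood_surface(obs = o_minus, alpha_axis = ax, ic_axis = ix)
  flipped <- s_minus$loglik[rev(seq_along(ix)), ]
  same <- is.finite(s_plus$loglik) & is.finite(flipped)
  expect_identical(is.finite(s_plus$loglik), is.finite(flipped))
  expect_lt(max(abs(s_plus$loglik[same] - flipped[same])), 1e-9)
})

test_that("the MLE recovers noiseless truth and respects its bounds", {
  obs <- noiseless_obs("saddle_node", 1, 1.5, n = 200)
  fit <- find_mle(obs = obs, alpha_bounds = c(0.05, 2),
                  ic_bounds = c(0.05, 2))
  expect_lt(abs(fit$theta_hat[["alpha"]] - 1), 1e-3)
  expect_lt(abs(fit$theta_hat[["ic"]] - 1.5), 1e-3)
  expect_gte(fit$theta_hat[["alpha"]], 0.05)
  expect_lte(fit$theta_hat[["ic"]], 2)
  expect_gt(fit$n_evaluations, 41L * 41L)

  # never below the surface argmax over the same bounds
  s <- likelihood_surface(obs = obs, alpha_axis = seq(0.05, 2, length.out = 41),
                          ic_axis = seq(0.05, 2, length.out = 41))
  expect_gte(fit$loglik_at_hat, log_likelihood(s$argmax, obs))

  # bounds entirely inside the diverging region: explicit error
  expect_error(
    find_mle(obs = obs, alpha_bounds = c(-2, -0.5), ic_bounds = c(-2, 2)),
    class = "bif_no_finite_likelihood")
})
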