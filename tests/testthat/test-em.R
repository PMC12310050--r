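test_that("trajectory MLE handles degenerate and noise-free trajectories", {
  tm <- trajectory_mle(rep(0.3, 10))
  expect_identical(c(tm$s1, tm$s2), c(0, 0))
  expect_true(tm$singular)
  # deterministic selection recursion is inverted exactly
  p <- numeric(120); p[1] <- 0.3
  for (t in 1:119) p[t + 1] <- mean_next_freq(p[t], 0.01, 0.02)
  tm <- trajectory_mle(p)
  expect_lt(abs(tm$s1 - 0.01), 1e-6)
  expect_lt(abs(tm$s2 - 0.02), 1e-6)
})

test_that("trajectory MLE maximizes the Gaussian path likelihood", {
  set.seed(405)
  Ne <- 500
  for (rep in 1:10) {
    p <- pmin(0.95, pmax(0.05,
      0.4 + cumsum(rnorm(20, 0, 0.03))))
    tm <- trajectory_mle(p)
    opt <- optim(c(0, 0), function(s) -gaussian_path_ll(s[1], s[2], p, Ne),
                 method = "BFGS", control = list(reltol = 1e-14))
    expect_lt(max(abs(c(tm$s1, tm$s2) - opt$par)), 1e-6)
  }
})

test_that("closed-form M-steps match numeric optimizers on random posteriors", {
  set.seed(406)
  Ne <- 300
  modes <- list(additive = c(2, 1), dominant = c(1, 1),
                recessive = c(1, 0), het_diff = c(0, 1))
  for (rep in 1:100) {
    rp <- random_posteriors(M = 5, TT = 4)
    obj <- function(s1, s2) expected_path_ll(s1, s2, rp$xi, rp$nodes, Ne)
    # unconstrained: numeric-differentiation Newton solve (the objective
    # is exactly quadratic, so this oracle is exact up to rounding)
    ms <- m_step_unconstrained(rp$acc)
    expect_lt(max(abs(c(ms$s1, ms$s2) - quad_vertex_2d(obj))), 1e-8)
    # each constrained mode: parabola vertex along the line (b, a) * u
    for (m in names(modes)) {
      ab <- modes[[m]]
      mc <- m_step_constrained(rp$acc, ab[1], ab[2])
      u_star <- quad_vertex_1d(function(u) obj(ab[2] * u, ab[1] * u))
      u_hat <- if (ab[2] != 0) mc$s1 / ab[2] else mc$s2 / ab[1]
      expect_lt(abs(u_hat - u_star), 1e-8)
      expect_identical(ab[1] * mc$s1 - ab[2] * mc$s2, 0)   # exactly on line
    }
  }
})

test_that("constrained M-step enforces its mode exactly", {
  set.seed(407)
  rp <- random_posteriors()
  expect_identical(m_step_constrained(rp$acc, 1, 0)$s1, 0)   # recessive
  mc <- m_step_constrained(rp$acc, 2, 1)                     # additive
  expect_identical(2 * mc$s1 - mc$s2, 0)
  expect_identical(m_step_constrained(rp$acc, 0, 1)$s2, 0)   # het diff
  expect_error(m_step_constrained(rp$acc, 0, 0), "zero")
})

test_that("beta initial-distribution update recovers known shapes", {
  grd <- freq_grid(500)
  g1 <- discretized_beta(grd, 2, 5)
  up <- beta_init_update(g1, grd, 1, 1)
  expect_lt(abs(up$alpha - 2) / 2, 0.05)
  expect_lt(abs(up$beta - 5) / 5, 0.05)
  upu <- beta_init_update(discretized_beta(grd, 1, 1), grd, 1.2, 0.8)
  expect_lt(abs(upu$alpha - 1), 0.05)
  expect_lt(abs(upu$beta - 1), 0.05)
  # mirror-symmetric posterior implies alpha = beta
  gs <- discretized_beta(grd, 3, 3)
  ups <- beta_init_update(gs, grd, 2, 2.5)
  expect_lt(abs(ups$alpha - ups$beta), 1e-4 * ups$alpha)
})

test_that("neutral fit with fixed init is a single forward pass", {
  set.seed(408)
  ds <- simulate_dataset(sim_config(T_gen = 51, K = 4, n = 30, n_rep = 1),
                         seed = 408)
  grd <- freq_grid(100)
  f <- run_em(ds$obs[[1]], "neutral", Ne = 1000, grid = grd,
              estimate_init = FALSE)
  fb <- forward_backward(ds$obs[[1]], grd, transition_matrix(grd, 0, 0, 1000),
                         discretized_beta(grd, 1, 1))
  expect_identical(f$ll, fb$ll)
  expect_identical(f$iterations, 1L)
})

test_that("mode fits are nested above neutral and stay on their lines", {
  set.seed(409)
  ds <- simulate_dataset(sim_config(mode = "additive", s = 0.05, T_gen = 101,
                                    K = 6, n = 40, Ne = 2000, n_rep = 2),
                         seed = 409)
  for (ob in ds$obs) {
    fa <- fit_all_modes(ob, Ne = 2000, M = 150)
    lls <- fa$summary$ll
    expect_true(all(lls[-1] >= lls[1] - 1e-6))
    fits <- fa$fits
    expect_identical(2 * fits$additive$s1 - fits$additive$s2, 0)
    expect_identical(fits$dominant$s1 - fits$dominant$s2, 0)
    expect_identical(fits$recessive$s1, 0)
    expect_identical(fits$het_diff$s2, 0)
    expect_equal(fits$additive$ll, max(fits$additive$trace))
  }
})

test_that("EM recovers the additive coefficient on average", {
  set.seed(410)
  ds <- simulate_dataset(sim_config(mode = "additive", s = 0.05, n_rep = 12),
                         seed = 410)
  shat <- vapply(ds$obs, function(ob)
    run_em(ob, "additive", Ne = 10000, M = 150)$s, 0)
  expect_lt(abs(median(shat) - 0.05), 0.015)
})

test_that("degenerate input is rejected", {
  expect_error(run_em(temporal_obs(1, 0, 0, T_gen = 10), "additive", 100),
               "nothing to fit")
})
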