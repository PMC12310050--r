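test_that("binomial emissions handle boundaries and missing data", {
  grd <- freq_grid(3)
  expect_equal(emission_probs(0, 0, grd), c(1, 1, 1))
  expect_equal(emission_probs(2, 1, grd)[2], 0.5)
  expect_equal(emission_probs(5, 3, grd)[1], 0)    # a > 0 impossible at g = 0
  expect_equal(emission_probs(5, 5, grd)[3], 1)
  expect_error(emission_probs(2, 3, grd), "0 <= a <= n")
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(402)
  grd <- freq_grid(3)
  for (rep in 1:5) {
    P <- transition_matrix(grd, runif(1, -0.2, 0.2), runif(1, -0.2, 0.2),
                           runif(1, 20, 200))
    init <- runif(3); init <- init / sum(init)
    n <- sample(0:6, 3, replace = TRUE)
    a <- vapply(n, function(x) if (x == 0) 0L else sample(0:x, 1), 0L)
    obs <- temporal_obs(times = which(n > 0 | seq_len(3) == 1),
                        n = n[n > 0 | seq_len(3) == 1],
                        a = a[n > 0 | seq_len(3) == 1], T_gen = 3)
    fb <- forward_backward(obs, grd, P, init, return_gamma = TRUE,
                           return_xi = TRUE)
    or <- enumerate_hmm(obs, grd, P, init)
    expect_lt(abs(fb$ll - or$ll), 1e-12)
    expect_lt(max(abs(fb$gamma - or$gamma)), 1e-12)
    for (t in 1:2) expect_lt(max(abs(fb$xi[[t]] - or$xi[t, , ])), 1e-12)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-10)
    for (t in 1:2) {
      expect_lt(abs(sum(fb$xi[[t]]) - 1), 1e-10)
      expect_lt(max(abs(rowSums(fb$xi[[t]]) - fb$gamma[t, ])), 1e-12)
    }
  }
})

test_that("M-step accumulators equal their joint-posterior definitions", {
  set.seed(403)
  grd <- freq_grid(4)
  g <- grd$nodes
  P <- transition_matrix(grd, 0.05, -0.02, 80)
  init <- rep(0.25, 4)
  obs <- temporal_obs(times = c(1, 4), n = c(8, 10), a = c(3, 9), T_gen = 4)
  fb <- forward_backward(obs, grd, P, init)
  or <- enumerate_hmm(obs, grd, P, init)
  h <- g * (1 - g)
  gsum <- colSums(or$gamma[1:3, ])
  S1 <- 0
  for (t in 1:3)
    S1 <- S1 + sum(or$xi[t, , ] * outer(g, g)) - sum(or$gamma[t, ] * g^2)
  expect_lt(abs(fb$acc$A - sum(gsum * h)), 1e-12)
  expect_lt(abs(fb$acc$B - sum(gsum * g * h)), 1e-12)
  expect_lt(abs(fb$acc$C - sum(gsum * g^2 * h)), 1e-12)
  expect_lt(abs(fb$acc$S0 - (sum(or$gamma[4, ] * g) - sum(or$gamma[1, ] * g))),
            1e-12)
  expect_lt(abs(fb$acc$S1 - S1), 1e-12)
})

test_that("uninformative data gives zero log-likelihood and propagated init", {
  grd <- freq_grid(20)
  P <- transition_matrix(grd, 0.01, 0.01, 100)
  init <- discretized_beta(grd, 2, 2)
  obs <- temporal_obs(times = c(1, 5), n = c(0, 0), a = c(0, 0), T_gen = 5)
  fb <- forward_backward(obs, grd, P, init, return_gamma = TRUE)
  expect_equal(fb$ll, 0)
  expect_equal(fb$gamma1, init, tolerance = 1e-12)
  # with no data the time-t marginal is the init pushed through t-1 steps
  expect_equal(fb$gamma[3, ], as.vector(init %*% P %*% P), tolerance = 1e-12)
})

test_that("impossible observations yield -Inf log-likelihood, not an error", {
  grd <- freq_grid(5)
  P <- transition_matrix(grd, 0, 0, 100)
  init <- c(1, 0, 0, 0, 0)             # all mass on loss
  obs <- temporal_obs(times = 2, n = 10, a = 10, T_gen = 3)
  fb <- forward_backward(obs, grd, P, init)
  expect_identical(fb$ll, -Inf)
})

test_that("banded C++ kernel agrees with the dense R reference", {
  set.seed(404)
  grd <- freq_grid(120)
  P <- transition_matrix(grd, 0.04, -0.03, 700)
  init <- discretized_beta(grd, 1.5, 3)
  obs <- temporal_obs(times = c(1, 7, 19, 40), n = c(25, 0, 40, 30),
                      a = c(6, 0, 21, 25), T_gen = 44)
  f1 <- forward_backward(obs, grd, P, init, return_gamma = TRUE)
  f2 <- selhmm:::.fb_r(obs, grd, P, init, return_gamma = TRUE)
  expect_lt(abs(f1$ll - f2$ll), 1e-10)
  expect_lt(max(abs(f1$gamma - f2$gamma)), 1e-10)
  expect_lt(max(abs(unlist(f1$acc) - unlist(f2$acc))), 1e-10)
})

test_that("inserting an explicit n = 0 sampling time changes nothing", {
  grd <- freq_grid(60)
  P <- transition_matrix(grd, 0.02, 0.02, 300)
  init <- discretized_beta(grd, 1, 1)
  o1 <- temporal_obs(times = c(1, 9), n = c(12, 14), a = c(3, 9), T_gen = 9)
  o2 <- temporal_obs(times = c(1, 4, 9), n = c(12, 0, 14), a = c(3, 0, 9),
                     T_gen = 9)
  f1 <- forward_backward(o1, grd, P, init)
  f2 <- forward_backward(o2, grd, P, init)
  expect_equal(f1$ll, f2$ll, tolerance = 1e-12)
  expect_equal(unlist(f1$acc), unlist(f2$acc), tolerance = 1e-12)
})
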