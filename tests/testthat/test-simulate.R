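test_that("trajectories absorb at the boundaries and conserve neutral means", {
  set.seed(413)
  expect_identical(simulate_trajectory(50, 0.1, 0.1, 100, 0), rep(0, 50))
  expect_identical(simulate_trajectory(50, 0.1, 0.1, 100, 1), rep(1, 50))
  # martingale property of neutral drift
  finals <- replicate(4000, simulate_trajectory(20, 0, 0, 50, 0.25)[20])
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.25), 3 * se)
  # neutral heterozygosity decays by (1 - 1/(2Ne)) per generation
  het <- replicate(4000, {p <- simulate_trajectory(11, 0, 0, 25, 0.5)[11]
                          p * (1 - p)})
  expected <- 0.25 * (1 - 1 / 50)^10
  expect_lt(abs(mean(het) - expected), 3 * sd(het) / sqrt(length(het)))
})

test_that("selection pushes the mean trajectory along the deterministic path", {
  set.seed(414)
  tr <- replicate(300, simulate_trajectory(101, 0.025, 0.05, 5000, 0.25))
  mean_path <- rowMeans(tr)
  expect_true(all(diff(mean_path) > -0.005))
  det <- numeric(101); det[1] <- 0.25
  for (t in 1:100) det[t + 1] <- mean_next_freq(det[t], 0.025, 0.05)
  expect_lt(max(abs(mean_path - det)), 0.02)
})

test_that("initial-frequency specs follow their distributions", {
  expect_identical(draw_initial(3, "fixed", p = 0.25), rep(0.25, 3))
  set.seed(415)
  # Ne = 2: support {1/4, 2/4, 3/4} with weights prop. to 1, 1/2, 1/3
  x <- draw_initial(40000, "one_over_i", Ne = 2)
  freq <- table(factor(x * 4, levels = 1:3)) / length(x)
  expect_equal(as.numeric(freq), c(6, 3, 2) / 11, tolerance = 0.02)
  big <- draw_initial(60000, "one_over_i", Ne = 1000)
  r <- mean(big == 1 / 2000) / mean(big == 2 / 2000)
  expect_equal(r, 2, tolerance = 0.15)
  expect_identical(draw_initial(4, "explicit", values = c(0.1, 0.2)),
                   c(0.1, 0.2, 0.1, 0.2))
})

test_that("sampling applies missingness and tracks the trajectory", {
  set.seed(416)
  ob <- sample_observations(rep(0.5, 20), times = c(1, 10, 20), n = 50,
                            missingness = 1)
  expect_true(all(ob$n == 0))
  ob2 <- sample_observations(rep(1, 20), times = c(1, 20), n = 30)
  expect_identical(ob2$a, ob2$n)
  a <- replicate(3000, sample_observations(rep(0.5, 5), 3, 50)$a)
  expect_lt(abs(mean(a) - 25), 3 * sd(a) / sqrt(length(a)))
})

test_that("conditioning rules accept and reject per mode", {
  ob_fixed_first <- temporal_obs(c(1, 10), n = c(20, 20), a = c(20, 5))
  ob_lost_last <- temporal_obs(c(1, 10), n = c(20, 20), a = c(5, 0))
  ob_seg <- temporal_obs(c(1, 10), n = c(20, 20), a = c(5, 7))
  expect_false(apply_conditioning(ob_fixed_first, "directional"))
  expect_false(apply_conditioning(ob_lost_last, "directional"))
  expect_true(apply_conditioning(ob_seg, "directional"))
  expect_true(apply_conditioning(ob_seg, "overdominance"))
  expect_false(apply_conditioning(ob_fixed_first, "underdominance"))
  expect_true(apply_conditioning(ob_lost_last, "underdominance"))
  expect_true(apply_conditioning(ob_fixed_first, "none"))
})

test_that("datasets are reproducible and satisfy their conditioning", {
  cfg <- sim_config(mode = "recessive", s = 0.025, T_gen = 101, K = 5,
                    n = 30, Ne = 500, init = list(type = "fixed", p = 0.05),
                    n_rep = 40)
  d1 <- simulate_dataset(cfg, seed = 417)
  d2 <- simulate_dataset(cfg, seed = 417)
  expect_identical(d1$obs, d2$obs)
  expect_true(all(vapply(d1$obs, apply_conditioning, TRUE,
                         condition = "directional")))
  expect_gt(d1$rejections, 0)   # low-frequency recessive start loses alleles
  expect_identical(equidistant_times(251, 11), seq(1L, 251L, by = 25L))
})

test_that("mode coefficient mapping matches the one-parameter definitions", {
  expect_identical(mode_coefficients("additive", 0.05), c(0.025, 0.05))
  expect_identical(mode_coefficients("dominant", 0.05), c(0.05, 0.05))
  expect_identical(mode_coefficients("recessive", 0.05), c(0, 0.05))
  expect_identical(mode_coefficients("overdominance", 0.05), c(0.05, 0))
  expect_identical(mode_coefficients("underdominance", -0.05), c(-0.05, 0))
  expect_identical(mode_coefficients("neutral"), c(0, 0))
})

test_that("permuting sampling times preserves the sample multiset", {
  set.seed(418)
  ds <- simulate_dataset(sim_config(n_rep = 10, T_gen = 51, K = 6, n = 25),
                         seed = 418)
  pm <- permute_sampling_times(ds, seed = 1)
  for (i in seq_along(ds$obs)) {
    expect_identical(sort(pm$obs[[i]]$a), sort(ds$obs[[i]]$a))
    expect_identical(sum(pm$obs[[i]]$n), sum(ds$obs[[i]]$n))
    expect_identical(pm$obs[[i]]$times, ds$obs[[i]]$times)
  }
  one <- temporal_obs(5, 10, 3, T_gen = 10)
  expect_identical(permute_sampling_times(list(one))[[1]], one)
})
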