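test_that("SNP filters apply the three criteria with strict thresholds", {
  one_tp <- temporal_obs(1, 100, 30, T_gen = 10)
  f <- snp_filters(one_tp)
  expect_false(f$pass)
  expect_true("timepoints" %in% f$reasons)
  # exactly 50 total fails, 51 passes (other filters passing)
  at50 <- temporal_obs(c(1, 5), n = c(25, 25), a = c(10, 10), T_gen = 5)
  at51 <- temporal_obs(c(1, 5), n = c(25, 26), a = c(10, 10), T_gen = 5)
  expect_false(snp_filters(at50)$pass)
  expect_true(snp_filters(at51)$pass)
  # pooled MAF exactly 0.05 fails the strict inequality
  maf05 <- temporal_obs(c(1, 5), n = c(50, 50), a = c(3, 2), T_gen = 5)
  f2 <- snp_filters(maf05)
  expect_false(f2$pass)
  expect_identical(f2$reasons, "maf")
  maf_above <- temporal_obs(c(1, 5), n = c(50, 50), a = c(3, 3), T_gen = 5)
  expect_true(snp_filters(maf_above)$pass)
})

test_that("window sums and the scaled chi-square fit behave", {
  p <- rep(0.3, 200)
  bw <- brown_window_pvalues(p, window = 50)
  expect_lt(diff(range(bw$S)), 1e-9)           # truncation rescaling
  expect_lt(diff(range(bw$post_p)), 1e-9)
  # moment matching recovers a known scaled chi-square
  set.seed(422)
  S <- 2 * rchisq(1e5, df = 10)
  c_hat <- var(S) / (2 * mean(S))
  f_hat <- 2 * mean(S)^2 / var(S)
  expect_lt(abs(c_hat - 2) / 2, 0.05)
  expect_lt(abs(f_hat - 10) / 10, 0.05)
  # post p decreases when a member p decreases, all else fixed
  set.seed(423)
  p2 <- runif(300)
  b1 <- brown_window_pvalues(p2, window = 50)
  p2b <- p2; p2b[150] <- p2b[150] / 100
  b2 <- brown_window_pvalues(p2b, window = 50)
  expect_gt(b2$S[140], b1$S[140])
  # under the same fitted null the post-processed p-value shrinks
  expect_lt(pchisq(b2$S[140] / b1$c_hat, b1$f_hat, lower.tail = FALSE),
            b1$post_p[140])
})

test_that("Brown-processed p-values stay uniform under independence", {
  set.seed(424)
  p <- runif(1e4)
  bw <- brown_window_pvalues(p, window = 50)
  ks <- suppressWarnings(ks.test(bw$post_p, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("BH step-up matches hand calculations", {
  expect_identical(bh_select(rep(1, 5))$significant, rep(FALSE, 5))
  r1 <- bh_select(c(0.001, 0.2, 0.9), alpha = 0.05)
  expect_identical(r1$significant, c(TRUE, FALSE, FALSE))
  expect_identical(r1$threshold, 0.001)
  r2 <- bh_select(c(0.01, 0.02, 0.9, 1), alpha = 0.05)
  expect_identical(r2$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r2$threshold, 0.02)
})

test_that("region calling keeps supported blocks and drops isolated spikes", {
  set.seed(425)
  m <- 2000            # enough null windows to dominate the pooled fit
  pos <- seq_len(m) * 1000
  # isolated raw-significant spike among uniform neighbors: the 50-locus
  # window dilutes it below the post-processed threshold
  p_spike <- runif(m, 0.05, 1)
  p_spike[1000] <- 1e-5
  sp <- scan_postprocess(data.frame(chrom = "7", pos = pos, p = p_spike))
  expect_true(sp$records$raw_sig[1000])
  expect_identical(nrow(sp$regions), 0L)
  # hitchhiking block: 30 consecutive low p around a strong lead
  p_block <- runif(m, 0.05, 1)
  p_block[986:1015] <- runif(30, 1e-6, 1e-4)
  p_block[1000] <- 1e-12
  bl <- scan_postprocess(data.frame(chrom = "5", pos = pos, p = p_block))
  expect_identical(nrow(bl$regions), 1L)
  expect_identical(bl$regions$lead_pos, 1000000)
  # the called region covers the core of the simulated block
  expect_true(bl$regions$start <= 990000 && bl$regions$end >= 1010000)
  expect_gte(bl$regions$n_loci, 25)
})

test_that("region calls are invariant to chromosome processing order", {
  set.seed(426)
  mk <- function(ch, spike) {
    p <- runif(800, 0.05, 1)
    if (spike) p[400:429] <- c(runif(29, 1e-6, 1e-4), 1e-11)
    data.frame(chrom = ch, pos = seq_len(800) * 500, p = p)
  }
  d1 <- rbind(mk("1", TRUE), mk("2", FALSE))
  d2 <- rbind(mk("2", FALSE), mk("1", TRUE))
  # rebuild with identical per-chromosome data, different order
  d2 <- d1[order(match(d1$chrom, c("2", "1"))), ]
  r1 <- scan_postprocess(d1)$regions
  r2 <- scan_postprocess(d2)$regions
  expect_identical(r1[order(r1$chrom), ], r2[order(r2$chrom), ])
})

test_that("parametric bootstrap CI covers a neutral truth", {
  set.seed(427)
  ds <- simulate_dataset(sim_config(T_gen = 51, K = 6, n = 40, Ne = 1000,
                                    n_rep = 1), seed = 427)
  ob <- ds$obs[[1]]
  fit <- run_em(ob, "additive", Ne = 1000, M = 100)
  ci <- bootstrap_ci(fit, ob, Ne = 1000, reps = 120, M = 100, seed = 428)
  expect_lt(ci$lower, 0)
  expect_gt(ci$upper, 0)
  expect_lte(ci$failures, 12)
})
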