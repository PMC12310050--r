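# Shared desk-scale simulation experiments, computed once per test run
# and reused across test blocks (the neutral-calibration fits feed both
# the delta-rejection check and the single-alternative uniformity check).

.exp_cache <- new.env(parent = emptyenv())

# 2,000 conditioned neutral replicates of the reference design
# (Ne = 10^4, T = 251, p0 = 0.25, 11 x 50 haploids), all modes fit.
neutral_calibration <- function() {
  if (!is.null(.exp_cache$calib)) return(.exp_cache$calib)
  n_rep <- 2000L
  ds <- simulate_dataset(
    sim_config(mode = "neutral", n_rep = n_rep, condition = "directional"),
    seed = 91101)
  grid <- freq_grid(250)
  delta_p <- numeric(n_rep)
  p_modes <- matrix(NA_real_, n_rep, 4,
                    dimnames = list(NULL, c("additive", "dominant",
                                            "recessive", "het_diff")))
  for (i in seq_len(n_rep)) {
    fa <- fit_all_modes(ds$obs[[i]], Ne = 10000, grid = grid)
    delta_p[i] <- classify_mode(fa)$p
    p_modes[i, ] <- fa$summary$p[match(colnames(p_modes), fa$summary$mode)]
  }
  .exp_cache$calib <- list(delta_p = delta_p, p_modes = p_modes,
                           n_rep = n_rep)
  .exp_cache$calib
}
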