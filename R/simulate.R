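#' Map a one-parameter selection mode to diploid coefficients
#'
#' @param mode simulation mode: `"neutral"`, `"additive"`, `"dominant"`,
#'   `"recessive"`, `"overdominance"`, `"underdominance"`.
#' @param s scalar selection coefficient for the mode (`s2` for additive /
#'   dominant / recessive, `s1` for over-/underdominance; negative for
#'   underdominance).
#' @return c(s1, s2)
#' @export
mode_coefficients <- function(mode, s = 0) {
  mode <- match.arg(mode, c("neutral", "additive", "dominant", "recessive",
                            "overdominance", "underdominance"))
  switch(mode,
    neutral        = c(0, 0),
    additive       = c(s / 2, s),
    dominant       = c(s, s),
    recessive      = c(0, s),
    overdominance  = c(s, 0),
    underdominance = c(s, 0))
}

#' Equidistant sampling times including both endpoints
#' @param T_gen total generations.
#' @param K number of sampling times.
#' @return integer vector of K generations from 1 to T_gen.
#' @export
equidistant_times <- function(T_gen, K) {
  as.integer(round(seq(1, T_gen, length.out = K)))
}

#' Simulate a discrete Wright-Fisher allele-frequency trajectory
#'
#' Forward simulation: each generation the next frequency is
#' `Binomial(2*Ne_t, p') / (2*Ne_t)` with `p'` the post-selection expected
#' frequency of [mean_next_freq()].  The boundaries 0 and 1 are absorbing.
#'
#' @param T_gen number of generations.
#' @param s1,s2 diploid selection coefficients.
#' @param Ne diploid effective size; scalar or per-transition vector of
#'   length `T_gen - 1`.
#' @param p0 initial frequency.
#' @return numeric vector of length `T_gen`.
#' @export
simulate_trajectory <- function(T_gen, s1, s2, Ne, p0) {
  Ne <- .expand_ne(Ne, T_gen)
  p <- numeric(T_gen)
  p[1] <- p0
  for (t in seq_len(T_gen - 1L)) {
    pp <- min(1, max(0, mean_next_freq(p[t], s1, s2)))
    N2 <- 2 * Ne[t]
    p[t + 1L] <- rbinom(1L, N2, pp) / N2
  }
  p
}

.expand_ne <- function(Ne, T_gen) {
  if (any(Ne <= 0)) stop("'Ne' must be positive")
  if (length(Ne) == 1L) rep(Ne, max(T_gen - 1L, 1L))
  else if (length(Ne) == T_gen - 1L) Ne
  else stop("'Ne' must be scalar or length T_gen - 1")
}

#' Draw initial allele frequencies
#'
#' Supported specifications: `fixed` (all replicates start at `p`),
#' `one_over_i` (frequency `i / (2*Ne)` with `i` drawn from
#' `{1, ..., 2*Ne - 1}` with probability proportional to `1/i`, the
#' neutral standing-variation spectrum), and `explicit` (per-replicate
#' frequencies supplied in `values`, recycled as needed).
#'
#' @param n_rep number of draws.
#' @param type `"fixed"`, `"one_over_i"` or `"explicit"`.
#' @param p fixed initial frequency (for `type = "fixed"`).
#' @param Ne diploid size defining the support of `one_over_i` (its first
#'   generation value when a schedule is supplied).
#' @param values explicit frequencies for `type = "explicit"`.
#' @return numeric vector of length `n_rep`.
#' @export
draw_initial <- function(n_rep, type = c("fixed", "one_over_i", "explicit"),
                         p = NULL, Ne = NULL, values = NULL) {
  type <- match.arg(type)
  switch(type,
    fixed = {
      if (is.null(p)) stop("'p' required for fixed initial frequencies")
      rep(p, n_rep)
    },
    one_over_i = {
      if (is.null(Ne)) stop("'Ne' required for one_over_i initial frequencies")
      N2 <- 2 * Ne[1L]
      i <- sample.int(N2 - 1L, n_rep, replace = TRUE, prob = 1 / seq_len(N2 - 1L))
      i / N2
    },
    explicit = {
      if (is.null(values)) stop("'values' required for explicit initial frequencies")
      rep_len(values, n_rep)
    })
}

#' Binomial sampling of haplotypes from a trajectory
#'
#' Draws `a_t ~ Binomial(n_t_eff, p_t)` at the requested generations,
#' where `n_t_eff` first thins the nominal sample size by the per-haplotype
#' missingness probability.
#'
#' @param traj frequency trajectory.
#' @param times sampling generations.
#' @param n nominal haploid sample sizes (scalar or per-time).
#' @param missingness probability that a sampled haplotype is missing.
#' @param id optional locus id.
#' @return a [temporal_obs()].
#' @export
sample_observations <- function(traj, times, n, missingness = 0, id = NULL) {
  K <- length(times)
  n <- rep_len(n, K)
  n_eff <- if (missingness > 0) rbinom(K, n, 1 - missingness) else n
  a <- rbinom(K, n_eff, traj[times])
  temporal_obs(times, n_eff, a, T_gen = length(traj), id = id)
}

#' Segregation-conditioning rule evaluated on the samples
#'
#' Rejection rules keeping replicates informative about the given mode:
#' directional modes (`neutral`, `additive`, `dominant`, `recessive`)
#' require the focal allele not fixed in the first sample and not lost in
#' the last; `overdominance` requires it segregating (0 < a < n) in the
#' last sample; `underdominance` segregating in the first sample;
#' `"none"` accepts everything.
#'
#' @param obs a [temporal_obs()].
#' @param condition conditioning rule name.
#' @return logical: accept (`TRUE`) or reject.
#' @export
apply_conditioning <- function(obs, condition = c("directional",
                                                  "overdominance",
                                                  "underdominance", "none")) {
  condition <- match.arg(condition)
  K <- length(obs$times)
  switch(condition,
    none = TRUE,
    directional = obs$a[1L] < obs$n[1L] && obs$a[K] > 0,
    overdominance = obs$a[K] > 0 && obs$a[K] < obs$n[K],
    underdominance = obs$a[1L] > 0 && obs$a[1L] < obs$n[1L])
}

.default_condition <- function(mode) {
  switch(mode,
    overdominance = "overdominance",
    underdominance = "underdominance",
    "directional")
}

#' Simulation configuration
#'
#' @param mode simulation mode, see [mode_coefficients()].
#' @param s scalar selection coefficient for the mode.
#' @param T_gen generations per trajectory.
#' @param Ne diploid effective size (scalar or length `T_gen - 1` schedule).
#' @param times sampling generations (default: `K` equidistant).
#' @param K number of equidistant sampling times when `times` is NULL.
#' @param n haploid samples per time (scalar or per-time).
#' @param init initial-frequency spec: list with `type` and the fields of
#'   [draw_initial()].
#' @param missingness per-haplotype missing probability.
#' @param n_rep replicates to accept.
#' @param condition conditioning rule (default chosen from `mode`).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(mode = "neutral", s = 0, T_gen = 251, Ne = 10000,
                       times = NULL, K = 11, n = 50,
                       init = list(type = "fixed", p = 0.25),
                       missingness = 0, n_rep = 100,
                       condition = NULL) {
  if (is.null(times)) times <- equidistant_times(T_gen, K)
  if (is.null(condition)) condition <- .default_condition(mode)
  structure(list(mode = mode, s = s, T_gen = T_gen, Ne = Ne,
                 times = as.integer(times), n = n, init = init,
                 missingness = missingness, n_rep = n_rep,
                 condition = condition),
            class = "sim_config")
}

#' Simulate a conditioned, sampled temporal dataset
#'
#' Vectorized rejection sampler: simulates Wright-Fisher trajectories in
#' chunks, draws binomial samples at the sampling times, and keeps
#' replicates until `n_rep` satisfy the mode's conditioning rule.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (set before any randomness).
#' @param keep_traj keep the true trajectories of accepted replicates.
#' @return list of class `replicate_set`: `obs` (list of
#'   [temporal_obs()]), `p0` (initial frequencies), `rejections`,
#'   `config`, `seed`, and optionally `traj` (matrix, rows = replicates at
#'   sampled generations only).
#' @export
simulate_dataset <- function(config, seed = NULL, keep_traj = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sc <- mode_coefficients(config$mode, config$s)
  TT <- config$T_gen
  Ne <- .expand_ne(config$Ne, TT)
  times <- config$times
  K <- length(times)
  nvec <- rep_len(config$n, K)

  accepted <- list()
  p0_acc <- numeric(0)
  traj_acc <- NULL
  rejections <- 0L
  total_tries <- 0L
  while (length(accepted) < config$n_rep) {
    need <- config$n_rep - length(accepted)
    R <- max(50L, ceiling(need * 1.3))
    total_tries <- total_tries + R
    if (total_tries > 1e6 + 100L * config$n_rep)
      stop("conditioning acceptance probability appears to be ~0")
    p0 <- do.call(draw_initial,
                  c(list(n_rep = R), config$init, list(Ne = Ne[1L])))
    p <- p0
    ptimes <- matrix(0, R, K)
    k <- 1L
    if (times[1L] == 1L) { ptimes[, 1L] <- p; k <- 2L }
    for (t in seq_len(TT - 1L)) {
      pp <- pmin(1, pmax(0, mean_next_freq(p, sc[1], sc[2])))
      N2 <- 2 * Ne[t]
      p <- rbinom(R, N2, pp) / N2
      if (k <= K && times[k] == t + 1L) { ptimes[, k] <- p; k <- k + 1L }
    }
    n_eff <- matrix(rep(nvec, each = R), R, K)
    if (config$missingness > 0)
      n_eff <- matrix(rbinom(R * K, n_eff, 1 - config$missingness), R, K)
    a <- matrix(rbinom(R * K, n_eff, ptimes), R, K)
    for (r in seq_len(R)) {
      if (length(accepted) >= config$n_rep) break
      ob <- temporal_obs(times, n_eff[r, ], a[r, ], T_gen = TT)
      if (apply_conditioning(ob, config$condition)) {
        accepted[[length(accepted) + 1L]] <- ob
        p0_acc <- c(p0_acc, p0[r])
        if (keep_traj) traj_acc <- rbind(traj_acc, ptimes[r, ])
      } else {
        rejections <- rejections + 1L
      }
    }
  }
  structure(list(obs = accepted, p0 = p0_acc, rejections = rejections,
                 config = config, seed = seed, traj = traj_acc),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("Replicate set: %d accepted loci (%d rejected), mode %s, s = %g\n",
              length(x$obs), x$rejections, x$config$mode, x$config$s))
  invisible(x)
}

#' Permute the sampling times of a dataset
#'
#' For each locus, randomly reassigns the observed `(n, a)` blocks to the
#' locus's sampling times, preserving the multiset of samples.  Used to
#' build an empirical null in which any temporal signal is destroyed.
#'
#' @param dataset a `replicate_set` or list of [temporal_obs()].
#' @param seed optional integer seed.
#' @return object of the same shape with permuted observations.
#' @export
permute_sampling_times <- function(dataset, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs_list <- if (inherits(dataset, "replicate_set")) dataset$obs else dataset
  perm <- lapply(obs_list, function(ob) {
    idx <- sample.int(length(ob$times))
    temporal_obs(ob$times, ob$n[idx], ob$a[idx], T_gen = ob$T_gen, id = ob$id)
  })
  if (inherits(dataset, "replicate_set")) {
    dataset$obs <- perm
    dataset
  } else perm
}
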