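#' Conditioned neutral log-likelihood of one locus
#'
#' Neutral HMM log-likelihood (s1 = s2 = 0, uniform-density initial
#' distribution) conditioned on observing at least one polymorphic sample:
#' the likelihood is divided by
#' `1 - P(no focal alleles observed) - P(no non-focal alleles observed)`,
#' where the two correction probabilities are the HMM likelihoods of the
#' pseudo-datasets with `a_t = 0` (resp. `a_t = n_t`) at every sampled
#' generation.  The conditioning penalizes large `Ne` (under which samples
#' are more often monomorphic purely because the frequency barely moves)
#' and sharpens the composite-likelihood surface.
#'
#' @param obs a [temporal_obs()].
#' @param Ne candidate diploid effective population size.
#' @param grid a [freq_grid()].
#' @param P optional precomputed neutral transition matrix for `Ne`.
#' @param cond optional precomputed conditioning log-denominator
#'   `log(1 - P0 - P1)` for this sampling scheme (see
#'   [conditioning_logdenominator()]).
#' @return scalar conditioned log-likelihood.
#' @export
conditioned_neutral_ll <- function(obs, Ne, grid = freq_grid(500),
                                   P = NULL, cond = NULL) {
  if (is.null(P)) P <- transition_matrix(grid, 0, 0, Ne)
  init <- discretized_beta(grid, 1, 1)
  if (is.null(cond)) cond <- conditioning_logdenominator(obs, grid, P, init)
  ll <- forward_backward(obs, grid, P, init)$ll
  ll - cond
}

#' Log-probability that a sampling scheme yields only monomorphic samples
#'
#' Computes `log(1 - P(all a_t = 0) - P(all a_t = n_t))` under the neutral
#' HMM; this depends only on the sampling times and sizes, not the
#' observed counts, so it can be shared across loci with a common scheme.
#'
#' @param obs a [temporal_obs()] (only its `times`, `n`, `T_gen` are used).
#' @param grid a [freq_grid()].
#' @param P neutral transition matrix.
#' @param init initial distribution.
#' @return scalar log-denominator; an error if the denominator is not
#'   positive (a locus with essentially no chance of polymorphism).
#' @export
conditioning_logdenominator <- function(obs, grid, P, init) {
  zero <- temporal_obs(obs$times, obs$n, rep(0L, length(obs$n)),
                       T_gen = obs$T_gen)
  full <- temporal_obs(obs$times, obs$n, obs$n, T_gen = obs$T_gen)
  p0 <- exp(forward_backward(zero, grid, P, init)$ll)
  p1 <- exp(forward_backward(full, grid, P, init)$ll)
  den <- 1 - p0 - p1
  if (!is.finite(den) || den <= 0)
    stop(sprintf("conditioning denominator is not positive for locus %s",
                 if (is.null(obs$id)) "<unnamed>" else obs$id))
  log(den)
}

#' Default log-spaced Ne candidate grid
#' @param Ne_guess center of the grid.
#' @param span multiplicative half-width (grid spans Ne_guess/span to
#'   Ne_guess*span).
#' @param length number of grid values.
#' @return numeric vector of candidate sizes.
#' @export
ne_grid <- function(Ne_guess, span = 8, length = 9) {
  exp(seq(log(Ne_guess / span), log(Ne_guess * span), length.out = length))
}

#' Composite-likelihood estimation of a constant effective population size
#'
#' Sums the conditioned neutral log-likelihoods of many loci on a grid of
#' candidate `Ne` values and interpolates the composite surface with a
#' cubic spline on `(log Ne, ll)`; the estimate is the interpolated
#' argmax.  Loci that fail the polymorphism precondition (conditioning
#' denominator not positive) are skipped and counted.
#'
#' Loci sharing an identical sampling scheme are detected automatically:
#' their between-sample transition matrices are collapsed into
#' matrix powers once per grid value, which makes batches of replicates
#' from a common design cheap to evaluate.
#'
#' @param loci list of [temporal_obs()].
#' @param grid_ne numeric vector of candidate sizes (length >= 3).
#' @param M number of hidden states.
#' @param grid optional [freq_grid()].
#' @return object of class `ne_fit`: `grid_ne`, `ll` (composite
#'   log-likelihood per candidate), `Ne_hat`, `boundary` (TRUE when the
#'   argmax hit the grid edge), `skipped`.
#' @export
estimate_ne <- function(loci, grid_ne, M = 500, grid = NULL) {
  if (length(loci) < 1) stop("at least one locus is required")
  if (length(grid_ne) == 1L) grid_ne <- sort(grid_ne)
  if (is.null(grid)) grid <- freq_grid(M)
  init <- discretized_beta(grid, 1, 1)

  sig <- vapply(loci, function(ob)
    paste(ob$T_gen, paste(ob$times, collapse = ","),
          paste(ob$n, collapse = ","), sep = "|"), "")
  groups <- split(seq_along(loci), sig)
  # loci sharing a scheme are evaluated together: one emission lookup
  # table per sampling time and one matrix product per between-sample gap
  prep <- lapply(groups, function(grp) {
    ob1 <- loci[[grp[1L]]]
    K <- length(ob1$times)
    amat <- matrix(0L, length(grp), K)
    for (r in seq_along(grp)) amat[r, ] <- loci[[grp[r]]]$a
    list(ob1 = ob1, amat = amat, n = length(grp))
  })

  lls <- numeric(length(grid_ne))
  skipped <- 0L
  for (gi in seq_along(grid_ne)) {
    P <- transition_matrix(grid, 0, 0, grid_ne[gi])
    tot <- 0
    for (pg in prep) {
      steps <- .collapsed_steps(pg$ob1, P)
      cond <- tryCatch(
        .collapsed_logdenominator(pg$ob1, steps, grid, init),
        error = function(e) NA_real_)
      if (is.na(cond)) { if (gi == 1L) skipped <- skipped + pg$n; next }
      tot <- tot + sum(.collapsed_ll_batch(pg$ob1$n, pg$amat, steps,
                                           grid$nodes, init)) - pg$n * cond
    }
    lls[gi] <- tot
  }

  if (length(grid_ne) < 3L) {
    Ne_hat <- grid_ne[which.max(lls)]
    boundary <- TRUE
  } else {
    sf <- splinefun(log(grid_ne), lls, method = "natural")
    opt <- optimize(sf, range(log(grid_ne)), maximum = TRUE, tol = 1e-8)
    Ne_hat <- exp(opt$maximum)
    boundary <- which.max(lls) %in% c(1L, length(grid_ne))
    if (boundary) {
      warning("composite-likelihood maximum at the grid boundary")
      Ne_hat <- grid_ne[which.max(lls)]
    }
  }
  structure(list(grid_ne = grid_ne, ll = lls, Ne_hat = Ne_hat,
                 boundary = boundary, skipped = skipped),
            class = "ne_fit")
}

#' @export
print.ne_fit <- function(x, ...) {
  cat(sprintf("Composite-likelihood Ne estimate: %.1f (grid %d values, %s)\n",
              x$Ne_hat, length(x$grid_ne),
              if (x$boundary) "at boundary" else "interior"))
  invisible(x)
}

# Precompute the between-sampling-time transition matrices P^gap for one
# sampling scheme (matrix powers by repeated squaring).
.collapsed_steps <- function(obs, P) {
  gaps <- diff(obs$times)
  pows <- unique(gaps)
  cache <- lapply(pows, function(k)
    if (k == 1L) P else .band_mat_pow(P, as.integer(k)))
  names(cache) <- as.character(pows)
  list(times = obs$times, gaps = gaps, cache = cache)
}

# Forward likelihood over the collapsed (sampling times only) chain.
.collapsed_ll_counts <- function(n, a, steps, nodes, init) {
  v <- init * dbinom(a[1L], n[1L], nodes)
  ll <- 0
  c1 <- sum(v)
  if (c1 <= 0) return(-Inf)
  ll <- log(c1)
  v <- v / c1
  for (k in seq_along(steps$gaps)) {
    v <- as.vector(v %*% steps$cache[[as.character(steps$gaps[k])]]) *
      dbinom(a[k + 1L], n[k + 1L], nodes)
    ck <- sum(v)
    if (ck <= 0) return(-Inf)
    ll <- ll + log(ck)
    v <- v / ck
  }
  ll
}

.collapsed_ll <- function(obs, steps, grid, init) {
  .collapsed_ll_counts(obs$n, obs$a, steps, grid$nodes, init)
}

# Vectorized collapsed-chain forward pass over all loci of a group:
# amat is loci x times; emissions come from a per-time lookup table over
# the possible counts 0..n_k.
.collapsed_ll_batch <- function(n, amat, steps, nodes, init) {
  R <- nrow(amat)
  M <- length(nodes)
  emit_tab <- function(k) {
    tab <- outer(0:n[k], nodes, function(a, g) dbinom(a, n[k], g))
    tab[amat[, k] + 1L, , drop = FALSE]
  }
  V <- rep(1, R) %o% init
  V <- V * emit_tab(1L)
  cs <- rowSums(V)
  ll <- log(cs)
  V <- V / cs
  for (k in seq_along(steps$gaps)) {
    V <- (V %*% steps$cache[[as.character(steps$gaps[k])]]) *
      emit_tab(k + 1L)
    cs <- rowSums(V)
    ll <- ll + log(cs)
    V <- V / cs
  }
  ll
}

.collapsed_logdenominator <- function(obs, steps, grid, init) {
  nodes <- grid$nodes
  p0 <- exp(.collapsed_ll_counts(obs$n, rep(0L, length(obs$n)), steps, nodes, init))
  p1 <- exp(.collapsed_ll_counts(obs$n, obs$n, steps, nodes, init))
  den <- 1 - p0 - p1
  if (!is.finite(den) || den <= 0)
    stop(sprintf("conditioning denominator is not positive for locus %s",
                 if (is.null(obs$id)) "<unnamed>" else obs$id))
  log(den)
}
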