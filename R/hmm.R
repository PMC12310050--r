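#' Temporal allele-count observations at one locus
#'
#' Container for a single locus sampled at a subset of generations.  Time is
#' 1-based: generation 1 is the first generation of the underlying
#' trajectory and `T_gen` the last.  Generations without data are treated
#' as `n = 0` (uninformative) by all downstream machinery.
#'
#' @param times integer sampling generations, strictly increasing, in
#'   \[1, T_gen\].
#' @param n haploid sample size at each sampling generation.
#' @param a focal-allele count at each sampling generation (0 <= a <= n).
#' @param T_gen total number of generations spanned by the locus
#'   (default: the last sampling time).
#' @param id optional locus identifier.
#' @return An object of class `temporal_obs`.
#' @examples
#' temporal_obs(times = c(1, 26, 51), n = c(50, 50, 50), a = c(12, 20, 31))
#' @export
temporal_obs <- function(times, n, a, T_gen = max(times), id = NULL) {
  times <- as.integer(times)
  if (length(times) == 0L) stop("at least one sampling time is required")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  if (length(n) != length(times) || length(a) != length(times))
    stop("'times', 'n' and 'a' must have equal length")
  if (any(n < 0) || any(a < 0) || any(a > n))
    stop("counts must satisfy 0 <= a <= n")
  if (times[1L] < 1L || times[length(times)] > T_gen)
    stop("'times' must lie in [1, T_gen]")
  structure(list(times = times, n = as.integer(round(n)),
                 a = as.integer(round(a)), T_gen = as.integer(T_gen),
                 id = id),
            class = "temporal_obs")
}

#' @export
print.temporal_obs <- function(x, ...) {
  cat(sprintf("Temporal observations%s: %d sampling times over %d generations\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              length(x$times), x$T_gen))
  print(data.frame(generation = x$times, n = x$n, a = x$a), row.names = FALSE)
  invisible(x)
}

#' Truncate a locus to its first k sampling times
#' @param obs a [temporal_obs()].
#' @param k number of sampling times to keep.
#' @return a [temporal_obs()] spanning up to the k-th sampling time.
#' @export
truncate_obs <- function(obs, k) {
  stopifnot(inherits(obs, "temporal_obs"), k >= 1, k <= length(obs$times))
  temporal_obs(obs$times[seq_len(k)], obs$n[seq_len(k)], obs$a[seq_len(k)],
               T_gen = obs$times[k], id = obs$id)
}

#' Binomial emission probabilities over the frequency grid
#'
#' Probability of observing `a` focal alleles among `n` sampled haplotypes
#' given each hidden population frequency: `a ~ Binomial(n, g_i)`.  With
#' `n = 0` (no data) every state has emission probability 1.
#'
#' @param n haploid sample size.
#' @param a focal-allele count (0 <= a <= n).
#' @param grid a [freq_grid()].
#' @return length-M vector of emission probabilities.
#' @export
emission_probs <- function(n, a, grid) {
  if (a < 0 || a > n) stop("'a' must satisfy 0 <= a <= n")
  dbinom(a, n, grid$nodes)
}

#' Scaled forward-backward pass for one locus
#'
#' Computes the exact data log-likelihood and the posterior summaries needed
#' by the EM M-step, under a fixed transition matrix and initial state
#' distribution.  Numerical stability comes from per-generation scaling of
#' the forward variables; the joint posteriors \eqn{\xi(t,i,j)} are never
#' materialized (unless requested for small problems) -- only the sums over
#' time of the posterior expectations that the M-step consumes.
#'
#' The accumulators returned (sums over t = 1..T-1 unless noted, with
#' \eqn{H = F(1-F)}):
#' `A` = sum E\[H_t\], `B` = sum E\[F_t H_t\], `C` = sum E\[F_t^2 H_t\],
#' `S0` = E\[F_T\] - E\[F_1\], `S1` = sum E\[F_t (F_{t+1} - F_t)\].
#'
#' @param obs a [temporal_obs()].
#' @param grid a [freq_grid()].
#' @param P M x M transition matrix.
#' @param init length-M initial distribution over the grid states.
#' @param return_gamma if `TRUE`, also return the full T x M matrix of
#'   marginal posteriors.
#' @param return_xi if `TRUE`, also return the (T-1)-list of M x M joint
#'   posterior slices (small problems only).
#' @return list with `ll` (log-likelihood; `-Inf` for impossible data),
#'   `gamma1`, `gammaT` (marginal posteriors at the first and last
#'   generation), `acc` (M-step accumulators), and optionally `gamma`,
#'   `xi`.
#' @export
forward_backward <- function(obs, grid, P, init,
                             return_gamma = FALSE, return_xi = FALSE) {
  stopifnot(inherits(obs, "temporal_obs"), inherits(grid, "freq_grid"))
  M <- grid$M
  if (length(init) != M) stop("'init' must have length M")
  if (!return_xi) {
    emit <- matrix(0, length(obs$times), M)
    for (k in seq_along(obs$times))
      emit[k, ] <- dbinom(obs$a[k], obs$n[k], grid$nodes)
    out <- .fb_core(P, init, obs$times, emit, obs$T_gen, grid$nodes,
                    return_gamma)
    if (!is.finite(out$ll))
      return(list(ll = -Inf, gamma1 = NULL, gammaT = NULL, acc = NULL))
    return(out)
  }
  .fb_r(obs, grid, P, init, return_gamma, return_xi)
}

# Pure-R reference implementation; also the only path materializing xi.
.fb_r <- function(obs, grid, P, init,
                  return_gamma = FALSE, return_xi = FALSE) {
  M <- grid$M
  g <- grid$nodes
  TT <- obs$T_gen

  # emissions only at sampled generations; elsewhere implicitly all-ones
  emit <- vector("list", TT)
  for (k in seq_along(obs$times))
    emit[[obs$times[k]]] <- dbinom(obs$a[k], obs$n[k], g)

  A <- matrix(0, TT, M)        # scaled forward variables
  cs <- numeric(TT)
  v <- if (is.null(emit[[1L]])) init else init * emit[[1L]]
  cs[1L] <- sum(v)
  if (cs[1L] <= 0) return(list(ll = -Inf, gamma1 = NULL, gammaT = NULL,
                               acc = NULL))
  A[1L, ] <- v / cs[1L]
  if (TT == 1L) {
    acc0 <- list(A = 0, B = 0, C = 0, S0 = 0, S1 = 0)
    out <- list(ll = log(cs[1L]), gamma1 = A[1L, ], gammaT = A[1L, ],
                acc = acc0)
    if (return_gamma) out$gamma <- A
    return(out)
  }
  for (t in 2:TT) {
    v <- A[t - 1L, ] %*% P
    v <- if (is.null(emit[[t]])) as.vector(v) else as.vector(v) * emit[[t]]
    cs[t] <- sum(v)
    if (cs[t] <= 0) return(list(ll = -Inf, gamma1 = NULL, gammaT = NULL,
                                acc = NULL))
    A[t, ] <- v / cs[t]
  }
  ll <- sum(log(cs))

  # backward pass, accumulating posterior expectations on the fly
  h <- g * (1 - g)
  gsum <- numeric(M)           # sum_{t=1}^{T-1} gamma(t, .)
  S1 <- 0
  bhat <- rep(1, M)
  gammaT <- A[TT, ]
  gamma_full <- if (return_gamma) matrix(0, TT, M) else NULL
  if (return_gamma) gamma_full[TT, ] <- gammaT
  xi <- if (return_xi) vector("list", TT - 1L) else NULL
  gamma_t <- gammaT
  for (t in (TT - 1L):1L) {
    w <- if (is.null(emit[[t + 1L]])) bhat else emit[[t + 1L]] * bhat
    u <- P %*% cbind(w, g * w)            # one dgemm: P w and P (g w)
    bhat_t <- u[, 1L] / cs[t + 1L]
    gamma_t <- A[t, ] * bhat_t
    gsum <- gsum + gamma_t
    S1 <- S1 + sum(A[t, ] * g * u[, 2L]) / cs[t + 1L] - sum(gamma_t * g^2)
    if (return_xi)
      xi[[t]] <- (A[t, ] * P) * rep(w, each = M) / cs[t + 1L]
    if (return_gamma) gamma_full[t, ] <- gamma_t
    bhat <- bhat_t
  }
  gamma1 <- gamma_t
  acc <- list(A = sum(gsum * h),
              B = sum(gsum * g * h),
              C = sum(gsum * g^2 * h),
              S0 = sum(gammaT * g) - sum(gamma1 * g),
              S1 = S1)
  out <- list(ll = ll, gamma1 = gamma1, gammaT = gammaT, acc = acc)
  if (return_gamma) out$gamma <- gamma_full
  if (return_xi) out$xi <- xi
  out
}
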