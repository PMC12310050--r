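# Independent oracles used to validate the implementation.

# Exhaustive-path HMM: likelihood, marginal and joint posteriors by
# enumerating all M^T hidden paths.
enumerate_hmm <- function(obs, grid, P, init) {
  M <- grid$M
  TT <- obs$T_gen
  emit <- matrix(1, TT, M)
  for (k in seq_along(obs$times))
    emit[obs$times[k], ] <- dbinom(obs$a[k], obs$n[k], grid$nodes)
  paths <- as.matrix(expand.grid(rep(list(seq_len(M)), TT)))
  w <- apply(paths, 1, function(st) {
    v <- init[st[1]] * emit[1, st[1]]
    for (t in seq_len(TT - 1))
      v <- v * P[st[t], st[t + 1]] * emit[t + 1, st[t + 1]]
    v
  })
  tot <- sum(w)
  gamma <- matrix(0, TT, M)
  xi <- array(0, c(max(TT - 1, 1), M, M))
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    for (t in seq_len(TT)) gamma[t, st[t]] <- gamma[t, st[t]] + w[r]
    for (t in seq_len(TT - 1))
      xi[t, st[t], st[t + 1]] <- xi[t, st[t], st[t + 1]] + w[r]
  }
  list(ll = log(tot), gamma = gamma / tot, xi = xi / tot)
}

# Expected complete-data Gaussian path log-likelihood assembled directly
# from joint posteriors (boundary states excluded: their transitions are
# point masses, constant in s1, s2).
expected_path_ll <- function(s1, s2, xi, nodes, Ne) {
  TT1 <- dim(xi)[1]
  M <- length(nodes)
  tot <- 0
  for (t in seq_len(TT1)) for (i in seq_len(M)) {
    h <- nodes[i] * (1 - nodes[i])
    if (h == 0) next
    mu <- nodes[i] + h * (s1 * (1 - 2 * nodes[i]) + s2 * nodes[i])
    for (j in seq_len(M)) {
      if (xi[t, i, j] == 0) next
      tot <- tot + xi[t, i, j] *
        dnorm(nodes[j], mu, sqrt(h / (2 * Ne)), log = TRUE)
    }
  }
  tot
}

# Random joint posteriors (consistent xi slices) on a small interior node
# set, plus the accumulators the M-step consumes.
random_posteriors <- function(M = 5, TT = 4) {
  nodes <- sort(runif(M, 0.05, 0.95))
  xi <- array(0, c(TT - 1, M, M))
  gamma <- matrix(0, TT, M)
  # forward-consistent random joints: chain a random marginal through
  # random conditionals so that slice t's row marginal equals slice
  # (t-1)'s column marginal
  marg <- runif(M); marg <- marg / sum(marg)
  gamma[1, ] <- marg
  for (t in seq_len(TT - 1)) {
    cond <- matrix(runif(M * M, 0.05, 1), M, M)
    cond <- cond / rowSums(cond)
    xi[t, , ] <- marg * cond
    marg <- colSums(xi[t, , ])
    gamma[t + 1, ] <- marg
  }
  h <- nodes * (1 - nodes)
  gsum <- colSums(gamma[-TT, , drop = FALSE])
  S1 <- 0
  for (t in seq_len(TT - 1))
    S1 <- S1 + sum(xi[t, , ] * outer(nodes, nodes)) - sum(gamma[t, ] * nodes^2)
  acc <- list(A = sum(gsum * h), B = sum(gsum * nodes * h),
              C = sum(gsum * nodes^2 * h),
              S0 = sum(gamma[TT, ] * nodes) - sum(gamma[1, ] * nodes),
              S1 = S1)
  list(nodes = nodes, gamma = gamma, xi = xi, acc = acc)
}

# Gaussian path log-likelihood of a fully observed trajectory.
gaussian_path_ll <- function(s1, s2, p, Ne) {
  TT <- length(p)
  tot <- 0
  for (t in seq_len(TT - 1)) {
    h <- p[t] * (1 - p[t])
    if (h == 0) next
    mu <- p[t] + h * (s1 * (1 - 2 * p[t]) + s2 * p[t])
    tot <- tot + dnorm(p[t + 1], mu, sqrt(h / (2 * Ne)), log = TRUE)
  }
  tot
}

# Numeric-differentiation oracles, exact for quadratic objectives (the
# expected complete-data path log-likelihood is exactly quadratic in the
# selection coefficients): parabola vertex through three points, and a
# 2-D Newton solve with central-difference gradient and Hessian.
quad_vertex_1d <- function(f, h = 0.5) {
  fm <- f(-h); f0 <- f(0); fp <- f(h)
  -h * (fp - fm) / (2 * (fp + fm - 2 * f0))
}

quad_vertex_2d <- function(f, h = 0.5) {
  f00 <- f(0, 0)
  gx <- (f(h, 0) - f(-h, 0)) / (2 * h)
  gy <- (f(0, h) - f(0, -h)) / (2 * h)
  hxx <- (f(h, 0) + f(-h, 0) - 2 * f00) / h^2
  hyy <- (f(0, h) + f(0, -h) - 2 * f00) / h^2
  hxy <- (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h^2)
  -solve(matrix(c(hxx, hxy, hxy, hyy), 2, 2), c(gx, gy))
}
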