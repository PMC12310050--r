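#' Selection modes and their linear constraints
#'
#' Each one-parameter mode restricts the diploid coefficients to a line
#' `a*s1 - b*s2 = 0` through the origin:
#' additive `s1 = s2/2` (a=2, b=1), dominant `s1 = s2` (1,1),
#' recessive `s1 = 0` (1,0), heterozygote difference `s2 = 0` (0,1).
#' The reported one-parameter coefficient `s` is `s2` for additive,
#' dominant and recessive, and `s1` for heterozygote difference.
#'
#' @param mode one of `"neutral"`, `"additive"`, `"dominant"`,
#'   `"recessive"`, `"het_diff"`, `"unconstrained"`.
#' @return list with `mode`, constraint coefficients `a`, `b` (NULL for
#'   neutral/unconstrained) and `s_of` (function mapping (s1, s2) to the
#'   mode's scalar s).
#' @export
selection_mode <- function(mode) {
  mode <- match.arg(mode, c("neutral", "additive", "dominant", "recessive",
                            "het_diff", "unconstrained"))
  ab <- switch(mode,
    additive = c(2, 1), dominant = c(1, 1), recessive = c(1, 0),
    het_diff = c(0, 1), NULL)
  s_of <- switch(mode,
    het_diff = function(s1, s2) s1,
    neutral  = function(s1, s2) 0,
    function(s1, s2) s2)
  list(mode = mode, a = ab[1], b = ab[2], s_of = s_of)
}

.mode_labels <- c("additive", "dominant", "recessive", "het_diff")

# Quadratic form of the expected complete-data Gaussian log-likelihood in
# (s1, s2): linear part L, curvature Q (up to the constant factor 2*Ne,
# which cancels in the maximizer).
.acc_quadratic <- function(acc) {
  L1 <- acc$S0 - 2 * acc$S1
  L2 <- acc$S1
  Q11 <- acc$A - 4 * acc$B + 4 * acc$C
  Q12 <- acc$B - 2 * acc$C
  Q22 <- acc$C
  list(L = c(L1, L2), Q = matrix(c(Q11, Q12, Q12, Q22), 2, 2))
}

#' Closed-form M-step for unconstrained diploid selection
#'
#' Maximizes the expected complete-data Gaussian path log-likelihood over
#' `(s1, s2)` given the posterior-expectation accumulators from
#' [forward_backward()].  The objective is an exact quadratic, so the
#' maximizer solves a 2x2 linear system.
#'
#' @param acc accumulator list (`A`, `B`, `C`, `S0`, `S1`).
#' @return list with `s1`, `s2`, and `singular` (TRUE when the normal
#'   equations are degenerate, in which case (0, 0) is returned).
#' @export
m_step_unconstrained <- function(acc) {
  qf <- .acc_quadratic(acc)
  det <- qf$Q[1, 1] * qf$Q[2, 2] - qf$Q[1, 2]^2
  scale <- max(abs(qf$Q)) ^ 2
  if (!is.finite(det) || scale == 0 || abs(det) < 1e-14 * scale)
    return(list(s1 = 0, s2 = 0, singular = TRUE))
  s1 <- (qf$L[1] * qf$Q[2, 2] - qf$L[2] * qf$Q[1, 2]) / det
  s2 <- (qf$Q[1, 1] * qf$L[2] - qf$Q[1, 2] * qf$L[1]) / det
  list(s1 = s1, s2 = s2, singular = FALSE)
}

#' Closed-form M-step under a linear mode constraint
#'
#' Restricts the quadratic M-step objective to the line `a*s1 = b*s2`
#' (parameterized as `(s1, s2) = u * (b, a)`), where the restricted
#' maximizer is available in closed form.  This is the Lagrange-multiplier
#' solution: for a quadratic objective the multiplier can be eliminated
#' analytically.
#'
#' @param acc accumulator list from [forward_backward()].
#' @param a,b constraint coefficients, not both zero.
#' @return list with `s1`, `s2` (exactly on the constraint line) and
#'   `singular`.
#' @export
m_step_constrained <- function(acc, a, b) {
  if (a == 0 && b == 0) stop("constraint coefficients must not both be zero")
  qf <- .acc_quadratic(acc)
  d <- c(b, a)
  Ld <- sum(d * qf$L)
  Qd <- as.numeric(d %*% qf$Q %*% d)
  if (!is.finite(Qd) || Qd <= 1e-14 * max(1, abs(Ld)))
    return(list(s1 = 0, s2 = 0, singular = TRUE))
  u <- Ld / Qd
  list(s1 = d[1] * u, s2 = d[2] * u, singular = FALSE)
}

#' Maximum-likelihood selection coefficients for a fully observed trajectory
#'
#' Closed-form estimator of `(s1, s2)` from an exactly observed population
#' frequency path `p_1, ..., p_T`, maximizing the normal-approximation
#' (Gaussian increment) path likelihood.  With `q_t = 1 - p_t`:
#' \deqn{\hat s_1 = \frac{(p_T-p_1)\sum p_t^3 q_t - \sum p_t\Delta_t \sum p_t^2 q_t}
#'   {\sum p_t q_t \sum p_t^3 q_t - (\sum p_t^2 q_t)^2}}
#' and symmetrically for \eqn{\hat s_2}, where \eqn{\Delta_t = p_{t+1}-p_t}
#' and sums run over t = 1..T-1.  The effective population size cancels
#' from the maximizer.
#'
#' @param p numeric trajectory in \[0, 1\], length >= 2.
#' @return list with `s1`, `s2`, `singular`.
#' @export
trajectory_mle <- function(p) {
  if (length(p) < 2) stop("trajectory must have length >= 2")
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  TT <- length(p)
  ph <- p[-TT]
  q <- 1 - ph
  d <- diff(p)
  acc <- list(A = sum(ph * q), B = sum(ph^2 * q), C = sum(ph^3 * q),
              S0 = p[TT] - p[1], S1 = sum(ph * d))
  res <- m_step_unconstrained(acc)
  if (res$singular) {
    qf <- .acc_quadratic(acc)
    if (max(abs(qf$L)) > 1e-12 * max(1, max(abs(qf$Q))))
      stop("singular normal equations for non-degenerate trajectory")
  }
  res
}

#' Discretized beta distribution over a frequency grid
#'
#' Integral of a Beta(alpha, beta) density over each grid interval (the
#' same midpoint intervals used for the transition matrix; the first and
#' last interval receive the integral from 0 and to 1 respectively, so the
#' boundary states carry the beta tail mass).
#'
#' @param grid a [freq_grid()].
#' @param alpha,beta positive shape parameters.
#' @return length-M mass vector summing to 1.
#' @export
discretized_beta <- function(grid, alpha = 1, beta = 1) {
  cb <- pmin(pmax(grid$cuts, 0), 1)
  diff(pbeta(cb, alpha, beta))
}

#' Update the beta initial-distribution parameters
#'
#' Numerically maximizes the posterior-weighted log-mass objective
#' \eqn{\sum_m \gamma(1, m) \log p(m; \alpha, \beta)} over positive
#' `(alpha, beta)`, where `p(m; .)` is the discretized beta mass of
#' [discretized_beta()].  Optimization is on the log scale (Nelder-Mead)
#' with the result clamped to \[1e-3, 1e3\].
#'
#' @param gamma1 length-M posterior over the first generation's states.
#' @param grid a [freq_grid()].
#' @param alpha0,beta0 starting values (kept on failure).
#' @return list with `alpha`, `beta`, `converged`.
#' @export
beta_init_update <- function(gamma1, grid, alpha0 = 1, beta0 = 1) {
  cb <- pmin(pmax(grid$cuts, 0), 1)
  # states with negligible posterior weight contribute nothing to the
  # objective; restrict the integrals to the support of gamma1
  nz <- which(gamma1 > 1e-12)
  lo <- cb[nz]
  hi <- cb[nz + 1L]
  wts <- gamma1[nz]
  nll <- function(lpar) {
    m <- pbeta(hi, exp(lpar[1]), exp(lpar[2])) -
         pbeta(lo, exp(lpar[1]), exp(lpar[2]))
    -sum(wts * log(pmax(m, 1e-300)))
  }
  bounds <- log(c(1e-3, 1e3))
  start <- pmin(pmax(log(c(alpha0, beta0)), bounds[1]), bounds[2])
  opt <- tryCatch(
    optim(start, nll, method = "L-BFGS-B",
          lower = bounds[1], upper = bounds[2],
          control = list(maxit = 100, factr = 1e10)),
    error = function(e) NULL)
  if (is.null(opt))
    opt <- tryCatch(
      optim(start, function(l) nll(pmin(pmax(l, bounds[1]), bounds[2])),
            method = "Nelder-Mead", control = list(maxit = 300)),
      error = function(e) NULL)
  if (is.null(opt)) {
    warning("beta initial-distribution update failed; keeping previous values")
    return(list(alpha = alpha0, beta = beta0, converged = FALSE))
  }
  # an exact EM update must never decrease the weighted objective
  if (opt$value > nll(start))
    return(list(alpha = alpha0, beta = beta0, converged = FALSE))
  par <- pmin(pmax(exp(opt$par), 1e-3), 1e3)
  list(alpha = par[1], beta = par[2], converged = TRUE)
}

#' Fit the EM-HMM for one selection mode at one locus
#'
#' Alternates E-steps (scaled forward-backward under the discretized
#' Wright-Fisher HMM) with closed-form M-steps for the selection
#' coefficients (unconstrained or restricted to the mode's constraint
#' line) and numeric updates of the beta initial distribution.  This is a
#' hybrid EM: expectations are computed in the discretized model while the
#' M-step maximizes the continuous Gaussian path likelihood, so the
#' log-likelihood is not guaranteed to ascend monotonically.  The fit
#' therefore runs at least `min_iter` iterations and reports the maximum
#' log-likelihood observed, together with the parameters that attained it.
#'
#' @param obs a [temporal_obs()].
#' @param mode selection mode, see [selection_mode()].
#' @param Ne diploid effective population size used for the drift variance.
#' @param M number of hidden states (used when `grid` is NULL).
#' @param grid optional [freq_grid()] (overrides `M`).
#' @param tol log-likelihood convergence tolerance.
#' @param min_iter minimum EM iterations before stopping.
#' @param max_iter iteration cap; exceeding it flags `converged = FALSE`.
#' @param estimate_init estimate the beta initial distribution (`TRUE`) or
#'   keep it fixed.
#' @param alpha0,beta0 starting (or fixed) beta shape parameters; the
#'   default (1, 1) is the uniform density.
#' @param init optional explicit length-M initial mass vector; implies a
#'   fixed initial distribution.
#' @return object of class `em_fit` with elements `mode`, `s1`, `s2`, `s`
#'   (the mode's scalar coefficient), `alpha`, `beta`, `ll`, `trace`,
#'   `iterations`, `converged`, `singular`.
#' @export
run_em <- function(obs, mode, Ne, M = 500, grid = NULL, tol = 1e-3,
                   min_iter = 5, max_iter = 500, estimate_init = TRUE,
                   alpha0 = 1, beta0 = 1, init = NULL) {
  stopifnot(inherits(obs, "temporal_obs"))
  if (all(obs$n == 0)) stop("all sampling times have n = 0: nothing to fit")
  md <- selection_mode(mode)
  if (is.null(grid)) grid <- freq_grid(M)
  fixed_init <- !is.null(init) || !estimate_init
  alpha <- alpha0; beta <- beta0
  init_vec <- if (!is.null(init)) init else discretized_beta(grid, alpha, beta)

  s1 <- 0; s2 <- 0
  singular <- FALSE
  P <- transition_matrix(grid, 0, 0, Ne)

  # nothing iterates for a neutral fit with fixed initial distribution
  if (md$mode == "neutral" && fixed_init) {
    fb <- forward_backward(obs, grid, P, init_vec)
    return(structure(list(mode = md$mode, s1 = 0, s2 = 0, s = 0,
                          alpha = alpha, beta = beta, ll = fb$ll,
                          trace = fb$ll, iterations = 1L, converged = TRUE,
                          singular = FALSE),
                     class = "em_fit"))
  }

  trace <- numeric(0)
  best <- list(ll = -Inf, s1 = 0, s2 = 0, alpha = alpha, beta = beta)
  prev_ll <- NULL
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    fb <- forward_backward(obs, grid, P, init_vec)
    trace <- c(trace, fb$ll)
    if (fb$ll > best$ll)
      best <- list(ll = fb$ll, s1 = s1, s2 = s2, alpha = alpha, beta = beta)
    if (!is.finite(fb$ll)) break
    if (!is.null(prev_ll) && k >= min_iter && abs(fb$ll - prev_ll) < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- fb$ll
    if (md$mode %in% c("unconstrained", .mode_labels)) {
      ms <- if (md$mode == "unconstrained") m_step_unconstrained(fb$acc)
            else m_step_constrained(fb$acc, md$a, md$b)
      if (ms$singular) {
        singular <- TRUE            # keep the current estimate
      } else {
        s1 <- ms$s1; s2 <- ms$s2
      }
      P <- transition_matrix(grid, s1, s2, Ne)
    }
    if (!fixed_init) {
      up <- beta_init_update(fb$gamma1, grid, alpha, beta)
      alpha <- up$alpha; beta <- up$beta
      init_vec <- discretized_beta(grid, alpha, beta)
    }
  }
  structure(list(mode = md$mode, s1 = best$s1, s2 = best$s2,
                 s = md$s_of(best$s1, best$s2),
                 alpha = best$alpha, beta = best$beta, ll = best$ll,
                 trace = trace, iterations = length(trace),
                 converged = converged, singular = singular),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("EM-HMM fit [%s]: s1 = %.5g, s2 = %.5g, ll = %.4f (%d iterations%s)\n",
              x$mode, x$s1, x$s2, x$ll, x$iterations,
              if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' Fit the neutral model and all one-parameter selection modes
#'
#' Runs [run_em()] for the neutral model and the four one-parameter modes
#' (optionally also the unconstrained two-parameter model) with shared
#' settings, and summarizes log-likelihoods, likelihood-ratio statistics
#' and single-alternative p-values.
#'
#' Every alternative mode nests the neutral model, so a mode fit ending
#' below (or within optimization noise of) the neutral log-likelihood
#' can only reflect an optimizer stuck on the nuisance parameters.  Such
#' modes are refit once, warm-started at the neutral fit's estimated
#' initial distribution, and the better of the two runs is kept; this
#' resolves very small likelihood-ratio statistics instead of collapsing
#' them to zero, which matters for p-value calibration near 1.
#'
#' @inheritParams run_em
#' @param unconstrained also fit the unconstrained two-parameter model.
#' @param restart_margin log-likelihood margin below which a mode is
#'   refit from the neutral fit's nuisance parameters.
#' @param ... further arguments passed to [run_em()].
#' @return object of class `mode_fits`: list with `fits` (named list of
#'   `em_fit`) and `summary` (data.frame with one row per mode: `mode`,
#'   `s1`, `s2`, `s`, `ll`, `D`, `p`).
#' @export
fit_all_modes <- function(obs, Ne, M = 500, grid = NULL,
                          unconstrained = FALSE, restart_margin = 0.01,
                          ...) {
  if (is.null(grid)) grid <- freq_grid(M)
  modes <- c("neutral", .mode_labels, if (unconstrained) "unconstrained")
  fits <- lapply(modes, function(m) run_em(obs, m, Ne, grid = grid, ...))
  names(fits) <- modes
  ll0 <- fits$neutral$ll
  warm_args <- list(...)
  warm_args$alpha0 <- fits$neutral$alpha
  warm_args$beta0 <- fits$neutral$beta
  init0 <- discretized_beta(grid, fits$neutral$alpha, fits$neutral$beta)
  for (m in setdiff(modes, "neutral")) {
    if (fits[[m]]$ll >= ll0 + restart_margin) next
    warm <- do.call(run_em, c(list(obs = obs, mode = m, Ne = Ne,
                                   grid = grid), warm_args))
    if (warm$ll > fits[[m]]$ll) fits[[m]] <- warm
    if (m == "unconstrained" || fits[[m]]$ll >= ll0 + restart_margin) next
    # the hybrid M-step cannot resolve likelihood gains below its own
    # discretization error; a direct profile search in s along the
    # constraint line (nuisance fixed at the neutral estimates, exact
    # HMM likelihood) resolves such near-zero statistics
    md <- selection_mode(m)
    prof <- .profile_mode_ll(obs, grid, Ne, md$a, md$b, init0)
    if (prof$ll > fits[[m]]$ll) {
      fits[[m]]$s1 <- prof$s1
      fits[[m]]$s2 <- prof$s2
      fits[[m]]$s <- md$s_of(prof$s1, prof$s2)
      fits[[m]]$ll <- prof$ll
      fits[[m]]$alpha <- fits$neutral$alpha
      fits[[m]]$beta <- fits$neutral$beta
    }
  }
  summ <- data.frame(
    mode = modes,
    s1 = vapply(fits, `[[`, 0, "s1"),
    s2 = vapply(fits, `[[`, 0, "s2"),
    s  = vapply(fits, `[[`, 0, "s"),
    ll = vapply(fits, `[[`, 0, "ll"),
    row.names = NULL)
  lr <- vapply(summ$ll, function(l) lrt_pvalue(l, ll0), numeric(2))
  summ$D <- lr[1, ]
  summ$p <- lr[2, ]
  summ$D[summ$mode == "neutral"] <- NA_real_
  summ$p[summ$mode == "neutral"] <- NA_real_
  structure(list(fits = fits, summary = summ, ll0 = ll0),
            class = "mode_fits")
}

# 1-D maximization of the exact discrete-HMM log-likelihood along a
# constraint line, with a fixed initial distribution.
.profile_mode_ll <- function(obs, grid, Ne, a, b, init_vec,
                             half_width = 0.25) {
  d <- c(b, a)
  f <- function(u)
    forward_backward(obs, grid,
                     transition_matrix(grid, d[1] * u, d[2] * u, Ne),
                     init_vec)$ll
  opt <- optimize(f, c(-half_width, half_width), maximum = TRUE,
                  tol = 1e-6)
  list(s1 = d[1] * opt$maximum, s2 = d[2] * opt$maximum,
       ll = opt$objective)
}

#' @export
print.mode_fits <- function(x, ...) {
  cat("EM-HMM fits across selection modes\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
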