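#' Chebychev frequency grid for the hidden state space
#'
#' Builds the discretized allele-frequency state space used by the HMM.
#' Nodes are the Chebychev points \eqn{g_i = 1/2 - 1/2 \cos(\pi i / (M-1))}
#' (sorted ascending), which concentrate states near the boundaries 0 and 1
#' where the Wright--Fisher transition variance collapses.  Equidistant
#' grids place too few states near the boundary and bias estimates under
#' strong selection; they are supported only for comparison.
#'
#' @param M integer number of hidden states (>= 2).
#' @param type `"chebychev"` (default) or `"equidistant"`.
#' @return An object of class `freq_grid` with components
#'   \item{M}{number of states}
#'   \item{nodes}{length-M ascending vector of frequencies, 0 and 1 at the ends}
#'   \item{cuts}{length-(M+1) interval boundaries: midpoints between adjacent
#'     nodes, with sentinels `-Inf` and `Inf` so that transition mass falling
#'     outside \[0,1\] is absorbed by the boundary states}
#' @examples
#' g <- freq_grid(5)
#' g$nodes
#' @export
freq_grid <- function(M, type = c("chebychev", "equidistant")) {
  type <- match.arg(type)
  if (!is.numeric(M) || length(M) != 1L || M < 2 || M != round(M))
    stop("'M' must be an integer >= 2")
  M <- as.integer(M)
  i <- seq_len(M) - 1L
  nodes <- switch(type,
    chebychev   = 0.5 - 0.5 * cos(pi * i / (M - 1L)),
    equidistant = i / (M - 1L)
  )
  # cos() endpoints are exact only up to floating point; pin them
  nodes[1L] <- 0
  nodes[M] <- 1
  cuts <- c(-Inf, (nodes[-1L] + nodes[-M]) / 2, Inf)
  structure(list(M = M, nodes = nodes, cuts = cuts, type = type),
            class = "freq_grid")
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("Frequency grid: %d %s nodes on [0, 1]\n", x$M, x$type))
  invisible(x)
}

#' Expected next-generation allele frequency under diploid selection
#'
#' Deterministic one-generation update for a focal allele at frequency `p`
#' when genotypes AA / Aa / aa have relative fitness `1 + s2` / `1 + s1` / 1:
#' \deqn{p' = p + p(1-p)\,(s_1(1-2p) + s_2 p),}
#' valid to first order in the selection coefficients.
#'
#' @param p frequency (vector allowed), in \[0, 1\].
#' @param s1 heterozygote selection coefficient (> -1).
#' @param s2 homozygote selection coefficient (> -1).
#' @return vector of expected next-generation frequencies (not clamped;
#'   callers integrating a normal approximation rely on the boundary
#'   intervals to absorb any mass outside \[0, 1\]).
#' @export
mean_next_freq <- function(p, s1, s2) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  p + p * (1 - p) * (s1 * (1 - 2 * p) + s2 * p)
}

#' Single-generation Wright-Fisher transition matrix
#'
#' Normal approximation to the Wright--Fisher update with general diploid
#' selection: from state \eqn{g_i}, the next frequency is
#' \eqn{N(\mu_i, g_i(1-g_i)/(2 N_e))} with \eqn{\mu_i} given by
#' [mean_next_freq()], integrated analytically over each grid interval
#' (difference of normal CDFs at the interval cuts).  The outermost
#' intervals extend to \eqn{\pm\infty}, so each row sums to one exactly and
#' mass drifting outside \[0,1\] is assigned to the boundary states.  The
#' states at 0 and 1 have zero variance and are exact absorbing point
#' masses.
#'
#' @param grid a [freq_grid()].
#' @param s1,s2 diploid selection coefficients.
#' @param Ne diploid effective population size (> 0).
#' @return M x M row-stochastic matrix; entry (i, j) is the probability of
#'   moving from node i to node j in one generation.
#' @export
transition_matrix <- function(grid, s1, s2, Ne) {
  stopifnot(inherits(grid, "freq_grid"))
  if (!is.numeric(Ne) || Ne <= 0) stop("'Ne' must be positive")
  M <- grid$M
  g <- grid$nodes
  interior <- which(g > 0 & g < 1)
  mu <- mean_next_freq(g[interior], s1, s2)
  sd <- sqrt(g[interior] * (1 - g[interior]) / (2 * Ne))
  P <- .transition_core(grid$cuts, mu, sd, interior, M)
  P[1L, 1L] <- 1      # loss is absorbing
  P[M, M] <- 1        # fixation is absorbing
  P
}
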