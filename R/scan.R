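#' Per-SNP quality filters for a selection scan
#'
#' A locus enters the scan only if (1) it has data at two or more
#' timepoints, (2) more than `min_total` haplotypes are genotyped in total
#' (strict inequality; by default 50, i.e. 10% of a 504-sample cohort),
#' and (3) the pooled minor-allele frequency across all samples is
#' strictly greater than `min_maf`.
#'
#' @param obs a [temporal_obs()].
#' @param min_total total-sample threshold (strict).
#' @param min_maf pooled minor-allele-frequency threshold (strict).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed filters, empty when passing).
#' @export
snp_filters <- function(obs, min_total = 50, min_maf = 0.05) {
  reasons <- character(0)
  if (sum(obs$n > 0) < 2) reasons <- c(reasons, "timepoints")
  tot <- sum(obs$n)
  if (!(tot > min_total)) reasons <- c(reasons, "total_samples")
  maf <- if (tot > 0) min(sum(obs$a) / tot, 1 - sum(obs$a) / tot) else 0
  if (!(maf > min_maf)) reasons <- c(reasons, "maf")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Windowed p-value aggregation by Brown's method
#'
#' For each locus, sums `-log p` over the window of `window` loci centered
#' on it (the focal locus plus 25 upstream and 24 downstream for the
#' default window of 50), within chromosome.  Windows truncated at
#' chromosome ends are rescaled by `window / actual size` to keep the sums
#' comparable.  A two-parameter scaled chi-square distribution (scale `c`,
#' degrees of freedom `f`) is then fit to all sums pooled genome-wide by
#' moment matching -- `c = Var / (2 Mean)`, `f = 2 Mean^2 / Var` -- and
#' each locus's post-processed p-value is the upper tail of the fitted
#' distribution at its sum.
#'
#' @param p per-locus raw p-values in (0, 1\], ordered by genomic position
#'   within chromosome.
#' @param chrom chromosome of each locus (single chromosome assumed when
#'   NULL).
#' @param window window size in loci.
#' @return list with `post_p`, `S` (window sums), `c_hat`, `f_hat`.
#' @export
brown_window_pvalues <- function(p, chrom = NULL, window = 50) {
  if (any(p <= 0)) {
    warning("p-values of 0 clamped to smallest positive representable value")
    p[p <= 0] <- .Machine$double.xmin
  }
  if (any(p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(chrom)) chrom <- rep(1L, length(p))
  nl <- -log(p)
  up <- floor(window / 2)          # loci upstream of the focal locus
  down <- window - up - 1L         # loci downstream
  S <- numeric(length(p))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cs <- cumsum(c(0, nl[idx]))
    m <- length(idx)
    lo <- pmax(seq_len(m) - up, 1L)
    hi <- pmin(seq_len(m) + down, m)
    size <- hi - lo + 1L
    S[idx] <- (cs[hi + 1L] - cs[lo]) * (window / size)
  }
  mu <- mean(S)
  v <- var(S)
  # near-zero spread (relative to the mean) means the moment fit is
  # numerically meaningless; treat as the degenerate all-equal case
  if (!is.finite(v) || v <= 1e-12 * mu^2) {
    # all sums identical: fall back to the unscaled fit with matching mean
    c_hat <- 0.5
    f_hat <- 2 * mu
  } else {
    c_hat <- v / (2 * mu)
    f_hat <- 2 * mu^2 / v
  }
  list(post_p = pchisq(S / c_hat, df = f_hat, lower.tail = FALSE),
       S = S, c_hat = c_hat, f_hat = f_hat)
}

#' Benjamini-Hochberg step-up selection
#'
#' Standard BH procedure: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' find the largest `k` with `p_(k) <= k * alpha / m`; every locus with
#' `p <= p_(k)` is selected.
#'
#' @param p p-values.
#' @param alpha false discovery rate.
#' @return list with `threshold` (`p_(k)`, or 0 when nothing is selected)
#'   and `significant` (logical vector).
#' @export
bh_select <- function(p, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= seq_len(m) * alpha / m
  if (!any(ok)) return(list(threshold = 0, significant = rep(FALSE, m)))
  thr <- p[o][max(which(ok))]
  list(threshold = thr, significant = p <= thr)
}

#' Call candidate regions of selection from scan p-values
#'
#' Takes each contiguous block (within chromosome, in position order) of
#' loci whose post-processed p-value passes the post threshold as a
#' candidate region, and keeps regions containing at least one locus that
#' also passes the raw threshold.  The lead locus is the member with the
#' smallest raw p-value.
#'
#' @param chrom,pos per-locus chromosome and position (non-decreasing
#'   within chromosome).
#' @param raw_p,post_p per-locus raw and post-processed p-values.
#' @param raw_threshold,post_threshold significance thresholds (typically
#'   from [bh_select()] on the raw and post-processed p-values).
#' @param id optional locus identifiers.
#' @return data.frame with one row per region: `chrom`, `start`, `end`
#'   (1-based inclusive positions), `n_loci`, `n_raw_sig`, `n_post_sig`,
#'   `lead_id`, `lead_pos`, `lead_p`.
#' @export
call_regions <- function(chrom, pos, raw_p, post_p,
                         raw_threshold, post_threshold, id = NULL) {
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    sig <- post_p[idx] <= post_threshold
    if (!any(sig)) next
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (b in which(r$values)) {
      mem <- idx[starts[b]:ends[b]]
      raw_sig <- raw_p[mem] <= raw_threshold
      if (!any(raw_sig)) next
      lead <- mem[which.min(raw_p[mem])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(pos[mem]), end = max(pos[mem]),
        n_loci = length(mem), n_raw_sig = sum(raw_sig),
        n_post_sig = length(mem), lead_id = id[lead],
        lead_pos = pos[lead], lead_p = raw_p[lead])
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_loci = integer(0),
                      n_raw_sig = integer(0), n_post_sig = integer(0),
                      lead_id = character(0), lead_pos = numeric(0),
                      lead_p = numeric(0)))
  do.call(rbind, out)
}

#' Parametric-bootstrap confidence interval for a lead SNP's coefficient
#'
#' Simulates `reps` replicates matching the lead locus's sampling scheme,
#' fitted initial frequency and fitted selection coefficient at the given
#' `Ne`, refits the same mode to each, bias-corrects the bootstrap
#' estimates by subtracting the mean bootstrap bias, and returns the 2.5%
#' and 97.5% quantiles.
#'
#' @param fit an `em_fit` for the lead locus.
#' @param obs the lead locus's [temporal_obs()] (defines the scheme).
#' @param Ne effective population size.
#' @param reps bootstrap replicates (>= 100).
#' @param M hidden states for the refits.
#' @param seed optional integer seed.
#' @param ... passed to [run_em()] for the refits.
#' @return list with `lower`, `upper`, `estimates` (bias-corrected
#'   bootstrap coefficients), `failures`.
#' @export
bootstrap_ci <- function(fit, obs, Ne, reps = 1000, M = 500, seed = NULL,
                         ...) {
  stopifnot(inherits(fit, "em_fit"), reps >= 100)
  if (!is.null(seed)) set.seed(seed)
  grid <- freq_grid(M)
  p0 <- fit$alpha / (fit$alpha + fit$beta)
  shat <- numeric(0)
  failures <- 0L
  for (r in seq_len(reps)) {
    traj <- simulate_trajectory(obs$T_gen, fit$s1, fit$s2, Ne, p0)
    ob <- sample_observations(traj, obs$times, obs$n)
    f <- tryCatch(run_em(ob, fit$mode, Ne, grid = grid, ...),
                  error = function(e) NULL)
    if (is.null(f) || !is.finite(f$ll)) failures <- failures + 1L
    else shat <- c(shat, f$s)
  }
  if (failures > 0.1 * reps)
    stop("more than 10% of bootstrap refits failed")
  corrected <- shat - (mean(shat) - fit$s)
  ci <- unname(quantile(corrected, c(0.025, 0.975)))
  list(lower = ci[1], upper = ci[2], estimates = corrected,
       failures = failures)
}
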