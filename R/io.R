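#' Bin sample dates into generations
#'
#' Converts dates (years before present) to 1-based generations, anchored
#' so that the oldest sample falls in generation 1.
#'
#' @param dates_bp numeric dates in years before present (>= 0).
#' @param generation_time years per generation.
#' @return integer generations.
#' @export
bin_dates_to_generations <- function(dates_bp, generation_time) {
  if (any(is.na(dates_bp))) stop("missing sample dates")
  if (any(dates_bp < 0)) stop("dates must be nonnegative (years BP)")
  as.integer(floor((max(dates_bp) - dates_bp) / generation_time)) + 1L
}

#' Write a multi-locus counts table
#'
#' Tab-separated, UTF-8, one row per locus with columns `id`, `chrom`,
#' `pos` followed by paired columns `n@g` / `a@g` for every sampling
#' generation `g` declared in the '#'-prefixed header.  Loci without data
#' at a generation carry `n = 0, a = 0`.
#'
#' @param obs_list list of [temporal_obs()] or a `replicate_set`.
#' @param path output file.
#' @param chrom,pos optional per-locus coordinates (default chromosome
#'   `"1"` and the locus index).
#' @param id optional per-locus identifiers.
#' @return `path`, invisibly.
#' @export
write_counts <- function(obs_list, path, chrom = NULL, pos = NULL, id = NULL) {
  if (inherits(obs_list, "replicate_set")) obs_list <- obs_list$obs
  L <- length(obs_list)
  gens <- sort(unique(unlist(lapply(obs_list, `[[`, "times"))))
  if (is.null(id))
    id <- vapply(seq_len(L), function(i)
      if (!is.null(obs_list[[i]]$id)) as.character(obs_list[[i]]$id)
      else sprintf("locus%04d", i), "")
  if (is.null(chrom)) chrom <- rep("1", L)
  if (is.null(pos)) pos <- seq_len(L)
  mat <- matrix(0L, L, 2L * length(gens))
  for (i in seq_len(L)) {
    ob <- obs_list[[i]]
    j <- match(ob$times, gens)
    mat[i, 2L * j - 1L] <- ob$n
    mat[i, 2L * j] <- ob$a
  }
  header <- paste(c("#id", "chrom", "pos",
                    as.vector(rbind(paste0("n@", gens), paste0("a@", gens)))),
                  collapse = "\t")
  rows <- paste(id, chrom, pos, apply(mat, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a multi-locus counts table
#'
#' Parses the format written by [write_counts()] and validates it: the
#' header must declare at least one strictly increasing generation, and
#' every cell must satisfy `a <= n`.
#'
#' @param path input file.
#' @param T_gen total generations spanned (default: the last declared
#'   generation).
#' @return list of [temporal_obs()], each carrying `id`, `chrom`, `pos`;
#'   locus order preserved.
#' @export
read_counts <- function(path, T_gen = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 1L || !startsWith(lines[1L], "#"))
    stop("missing '#'-prefixed header line")
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 5L)
    stop("header declares no sampling generations")
  pair_cols <- header[-(1:3)]
  ncols <- length(pair_cols)
  if (ncols %% 2L != 0L) stop("unpaired n@/a@ columns in header")
  gens <- as.integer(sub("^n@", "", pair_cols[seq(1L, ncols, by = 2L)]))
  gens_a <- as.integer(sub("^a@", "", pair_cols[seq(2L, ncols, by = 2L)]))
  if (any(is.na(gens)) || any(gens != gens_a))
    stop("header n@/a@ generation pairs do not match")
  if (is.unsorted(gens, strictly = TRUE))
    stop("generations in header must be strictly increasing")
  if (is.null(T_gen)) T_gen <- max(gens)

  body <- lines[-1L]
  body <- body[nzchar(body)]
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L + ncols)
      stop(sprintf("row %d: expected %d fields, found %d", i, 3L + ncols,
                   length(f)))
    counts <- as.integer(f[-(1:3)])
    n <- counts[seq(1L, ncols, by = 2L)]
    a <- counts[seq(2L, ncols, by = 2L)]
    if (any(a > n))
      stop(sprintf("row %d (%s): focal count exceeds sample size", i, f[1L]))
    keep <- n > 0L | a > 0L
    if (!any(keep)) keep[1L] <- TRUE    # all-missing locus kept as n = 0
    ob <- temporal_obs(gens[keep], n[keep], a[keep], T_gen = T_gen,
                       id = f[1L])
    ob$chrom <- f[2L]
    ob$pos <- as.numeric(f[3L])
    out[[i]] <- ob
  }
  out
}

#' Convert VCF genotypes plus sample dates to a counts table
#'
#' Bins samples into generations ([bin_dates_to_generations()]) and counts
#' focal (ALT by default) alleles per generation at every biallelic site.
#' Pseudo-haploid samples (ploidy 1 in the metadata) contribute one
#' haplotype per called site; diploid samples contribute two.  Missing
#' calls contribute nothing.  Sites with more than one ALT allele are
#' skipped and counted.
#'
#' @param vcf_path path to an (uncompressed or gzipped) VCF file.
#' @param metadata data.frame with columns `sample`, `date_bp`, `ploidy`
#'   (1 = pseudo-haploid, 2 = diploid); must cover every VCF sample.
#' @param generation_time years per generation.
#' @param focal `"alt"` (default) or `"ref"`.
#' @return list with `obs` (list of [temporal_obs()] carrying `chrom` and
#'   `pos`), `generations`, `skipped_multiallelic`.
#' @export
vcf_to_counts <- function(vcf_path, metadata, generation_time = 28.1,
                          focal = c("alt", "ref")) {
  focal <- match.arg(focal)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  need <- c("sample", "date_bp", "ploidy")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns sample, date_bp, ploidy")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  mi <- match(samples, metadata$sample)
  if (any(is.na(mi))) stop("metadata does not cover all VCF samples")
  if (any(is.na(metadata$date_bp[mi]))) stop("missing sample dates")
  gen <- bin_dates_to_generations(metadata$date_bp[mi], generation_time)
  ploidy <- metadata$ploidy[mi]
  gens <- sort(unique(gen))

  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  skipped <- sum(multi)
  keep <- which(!multi)

  obs <- vector("list", length(keep))
  for (r in seq_along(keep)) {
    row <- gt[keep[r], ]
    n <- integer(length(gens))
    a <- integer(length(gens))
    for (s in seq_along(row)) {
      call <- row[s]
      if (is.na(call) || call %in% c(".", "./.", ".|.")) next
      alleles <- strsplit(call, "[/|]")[[1L]]
      alleles <- alleles[alleles != "."]
      if (length(alleles) == 0L) next
      if (ploidy[s] == 1L) alleles <- alleles[1L]
      gi <- match(gen[s], gens)
      n[gi] <- n[gi] + length(alleles)
      cnt <- sum(alleles == "1")
      a[gi] <- a[gi] + if (focal == "alt") cnt else length(alleles) - cnt
    }
    has <- n > 0L
    ob <- temporal_obs(gens[has], n[has], a[has], T_gen = max(gens),
                       id = if (!is.na(fix[keep[r], "ID"])) fix[keep[r], "ID"]
                            else paste0(fix[keep[r], "CHROM"], ":",
                                        fix[keep[r], "POS"]))
    ob$chrom <- fix[keep[r], "CHROM"]
    ob$pos <- as.numeric(fix[keep[r], "POS"])
    obs[[r]] <- ob
  }
  list(obs = obs, generations = gens, skipped_multiallelic = skipped)
}

#' Horse coat-color (ASIP) ancient-DNA allele counts
#'
#' Loads the classic temporal allele-count series for the ASIP
#' coat-coloration locus in domesticated horses (Ludwig et al. 2009,
#' Science 324:485), 146 haplotypes sampled at six times spanning roughly
#' 20,000 years, binned into generations at the given generation time.
#'
#' @param generation_time years per generation (default 8).
#' @return a [temporal_obs()].
#' @export
asip_counts <- function(generation_time = 8) {
  path <- system.file("extdata", "asip_horse.tsv", package = "selhmm")
  d <- read.delim(path, comment.char = "#")
  gen <- bin_dates_to_generations(d$years_bp, generation_time)
  o <- order(gen)
  temporal_obs(gen[o], d$n[o], d$a[o], id = "ASIP")
}

#' Post-process a table of per-locus scan p-values
#'
#' Applies windowed aggregation ([brown_window_pvalues()]) and
#' Benjamini-Hochberg thresholds to raw per-locus p-values, and calls
#' candidate regions ([call_regions()]).
#'
#' @param records data.frame with columns `chrom`, `pos`, `p` and
#'   optionally `id`, ordered by position within chromosome.
#' @param window Brown window size in loci.
#' @param alpha FDR level for both BH passes.
#' @return list with `records` (input plus `post_p`, `raw_sig`,
#'   `post_sig`), `raw_threshold`, `post_threshold`, `regions`, `c_hat`,
#'   `f_hat`.
#' @export
scan_postprocess <- function(records, window = 50, alpha = 0.05) {
  stopifnot(all(c("chrom", "pos", "p") %in% names(records)))
  if (is.null(records$id)) records$id <- paste0(records$chrom, ":", records$pos)
  bw <- brown_window_pvalues(records$p, records$chrom, window = window)
  records$post_p <- bw$post_p
  raw <- bh_select(records$p, alpha)
  post <- bh_select(records$post_p, alpha)
  records$raw_sig <- raw$significant
  records$post_sig <- post$significant
  regions <- call_regions(records$chrom, records$pos, records$p,
                          records$post_p, raw$threshold, post$threshold,
                          id = records$id)
  list(records = records, raw_threshold = raw$threshold,
       post_threshold = post$threshold, regions = regions,
       c_hat = bw$c_hat, f_hat = bw$f_hat)
}
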