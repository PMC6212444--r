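#' Per-site nucleotide diversity
#'
#' Unbiased mean pairwise difference at a biallelic site:
#' `c_ref * c_alt / choose(n, 2)` with `n = c_ref + c_alt` called
#' chromosomes. Vectorised.
#'
#' @param c_ref,c_alt allele-copy counts.
#' @return per-site pi; `NA` where fewer than 2 chromosomes are called.
#' @examples
#' site_pi(2, 2)  # 4 concordant of 6 pairs differ -> 2/3
#' @export
site_pi <- function(c_ref, c_alt) {
  n <- c_ref + c_alt
  ifelse(n >= 2, c_ref * c_alt / choose(n, 2), NA_real_)
}

#' Windowed nucleotide diversity in SNP-count windows
#'
#' Sums per-site pi of one population over consecutive non-overlapping
#' windows of `window_snps` SNPs per arm (the trailing window may be
#' partial and is flagged). Reports both per-bp pi (summed pi over the
#' window's genomic span) and per-SNP pi.
#'
#' @param x a filtered [genotype_matrix()] (diploid or pseudo-haploid).
#' @param population population label(s) to compute within.
#' @param window_snps SNPs per window.
#' @return data.frame: `arm`, `start`, `end`, `n_snps`, `pi_sum`,
#'   `span_bp`, `pi_per_bp`, `pi_per_snp`, `partial`.
#' @export
windowed_pi <- function(x, population, window_snps = 10000L) {
  stopifnot(inherits(x, "genotype_matrix"), window_snps >= 1)
  s <- pop_site_summary(x, population)
  pi <- site_pi(s$c_ref, s$c_alt)
  out <- list()
  for (arm in unique(x$sites$arm)) {
    idx <- which(x$sites$arm == arm & !is.na(pi))
    if (!length(idx)) next
    win <- (seq_along(idx) - 1L) %/% window_snps
    for (w in unique(win)) {
      ii <- idx[win == w]
      first <- x$sites$pos[ii[1]]
      last <- x$sites$pos[ii[length(ii)]]
      span <- last - first + 1L
      out[[length(out) + 1L]] <- data.frame(
        arm = arm, start = first, end = last, n_snps = length(ii),
        pi_sum = sum(pi[ii]), span_bp = span,
        pi_per_bp = sum(pi[ii]) / span,
        pi_per_snp = mean(pi[ii]),
        partial = length(ii) < window_snps,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(arm = character(), start = integer(), end = integer(),
                      n_snps = integer(), pi_sum = numeric(),
                      span_bp = integer(), pi_per_bp = numeric(),
                      pi_per_snp = numeric(), partial = logical()))
  }
  do.call(rbind, out)
}

#' Pseudo-haploid one-allele sampling
#'
#' Because each isofemale strain may effectively contribute more or fewer
#' than two alleles per locus, diversity can be re-estimated after sampling
#' exactly one allele per strain per site, drawn with probability
#' proportional to the allelic read depths (AD). Calls with a genotype but
#' no usable depth information (DP = 0 or AD unknown) fall back to a
#' uniform draw from the two genotype alleles; their count is reported.
#'
#' @param x a diploid [genotype_matrix()].
#' @param seed integer seed making the draw reproducible.
#' @return A ploidy-1 [genotype_matrix()] (sampled allele in `a1` and
#'   `a2`), with attribute `n_uniform_fallback`.
#' @export
pseudo_haploid_sample <- function(x, seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"), x$ploidy == 2L)
  set.seed(seed)
  called <- !is.na(x$a1) & !is.na(x$a2)
  dp_known <- !is.na(x$ad_ref) & !is.na(x$ad_alt) &
    (x$ad_ref + x$ad_alt) > 0
  use_ad <- called & dp_known
  fallback <- called & !dp_known
  p_alt <- matrix(NA_real_, nrow(x$a1), ncol(x$a1))
  p_alt[use_ad] <- x$ad_alt[use_ad] / (x$ad_ref[use_ad] + x$ad_alt[use_ad])
  # uniform over the two genotype alleles when depths are unusable
  p_alt[fallback] <- (x$a1[fallback] + x$a2[fallback]) / 2
  draw <- matrix(NA_integer_, nrow(x$a1), ncol(x$a1))
  draw[called] <- rbinom(sum(called), 1L, p_alt[called])
  out <- x
  out$a1 <- draw
  out$a2 <- draw
  out$ploidy <- 1L
  attr(out, "n_uniform_fallback") <- sum(fallback)
  out
}

#' Global weighted Weir & Cockerham F_ST between two populations
#'
#' Ratio of summed variance components over all usable sites,
#' `sum(a) / sum(a + b + c)` (not the mean of per-site ratios).
#'
#' @param x a filtered [genotype_matrix()].
#' @param pop_a,pop_b population labels.
#' @return list with `theta` (the global weighted estimate), `n_sites`
#'   (usable sites) and the summed components.
#' @export
global_fst <- function(x, pop_a = NULL, pop_b = NULL) {
  ss <- fst_scan(x, pop_a, pop_b)
  u <- ss$usable
  if (!any(u)) stop("no usable site for the global F_ST")
  list(theta = sum(ss$a[u]) / sum(ss$a[u] + ss$b[u] + ss$c[u]),
       n_sites = sum(u),
       sum_a = sum(ss$a[u]), sum_abc = sum(ss$a[u] + ss$b[u] + ss$c[u]))
}
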