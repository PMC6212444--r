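#' Weir & Cockerham (1984) variance components for one or more biallelic sites
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the two-population
#' diploid estimator, and the per-site estimate theta = a / (a + b + c).
#' All arguments are vectorised over sites.
#'
#' With r = 2 populations, n_i called individuals, p_i alternate-allele
#' frequency and h_i observed heterozygote fraction in population i:
#' nbar = (n1+n2)/2, n_c = (r*nbar - sum(n_i^2)/(r*nbar))/(r-1),
#' pbar = sum(n_i p_i)/(r*nbar), s2 = sum(n_i (p_i - pbar)^2)/((r-1)*nbar),
#' hbar = sum(n_i h_i)/(r*nbar), and
#' a = (nbar/n_c) * (s2 - (pbar(1-pbar) - s2*(r-1)/r - hbar/4)/(nbar-1)),
#' b = (nbar/(nbar-1)) * (pbar(1-pbar) - s2*(r-1)/r - hbar*(2*nbar-1)/(4*nbar)),
#' c = hbar/2.
#'
#' A site is flagged unusable when either population has no called
#' individual, when nbar <= 1, or when a + b + c <= 0 (theta undefined,
#' e.g. a site monomorphic in both populations).
#'
#' @param n1,n2 called individuals per population.
#' @param p1,p2 alternate-allele sample frequencies.
#' @param h1,h2 observed heterozygote fractions.
#' @return data.frame with columns `a`, `b`, `c`, `theta`, `usable` and the
#'   intermediates `nbar`, `nc`, `pbar`, `s2`, `hbar`.
#' @export
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  usable <- is.finite(denom) & denom > 0 & n1 > 0 & n2 > 0 & nbar > 1
  theta <- ifelse(usable, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta, usable = usable,
             nbar = nbar, nc = nc, pbar = pbar, s2 = s2, hbar = hbar)
}

#' Site F_ST from genotype counts
#'
#' Convenience front end to [wc_components()] taking per-population genotype
#' counts `(hom-ref, het, hom-alt)` for a biallelic site, as a length-3
#' vector or a sites x 3 matrix.
#'
#' @param counts1,counts2 genotype counts for population 1 / 2.
#' @return As [wc_components()].
#' @examples
#' # two populations fixed for different alleles: theta = 1
#' site_fst_wc(c(10, 0, 0), c(0, 0, 10))$theta
#' @export
site_fst_wc <- function(counts1, counts2) {
  as_m <- function(x) {
    if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
    stopifnot(ncol(x) == 3)
    x
  }
  g1 <- as_m(counts1); g2 <- as_m(counts2)
  n1 <- rowSums(g1); n2 <- rowSums(g2)
  p1 <- ifelse(n1 > 0, (g1[, 2] + 2 * g1[, 3]) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, (g2[, 2] + 2 * g2[, 3]) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, g1[, 2] / n1, NA_real_)
  h2 <- ifelse(n2 > 0, g2[, 2] / n2, NA_real_)
  wc_components(n1, p1, h1, n2, p2, h2)
}

#' Per-site F_ST scan over a filtered cohort
#'
#' Computes the Weir & Cockerham components and theta at every site for the
#' contrast between two population labels, together with the pooled minor
#' allele frequency. Sites where theta is undefined are retained with
#' `usable = FALSE` and a `reason` string.
#'
#' @param x a filtered [genotype_matrix()].
#' @param pop_a,pop_b the two population labels (defaults: the first two
#'   labels present, in order of appearance).
#' @param inversion optional `list(arm, start, end)`; fills the
#'   `inside_inversion` flag.
#' @return data.frame (one row per site): `arm`, `pos`, `ref`, `alt`,
#'   `maf`, `a`, `b`, `c`, `theta`, `usable`, `reason`, `inside_inversion`.
#' @export
fst_scan <- function(x, pop_a = NULL, pop_b = NULL, inversion = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  labs <- unique(x$strains$population)
  pop_a <- pop_a %||% labs[1]
  pop_b <- pop_b %||% labs[2]
  s1 <- pop_site_summary(x, pop_a)
  s2 <- pop_site_summary(x, pop_b)
  comp <- wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
  p_pool <- (s1$c_alt + s2$c_alt) / pmax(s1$n_chrom + s2$n_chrom, 1)
  maf <- pmin(p_pool, 1 - p_pool)
  reason <- rep(NA_character_, nrow(comp))
  reason[s1$n == 0 | s2$n == 0] <- "population fully missing"
  mono <- s1$n > 0 & s2$n > 0 & !comp$usable
  reason[mono] <- "a+b+c <= 0 (no variance)"
  out <- data.frame(
    arm = x$sites$arm, pos = x$sites$pos,
    ref = x$sites$ref, alt = x$sites$alt,
    maf = maf,
    a = comp$a, b = comp$b, c = comp$c,
    theta = comp$theta, usable = comp$usable, reason = reason,
    stringsAsFactors = FALSE
  )
  out$inside_inversion <- FALSE
  if (!is.null(inversion)) {
    out$inside_inversion <- out$arm == inversion$arm &
      out$pos >= inversion$start & out$pos <= inversion$end
  }
  out
}

#' Per-arm empirical outlier thresholds and tier assignment
#'
#' Ranks usable sites by theta within each chromosome arm and marks, for
#' each tail size t, the top `floor(t * n_arm)` sites as tier-t outliers.
#' Ties in theta are broken by genomic position (the earlier position
#' ranks higher). The critical value of a tier is the smallest theta inside
#' it; tiers nest by construction.
#'
#' @param site_stats output of [fst_scan()] (or any data.frame with `arm`,
#'   `pos`, `theta`, `usable`).
#' @param tails decreasing tail sizes; default top 5%, 1% and 0.5%.
#' @return list with `thresholds` (data.frame: `arm`, `tail`, `n_tier`,
#'   `critical`) and `tier` (character vector aligned with `site_stats`
#'   rows: the smallest tail the site belongs to, or `"none"`).
#' @export
arm_thresholds <- function(site_stats, tails = c(0.05, 0.01, 0.005)) {
  stopifnot(all(tails > 0), all(tails < 1))
  tails <- sort(tails, decreasing = TRUE)
  tier <- rep("none", nrow(site_stats))
  thr <- list()
  for (arm in unique(site_stats$arm)) {
    idx <- which(site_stats$arm == arm & site_stats$usable)
    n_arm <- length(idx)
    if (n_arm < 1 / min(tails)) {
      warning("arm ", arm, " has too few usable sites (", n_arm,
              ") for tail ", min(tails), "; skipped")
      next
    }
    ord <- idx[order(-site_stats$theta[idx], site_stats$pos[idx])]
    for (t in tails) {
      k <- floor(t * n_arm)
      if (k < 1) next
      sel <- ord[seq_len(k)]
      tier[sel] <- tier_label(t)
      thr[[length(thr) + 1L]] <- data.frame(
        arm = arm, tail = t, n_tier = k,
        critical = site_stats$theta[sel[k]], stringsAsFactors = FALSE
      )
    }
  }
  list(thresholds = do.call(rbind, thr), tier = tier)
}

#' Is a site in a given tail tier (nested membership)
#'
#' Tier labels produced by [arm_thresholds()] are nested: a site in the
#' top-0.5% tier is also in the top-1% and top-5% tiers.
#'
#' @param tier character vector of tier labels.
#' @param tail tail size to test membership for.
#' @param tails the tail set used when assigning tiers.
#' @return logical vector.
#' @export
in_tier <- function(tier, tail, tails = c(0.05, 0.01, 0.005)) {
  tails <- sort(tails, decreasing = TRUE)
  keep <- vapply(tails[tails <= tail], tier_label, "")
  tier %in% keep
}

# "top5", "top1", "top0.5", ... (percentage labels)
tier_label <- function(t) {
  paste0("top", format(100 * t, trim = TRUE, drop0trailing = TRUE))
}

#' One-way ANOVA of F_ST heterogeneity across chromosome arms
#'
#' @param site_stats output of [fst_scan()]; only usable sites enter.
#' @return list with `F`, `p`, `df` and the fitted ANOVA table.
#' @export
arm_heterogeneity_anova <- function(site_stats) {
  d <- site_stats[site_stats$usable, c("arm", "theta")]
  if (length(unique(d$arm)) < 2) stop("need >= 2 arms")
  if (min(table(d$arm)) < 2) stop("need >= 2 sites per arm")
  if (var(d$theta) == 0) {
    return(list(F = NA_real_, p = NA_real_, df = NULL,
                note = "zero total variance: F undefined"))
  }
  tab <- anova(lm(theta ~ arm, data = d))
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = tab$Df, table = tab)
}

#' Inversion versus rest-of-arm F_ST contrast
#'
#' Compares theta of usable sites inside a chromosomal inversion with sites
#' on the same arm outside it: group medians, a two-sided Mann-Whitney U
#' test (exact for small samples without ties, normal approximation with tie
#' correction otherwise), and per-tier inside/outside 2x2 contingency
#' tables suitable for Fisher tests of candidate-SNP accumulation.
#'
#' @param site_stats output of [fst_scan()] with tiers assigned (a `tier`
#'   column, e.g. `arm_thresholds(ss)$tier`).
#' @param region `list(arm, start, end)`, 1-based inclusive.
#' @param tails tail sizes matching the tier labels.
#' @return list with `median_inside`, `median_outside`, `p`, `statistic`,
#'   `n_inside`, `n_outside` and `tier_tables` (named list of 2x2 matrices).
#' @export
inversion_contrast <- function(site_stats, region,
                               tails = c(0.05, 0.01, 0.005)) {
  on_arm <- site_stats$arm == region$arm & site_stats$usable
  if (!any(on_arm)) stop("no usable sites on arm ", region$arm)
  inside <- on_arm & site_stats$pos >= region$start & site_stats$pos <= region$end
  outside <- on_arm & !inside
  if (!any(outside)) stop("region covers the whole arm: no outside group")
  if (!any(inside)) stop("no usable sites inside the region")
  wt <- wilcox.test(site_stats$theta[inside], site_stats$theta[outside],
                    alternative = "two.sided")
  tier_tables <- NULL
  if (!is.null(site_stats$tier)) {
    tier_tables <- lapply(tails, function(t) {
      hit <- in_tier(site_stats$tier, t, tails)
      m <- matrix(c(sum(inside & hit), sum(inside & !hit),
                    sum(outside & hit), sum(outside & !hit)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("inside", "outside"),
                                  c("candidate", "non_candidate")))
      m
    })
    names(tier_tables) <- paste0("tail_", tails)
  }
  list(
    median_inside = median(site_stats$theta[inside]),
    median_outside = median(site_stats$theta[outside]),
    p = wt$p.value, statistic = unname(wt$statistic),
    n_inside = sum(inside), n_outside = sum(outside),
    tier_tables = tier_tables
  )
}

#' Inversion frequency from marker SNPs
#'
#' Estimates the population frequency of a chromosomal inversion as the mean
#' across marker SNPs of the inversion-tagging allele's sample frequency.
#'
#' @param x a [genotype_matrix()].
#' @param marker_panel data.frame with columns `arm`, `pos` and
#'   `tag_allele` (`"ref"` or `"alt"`).
#' @param populations population labels to estimate for (default: all).
#' @return list with `frequency` (named per population) and `per_marker`
#'   (data.frame of per-marker tagging-allele frequencies).
#' @export
inversion_frequency <- function(x, marker_panel, populations = NULL) {
  stopifnot(all(c("arm", "pos", "tag_allele") %in% names(marker_panel)))
  populations <- populations %||% unique(x$strains$population)
  key <- site_key(x$sites)
  mk <- match(paste(marker_panel$arm, marker_panel$pos, sep = ":"), key)
  found <- !is.na(mk)
  if (!any(found)) {
    warning("no marker SNP genotyped in the matrix; frequency undefined")
    return(list(frequency = setNames(rep(NA_real_, length(populations)),
                                     populations),
                per_marker = NULL))
  }
  per <- lapply(populations, function(pop) {
    s <- pop_site_summary(x, pop)[mk[found], ]
    p_alt <- s$p
    f <- ifelse(marker_panel$tag_allele[found] == "alt", p_alt, 1 - p_alt)
    data.frame(population = pop,
               arm = marker_panel$arm[found], pos = marker_panel$pos[found],
               tag_freq = f, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  freq <- vapply(populations, function(pop) {
    mean(per$tag_freq[per$population == pop], na.rm = TRUE)
  }, 0)
  list(frequency = freq, per_marker = per)
}
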