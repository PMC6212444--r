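#' Per-strain maximum-coverage threshold
#'
#' Nearest-rank empirical quantile of the per-call read depth of one strain:
#' the default 0.975 quantile is the per-strain cap above which calls are
#' treated as suspect (collapsed repeats, CNVs).
#'
#' @param x a [genotype_matrix()].
#' @param strain strain id.
#' @param q quantile in (0, 1].
#' @return the threshold (a depth value observed for that strain).
#' @export
compute_coverage_threshold <- function(x, strain, q = 0.975) {
  stopifnot(inherits(x, "genotype_matrix"), q > 0, q <= 1)
  j <- match(strain, x$strains$id)
  if (is.na(j)) stop("unknown strain: ", strain)
  dp <- x$dp[, j]
  dp <- dp[!is.na(dp)]
  if (!length(dp)) stop("strain ", strain, " has no DP data")
  sort(dp)[ceiling(q * length(dp))]
}

#' Genotype-level coverage QC
#'
#' Sets individual calls to missing when DP < `min_dp` or DP exceeds the
#' strain's maximum-coverage threshold (equality is kept on both bounds'
#' reading: DP = `min_dp` is retained, DP = threshold is retained).
#' Calls with unknown DP are left untouched.
#'
#' @param x a [genotype_matrix()].
#' @param min_dp minimum depth (calls with DP strictly lower are dropped).
#' @param max_dp named vector of per-strain maximum thresholds; by default
#'   computed with [compute_coverage_threshold()] at `q`.
#' @param q quantile used when `max_dp` is NULL.
#' @return The matrix with failing calls set to missing.
#' @export
apply_genotype_qc <- function(x, min_dp = 10, max_dp = NULL, q = 0.975) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(max_dp)) {
    max_dp <- vapply(x$strains$id, function(s)
      compute_coverage_threshold(x, s, q), 0)
  }
  missing <- setdiff(x$strains$id, names(max_dp))
  if (length(missing)) stop("no max-depth threshold for: ",
                            paste(missing, collapse = ", "))
  cap <- matrix(max_dp[x$strains$id], nrow(x$dp), ncol(x$dp), byrow = TRUE)
  bad <- !is.na(x$dp) & (x$dp < min_dp | x$dp > cap)
  x$a1[bad] <- NA_integer_
  x$a2[bad] <- NA_integer_
  x
}

#' Site- and genotype-level filtering pipeline
#'
#' Applies, in order: euchromatin inclusion, repeat-mask exclusion,
#' indel-proximity exclusion (distance <= `indel_flank` bp from an indel's
#' affected span), biallelic-SNV restriction, non-singleton restriction
#' (minor allele observed in more than one allele copy), genotype coverage
#' QC ([apply_genotype_qc()]), call-rate >= `call_rate_min`, and pooled
#' minor allele frequency >= `maf_min` (computed over all strains of the
#' focal populations; missing calls excluded from numerator and
#' denominator). A site count log is kept per stage.
#'
#' @param x a [genotype_matrix()].
#' @param masks a `scan_masks` object ([load_masks()] / [scan_masks()]).
#' @param maf_min pooled MAF cutoff (a site at exactly `maf_min` is kept).
#' @param call_rate_min genotyping-rate cutoff (kept at equality).
#' @param min_dp,max_dp,q genotype QC parameters (see [apply_genotype_qc()]).
#' @param indel_flank exclusion distance around indels, bp.
#' @param maf_scope `"pooled"` (default): MAF over both focal populations
#'   combined; `"per_population"`: keep sites whose MAF reaches `maf_min`
#'   in at least one focal population.
#' @return list with `matrix` (filtered [genotype_matrix()]) and `log`
#'   (data.frame `stage`, `n_in`, `n_out`).
#' @export
apply_site_filters <- function(x, masks, maf_min = 0.05,
                               call_rate_min = 0.70, min_dp = 10,
                               max_dp = NULL, q = 0.975, indel_flank = 5L,
                               maf_scope = c("pooled", "per_population")) {
  maf_scope <- match.arg(maf_scope)
  stopifnot(inherits(x, "genotype_matrix"), inherits(masks, "scan_masks"))
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)
  }
  keep_sites <- function(x, keep, stage) {
    note(stage, nrow(x$sites), sum(keep))
    subset_matrix(x, sites = keep)
  }

  x <- keep_sites(x, sites_in_ranges(x$sites$arm, x$sites$pos,
                                     masks$euchromatin), "euchromatin")
  x <- keep_sites(x, !sites_in_ranges(x$sites$arm, x$sites$pos,
                                      masks$repeats), "repeat_mask")
  ind <- masks$indels
  if (!is.null(ind) && nrow(ind)) {
    flank <- data.frame(arm = ind$arm, start = ind$start - indel_flank,
                        end = ind$end + indel_flank)
    x <- keep_sites(x, !sites_in_ranges(x$sites$arm, x$sites$pos, flank),
                    "indel_proximity")
  } else {
    note("indel_proximity", nrow(x$sites), nrow(x$sites))
  }
  snv <- !x$sites$multiallelic & nchar(x$sites$ref) == 1L &
    nchar(x$sites$alt) == 1L & x$sites$alt %in% c("A", "C", "G", "T")
  x <- keep_sites(x, snv, "biallelic_snv")

  mac <- minor_allele_count(x)
  x <- keep_sites(x, mac$minor_copies != 1L, "non_singleton")

  n0 <- nrow(x$sites)
  x <- apply_genotype_qc(x, min_dp = min_dp, max_dp = max_dp, q = q)
  note("genotype_qc", n0, n0)

  called <- !is.na(x$a1) & !is.na(x$a2)
  rate <- rowSums(called) / ncol(called)
  x <- keep_sites(x, rate >= call_rate_min, "call_rate")

  if (maf_scope == "pooled") {
    mac <- minor_allele_count(x)
    x <- keep_sites(x, !is.na(mac$maf) & mac$maf >= maf_min, "pooled_maf")
  } else {
    pops <- unique(x$strains$population)
    maf_pop <- vapply(pops, function(p) {
      s <- pop_site_summary(x, p)
      pmin(s$p, 1 - s$p)
    }, numeric(nrow(x$sites)))
    best <- suppressWarnings(apply(rbind(maf_pop), 1, max, na.rm = TRUE))
    x <- keep_sites(x, is.finite(best) & best >= maf_min,
                    "per_population_maf")
  }

  list(matrix = x, log = do.call(rbind, log))
}

# pooled minor-allele copy count and frequency over all strains
minor_allele_count <- function(x) {
  called <- !is.na(x$a1) & !is.na(x$a2)
  alt <- rowSums((x$a1 == 1L) * called, na.rm = TRUE) +
    rowSums((x$a2 == 1L) * called, na.rm = TRUE)
  tot <- 2L * rowSums(called)
  p <- ifelse(tot > 0, alt / tot, NA_real_)
  list(minor_copies = pmin(alt, tot - alt), maf = pmin(p, 1 - p))
}
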