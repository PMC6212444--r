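#' Genotype matrix container
#'
#' Holds a two-population cohort of strains genotyped at SNP sites: site
#' coordinates and alleles, strain population labels, and per-call genotype,
#' total depth (DP) and allelic depths (AD). Genotypes are stored as two
#' allele-code matrices (`0` = reference, `1, 2, ...` = alternate alleles,
#' `NA` = missing call) of dimension sites x strains.
#'
#' @param sites data.frame with columns `arm`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multi-allelic records) and logical `multiallelic`.
#' @param strains data.frame with columns `id` and `population`.
#' @param a1,a2 integer matrices of allele codes (`NA` = missing call).
#' @param dp integer matrix of read depths (`NA` = unknown).
#' @param ad_ref,ad_alt integer matrices of reference / first-alternate
#'   allelic depths (`NA` = unknown).
#' @param ploidy 2 for diploid calls, 1 for pseudo-haploid matrices in which
#'   each strain contributes a single allele (stored in `a1`).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, strains, a1, a2, dp = NULL, ad_ref = NULL,
                            ad_alt = NULL, ploidy = 2L) {
  stopifnot(
    is.data.frame(sites), all(c("arm", "pos", "ref", "alt") %in% names(sites)),
    is.data.frame(strains), all(c("id", "population") %in% names(strains)),
    nrow(a1) == nrow(sites), ncol(a1) == nrow(strains),
    identical(dim(a1), dim(a2))
  )
  if (anyNA(strains$population)) stop("every strain must have a population label")
  if (is.null(sites$multiallelic)) {
    sites$multiallelic <- grepl(",", sites$alt, fixed = TRUE)
  }
  # positions strictly increasing within each arm
  for (arm in unique(sites$arm)) {
    p <- sites$pos[sites$arm == arm]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("site positions must be strictly increasing within arm ", arm)
    }
  }
  blank <- function(m) if (is.null(m)) matrix(NA_integer_, nrow(a1), ncol(a1)) else m
  structure(
    list(sites = sites, strains = strains,
         a1 = a1, a2 = a2, dp = blank(dp),
         ad_ref = blank(ad_ref), ad_alt = blank(ad_alt),
         ploidy = as.integer(ploidy)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d sites x %d strains (%s), ploidy %d\n",
    nrow(x$sites), nrow(x$strains),
    paste(sprintf("%s=%d", names(table(x$strains$population)),
                  as.integer(table(x$strains$population))), collapse = ", "),
    x$ploidy
  ))
  cat("arms:", paste(unique(x$sites$arm), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), nrow(x$strains))

#' Subset a genotype matrix by sites and/or strains
#'
#' @param x a [genotype_matrix()].
#' @param sites logical or integer index over sites.
#' @param strains logical or integer index over strains (or strain ids).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_matrix <- function(x, sites = NULL, strains = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  if (is.character(strains)) strains <- match(strains, x$strains$id)
  ci <- if (is.null(strains)) seq_len(nrow(x$strains)) else strains
  genotype_matrix(
    sites = x$sites[si, , drop = FALSE],
    strains = x$strains[ci, , drop = FALSE],
    a1 = x$a1[si, ci, drop = FALSE], a2 = x$a2[si, ci, drop = FALSE],
    dp = x$dp[si, ci, drop = FALSE],
    ad_ref = x$ad_ref[si, ci, drop = FALSE],
    ad_alt = x$ad_alt[si, ci, drop = FALSE],
    ploidy = x$ploidy
  )
}

#' Per-site genotype summaries for one population
#'
#' For the strains of one population, counts called individuals and tallies
#' the first-alternate allele frequency and observed heterozygosity per site.
#' For pseudo-haploid matrices each strain contributes one allele and
#' heterozygosity is 0 by construction.
#'
#' @param x a [genotype_matrix()].
#' @param population population label, or a character vector of several.
#' @return data.frame with `n` (called individuals), `n_chrom` (called
#'   allele copies), `c_ref`, `c_alt` (allele-copy counts), `p` (alt
#'   frequency) and `h` (observed het fraction among called individuals).
#' @export
pop_site_summary <- function(x, population) {
  stopifnot(inherits(x, "genotype_matrix"))
  cols <- x$strains$population %in% population
  if (!any(cols)) stop("no strains with population label ", paste(population, collapse = "/"))
  a1 <- x$a1[, cols, drop = FALSE]
  a2 <- x$a2[, cols, drop = FALSE]
  if (x$ploidy == 1L) {
    called <- !is.na(a1)
    n <- rowSums(called)
    c_alt <- rowSums(a1 == 1L, na.rm = TRUE)
    c_ref <- rowSums(a1 == 0L, na.rm = TRUE)
    n_chrom <- n
    het <- rep(0, nrow(a1))
  } else {
    called <- !is.na(a1) & !is.na(a2)
    n <- rowSums(called)
    c_alt <- rowSums((a1 == 1L) * called, na.rm = TRUE) +
      rowSums((a2 == 1L) * called, na.rm = TRUE)
    c_ref <- rowSums((a1 == 0L) * called, na.rm = TRUE) +
      rowSums((a2 == 0L) * called, na.rm = TRUE)
    n_chrom <- 2L * n
    het <- rowSums((a1 != a2) * called, na.rm = TRUE)
  }
  data.frame(
    n = n, n_chrom = n_chrom, c_ref = c_ref, c_alt = c_alt,
    p = ifelse(n_chrom > 0, c_alt / n_chrom, NA_real_),
    h = ifelse(n > 0, het / pmax(n, 1), NA_real_)
  )
}

site_key <- function(sites) paste(sites$arm, sites$pos, sep = ":")
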