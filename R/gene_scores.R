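#' Per-gene maximum F_ST
#'
#' Assigns to each gene the maximum per-site theta among SNPs in its
#' scoring region: the transcribed span plus the strand-aware 1 kb region
#' upstream of the TSS. A SNP may contribute to several overlapping genes.
#' Genes with no usable SNP in their region are excluded (listed in the
#' `unscored` attribute).
#'
#' @param site_stats output of [fst_scan()].
#' @param gm a [gene_models()] object.
#' @param upstream_bp upstream window size.
#' @return data.frame: `gene_id`, `arm`, `n_snps`, `max_fst`; attribute
#'   `unscored` holds the gene ids with zero SNPs.
#' @export
gene_max_fst <- function(site_stats, gm, upstream_bp = 1000L) {
  stopifnot(inherits(gm, "gene_models"))
  sr <- gene_scoring_regions(gm, upstream_bp)
  res <- data.frame(gene_id = sr$gene_id, arm = sr$arm,
                    n_snps = 0L, max_fst = NA_real_, stringsAsFactors = FALSE)
  for (a in unique(sr$arm)) {
    gi <- which(sr$arm == a)
    si <- which(site_stats$arm == a & site_stats$usable)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(site_stats$pos[si], site_stats$pos[si]),
      IRanges::IRanges(sr$start[gi], sr$end[gi])
    )
    qh <- si[S4Vectors::queryHits(ov)]
    gh <- gi[S4Vectors::subjectHits(ov)]
    if (!length(qh)) next
    agg_n <- tapply(site_stats$theta[qh], gh, length)
    agg_m <- tapply(site_stats$theta[qh], gh, max)
    ii <- as.integer(names(agg_n))
    res$n_snps[ii] <- as.integer(agg_n)
    res$max_fst[ii] <- as.numeric(agg_m)
  }
  out <- res[res$n_snps > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unscored") <- res$gene_id[res$n_snps == 0L]
  out
}

#' Per-arm rank-based inverse-normal Z scores
#'
#' Normalises per-gene maximum F_ST values to Z scores within each
#' chromosome arm using the arm's empirical distribution: the rank-based
#' inverse-normal transform `Z = qnorm((rank - 0.5) / n_arm)` with average
#' ranks for ties, so the arm-wise Z distribution is standard-normal-like
#' by construction even though maximum F_ST is strongly skewed.
#'
#' @param gene_scores output of [gene_max_fst()].
#' @param method `"rank"` (default) for the inverse-normal transform, or
#'   `"zscore"` for plain per-arm mean/sd standardisation (kept for
#'   comparison; max-F_ST is strongly skewed, so these Z are not normal).
#' @return The input with a `Z` column appended.
#' @export
z_normalize_per_arm <- function(gene_scores, method = c("rank", "zscore")) {
  method <- match.arg(method)
  Z <- rep(NA_real_, nrow(gene_scores))
  for (a in unique(gene_scores$arm)) {
    ii <- which(gene_scores$arm == a)
    if (length(ii) < 2) {
      warning("arm ", a, " has a single scored gene; Z set to 0")
      Z[ii] <- 0
      next
    }
    if (method == "rank") {
      r <- rank(gene_scores$max_fst[ii], ties.method = "average")
      Z[ii] <- qnorm((r - 0.5) / length(ii))
    } else {
      v <- gene_scores$max_fst[ii]
      s <- stats::sd(v)
      Z[ii] <- if (s > 0) (v - mean(v)) / s else 0
    }
  }
  gene_scores$Z <- Z
  gene_scores
}

#' SNP-count bias correction of gene Z scores
#'
#' Genes with more SNPs in their scoring region have systematically larger
#' maximum F_ST (a maximum over more draws), hence larger Z. Genes are
#' sorted by SNP count and split into `n_bins` equal-occupancy bins (genes
#' tied at a bin boundary stay in the same bin); the corrected score is the
#' Z score centred by its bin median: `Z_ST = Z - median(Z in bin)`, so
#' within each bin the median Z_ST is exactly 0.
#'
#' @param gene_scores output of [z_normalize_per_arm()].
#' @param n_bins number of SNP-count bins.
#' @return The input with `bin` and `Z_ST` columns; attribute
#'   `bin_boundaries` gives each bin's SNP-count range.
#' @export
bin_correct <- function(gene_scores, n_bins = 16L) {
  n <- nrow(gene_scores)
  if (n < n_bins) {
    warning("fewer genes (", n, ") than bins (", n_bins, "); bins collapsed")
    n_bins <- max(1L, n)
  }
  ord <- order(gene_scores$n_snps, gene_scores$gene_id)
  bin0 <- floor((seq_len(n) - 1L) * n_bins / n) + 1L
  # boundary ties: all genes with the same SNP count share the bin of the
  # first of them in sort order
  bin <- integer(n)
  bin[ord] <- ave(bin0, gene_scores$n_snps[ord], FUN = function(b) b[1])
  med <- ave(gene_scores$Z, bin, FUN = median)
  gene_scores$bin <- bin
  gene_scores$Z_ST <- gene_scores$Z - med
  bb <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(bin = b, n_genes = sum(bin == b),
               snps_min = min(gene_scores$n_snps[bin == b]),
               snps_max = max(gene_scores$n_snps[bin == b]))
  }))
  attr(gene_scores, "bin_boundaries") <- bb
  gene_scores
}

#' Candidate differentiated genes: top tail of the Z_ST distribution
#'
#' Takes the top `floor(tail * N)` genes by Z_ST genome-wide (not per arm).
#' Ties exactly at the cut are broken by gene id (lexicographically
#' earlier wins) and reported.
#'
#' @param gene_scores output of [bin_correct()].
#' @param tail tail fraction.
#' @return character vector of candidate gene ids; attribute `tie_break`
#'   TRUE when the cut fell inside a tie.
#' @export
candidate_genes <- function(gene_scores, tail = 0.05) {
  stopifnot(nrow(gene_scores) > 0)
  k <- floor(tail * nrow(gene_scores))
  if (k < 1) return(character(0))
  ord <- order(-gene_scores$Z_ST, gene_scores$gene_id)
  cut_val <- gene_scores$Z_ST[ord[k]]
  tie <- k < nrow(gene_scores) && gene_scores$Z_ST[ord[k + 1]] == cut_val
  out <- gene_scores$gene_id[ord[seq_len(k)]]
  attr(out, "tie_break") <- tie
  out
}

#' Full gene-level Z_ST scoring pipeline
#'
#' [gene_max_fst()] then [z_normalize_per_arm()] then [bin_correct()], with
#' the candidate flag at the given tail appended.
#'
#' @inheritParams gene_max_fst
#' @inheritParams bin_correct
#' @inheritParams candidate_genes
#' @return data.frame: `gene_id`, `arm`, `n_snps`, `max_fst`, `Z`, `bin`,
#'   `Z_ST`, `candidate`.
#' @export
gene_zst <- function(site_stats, gm, upstream_bp = 1000L, n_bins = 16L,
                     tail = 0.05) {
  gs <- gene_max_fst(site_stats, gm, upstream_bp)
  gs <- z_normalize_per_arm(gs)
  gs <- bin_correct(gs, n_bins)
  gs$candidate <- gs$gene_id %in% candidate_genes(gs, tail)
  gs
}
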