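#' Assign each SNP a single functional category
#'
#' Categories, by precedence when a SNP overlaps features of several genes
#' or several features of one gene: coding (split into synonymous /
#' non-synonymous) > splice site (the 2 intronic bases at each intron end)
#' > 5' UTR > 3' UTR > intron, where intronic SNPs at offsets 8-30 from the
#' intron's 5' end (transcribed strand) of small introns (<= 65 bp) form
#' the near-neutral background class `small_intron_bg` and the rest are
#' `intron_other` > core promoter (316 bp upstream of the TSS,
#' strand-aware) > promoter (317-1000 bp upstream) > intergenic.
#'
#' Coding SNPs are translated against the gene's CDS sequence: the codon
#' containing the site is extracted, the alternate base substituted
#' (reverse-complemented for minus-strand genes) and both codons translated
#' with the standard genetic code. When the reference allele does not match
#' the CDS base the codon cannot be resolved: the SNP stays `coding` with
#' unknown synonymy and is counted in the log.
#'
#' @param site_stats data.frame with at least `arm`, `pos`, `ref`, `alt`.
#' @param gm a [gene_models()] object.
#' @param small_intron_max,small_intron_window background definition:
#'   introns of length <= `small_intron_max` bp, offsets
#'   `small_intron_window[1]`..`[2]` from the 5' end.
#' @param core_promoter_bp,promoter_bp upstream window sizes.
#' @return data.frame: `arm`, `pos`, `category`, `gene_id` (NA for
#'   intergenic), `unresolved_codon` count as attribute.
#' @export
annotate_sites <- function(site_stats, gm, small_intron_max = 65L,
                           small_intron_window = c(8L, 30L),
                           core_promoter_bp = 316L, promoter_bp = 1000L) {
  stopifnot(inherits(gm, "gene_models"))
  blocks <- gene_feature_blocks(gm, small_intron_max, small_intron_window,
                                core_promoter_bp, promoter_bp)
  # precedence rank; lower wins
  rank_of <- c(cds = 1, splice = 2, utr5 = 3, utr3 = 4, small_intron_bg = 5,
               intron = 6, core_promoter = 7, promoter = 8)
  blocks$rank <- rank_of[blocks$type]
  n <- nrow(site_stats)
  best_rank <- rep(9, n)
  best_gene <- rep(NA_character_, n)
  for (a in unique(site_stats$arm)) {
    si <- which(site_stats$arm == a)
    blk <- blocks[blocks$arm == a, ]
    if (!nrow(blk)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(site_stats$pos[si], site_stats$pos[si]),
      IRanges::IRanges(blk$start, blk$end)
    )
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (!length(qh)) next
    ord <- order(qh, blk$rank[sh])
    first <- !duplicated(qh[ord])
    qi <- qh[ord][first]; bi <- sh[ord][first]
    upd <- blk$rank[bi] < best_rank[si[qi]]
    best_rank[si[qi][upd]] <- blk$rank[bi][upd]
    best_gene[si[qi][upd]] <- blk$gene_id[bi][upd]
  }
  category <- c("cds", "splice_site", "utr5", "utr3", "small_intron_bg",
                "intron_other", "core_promoter", "promoter",
                "intergenic")[best_rank]
  # synonymous / non-synonymous classification of coding SNPs
  unresolved <- 0L
  coding <- which(category == "cds")
  for (i in coding) {
    g <- best_gene[i]
    syn <- classify_codon(gm, g, site_stats$pos[i],
                          site_stats$ref[i], site_stats$alt[i])
    if (is.na(syn)) {
      unresolved <- unresolved + 1L
      category[i] <- "coding_unresolved"
    } else {
      category[i] <- if (syn) "coding_syn" else "coding_nonsyn"
    }
  }
  out <- data.frame(arm = site_stats$arm, pos = site_stats$pos,
                    category = category, gene_id = best_gene,
                    stringsAsFactors = FALSE)
  attr(out, "unresolved_codon") <- unresolved
  out
}

# TRUE = synonymous, FALSE = non-synonymous, NA = codon unresolvable
classify_codon <- function(gm, gene_id, pos, ref, alt) {
  off <- cds_offset(gm, gene_id, pos)
  if (is.na(off)) return(NA)
  strand <- gm$genes$strand[gm$genes$gene_id == gene_id]
  seq <- gm$cds_seq[[gene_id]]
  ref_c <- if (strand == "+") ref else chartr("ACGT", "TGCA", ref)
  alt_c <- if (strand == "+") alt else chartr("ACGT", "TGCA", alt)
  if (substr(seq, off + 1L, off + 1L) != ref_c) return(NA)
  codon_start <- off - off %% 3L
  codon <- substr(seq, codon_start + 1L, codon_start + 3L)
  if (nchar(codon) != 3L) return(NA)
  mut <- codon
  substr(mut, off - codon_start + 1L, off - codon_start + 1L) <- alt_c
  aa1 <- Biostrings::GENETIC_CODE[[codon]]
  aa2 <- Biostrings::GENETIC_CODE[[mut]]
  if (is.null(aa1) || is.null(aa2)) return(NA)
  aa1 == aa2
}

#' Stratified enrichment of outlier SNPs per functional category
#'
#' For each functional category (versus the small-intron neutral
#' background), tests association between category membership and falling
#' in a given F_ST outlier tier, controlling for pooled-MAF bin, chromosome
#' arm and inversion status by combining per-stratum 2x2 tables with the
#' Cochran-Mantel-Haenszel test (common odds ratio; two-sided). A plain
#' (unstratified, two-sided) Fisher exact test on the pooled table is
#' reported alongside. With a single informative stratum the CMH p-value
#' falls back to the Fisher test of that stratum.
#'
#' @param calls output of [annotate_sites()].
#' @param site_stats matching [fst_scan()] rows with a `tier` column (see
#'   [arm_thresholds()]) and `maf`, `inside_inversion`.
#' @param tail tier to test (e.g. 0.05).
#' @param tails tail set used for tier labels.
#' @param maf_bins number of pooled-MAF quantile bins in the strata
#'   (quintiles by default: finer bins starve the background sets of the
#'   stratified test at moderate SNP counts).
#' @param background category used as the neutral reference.
#' @return data.frame: `category`, `tier`, `n_cat`, `n_cat_tier`, `or_cmh`,
#'   `p_cmh`, `or_fisher`, `p_fisher`.
#' @export
enrichment_test <- function(calls, site_stats, tail = 0.05,
                            tails = c(0.05, 0.01, 0.005), maf_bins = 5L,
                            background = "small_intron_bg") {
  stopifnot(nrow(calls) == nrow(site_stats))
  ok <- site_stats$usable & calls$category != "coding_unresolved"
  cat_ <- calls$category[ok]
  hit <- in_tier(site_stats$tier[ok], tail, tails)
  maf <- site_stats$maf[ok]
  arm <- site_stats$arm[ok]
  inv <- site_stats$inside_inversion[ok] %||% rep(FALSE, sum(ok))
  qs <- unique(quantile(maf, probs = seq(0, 1, length.out = maf_bins + 1),
                        type = 1))
  mbin <- if (length(qs) >= 2) cut(maf, breaks = qs, include.lowest = TRUE)
  else factor(rep("all", length(maf)))
  stratum <- interaction(mbin, arm, inv, drop = TRUE)
  if (!any(cat_ == background)) stop("background category '", background,
                                     "' is empty")
  cats <- setdiff(unique(cat_), background)
  out <- lapply(sort(cats), function(cc) {
    sel <- cat_ %in% c(cc, background)
    if (!any(cat_ == cc)) return(NULL)
    is_cat <- factor(cat_[sel] == cc, levels = c(TRUE, FALSE))
    is_hit <- factor(hit[sel], levels = c(TRUE, FALSE))
    st <- droplevels(stratum[sel])
    tabs <- table(is_cat, is_hit, st)
    # keep informative strata (some sites on both category sides)
    keep <- apply(tabs, 3, function(m) sum(m) > 0 && all(rowSums(m) > 0))
    tabs <- tabs[, , keep, drop = FALSE]
    pooled <- table(is_cat, is_hit)
    fis <- fisher.test(pooled)
    if (dim(tabs)[3] >= 2) {
      cmh <- tryCatch(mantelhaen.test(tabs, correct = FALSE),
                      error = function(e) NULL)
    } else if (dim(tabs)[3] == 1) {
      cmh <- fisher.test(tabs[, , 1])
    } else {
      cmh <- NULL
    }
    data.frame(
      category = cc, tier = tier_label(tail),
      n_cat = sum(cat_ == cc), n_cat_tier = sum(cat_ == cc & hit),
      or_cmh = if (!is.null(cmh) && !is.null(cmh$estimate))
        unname(cmh$estimate) else NA_real_,
      p_cmh = if (!is.null(cmh)) cmh$p.value else NA_real_,
      or_fisher = unname(fis$estimate), p_fisher = fis$p.value,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
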