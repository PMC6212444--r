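#' Gene model container
#'
#' Transcript-level gene models: one canonical transcript per gene with
#' exon and CDS blocks (1-based inclusive genomic coordinates, plus-strand
#' ordering) and the CDS nucleotide sequence in coding orientation.
#'
#' @param genes data.frame: `gene_id`, `arm`, `strand` (`"+"`/`"-"`),
#'   `tx_start`, `tx_end`, `tss`.
#' @param exons data.frame: `gene_id`, `start`, `end`.
#' @param cds data.frame: `gene_id`, `start`, `end` (subset of exon space).
#' @param cds_seq named character vector of CDS sequences (coding strand).
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, exons, cds, cds_seq) {
  stopifnot(
    all(c("gene_id", "arm", "strand", "tx_start", "tx_end", "tss") %in% names(genes)),
    all(c("gene_id", "start", "end") %in% names(exons)),
    all(c("gene_id", "start", "end") %in% names(cds))
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  cds_len <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
  bad <- names(cds_len)[cds_len %% 3L != 0L]
  if (length(bad)) stop("CDS length not divisible by 3 for: ",
                        paste(head(bad, 5), collapse = ", "))
  for (g in unique(exons$gene_id)) {
    b <- exons[exons$gene_id == g, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("overlapping exon blocks in gene ", g)
    }
  }
  structure(list(genes = genes, exons = exons, cds = cds, cds_seq = cds_seq),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on arms %s\n", nrow(x$genes),
              paste(sort(unique(x$genes$arm)), collapse = " ")))
  invisible(x)
}

# Derive introns from exon blocks; returns gene_id, arm, strand, start, end,
# length and intron index in transcription order.
gene_introns <- function(gm) {
  out <- list()
  strand <- setNames(gm$genes$strand, gm$genes$gene_id)
  arm <- setNames(gm$genes$arm, gm$genes$gene_id)
  for (g in unique(gm$exons$gene_id)) {
    b <- gm$exons[gm$exons$gene_id == g, ]
    b <- b[order(b$start), ]
    if (nrow(b) < 2) next
    st <- b$end[-nrow(b)] + 1L
    en <- b$start[-1] - 1L
    keep <- en >= st
    if (!any(keep)) next
    idx <- seq_len(sum(keep))
    if (strand[[g]] == "-") idx <- rev(idx)
    out[[g]] <- data.frame(
      gene_id = g, arm = arm[[g]], strand = strand[[g]],
      start = st[keep], end = en[keep],
      length = en[keep] - st[keep] + 1L, intron_rank = idx,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(), arm = character(),
                      strand = character(), start = integer(), end = integer(),
                      length = integer(), intron_rank = integer()))
  }
  do.call(rbind, unname(out))
}

# All annotation feature blocks for every gene, as one table:
# type in {cds, splice, utr5, utr3, small_intron_bg, intron,
#          core_promoter, promoter}. Promoter windows are strand-aware:
# core promoter covers TSS-1..TSS-316 and the distal promoter
# TSS-317..TSS-1000 on the transcribed strand.
#' @keywords internal
gene_feature_blocks <- function(gm, small_intron_max = 65L,
                                small_intron_window = c(8L, 30L),
                                core_promoter_bp = 316L, promoter_bp = 1000L,
                                splice_bp = 2L) {
  blocks <- list()
  add <- function(gene_id, arm, start, end, type) {
    keep <- end >= start
    if (!any(keep)) return()
    blocks[[length(blocks) + 1L]] <<- data.frame(
      gene_id = gene_id, arm = arm,
      start = as.integer(start[keep]), end = as.integer(end[keep]),
      type = type, stringsAsFactors = FALSE
    )
  }
  ga <- setNames(gm$genes$arm, gm$genes$gene_id)
  # CDS blocks
  add(gm$cds$gene_id, ga[gm$cds$gene_id], gm$cds$start, gm$cds$end, "cds")
  # introns, splice windows, small-intron background windows
  intr <- gene_introns(gm)
  if (nrow(intr)) {
    add(intr$gene_id, intr$arm, intr$start, intr$end, "intron")
    add(intr$gene_id, intr$arm, intr$start,
        pmin(intr$start + splice_bp - 1L, intr$end), "splice")
    add(intr$gene_id, intr$arm, pmax(intr$end - splice_bp + 1L, intr$start),
        intr$end, "splice")
    small <- intr[intr$length <= small_intron_max, ]
    if (nrow(small)) {
      lo <- small_intron_window[1]; hi <- small_intron_window[2]
      plus <- small$strand == "+"
      # window counted from the intron's 5' end on the transcribed strand
      ws <- ifelse(plus, small$start + lo - 1L, small$end - hi + 1L)
      we <- ifelse(plus, small$start + hi - 1L, small$end - lo + 1L)
      add(small$gene_id, small$arm, pmax(ws, small$start),
          pmin(we, small$end), "small_intron_bg")
    }
  }
  # UTRs: exonic space outside the CDS span, 5' vs 3' by strand
  for (g in gm$genes$gene_id) {
    ex <- gm$exons[gm$exons$gene_id == g, ]
    cd <- gm$cds[gm$cds$gene_id == g, ]
    info <- gm$genes[gm$genes$gene_id == g, ]
    if (nrow(cd)) {
      cs <- min(cd$start); ce <- max(cd$end)
      left_s <- pmin(ex$start, cs - 1L); left_e <- pmin(ex$end, cs - 1L)
      right_s <- pmax(ex$start, ce + 1L); right_e <- pmax(ex$end, ce + 1L)
      keep_l <- ex$start <= cs - 1L
      keep_r <- ex$end >= ce + 1L
      lt <- if (info$strand == "+") "utr5" else "utr3"
      rt <- if (info$strand == "+") "utr3" else "utr5"
      if (any(keep_l)) add(g, info$arm, left_s[keep_l], left_e[keep_l], lt)
      if (any(keep_r)) add(g, info$arm, right_s[keep_r], right_e[keep_r], rt)
    }
    # promoter windows upstream of the TSS
    if (info$strand == "+") {
      add(g, info$arm, info$tss - core_promoter_bp, info$tss - 1L, "core_promoter")
      add(g, info$arm, info$tss - promoter_bp, info$tss - core_promoter_bp - 1L,
          "promoter")
    } else {
      add(g, info$arm, info$tss + 1L, info$tss + core_promoter_bp, "core_promoter")
      add(g, info$arm, info$tss + core_promoter_bp + 1L, info$tss + promoter_bp,
          "promoter")
    }
  }
  do.call(rbind, blocks)
}

# Scoring regions for gene-level statistics: transcript span plus the
# strand-aware 1 kb (by default) upstream window.
#' @keywords internal
gene_scoring_regions <- function(gm, upstream_bp = 1000L) {
  g <- gm$genes
  data.frame(
    gene_id = g$gene_id, arm = g$arm,
    start = ifelse(g$strand == "+", g$tx_start - upstream_bp, g$tx_start),
    end = ifelse(g$strand == "+", g$tx_end, g$tx_end + upstream_bp),
    stringsAsFactors = FALSE
  )
}

# Map genomic position -> 0-based offset in the coding-strand CDS sequence.
# Returns NA when the position is not in the CDS of that gene.
#' @keywords internal
cds_offset <- function(gm, gene_id, pos) {
  cd <- gm$cds[gm$cds$gene_id == gene_id, ]
  cd <- cd[order(cd$start), ]
  if (!nrow(cd)) return(NA_integer_)
  strand <- gm$genes$strand[gm$genes$gene_id == gene_id]
  widths <- cd$end - cd$start + 1L
  cum <- cumsum(c(0L, widths))
  hit <- which(pos >= cd$start & pos <= cd$end)
  if (!length(hit)) return(NA_integer_)
  off_plus <- cum[hit] + (pos - cd$start[hit])
  total <- sum(widths)
  if (strand == "+") off_plus else total - 1L - off_plus
}
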