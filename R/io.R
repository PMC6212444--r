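#' Load a multi-sample VCF into a genotype matrix
#'
#' Reads a VCFv4.2 file (via vcfR) with per-call GT and optional DP/AD,
#' returning a [genotype_matrix()]. Multi-allelic records are retained and
#' flagged; missing DP/AD are stored as unknown (`NA`).
#'
#' @param path VCF file (plain or gzipped).
#' @param populations data.frame with columns `id`, `population` labelling
#'   each strain, or a named character vector (names = strain ids).
#' @param sample_subset optional character vector of sample ids to keep; an
#'   absent sample is an error naming it.
#' @return A [genotype_matrix()].
#' @export
load_vcf <- function(path, populations, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    stop("malformed VCF record (non-numeric POS) at data line ",
         which(is.na(pos))[1])
  }
  samples <- colnames(v@gt)[-1]
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing)) {
      stop("requested sample(s) absent from VCF: ",
           paste(missing, collapse = ", "))
    }
    keep <- samples %in% sample_subset
  } else {
    keep <- rep(TRUE, length(samples))
  }
  gt <- vcfR::extract.gt(v, "GT")[, keep, drop = FALSE]
  dp <- suppressWarnings(
    vcfR::extract.gt(v, "DP", as.numeric = TRUE)[, keep, drop = FALSE])
  ad <- vcfR::extract.gt(v, "AD")[, keep, drop = FALSE]
  samples <- samples[keep]

  if (is.null(dim(gt))) gt <- matrix(gt, ncol = length(samples))
  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))),
               nrow(gt), ncol(gt))
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))),
               nrow(gt), ncol(gt))
  a2[is.na(a1)] <- NA_integer_
  a1[is.na(a2)] <- NA_integer_
  ad_ref <- matrix(suppressWarnings(as.integer(sub(",.*", "", ad))),
                   nrow(gt), ncol(gt))
  ad_alt <- matrix(suppressWarnings(
    as.integer(sub("^[^,]*,([^,]*).*", "\\1", ad))), nrow(gt), ncol(gt))

  if (is.data.frame(populations)) {
    pop <- setNames(populations$population, populations$id)
  } else {
    pop <- populations
  }
  unlabelled <- setdiff(samples, names(pop))
  if (length(unlabelled)) {
    stop("no population label for strain(s): ",
         paste(unlabelled, collapse = ", "))
  }
  sites <- data.frame(arm = fix[, "CHROM"], pos = pos,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      multiallelic = grepl(",", fix[, "ALT"], fixed = TRUE),
                      stringsAsFactors = FALSE)
  ord <- order(sites$arm, sites$pos)
  dpm <- matrix(as.integer(dp), nrow(gt), ncol(gt))
  genotype_matrix(
    sites = sites[ord, , drop = FALSE],
    strains = data.frame(id = samples, population = unname(pop[samples]),
                         stringsAsFactors = FALSE),
    a1 = a1[ord, , drop = FALSE], a2 = a2[ord, , drop = FALSE],
    dp = dpm[ord, , drop = FALSE],
    ad_ref = ad_ref[ord, , drop = FALSE], ad_alt = ad_alt[ord, , drop = FALSE]
  )
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits a plain-text VCF with GT:DP:AD per call and contig header lines,
#' byte-deterministic for a given matrix.
#'
#' @param x a [genotype_matrix()].
#' @param path output file.
#' @param contig_lengths optional named vector of contig lengths.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  arms <- unique(x$sites$arm)
  contigs <- vapply(arms, function(a) {
    len <- if (!is.null(contig_lengths)) contig_lengths[[a]] else
      max(x$sites$pos[x$sites$arm == a])
    sprintf("##contig=<ID=%s,length=%d>", a, as.integer(len))
  }, "")
  header <- c(
    "##fileformat=VCFv4.2",
    contigs,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$strains$id), collapse = "\t")
  )
  gt <- matrix(paste0(x$a1, "/", x$a2), nrow(x$a1), ncol(x$a1))
  gt[is.na(x$a1) | is.na(x$a2)] <- "./."
  dp <- matrix(as.character(x$dp), nrow(x$dp))
  dp[is.na(x$dp)] <- "."
  ad <- matrix(paste0(x$ad_ref, ",", x$ad_alt), nrow(x$dp))
  ad[is.na(x$ad_ref) | is.na(x$ad_alt)] <- "."
  cells <- matrix(paste0(gt, ":", dp, ":", ad), nrow(x$dp))
  body <- do.call(paste, c(
    list(x$sites$arm, x$sites$pos, ".", x$sites$ref, x$sites$alt,
         ".", "PASS", ".", "GT:DP:AD"),
    lapply(seq_len(ncol(cells)), function(j) cells[, j]),
    sep = "\t"
  ))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load (or default) the site masks
#'
#' Builds the mask set used by [apply_site_filters()]: the euchromatin
#' inclusion mask, a repeat/low-complexity exclusion mask, and indel
#' positions (SNPs within a flank of an indel's affected span are excluded).
#' BED inputs are 0-based half-open; internal coordinates are 1-based
#' inclusive. Overlapping intervals are merged.
#'
#' When `euchromatin_bed` is `NULL` the euchromatin bounds of the
#' D. melanogaster reference arms (2L, 2R, 3L, 3R, X) ship as the default.
#'
#' @param euchromatin_bed,repeat_bed BED file paths (or `NULL`).
#' @param indel_positions TSV path with header `arm`, `start`, `end`
#'   (1-based inclusive affected span), or `NULL` for none.
#' @return Object of class `scan_masks`.
#' @export
load_masks <- function(euchromatin_bed = NULL, repeat_bed = NULL,
                       indel_positions = NULL) {
  eu <- if (is.null(euchromatin_bed)) EUCHROMATIN_DEFAULT else
    read_bed(euchromatin_bed)
  rp <- if (is.null(repeat_bed)) NULL else read_bed(repeat_bed)
  ind <- if (is.null(indel_positions)) NULL else
    read.table(indel_positions, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  structure(list(euchromatin = merge_intervals(eu),
                 repeats = if (!is.null(rp) && nrow(rp)) merge_intervals(rp) else NULL,
                 indels = ind),
            class = "scan_masks")
}

#' Construct masks directly from data.frames
#'
#' @param euchromatin,repeats,indels data.frames with `arm`, `start`, `end`
#'   (1-based inclusive); `repeats`/`indels` may be `NULL`.
#' @return Object of class `scan_masks`.
#' @export
scan_masks <- function(euchromatin = EUCHROMATIN_DEFAULT, repeats = NULL,
                       indels = NULL) {
  structure(list(euchromatin = merge_intervals(euchromatin),
                 repeats = if (!is.null(repeats)) merge_intervals(repeats) else NULL,
                 indels = indels),
            class = "scan_masks")
}

read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(data.frame(arm = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  data.frame(arm = b[[1]], start = b[[2]] + 1L, end = b[[3]],
             stringsAsFactors = FALSE)
}

write_bed <- function(df, path) {
  writeLines(sprintf("%s\t%d\t%d", df$arm, as.integer(df$start) - 1L,
                     as.integer(df$end)), path)
  invisible(path)
}

merge_intervals <- function(df) {
  out <- lapply(split(df, df$arm), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(arm = d$arm[1], start = IRanges::start(r),
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, unname(out))
  res[order(res$arm, res$start), , drop = FALSE]
}

# logical: is each (arm, pos) site inside any interval of df
sites_in_ranges <- function(arm, pos, df) {
  hit <- rep(FALSE, length(arm))
  if (is.null(df) || !nrow(df)) return(hit)
  for (a in intersect(unique(arm), unique(df$arm))) {
    si <- which(arm == a)
    d <- df[df$arm == a, ]
    ov <- IRanges::overlapsAny(IRanges::IRanges(pos[si], pos[si]),
                               IRanges::IRanges(d$start, d$end))
    hit[si] <- ov
  }
  hit
}

#' Write the complete synthetic cohort to a directory
#'
#' Emits plain-text files: `cohort.vcf` (VCFv4.2, GT:DP:AD),
#' `populations.tsv`, `euchromatin.bed` and `repeats.bed` (0-based
#' half-open), `indels.tsv` (1-based inclusive), `genes.tsv` (gene models
#' with exon/CDS blocks), `cds.fasta`, `go.obo` (OBO 1.2), `gene2go.tsv`,
#' `te_calls.tsv`, `markers.tsv` and the ground-truth tables
#' `truth_sites.tsv`, `truth_genes.tsv`, `truth_te.tsv`. Output is
#' byte-identical for a fixed config seed.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_vcf(sim$matrix, fp("cohort.vcf"),
            contig_lengths = sim$config$arms)
  wt <- function(d, f) write.table(d, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(sim$matrix$strains, "populations.tsv")
  write_bed(sim$masks$euchromatin, fp("euchromatin.bed"))
  write_bed(sim$masks$repeats, fp("repeats.bed"))
  wt(sim$masks$indels, "indels.tsv")
  write_gene_models(sim$gene_models, fp("genes.tsv"), fp("cds.fasta"))
  write_obo(sim$go_terms, sim$go_edges, fp("go.obo"))
  wt(sim$gene2go, "gene2go.tsv")
  wt(sim$te$calls, "te_calls.tsv")
  wt(sim$markers, "markers.tsv")
  wt(sim$truth$sites, "truth_sites.tsv")
  wt(sim$truth$genes, "truth_genes.tsv")
  wt(sim$truth$te, "truth_te.tsv")
  invisible(dir)
}

#' Write / read gene models as TSV + CDS FASTA
#'
#' The TSV has one row per gene: `gene_id`, `arm`, `strand`, `tss`,
#' `tx_start`, `tx_end`, and `exons` / `cds` block lists encoded as
#' `start-end` pairs joined by `,` (1-based inclusive).
#'
#' @param gm a [gene_models()] object.
#' @param genes_tsv,cds_fasta output paths.
#' @return `genes_tsv`, invisibly.
#' @export
write_gene_models <- function(gm, genes_tsv, cds_fasta) {
  enc <- function(blocks) {
    vapply(gm$genes$gene_id, function(g) {
      b <- blocks[blocks$gene_id == g, ]
      b <- b[order(b$start), ]
      paste(sprintf("%d-%d", b$start, b$end), collapse = ",")
    }, "")
  }
  tab <- data.frame(gm$genes, exons = enc(gm$exons), cds = enc(gm$cds),
                    stringsAsFactors = FALSE)
  write.table(tab, genes_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- unlist(lapply(gm$genes$gene_id, function(g) {
    s <- gm$cds_seq[[g]]
    c(paste0(">", g),
      substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60),
                                              nchar(s))))
  }))
  writeLines(lines, cds_fasta)
  invisible(genes_tsv)
}

#' @rdname write_gene_models
#' @export
load_gene_models <- function(genes_tsv, cds_fasta) {
  tab <- read.table(genes_tsv, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  dec <- function(col) {
    do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      parts <- strsplit(tab[[col]][i], ",", fixed = TRUE)[[1]]
      se <- do.call(rbind, strsplit(parts, "-", fixed = TRUE))
      data.frame(gene_id = tab$gene_id[i],
                 start = as.integer(se[, 1]), end = as.integer(se[, 2]),
                 stringsAsFactors = FALSE)
    }))
  }
  fa <- readLines(cds_fasta)
  hdr <- grepl("^>", fa)
  ids <- sub("^>", "", fa[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(fa[!hdr], grp[!hdr]), paste, "", collapse = "")
  names(seqs) <- ids
  gene_models(tab[, c("gene_id", "arm", "strand", "tx_start", "tx_end", "tss")],
              dec("exons"), dec("cds"), seqs)
}

# minimal OBO 1.2 writer for the toy ontology
write_obo <- function(terms, edges, path) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    par <- edges$parent[edges$child == id]
    out <- c(out, "[Term]",
             paste0("id: ", id),
             paste0("name: ", terms$name[i]),
             paste0("namespace: ", terms$namespace[i]),
             if (length(par)) paste0("is_a: ", par, " ! parent"),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
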