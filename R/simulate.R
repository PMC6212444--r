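#' Configuration for the synthetic two-population cohort
#'
#' Defines the study conditions emulated by the generator: two populations
#' of near-homozygous (isofemale-line-like) strains genotyped at independent
#' SNP sites whose population allele frequencies follow the Balding-Nichols
#' model (Beta-distributed around an ancestral frequency with dispersion F),
#' plus gene models with small introns, a toy GO DAG, a transposable-element
#' presence/absence table, and one inversion region tagged by marker SNPs.
#'
#' The default cohort mirrors the 26 + 16 strain design and the ~28.6x mean
#' coverage of the sequencing study the pipeline is built for, at desk
#' scale: five arms named 2L, 2R, 3L, 3R, X of 500 kb each with 10,000 SNP
#' sites and 600 genes.
#'
#' @param n_strains_pop1,n_strains_pop2 strains per population.
#' @param n_sites number of SNP sites.
#' @param arms named numeric vector of arm lengths (bp).
#' @param baseline_F Balding-Nichols dispersion for neutral sites, in (0,1).
#' @param selected_fraction fraction of sites planted as selected.
#' @param selected_F dispersion parameter for selected sites; planted draws
#'   are conditioned on realized divergence >= `selected_F` (see
#'   [simulate_cohort()] details).
#' @param inbreeding per-site probability that a strain is homozygous.
#' @param mean_depth expected reads per genotype call (Poisson mean).
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_genes,n_te number of gene models / TE insertions.
#' @param tx_len_range transcript length range (bp), log-uniform.
#' @param p_anc_range ancestral allele frequency range (uniform draw).
#' @param inversion_region `list(arm, start, end)` of the simulated
#'   inversion.
#' @param inversion_freq planted inversion frequencies, one per population
#'   (carrier counts are rounded to whole strains).
#' @param inversion_F_multiplier multiplier applied to the dispersion of
#'   neutral sites inside the inversion region.
#' @param n_markers inversion marker SNPs (in perfect association).
#' @param te_frac_fixed,te_frac_rare,te_frac_undetermined fractions of TEs
#'   planted as fixed in both populations, rare (< 5%) in both, and
#'   missing-data-heavy (frequency not determinable).
#' @param te_selected number of TEs planted as selected (high divergence).
#' @param te_missing_rate background missing-call rate in the TE table.
#' @param pop_labels labels for the two populations.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains_pop1 = 26L, n_strains_pop2 = 16L,
                       n_sites = 10000L,
                       arms = c("2L" = 1.2e6, "2R" = 1.2e6, "3L" = 1.2e6,
                                "3R" = 1.2e6, "X" = 1.2e6),
                       baseline_F = 0.05, selected_fraction = 0.002,
                       selected_F = 0.6, selected_cluster_size = 3L,
                       inbreeding = 0.95,
                       mean_depth = 28.6, seed = 1L,
                       n_genes = 1000L, n_te = 100L,
                       tx_len_range = c(600L, 8000L),
                       p_anc_range = c(0.05, 0.95),
                       inversion_region = list(arm = "2L", start = 3e5,
                                               end = 8e5),
                       inversion_freq = c(0.30, 0.15),
                       inversion_F_multiplier = 1.3,
                       n_markers = 20L,
                       te_frac_fixed = 0.55, te_frac_rare = 0.30,
                       te_frac_undetermined = 0.02, te_selected = 2L,
                       te_missing_rate = 0.03,
                       pop_labels = c("pop1", "pop2")) {
  stopifnot(
    n_sites >= 1, n_genes >= 1, n_te >= 1,
    baseline_F > 0, baseline_F < selected_F, selected_F < 1,
    inbreeding >= 0, inbreeding <= 1, mean_depth > 0,
    length(pop_labels) == 2, !is.null(names(arms))
  )
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Balding-Nichols per-population allele frequencies
#'
#' Draws, independently for each population, an allele frequency from
#' `Beta(p_anc (1-F)/F, (1-p_anc)(1-F)/F)`. Under this model the expected
#' frequency is `p_anc` in every population and the among-population
#' variance is `F p_anc (1-p_anc)`, so `F` is exactly the estimand of the
#' Weir & Cockerham theta estimator.
#'
#' Vectorised over sites; uses the ambient R RNG (call `set.seed()` for
#' reproducibility).
#'
#' @param p_anc ancestral frequency (strictly inside (0,1)).
#' @param F dispersion parameter in (0,1).
#' @param n_pops number of populations.
#' @return matrix of dimension `length(p_anc)` x `n_pops`.
#' @export
simulate_site_frequencies <- function(p_anc, F, n_pops = 2L) {
  if (any(p_anc <= 0 | p_anc >= 1)) {
    stop("p_anc must be strictly between 0 and 1 (monomorphic ancestral site)")
  }
  stopifnot(F > 0, F < 1, n_pops >= 1)
  shape1 <- p_anc * (1 - F) / F
  shape2 <- (1 - p_anc) * (1 - F) / F
  n <- length(p_anc)
  vapply(seq_len(n_pops), function(k) rbeta(n, shape1, shape2), numeric(n))
}

# Selected-site frequency planting: BN draws at F accepted only when the
# realized frequency-level divergence (p1-p2)^2 / (2 pbar qbar) reaches F
# and the pooled frequency is within [maf_floor, 1 - maf_floor], so the
# planted locus is both genuinely divergent and MAF-filter-proof.
plant_selected_frequencies <- function(n, F, p_anc_range = c(0.2, 0.8),
                                       maf_floor = 0.1) {
  p1 <- p2 <- numeric(0)
  guard <- 0L
  while (length(p1) < n) {
    guard <- guard + 1L
    if (guard > 1000L) stop("rejection sampling failed to plant selected loci")
    m <- max(4L * n, 100L)
    pa <- runif(m, p_anc_range[1], p_anc_range[2])
    fr <- simulate_site_frequencies(pa, F, 2L)
    pb <- (fr[, 1] + fr[, 2]) / 2
    ok <- pb > 0 & pb < 1 &
      (fr[, 1] - fr[, 2])^2 / (2 * pb * (1 - pb)) >= F &
      pmin(pb, 1 - pb) >= maf_floor
    p1 <- c(p1, fr[ok, 1]); p2 <- c(p2, fr[ok, 2])
  }
  cbind(p1[seq_len(n)], p2[seq_len(n)])
}

#' Simulate diploid genotypes for inbred strains
#'
#' With probability `inbreeding` a strain is homozygous at the site (alt
#' with probability `freq`); otherwise both alleles are drawn independently
#' (Hardy-Weinberg). Vectorised over sites.
#'
#' @param freq alt allele frequency (scalar or per-site vector).
#' @param n_strains number of strains.
#' @param inbreeding per-site homozygosity probability.
#' @return list with integer matrices `a1`, `a2` (sites x strains, 0 = ref,
#'   1 = alt).
#' @export
simulate_genotypes <- function(freq, n_strains, inbreeding) {
  stopifnot(all(freq >= 0 & freq <= 1), inbreeding >= 0, inbreeding <= 1)
  S <- length(freq)
  p <- matrix(freq, S, n_strains)
  ib <- matrix(runif(S * n_strains) < inbreeding, S, n_strains)
  a1 <- matrix(rbinom(S * n_strains, 1L, p), S, n_strains)
  a2 <- matrix(rbinom(S * n_strains, 1L, p), S, n_strains)
  a2[ib] <- a1[ib]
  list(a1 = a1, a2 = a2)
}

#' Simulate read depths and allelic depths
#'
#' Total depth is Poisson(`mean_depth`) per call. Heterozygous calls split
#' reads Binomial(DP, 0.5) between alleles; homozygous calls put all reads
#' on the carried allele.
#'
#' @param a1,a2 allele-code matrices (0/1) as from [simulate_genotypes()].
#' @param mean_depth Poisson mean.
#' @return list of integer matrices `dp`, `ad_ref`, `ad_alt`.
#' @export
simulate_read_depths <- function(a1, a2, mean_depth) {
  stopifnot(mean_depth > 0, identical(dim(a1), dim(a2)))
  dp <- matrix(rpois(length(a1), mean_depth), nrow(a1), ncol(a1))
  het <- a1 != a2
  ad_alt <- matrix(0L, nrow(a1), ncol(a1))
  ad_alt[het] <- rbinom(sum(het), dp[het], 0.5)
  hom_alt <- !het & a1 == 1L
  ad_alt[hom_alt] <- dp[hom_alt]
  list(dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt)
}

#' Generate gene models, CDS sequences, a toy GO DAG and gene annotations
#'
#' Places non-overlapping gene models on the configured arms. Each gene has
#' one transcript with 3-5 exons, UTRs at both ends, a CDS in frame
#' (length divisible by 3, starting ATG) and introns of which most are
#' small (<= 65 bp), so the small-intron neutral background class is well
#' populated. A single-rooted acyclic toy ontology (biological_process
#' namespace, clearly synthetic term ids/names) and a gene-to-term map are
#' generated alongside.
#'
#' @param config a [sim_config()].
#' @return list with `gene_models` (a [gene_models()] object), `go_terms`
#'   (data.frame `id`, `name`, `namespace`), `go_edges` (data.frame
#'   `child`, `parent`) and `gene2go` (data.frame `gene_id`, `term`).
#' @export
generate_annotations <- function(config) {
  arms <- config$arms
  n_genes <- config$n_genes
  # proportional allocation of genes to arms
  n_per <- floor(n_genes * arms / sum(arms))
  rem <- n_genes - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  genes <- exons <- cds <- list()
  cds_seq <- character(0)
  gi <- 0L
  for (arm in names(arms)) {
    L <- arms[[arm]]
    eu_start <- floor(L * 0.025) + 1L
    eu_end <- floor(L * 0.975)
    span <- eu_end - eu_start + 1L
    ng <- n_per[[arm]]
    if (ng == 0L) next
    # transcript lengths log-uniform, then packed with random inter-gene
    # gaps (>= 1.1 kb margin each side keeps promoter windows gene-free)
    tx_len <- round(exp(runif(ng, log(config$tx_len_range[1]),
                              log(config$tx_len_range[2]))))
    needed <- sum(tx_len + 2200L)
    slack <- span - needed
    if (slack < 0L) {
      stop("arm ", arm, " too short to place ", ng, " genes (need ",
           needed, " bp, have ", span, ")")
    }
    cuts <- sort(sample.int(slack + 1L, ng)) - 1L
    gap <- diff(c(0L, cuts))
    tx_start <- eu_start + 1100L +
      cumsum(gap + c(0L, tx_len[-ng] + 2200L))
    for (k in seq_len(ng)) {
      gi <- gi + 1L
      gene_id <- sprintf("G%04d", gi)
      g <- make_gene(gene_id, arm, tx_start[k], tx_len[k])
      genes[[gi]] <- g$gene
      exons[[gi]] <- g$exons
      cds[[gi]] <- g$cds
      cds_seq[[gene_id]] <- g$cds_seq
    }
  }
  gm <- gene_models(do.call(rbind, genes), do.call(rbind, exons),
                    do.call(rbind, cds), cds_seq)
  go <- make_toy_godag(gm$genes$gene_id)
  c(list(gene_models = gm), go)
}

# One gene model: exon/intron layout, UTRs, in-frame CDS and its sequence.
make_gene <- function(gene_id, arm, tx_start, tx_len) {
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(3:5, 1L)
  n_in <- n_ex - 1L
  intr <- ifelse(runif(n_in) < 0.7, sample(40:65, n_in, replace = TRUE),
                 sample(200:800, n_in, replace = TRUE))
  if (sum(intr) > tx_len - 80L * n_ex) {
    intr <- pmax(40L, floor(intr * (tx_len - 80L * n_ex) / sum(intr)))
  }
  exon_total <- tx_len - sum(intr)
  w <- runif(n_ex, 0.5, 1.5)
  ex_len <- floor(exon_total * w / sum(w))
  ex_len[n_ex] <- exon_total - sum(ex_len[-n_ex])
  if (any(ex_len < 50L)) ex_len <- rep(floor(exon_total / n_ex), n_ex)
  ex_start <- tx_start + c(0L, cumsum(ex_len[-n_ex] + intr))
  ex_end <- ex_start + ex_len - 1L
  tx_end <- ex_end[n_ex]
  tss <- if (strand == "+") tx_start else tx_end
  # CDS in transcript coordinates (from the 5' end on the coding strand)
  utr5 <- sample(20:100, 1L); utr3 <- sample(20:100, 1L)
  cds_len <- sum(ex_len) - utr5 - utr3
  cds_len <- cds_len - cds_len %% 3L
  if (cds_len < 60L) {
    utr5 <- utr3 <- 10L
    cds_len <- sum(ex_len) - 20L
    cds_len <- cds_len - cds_len %% 3L
  }
  exonic <- unlist(mapply(seq.int, ex_start, ex_end, SIMPLIFY = FALSE))
  five_prime <- if (strand == "+") exonic else rev(exonic)
  coding_pos <- sort(five_prime[(utr5 + 1L):(utr5 + cds_len)])
  runs <- cumsum(c(1L, diff(coding_pos) != 1L))
  cds_blocks <- data.frame(
    gene_id = gene_id,
    start = as.integer(tapply(coding_pos, runs, min)),
    end = as.integer(tapply(coding_pos, runs, max)),
    stringsAsFactors = FALSE
  )
  bases <- sample(c("A", "C", "G", "T"), cds_len, replace = TRUE)
  bases[1:3] <- c("A", "T", "G")
  list(
    gene = data.frame(gene_id = gene_id, arm = arm, strand = strand,
                      tx_start = tx_start, tx_end = tx_end, tss = tss,
                      stringsAsFactors = FALSE),
    exons = data.frame(gene_id = gene_id, start = ex_start, end = ex_end,
                       stringsAsFactors = FALSE),
    cds = cds_blocks,
    cds_seq = paste(bases, collapse = "")
  )
}

# Toy single-rooted biological_process DAG (synthetic ids and names) and a
# random gene-to-leaf-term annotation map.
make_toy_godag <- function(gene_ids, n_branches = 6L, leaves_per_branch = 4:6) {
  root <- "GO:7000000"
  branch <- sprintf("GO:%07d", 7000000 + seq_len(n_branches))
  terms <- data.frame(id = c(root, branch),
                      name = c("synthetic biological process root",
                               paste("synthetic branch process", seq_len(n_branches))),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = branch, parent = root, stringsAsFactors = FALSE)
  leaves <- character(0)
  li <- 0L
  for (b in seq_len(n_branches)) {
    for (k in seq_len(sample(leaves_per_branch, 1L))) {
      li <- li + 1L
      id <- sprintf("GO:%07d", 7000100 + li)
      leaves <- c(leaves, id)
      terms <- rbind(terms, data.frame(
        id = id, name = paste("synthetic leaf process", li),
        namespace = "biological_process", stringsAsFactors = FALSE))
      edges <- rbind(edges, data.frame(child = id, parent = branch[b],
                                       stringsAsFactors = FALSE))
      if (runif(1) < 0.2 && n_branches > 1) {
        other <- sample(branch[-b], 1L)
        edges <- rbind(edges, data.frame(child = id, parent = other,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  ann <- lapply(gene_ids, function(g) {
    data.frame(gene_id = g,
               term = sample(leaves, sample(1:3, 1L)),
               stringsAsFactors = FALSE)
  })
  list(go_terms = terms, go_edges = edges, gene2go = do.call(rbind, ann))
}

#' Generate a transposable-element presence/absence table
#'
#' Emulates a T-lex2-style per-strain presence/absence call table. TEs are
#' planted in four classes: fixed in both populations, rare (< 5%) in both,
#' missing-data-heavy (frequency not determinable), and segregating;
#' `te_selected` of the segregating TEs are planted as divergent using the
#' same conditioned Balding-Nichols scheme as selected SNPs.
#'
#' @param config a [sim_config()].
#' @param strain_ids list with per-population character vectors of strain
#'   ids (defaults to the ids [simulate_cohort()] uses).
#' @return list with `calls` (data.frame: `te_id`, `family`, `arm`, `pos`,
#'   then one `P`/`A`/`-` column per strain) and `truth` (data.frame:
#'   `te_id`, `planted_class`, `selected`, `freq_pop1`, `freq_pop2`).
#' @export
generate_te_table <- function(config, strain_ids = NULL) {
  n <- config$n_te
  n1 <- config$n_strains_pop1; n2 <- config$n_strains_pop2
  if (is.null(strain_ids)) {
    strain_ids <- list(sprintf("SW%02d", seq_len(n1)),
                       sprintf("IT%02d", seq_len(n2)))
  }
  n_fixed <- round(config$te_frac_fixed * n)
  n_rare <- round(config$te_frac_rare * n)
  n_undet <- max(round(config$te_frac_undetermined * n), 1L)
  n_sel <- config$te_selected
  n_null <- n - n_fixed - n_rare - n_undet - n_sel
  if (n_null < 0) stop("TE class fractions exceed n_te")
  cls <- c(rep("fixed", n_fixed), rep("rare", n_rare),
           rep("undetermined", n_undet), rep("segregating", n_null),
           rep("selected", n_sel))
  cls <- sample(cls)
  f <- matrix(NA_real_, n, 2)
  f[cls == "fixed", ] <- 1
  f[cls == "rare", ] <- runif(2 * sum(cls == "rare"), 0, 0.04)
  nb <- cls %in% c("undetermined", "segregating")
  if (any(nb)) {
    pa <- runif(sum(nb), 0.15, 0.85)
    f[nb, ] <- simulate_site_frequencies(pa, config$baseline_F, 2L)
  }
  if (n_sel > 0) {
    f[cls == "selected", ] <- plant_selected_frequencies(n_sel, config$selected_F)
  }
  pres1 <- matrix(rbinom(n * n1, 1L, f[, 1]), n, n1)
  pres2 <- matrix(rbinom(n * n2, 1L, f[, 2]), n, n2)
  call1 <- ifelse(pres1 == 1L, "P", "A")
  call2 <- ifelse(pres2 == 1L, "P", "A")
  miss1 <- matrix(runif(n * n1) < config$te_missing_rate, n, n1)
  miss2 <- matrix(runif(n * n2) < config$te_missing_rate, n, n2)
  # missing-heavy TEs: an exact 40% of strains uncalled in each population
  for (i in which(cls == "undetermined")) {
    miss1[i, sample.int(n1, ceiling(0.4 * n1))] <- TRUE
    miss2[i, sample.int(n2, ceiling(0.4 * n2))] <- TRUE
  }
  call1[miss1] <- "-"; call2[miss2] <- "-"
  arms <- config$arms
  te_arm <- sample(names(arms), n, replace = TRUE, prob = arms / sum(arms))
  te_pos <- vapply(te_arm, function(a) sample.int(arms[[a]], 1L), 1L)
  fam <- sample(c("roo", "jockey", "pogo", "copia", "FB", "297"), n,
                replace = TRUE)
  calls <- data.frame(te_id = sprintf("TE%04d", seq_len(n)), family = fam,
                      arm = te_arm, pos = as.integer(te_pos),
                      stringsAsFactors = FALSE)
  calls <- cbind(calls,
                 as.data.frame(call1, col.names = strain_ids[[1]]),
                 as.data.frame(call2, col.names = strain_ids[[2]]))
  names(calls) <- c("te_id", "family", "arm", "pos",
                    strain_ids[[1]], strain_ids[[2]])
  truth <- data.frame(te_id = calls$te_id, planted_class = cls,
                      selected = cls == "selected",
                      freq_pop1 = f[, 1], freq_pop2 = f[, 2],
                      stringsAsFactors = FALSE)
  list(calls = calls, truth = truth)
}

#' Simulate the complete synthetic cohort
#'
#' Generates, under a single seed, a deterministic cohort: gene models plus
#' toy ontology, SNP sites with Balding-Nichols population frequencies
#' (baseline dispersion, planted selected loci, an inversion region with a
#' dispersion multiplier and planted carrier strains tagged by marker SNPs),
#' near-homozygous diploid genotypes with Poisson depths, masks (euchromatin
#' bounds, repeats, indel positions), and a TE presence/absence table.
#'
#' Reference alleles at coding positions agree with the generated CDS
#' sequences so synonymous/non-synonymous calls are well defined.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_cohort`: list with `config`, `matrix`
#'   (a [genotype_matrix()]), `gene_models`, `go_terms`/`go_edges`/`gene2go`,
#'   `te` (calls + truth), `markers`, `masks`, `inversion` and `truth`
#'   (per-site, per-gene and per-TE ground truth).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ann <- generate_annotations(config)
  gm <- ann$gene_models
  arms <- config$arms
  n1 <- config$n_strains_pop1; n2 <- config$n_strains_pop2
  strains <- data.frame(
    id = c(sprintf("SW%02d", seq_len(n1)), sprintf("IT%02d", seq_len(n2))),
    population = rep(config$pop_labels, c(n1, n2)),
    stringsAsFactors = FALSE
  )

  # --- site positions (plus marker positions inside the inversion) ---
  n_per <- floor(config$n_sites * arms / sum(arms))
  rem <- config$n_sites - sum(n_per)
  if (rem > 0) n_per[seq_len(rem)] <- n_per[seq_len(rem)] + 1L
  inv <- config$inversion_region
  marker_pos <- sort(sample(seq(inv$start, inv$end), config$n_markers))
  sites <- do.call(rbind, lapply(names(arms), function(a) {
    pos <- sort(sample.int(arms[[a]], n_per[[a]]))
    if (a == inv$arm) {
      pos <- sort(unique(c(setdiff(pos, marker_pos), marker_pos)))
    }
    data.frame(arm = a, pos = pos, stringsAsFactors = FALSE)
  }))
  S <- nrow(sites)
  is_marker <- sites$arm == inv$arm & sites$pos %in% marker_pos
  in_inv <- sites$arm == inv$arm & sites$pos >= inv$start & sites$pos <= inv$end

  # --- per-site dispersion and population frequencies ---
  p_anc <- runif(S, config$p_anc_range[1], config$p_anc_range[2])
  Fsite <- rep(config$baseline_F, S)
  Fsite[in_inv] <- pmin(config$baseline_F * config$inversion_F_multiplier, 0.9)
  # selected loci planted as clusters of adjacent sites: a sweep leaves a
  # multi-SNP footprint, so candidate genes carry several high-F_ST SNPs
  n_sel <- round(config$selected_fraction * S)
  csize <- max(1L, config$selected_cluster_size)
  n_clust <- ceiling(n_sel / csize)
  anchors <- integer(0)
  cand <- which(!is_marker & seq_len(S) <= S - csize + 1L)
  guard <- 0L
  while (length(anchors) < n_clust && guard < 10000L) {
    guard <- guard + 1L
    a <- sample(cand, 1L)
    span <- a + seq_len(csize) - 1L
    if (any(is_marker[span]) || length(unique(sites$arm[span])) > 1L) next
    if (length(anchors) && min(abs(anchors - a)) < csize) next
    anchors <- c(anchors, a)
  }
  sel_idx <- unlist(lapply(sort(anchors), function(a) a + seq_len(csize) - 1L))
  sel_idx <- sel_idx[seq_len(min(n_sel, length(sel_idx)))]
  n_sel <- length(sel_idx)
  selected <- rep(FALSE, S); selected[sel_idx] <- TRUE
  freqs <- matrix(NA_real_, S, 2)
  neut <- !selected
  for (Fv in unique(Fsite[neut])) {
    ii <- which(neut & Fsite == Fv)
    freqs[ii, ] <- simulate_site_frequencies(p_anc[ii], Fv, 2L)
  }
  if (n_sel > 0) {
    freqs[sel_idx, ] <- plant_selected_frequencies(n_sel, config$selected_F)
  }

  # --- genotypes and read depths ---
  g1 <- simulate_genotypes(freqs[, 1], n1, config$inbreeding)
  g2 <- simulate_genotypes(freqs[, 2], n2, config$inbreeding)

  # inversion carriers: exact planted counts, markers in perfect association
  carriers1 <- sample.int(n1, round(config$inversion_freq[1] * n1))
  carriers2 <- sample.int(n2, round(config$inversion_freq[2] * n2))
  mi <- which(is_marker)
  for (m in mi) {
    g1$a1[m, ] <- g1$a2[m, ] <- as.integer(seq_len(n1) %in% carriers1)
    g2$a1[m, ] <- g2$a2[m, ] <- as.integer(seq_len(n2) %in% carriers2)
    freqs[m, ] <- c(length(carriers1) / n1, length(carriers2) / n2)
  }
  d1 <- simulate_read_depths(g1$a1, g1$a2, config$mean_depth)
  d2 <- simulate_read_depths(g2$a1, g2$a2, config$mean_depth)

  # --- alleles: coding sites take REF from the CDS sequence ---
  alleles <- assign_alleles(sites, gm)
  mat <- genotype_matrix(
    sites = data.frame(sites, ref = alleles$ref, alt = alleles$alt,
                       multiallelic = FALSE, stringsAsFactors = FALSE),
    strains = strains,
    a1 = cbind(g1$a1, g2$a1), a2 = cbind(g1$a2, g2$a2),
    dp = cbind(d1$dp, d2$dp),
    ad_ref = cbind(d1$ad_ref, d2$ad_ref),
    ad_alt = cbind(d1$ad_alt, d2$ad_alt)
  )

  # --- masks ---
  masks_tbl <- list(
    euchromatin = data.frame(
      arm = names(arms),
      start = floor(unname(arms) * 0.025) + 1L,
      end = floor(unname(arms) * 0.975), stringsAsFactors = FALSE),
    repeats = do.call(rbind, lapply(names(arms), function(a) {
      st <- sort(sample.int(arms[[a]] - 5000L, 8L))
      data.frame(arm = a, start = st, end = st + sample(2000:5000, 8L, TRUE),
                 stringsAsFactors = FALSE)
    })),
    indels = do.call(rbind, lapply(names(arms), function(a) {
      p <- sort(sample.int(arms[[a]], 150L))
      data.frame(arm = a, start = p, end = p, stringsAsFactors = FALSE)
    }))
  )

  # --- TE table ---
  te <- generate_te_table(config, split(strains$id, strains$population)[
    unique(strains$population)])

  markers <- data.frame(arm = inv$arm, pos = sites$pos[mi],
                        tag_allele = "alt", stringsAsFactors = FALSE)

  # --- truth tables ---
  truth_sites <- data.frame(
    site_id = site_key(sites), arm = sites$arm, pos = sites$pos,
    p_anc = p_anc, p_pop1 = freqs[, 1], p_pop2 = freqs[, 2],
    selected = selected, marker = is_marker, inside_inversion = in_inv,
    stringsAsFactors = FALSE
  )
  sr <- gene_scoring_regions(gm)
  truth_genes <- data.frame(
    gene_id = sr$gene_id,
    contains_selected = vapply(seq_len(nrow(sr)), function(i) {
      any(selected & sites$arm == sr$arm[i] &
            sites$pos >= sr$start[i] & sites$pos <= sr$end[i])
    }, TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(
    config = config, matrix = mat, gene_models = gm,
    go_terms = ann$go_terms, go_edges = ann$go_edges, gene2go = ann$gene2go,
    te = te, markers = markers, masks = masks_tbl,
    inversion = c(inv, list(freq = setNames(config$inversion_freq,
                                            config$pop_labels))),
    truth = list(sites = truth_sites, genes = truth_genes, te = te$truth)
  ), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d sites x %d strains, %d genes, %d TEs, seed %d\n",
    nrow(x$matrix$sites), nrow(x$matrix$strains),
    nrow(x$gene_models$genes), nrow(x$te$calls), x$config$seed))
  invisible(x)
}

# REF/ALT assignment; coding positions take REF from the CDS base so codon
# translation against the reference is consistent.
assign_alleles <- function(sites, gm) {
  B <- c("A", "C", "G", "T")
  ref <- sample(B, nrow(sites), replace = TRUE)
  cdsb <- gm$cds
  cdsb$arm <- gm$genes$arm[match(cdsb$gene_id, gm$genes$gene_id)]
  for (a in unique(sites$arm)) {
    blk <- cdsb[cdsb$arm == a, ]
    if (!nrow(blk)) next
    si <- which(sites$arm == a)
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[si], sites$pos[si]),
      IRanges::IRanges(blk$start, blk$end)
    )
    for (k in seq_along(ov)) {
      i <- si[S4Vectors::queryHits(ov)[k]]
      g <- blk$gene_id[S4Vectors::subjectHits(ov)[k]]
      off <- cds_offset(gm, g, sites$pos[i])
      if (is.na(off)) next
      base <- substr(gm$cds_seq[[g]], off + 1L, off + 1L)
      strand <- gm$genes$strand[gm$genes$gene_id == g]
      ref[i] <- if (strand == "+") base else chartr("ACGT", "TGCA", base)
    }
  }
  alt <- vapply(ref, function(r) sample(setdiff(B, r), 1L), "")
  list(ref = ref, alt = unname(alt))
}
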