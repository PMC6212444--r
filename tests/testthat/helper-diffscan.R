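# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Weir & Cockerham (1984) components for one biallelic site,
# written directly from the two-population component formulas on raw
# per-individual genotypes (0/1/2 alt-allele dosage, NA = missing).
# Deliberately scalar and literal: the oracle for the vectorised path.
wc_brute <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- sum(g1 == 1) / n1; h2 <- sum(g2 == 1) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# dosage matrix (sites x strains) -> genotype_matrix with constant depth
toy_matrix <- function(dos1, dos2, arm = "2L", pos = NULL, dp = 30L) {
  dos1 <- rbind(dos1); dos2 <- rbind(dos2)
  S <- nrow(dos1)
  dos <- cbind(dos1, dos2)
  a1 <- ifelse(dos >= 1L, 1L, 0L)
  a1[dos == 1L] <- 0L
  a2 <- ifelse(dos >= 1L, 1L, 0L)
  a1[is.na(dos)] <- NA_integer_; a2[is.na(dos)] <- NA_integer_
  n <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(S) * 100L
  genotype_matrix(
    sites = data.frame(arm = rep(arm, S), pos = pos,
                       ref = "A", alt = "T", multiallelic = FALSE,
                       stringsAsFactors = FALSE),
    strains = data.frame(
      id = sprintf("S%02d", seq_len(n)),
      population = rep(c("pop1", "pop2"), c(ncol(dos1), ncol(dos2))),
      stringsAsFactors = FALSE),
    a1 = a1, a2 = a2,
    dp = matrix(as.integer(dp), S, n),
    ad_ref = matrix(as.integer(dp - dp / 2 * dos), S, n),
    ad_alt = matrix(as.integer(dp / 2 * dos), S, n)
  )
}

# small simulated cohort, cached across tests in the session
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 101L, n_sites = 2500L, n_genes = 220L,
                        arms = c("2L" = 4.5e5, "2R" = 4.5e5, "3L" = 4.5e5),
                        tx_len_range = c(600L, 2500L),
                        inversion_region = list(arm = "2L", start = 1e5,
                                                end = 2.5e5),
                        n_te = 60L)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

sim_masks <- function(sim) {
  scan_masks(sim$masks$euchromatin, sim$masks$repeats, sim$masks$indels)
}

# a hand-built two-gene model for annotation boundary tests:
#   plus-strand gene gp: tx 10001..12060, exons [10001..10600],
#   [10651..10800] (50 bp intron), [11001..12060] (200 bp intron),
#   CDS 10101..12000 (within exon space), so utr5 = 10001..10100 and
#   utr3 = 12001..12060
#   minus-strand gene gm: tx 20001..21500, exons [20001..20700],
#   [20761..21500] (60 bp intron 20701..20760), CDS 20101..21400
hand_genes <- function(cds_seq_p = NULL, cds_seq_m = NULL) {
  genes <- data.frame(
    gene_id = c("gp", "gm"), arm = "2L", strand = c("+", "-"),
    tx_start = c(10001L, 20001L), tx_end = c(12060L, 21500L),
    tss = c(10001L, 21500L), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gp", "gp", "gp", "gm", "gm"),
    start = c(10001L, 10651L, 11001L, 20001L, 20761L),
    end = c(10600L, 10800L, 12060L, 20700L, 21500L),
    stringsAsFactors = FALSE)
  cds <- data.frame(
    gene_id = c("gp", "gp", "gp", "gm", "gm"),
    start = c(10101L, 10651L, 11001L, 20101L, 20761L),
    end = c(10600L, 10800L, 12000L, 20700L, 21402L),
    stringsAsFactors = FALSE)
  len_p <- (10600 - 10101 + 1) + (10800 - 10651 + 1) + (12000 - 11001 + 1)
  len_m <- (20700 - 20101 + 1) + (21402 - 20761 + 1)
  stopifnot(len_p %% 3 == 0, len_m %% 3 == 0)
  if (is.null(cds_seq_p)) cds_seq_p <- strrep("TTT", len_p / 3)
  if (is.null(cds_seq_m)) cds_seq_m <- strrep("AAA", len_m / 3)
  gene_models(genes, exons, cds,
              c(gp = cds_seq_p, gm = cds_seq_m))
}

# site_stats row skeleton for annotation tests
site_row <- function(pos, ref = "T", alt = "C", arm = "2L") {
  data.frame(arm = arm, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
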