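test_that("VCF round-trip preserves sites, genotypes and depths", {
  sim <- small_cohort()
  p <- file.path(tempdir(), "rt.vcf")
  write_vcf(sim$matrix, p, contig_lengths = sim$config$arms)
  back <- load_vcf(p, populations = sim$matrix$strains)
  expect_identical(back$sites$arm, sim$matrix$sites$arm)
  expect_identical(back$sites$pos, sim$matrix$sites$pos)
  expect_identical(back$sites$ref, sim$matrix$sites$ref)
  expect_identical(unname(back$a1), unname(sim$matrix$a1))
  expect_identical(unname(back$a2), unname(sim$matrix$a2))
  expect_identical(unname(back$dp), unname(sim$matrix$dp))
  expect_identical(unname(back$ad_alt), unname(sim$matrix$ad_alt))
})

test_that("sample subsetting and missing genotypes behave as declared", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("2L", "100", ".", "A", "T", ".", "PASS", ".", "GT",
          "0/0", "./.", "1/1", sep = "\t"),
    paste("2L", "200", ".", "C", "G,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "0/0", sep = "\t")
  )
  p <- file.path(tempdir(), "mini.vcf")
  writeLines(vcf, p)
  pops <- data.frame(id = c("s1", "s2", "s3"),
                     population = c("pop1", "pop1", "pop2"))
  m <- load_vcf(p, pops, sample_subset = c("s1", "s2"))
  expect_equal(nrow(m$strains), 2)
  expect_true(is.na(m$a1[1, 2]) && is.na(m$a2[1, 2]))  # ./. call
  expect_true(m$sites$multiallelic[2])
  expect_true(is.na(m$dp[1, 1]))  # DP absent -> unknown
  expect_error(load_vcf(p, pops, sample_subset = c("s1", "nope")), "nope")
})

test_that("coverage thresholds use the nearest-rank convention", {
  S <- 1000L
  m <- toy_matrix(matrix(0L, S, 1), matrix(2L, S, 1))
  m$dp[, 1] <- 1:1000
  expect_equal(compute_coverage_threshold(m, "S01", 0.975), 975)
  expect_equal(compute_coverage_threshold(m, "S01", 1), 1000)
  m$dp[, 2] <- 30L
  expect_equal(compute_coverage_threshold(m, "S02", 0.975), 30)
})

test_that("genotype QC drops calls outside [min_dp, strain threshold]", {
  m <- toy_matrix(matrix(c(1L, 1L, 1L), 3, 1), matrix(c(2L, 2L, 2L), 3, 1))
  m$dp[, 1] <- c(9L, 10L, 30L)
  m$dp[, 2] <- c(30L, 30L, 31L)
  qc <- apply_genotype_qc(m, min_dp = 10, max_dp = c(S01 = 30, S02 = 30))
  expect_true(is.na(qc$a1[1, 1]))   # DP 9 < 10 -> missing
  expect_false(is.na(qc$a1[2, 1]))  # DP 10 kept (strict inequality)
  expect_false(is.na(qc$a1[3, 1]))  # DP at the threshold kept
  expect_true(is.na(qc$a1[3, 2]))   # DP above the threshold -> missing
})

test_that("default euchromatin bounds and BED conversion are exact", {
  masks <- load_masks()
  expect_true(sites_in_ranges("2L", 530000L, masks$euchromatin))
  expect_false(sites_in_ranges("2L", 529999L, masks$euchromatin))
  expect_true(sites_in_ranges("X", 21210000L, masks$euchromatin))
  expect_false(sites_in_ranges("X", 21210001L, masks$euchromatin))

  # empty repeat BED -> no repeat exclusions
  p <- file.path(tempdir(), "empty.bed")
  writeLines(character(0), p)
  expect_null(load_masks(repeat_bed = p)$repeats)

  # BED half-open inputs become 1-based inclusive; overlaps merge
  p2 <- file.path(tempdir(), "two.bed")
  writeLines(c("2L\t99\t200", "2L\t150\t300"), p2)
  rp <- load_masks(repeat_bed = p2)$repeats
  expect_equal(rp$start, 100L)
  expect_equal(rp$end, 300L)
})

test_that("the site-filter cascade applies every rule at its boundary", {
  # 8 sites x (4 + 4) strains on one arm
  dos1 <- rbind(
    c(0L, 0L, 0L, 0L),  # 1: in repeat
    c(0L, 0L, 0L, 1L),  # 2: singleton (one alt copy)
    c(2L, 2L, 2L, 2L),  # 3: indel at distance 5 -> excluded
    c(2L, 2L, 2L, 2L),  # 4: indel at distance 6 -> kept
    c(0L, 0L, 0L, 0L),  # 5: pooled MAF 0 -> excluded
    c(1L, 1L, 0L, 0L),  # 6: kept
    c(0L, 1L, 0L, 0L),  # 7: MAF exactly 1/16 < 0.05? no: see below, kept rule
    c(2L, 2L, 2L, 2L)   # 8: outside euchromatin
  )
  dos2 <- rbind(
    c(0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(0L, 0L, 0L, 0L),
    c(1L, 0L, 0L, 0L),  # second alt copy -> non-singleton, MAF 2/16 = 0.125
    c(0L, 0L, 0L, 0L)
  )
  pos <- c(1000L, 2000L, 3005L, 4006L, 5000L, 6000L, 7000L, 99000L)
  m <- toy_matrix(dos1, dos2, pos = pos)
  masks <- scan_masks(
    euchromatin = data.frame(arm = "2L", start = 1L, end = 50000L),
    repeats = data.frame(arm = "2L", start = 900L, end = 1100L),
    indels = data.frame(arm = "2L", start = 3000L, end = 3000L)
  )
  # second indel exactly 6 bp from site 4
  masks$indels <- rbind(masks$indels,
                        data.frame(arm = "2L", start = 4000L, end = 4000L))
  fl <- apply_site_filters(m, masks)
  kept <- fl$matrix$sites$pos
  expect_false(1000L %in% kept)   # repeat-masked
  expect_false(2000L %in% kept)   # singleton
  expect_false(3005L %in% kept)   # distance 5 from indel
  expect_true(4006L %in% kept)    # distance 6 from indel
  expect_false(5000L %in% kept)   # monomorphic -> MAF 0
  expect_true(6000L %in% kept)
  expect_true(7000L %in% kept)    # MAF 0.125 >= 0.05, two alt copies
  expect_false(99000L %in% kept)  # outside euchromatin

  expect_identical(fl$log$stage,
                   c("euchromatin", "repeat_mask", "indel_proximity",
                     "biallelic_snv", "non_singleton", "genotype_qc",
                     "call_rate", "pooled_maf"))
  expect_true(all(fl$log$n_out <= fl$log$n_in))
  expect_identical(fl$log$n_in[-1], fl$log$n_out[-nrow(fl$log)])

  # idempotence: filtering the filtered matrix changes nothing
  fl2 <- apply_site_filters(fl$matrix, masks)
  expect_identical(fl2$matrix$sites, fl$matrix$sites)
  expect_identical(fl2$matrix$a1, fl$matrix$a1)
})

test_that("per-population MAF mode keeps sites common in either population", {
  # 10% in the small pop1 (2 copies / 20), absent in the large pop2:
  # pooled MAF 2/100 = 2% fails the pooled rule but passes per-population
  dos1 <- rbind(c(2L, rep(0L, 9)))
  dos2 <- rbind(rep(0L, 40))
  m <- toy_matrix(dos1, dos2, pos = 500L)
  masks <- scan_masks(euchromatin = data.frame(arm = "2L", start = 1L,
                                               end = 10000L))
  pooled <- apply_site_filters(m, masks)
  expect_equal(nrow(pooled$matrix$sites), 0)
  per_pop <- apply_site_filters(m, masks, maf_scope = "per_population")
  expect_equal(per_pop$matrix$sites$pos, 500L)
  expect_true("per_population_maf" %in% per_pop$log$stage)
})

test_that("pooled MAF boundary: a site at exactly 5% is retained", {
  # 10 + 10 strains -> 40 chromosomes; 2 alt copies = 0.05 exactly
  dos1 <- rbind(c(2L, rep(0L, 9)))
  dos2 <- rbind(rep(0L, 10))
  m <- toy_matrix(dos1, dos2, pos = 500L)
  masks <- scan_masks(euchromatin = data.frame(arm = "2L", start = 1L,
                                               end = 10000L))
  fl <- apply_site_filters(m, masks)
  expect_equal(nrow(fl$matrix$sites), 1)
})
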