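test_that("promoter windows and intergenic boundaries are exact", {
  gm <- hand_genes()
  # plus-strand gene gp: TSS = 10001
  sites <- rbind(site_row(10001 - 316), site_row(10001 - 317),
                 site_row(10001 - 1000), site_row(10001 - 1001))
  ann <- annotate_sites(sites, gm)
  expect_equal(ann$category,
               c("core_promoter", "promoter", "promoter", "intergenic"))
  # minus-strand gene gm: TSS = 21500, upstream is rightward
  sites_m <- rbind(site_row(21500 + 316), site_row(21500 + 317),
                   site_row(21500 + 1000), site_row(21500 + 1001))
  ann_m <- annotate_sites(sites_m, gm)
  expect_equal(ann_m$category,
               c("core_promoter", "promoter", "promoter", "intergenic"))
})

test_that("small-intron background windows follow the offset rule", {
  gm <- hand_genes()
  # gp intron 1: 10601..10650, 50 bp (small); offsets from the 5' end
  sites <- rbind(site_row(10600 + 8), site_row(10600 + 30),
                 site_row(10600 + 7), site_row(10600 + 31),
                 site_row(10600 + 1),   # splice (first 2 intronic bases)
                 site_row(10650))       # splice (last 2 intronic bases)
  ann <- annotate_sites(sites, gm)
  expect_equal(ann$category,
               c("small_intron_bg", "small_intron_bg", "intron_other",
                 "intron_other", "splice_site", "splice_site"))
  # gp intron 2: 10801..11000, 200 bp (not small): offset 8 is plain intron
  expect_equal(annotate_sites(site_row(10800 + 8), gm)$category,
               "intron_other")
  # minus-strand small intron 20701..20760 (60 bp): 5' end is the right end
  sites_m <- rbind(site_row(20760 - 7), site_row(20760 - 29),
                   site_row(20760 - 6), site_row(20760 - 30))
  ann_m <- annotate_sites(sites_m, gm)
  expect_equal(ann_m$category,
               c("small_intron_bg", "small_intron_bg", "intron_other",
                 "intron_other"))
})

test_that("UTRs and precedence resolve as declared", {
  gm <- hand_genes()
  ann <- annotate_sites(rbind(site_row(10050), site_row(12030),
                              site_row(20050), site_row(21450)), gm)
  expect_equal(ann$category, c("utr5", "utr3", "utr3", "utr5"))
  expect_equal(ann$gene_id, c("gp", "gp", "gm", "gm"))
})

test_that("synonymous and non-synonymous codon calls are correct", {
  # gp CDS is TTT repeated: TTT -> TTC (third position) is synonymous Phe;
  # TTT -> ATT (first position) is Phe -> Ile
  gm <- hand_genes()
  # CDS starts at 10101 (offset 0); third codon position at 10103
  syn <- annotate_sites(site_row(10103, ref = "T", alt = "C"), gm)
  expect_equal(syn$category, "coding_syn")
  nonsyn <- annotate_sites(site_row(10101, ref = "T", alt = "A"), gm)
  expect_equal(nonsyn$category, "coding_nonsyn")

  # minus-strand gene: CDS sequence is AAA... (Lys); genomic plus-strand
  # base is T. AAA -> AAG (Lys, synonymous) is genomic T -> C at the
  # codon's third position, which sits leftmost on the plus strand.
  # CDS 5' end is at genomic 21402; third position of codon 1 is 21400.
  syn_m <- annotate_sites(site_row(21400, ref = "T", alt = "C"), gm)
  expect_equal(syn_m$category, "coding_syn")
  nonsyn_m <- annotate_sites(site_row(21402, ref = "T", alt = "G"), gm)
  expect_equal(nonsyn_m$category, "coding_nonsyn")

  # reference mismatching the CDS base: unresolved, logged
  bad <- annotate_sites(site_row(10103, ref = "G", alt = "C"), gm)
  expect_equal(bad$category, "coding_unresolved")
  expect_equal(attr(bad, "unresolved_codon"), 1L)
})

test_that("every SNP gets exactly one category and counts add up", {
  sim <- small_cohort()
  ss <- fst_scan(sim$matrix)
  ann <- annotate_sites(ss, sim$gene_models)
  expect_equal(nrow(ann), nrow(ss))
  expect_false(anyNA(ann$category))
  expect_equal(sum(table(ann$category)), nrow(ss))
  # determinism
  ann2 <- annotate_sites(ss, sim$gene_models)
  expect_identical(ann, ann2)
})

test_that("single-stratum enrichment reduces to the exact Fisher oracle", {
  # 3 category SNPs all in the tier, 3 background SNPs all outside:
  # table [[3,0],[0,3]] -> two-sided p = 2 / C(6,3) = 0.1
  calls <- data.frame(arm = "2L", pos = 1:6 * 10L,
                      category = rep(c("utr5", "small_intron_bg"), each = 3),
                      gene_id = "g1")
  ss <- data.frame(arm = "2L", pos = 1:6 * 10L, maf = 0.2,
                   usable = TRUE, inside_inversion = FALSE,
                   tier = rep(c("top5", "none"), each = 3))
  et <- enrichment_test(calls, ss, tail = 0.05, maf_bins = 1L)
  expect_equal(et$p_fisher, 0.1)
  expect_equal(et$p_cmh, 0.1)   # single stratum falls back to Fisher
  # enumeration oracle: hypergeometric tables {0..3} alt copies
  p_tab <- choose(3, 3) * choose(3, 0) / choose(6, 3)
  expect_equal(et$p_fisher, 2 * p_tab)

  # independence: OR = 1, p = 1
  calls2 <- data.frame(arm = "2L", pos = 1:40 * 10L,
                       category = rep(c("utr5", "small_intron_bg"), each = 20),
                       gene_id = "g1")
  ss2 <- data.frame(arm = "2L", pos = 1:40 * 10L, maf = 0.2, usable = TRUE,
                    inside_inversion = FALSE,
                    tier = rep(c("top5", "none"), times = 20))
  et2 <- enrichment_test(calls2, ss2, tail = 0.05, maf_bins = 1L)
  expect_equal(et2$p_fisher, 1)
  expect_equal(unname(et2$or_fisher), 1, tolerance = 1e-6)
})

test_that("duplicating a stratum leaves the CMH common odds ratio unchanged", {
  set.seed(14)
  n <- 400
  calls <- data.frame(arm = rep("2L", n), pos = 1:n * 10L,
                      category = sample(c("utr5", "small_intron_bg"), n,
                                        replace = TRUE),
                      gene_id = "g1")
  ss <- data.frame(arm = "2L", pos = 1:n * 10L,
                   maf = runif(n, 0.05, 0.5), usable = TRUE,
                   inside_inversion = FALSE,
                   tier = sample(c("top5", "none"), n, TRUE, c(.2, .8)))
  one <- enrichment_test(calls, ss, maf_bins = 2L)
  # duplicate every site onto a second arm: two identical strata per bin
  calls2 <- rbind(calls, transform(calls, arm = "2R"))
  ss2 <- rbind(ss, transform(ss, arm = "2R"))
  two <- enrichment_test(calls2, ss2, maf_bins = 2L)
  expect_equal(two$or_cmh, one$or_cmh, tolerance = 1e-8)
})
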