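test_that("variance components match hand-derived cases", {
  # fixed difference: theta = 1 exactly
  fd <- site_fst_wc(c(10, 0, 0), c(0, 0, 10))
  expect_equal(fd$theta, 1)

  # both populations all-heterozygous (n = 10, p = 0.5, h = 1):
  # a = 0, b = -0.25, c = 0.5, theta = 0
  hh <- site_fst_wc(c(0, 10, 0), c(0, 10, 0))
  expect_equal(hh$a, 0)
  expect_equal(hh$b, -0.25)
  expect_equal(hh$c, 0.5)
  expect_equal(hh$theta, 0)

  # monomorphic in both populations: unusable
  mono <- site_fst_wc(c(10, 0, 0), c(8, 0, 0))
  expect_false(mono$usable)
  expect_true(is.na(mono$theta))

  # estimator is symmetric in population labels
  x <- site_fst_wc(c(3, 4, 5), c(7, 1, 2))
  y <- site_fst_wc(c(7, 1, 2), c(3, 4, 5))
  expect_equal(x$theta, y$theta)
})

test_that("vectorised scan agrees with the brute-force oracle", {
  set.seed(10)
  for (k in 1:300) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    g1 <- sample(0:2, n1, replace = TRUE)
    g2 <- sample(0:2, n2, replace = TRUE)
    oracle <- wc_brute(g1, g2)
    got <- site_fst_wc(
      c(sum(g1 == 0), sum(g1 == 1), sum(g1 == 2)),
      c(sum(g2 == 0), sum(g2 == 1), sum(g2 == 2))
    )
    expect_equal(got$a, oracle$a, tolerance = 1e-12)
    expect_equal(got$b, oracle$b, tolerance = 1e-12)
    expect_equal(got$c, oracle$c, tolerance = 1e-12)
    if (!is.na(oracle$theta)) {
      expect_equal(got$theta, oracle$theta, tolerance = 1e-12)
    }
  }
})

test_that("the scan is invariant to site and strain order", {
  sim <- small_cohort()
  m <- sim$matrix
  ss <- fst_scan(m)
  perm <- sample(nrow(m$strains))
  m2 <- subset_matrix(m, strains = perm)
  ss2 <- fst_scan(m2)
  expect_equal(ss2$theta, ss$theta)

  g1 <- global_fst(m)
  g2 <- global_fst(m2)
  expect_equal(g1$theta, g2$theta)
})

test_that("tier assignment follows the floor(t*n) rank rule and nests", {
  set.seed(11)
  n <- 1000L
  ss <- data.frame(arm = "2L", pos = seq_len(n) * 10L,
                   theta = runif(n), usable = TRUE)
  at <- arm_thresholds(ss)
  expect_equal(sum(at$tier != "none"), floor(0.05 * n))
  expect_equal(sum(in_tier(at$tier, 0.05)), 50)
  expect_equal(sum(in_tier(at$tier, 0.01)), 10)
  expect_equal(sum(in_tier(at$tier, 0.005)), 5)
  # nesting
  expect_true(all(in_tier(at$tier, 0.01) | !in_tier(at$tier, 0.005)))
  expect_true(all(in_tier(at$tier, 0.05) | !in_tier(at$tier, 0.01)))
  # the critical value is the smallest theta inside each tier
  thr5 <- at$thresholds$critical[at$thresholds$tail == 0.05]
  expect_equal(sum(ss$theta >= thr5), 50)
  # ties at the cut broken by earlier genomic position
  ss2 <- data.frame(arm = "2L", pos = c(10L, 20L, 30L, 40L),
                    theta = c(0.5, 0.5, 0.5, 0.5), usable = TRUE)
  at2 <- arm_thresholds(ss2, tails = 0.25)
  expect_identical(which(at2$tier != "none"), 1L)
})

test_that("arm-heterogeneity ANOVA matches a hand computation", {
  # identical value multisets in both groups -> F = 0
  ss <- data.frame(arm = rep(c("2L", "2R"), each = 3),
                   pos = 1:6 * 10L,
                   theta = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), usable = TRUE)
  expect_equal(arm_heterogeneity_anova(ss)$F, 0)

  # oracle: explicit between/within sums of squares
  set.seed(12)
  for (k in 1:20) {
    d <- data.frame(arm = rep(c("a", "b", "c"), times = c(5, 7, 9)),
                    pos = 1:21, theta = rnorm(21), usable = TRUE)
    res <- arm_heterogeneity_anova(d)
    gm <- mean(d$theta)
    ssb <- sum(tapply(d$theta, d$arm, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(d$theta, d$arm, function(v) sum((v - mean(v))^2)))
    Fman <- (ssb / 2) / (ssw / (21 - 3))
    expect_equal(res$F, Fman, tolerance = 1e-10)
  }

  # strong separation: p below machine-level
  d2 <- data.frame(arm = rep(c("a", "b"), each = 3), pos = 1:6,
                   theta = c(0, 0, 1e-3, 1, 1, 1.001), usable = TRUE)
  expect_lt(arm_heterogeneity_anova(d2)$p, 1e-10)
})

test_that("inversion contrast reproduces the exact Mann-Whitney oracle", {
  ss <- data.frame(arm = "2L", pos = c(10L, 20L, 30L, 110L, 120L, 130L),
                   theta = c(1, 2, 3, 4, 5, 6), usable = TRUE)
  region <- list(arm = "2L", start = 1L, end = 100L)
  ic <- inversion_contrast(ss, region)
  # enumeration over the C(6,3) = 20 equally likely assignments: 2 are as
  # extreme as rank-sum 6 -> two-sided p = 2/20 = 0.1
  expect_equal(ic$p, 0.1)
  expect_equal(ic$median_inside, 2)
  expect_equal(ic$median_outside, 5)

  # identical groups: no evidence
  ss$theta <- rep(c(1, 2, 3), 2)
  expect_equal(suppressWarnings(inversion_contrast(ss, region)$p), 1)

  # region swallowing the whole arm is an error
  expect_error(inversion_contrast(ss, list(arm = "2L", start = 1L,
                                           end = 1000L)), "whole arm")
})

test_that("shifted inside-group distributions yield smaller p-values", {
  set.seed(13)
  base <- rnorm(200)
  ps <- vapply(c(0, 0.3, 0.8), function(shift) {
    ss <- data.frame(arm = "2L",
                     pos = c(seq_len(100) * 2L, 1000L + seq_len(100) * 2L),
                     theta = c(base[1:100] + shift, base[101:200]),
                     usable = TRUE)
    inversion_contrast(ss, list(arm = "2L", start = 1L, end = 500L))$p
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("marker-based inversion frequencies hit the planted values", {
  m <- toy_matrix(rbind(c(2L, 2L, 2L), c(0L, 0L, 0L)),
                  rbind(c(2L, 2L), c(0L, 0L)), pos = c(100L, 200L))
  panel <- data.frame(arm = "2L", pos = c(100L, 200L),
                      tag_allele = c("alt", "alt"))
  f <- inversion_frequency(m, panel)
  expect_equal(unname(f$frequency), c(0.5, 0.5))  # one fixed, one absent
  panel1 <- panel[1, ]
  expect_equal(unname(inversion_frequency(m, panel1)$frequency), c(1, 1))
  panel2 <- panel[2, ]
  expect_equal(unname(inversion_frequency(m, panel2)$frequency), c(0, 0))
})
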