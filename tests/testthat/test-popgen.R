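test_that("allele frequencies count gene copies and flag empty loci", {
  gt <- multi_locus_gt(list(L1 = rbind(c(1, 1), c(1, 2)),
                            L2 = rbind(c(NA, NA), c(NA, NA))),
                       role = "adult")
  af <- allele_frequencies(gt)
  expect_equal(af$freqs$L1, c("1" = 0.75, "2" = 0.25))
  expect_equal(af$n_copies[["L1"]], 4L)
  expect_equal(af$empty_loci, "L2")
  expect_length(af$freqs$L2, 0L)
  # frequencies sum to 1 per (non-empty) locus
  expect_equal(sum(af$freqs$L1), 1, tolerance = 1e-12)
  # uniform_minimal gives equal weight per observed allele
  afu <- allele_frequencies(gt, mode = "uniform_minimal")
  expect_equal(unname(afu$freqs$L1), c(0.5, 0.5))
})

test_that("frequency estimates converge to truth under binomial sampling", {
  set.seed(41)
  p_true <- c(0.5, 0.3, 0.2)
  n <- 400L
  draws <- matrix(sample.int(3L, 2L * n, replace = TRUE, prob = p_true), n, 2L)
  gt <- one_locus_gt(cbind(pmin(draws[, 1], draws[, 2]), pmax(draws[, 1], draws[, 2])),
                     role = "adult")
  af <- allele_frequencies(gt)
  se <- sqrt(p_true * (1 - p_true) / (2 * n))
  expect_true(all(abs(af$freqs$L1 - p_true) < 3 * se))
})

test_that("heterozygosities follow the unbiased estimator", {
  gt <- one_locus_gt(rbind(c(1, 1), c(2, 2)), role = "adult")
  h <- heterozygosities(gt)
  expect_equal(h$ho, 0)
  expect_equal(h$he, (4 / 3) * 0.5, tolerance = 1e-12)
  # all heterozygous at a biallelic locus
  gt2 <- one_locus_gt(matrix(rep(c(1L, 2L), each = 10L), ncol = 2L), role = "adult")
  expect_equal(heterozygosities(gt2)$ho, 1)
  # uncorrected form on request
  expect_equal(heterozygosities(gt, unbiased = FALSE)$he, 0.5)
  # invariant under allele relabelling
  gt3 <- one_locus_gt(rbind(c(7, 7), c(9, 9)), role = "adult")
  expect_equal(heterozygosities(gt3)$he, h$he)
  # n < 2 flagged undefined
  gt4 <- one_locus_gt(rbind(c(1, 2), c(NA, NA)), role = "adult")
  h4 <- heterozygosities(gt4)
  expect_true(is.na(h4$he))
  expect_equal(attr(h4, "undefined_loci"), "L1")
})

test_that("HWE exact test: monomorphic, extreme heterozygote excess, seeding", {
  gt_mono <- one_locus_gt(matrix(1L, 20L, 2L), role = "adult")
  p <- hwe_exact_test(gt_mono, "L1")
  expect_equal(as.numeric(p), 1)
  expect_equal(attr(p, "method"), "monomorphic")
  # 20 individuals all heterozygous, p = q: strong HWE deviation
  gt_het <- one_locus_gt(matrix(rep(c(1L, 2L), each = 20L), ncol = 2L), role = "adult")
  p2 <- hwe_exact_test(gt_het, "L1")
  expect_equal(attr(p2, "method"), "enumeration")
  expect_lt(as.numeric(p2), 0.001)
  # Monte-Carlo path is bit-reproducible under a fixed seed
  g <- matrix(c(1L, 1L, 2L, 3L, 1L, 2L, 2L, 3L, 3L, 3L,
                1L, 3L, 2L, 2L, 1L, 1L, 2L, 3L, 1L, 2L), 10L, 2L)
  gt3 <- one_locus_gt(cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2])), role = "adult")
  pa <- hwe_exact_test(gt3, "L1", mc_reps = 2000L, seed = 99L)
  pb <- hwe_exact_test(gt3, "L1", mc_reps = 2000L, seed = 99L)
  expect_identical(as.numeric(pa), as.numeric(pb))
  expect_equal(attr(pa, "method"), "monte_carlo")
  expect_error(hwe_exact_test(one_locus_gt(matrix(1L, 3L, 2L), role = "adult"), "L1"),
               "fewer than 5")
})

test_that("HWE p-values are calibrated under the null", {
  set.seed(17)
  ps <- replicate(200L, {
    g <- matrix(sample.int(4L, 80L, replace = TRUE), 40L, 2L)
    gt <- one_locus_gt(cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2])), role = "adult")
    as.numeric(hwe_exact_test(gt, "L1", mc_reps = 1200L, seed = sample.int(1e6, 1L)))
  })
  # exact conditional test: close to uniform, at most mildly conservative
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.62)
  expect_lte(mean(ps <= 0.05), 0.09)
})

test_that("parent-pair exclusion matches the brute-force enumeration oracle", {
  # frozen oracle value for a biallelic locus, p = 0.5 (27 genotype combos)
  expect_equal(oracle_exclusion(c(0.5, 0.5)), 0.28125, tolerance = 1e-12)
  af <- make_freqs(list(L1 = c("1" = 0.5, "2" = 0.5)))
  expect_equal(unname(exclusion_probability(af)$per_locus), 0.28125, tolerance = 1e-12)
  # skewed and triallelic cases against the oracle
  for (p in list(c(0.9, 0.1), c(0.5, 0.3, 0.2), c(0.25, 0.25, 0.25, 0.25))) {
    names(p) <- seq_along(p)
    af_p <- make_freqs(list(L1 = p))
    expect_equal(unname(exclusion_probability(af_p)$per_locus), oracle_exclusion(p),
                 tolerance = 1e-10)
  }
  # single allele -> 0; combined over zero-power loci -> 0
  af0 <- make_freqs(list(L1 = c("1" = 1), L2 = c("9" = 1)))
  e0 <- exclusion_probability(af0)
  expect_equal(unname(e0$per_locus), c(0, 0))
  expect_equal(e0$combined, 0)
})

test_that("exclusion power is non-decreasing in the number of equifrequent alleles", {
  vals <- vapply(2:10, function(k) {
    p <- stats::setNames(rep(1 / k, k), seq_len(k))
    unname(exclusion_probability(make_freqs(list(L1 = p)))$per_locus)
  }, 0)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("first- and second-parent exclusion forms are ordered sensibly", {
  p <- stats::setNames(rep(0.125, 8L), 1:8)
  af <- make_freqs(list(L1 = p))
  e1 <- unname(exclusion_probability(af, "first_parent")$per_locus)
  e2 <- unname(exclusion_probability(af, "second_parent")$per_locus)
  ep <- unname(exclusion_probability(af, "parent_pair")$per_locus)
  # knowing one parent helps; excluding a pair is easier still
  expect_lt(e1, e2)
  expect_lt(e2, ep)
})

test_that("haplotype diversity follows the corrected gene-diversity formula", {
  expect_equal(haplotype_diversity(c(a = "H1", b = "H1", c = "H2", d = "H2")),
               (4 / 3) * 0.5, tolerance = 1e-12)
  expect_equal(haplotype_diversity(rep("H1", 10L)), 0)
  expect_error(haplotype_diversity(c(a = "H1")), "fewer than 2")
  ht <- haplotype_table(c(x = "H1", y = "H2"))
  expect_equal(haplotype_diversity(ht), 1)
})

test_that("marker summary reports per-locus stats and panel means", {
  set.seed(5)
  panel <- test_panel(4L, 6L)
  d <- generate_dataset(population_model(panel, n_adults = 40L),
                        mating_design(list(list(clutch_id = "C1", year = 2019L,
                                                matings = data.frame(dam = "F", sire = "M", n = 3L)))),
                        seed = 8L)
  ms <- marker_summary(d$gt, mc_reps = 500L)
  expect_equal(nrow(ms$per_locus), 4L)
  expect_true(all(ms$per_locus$ho >= 0 & ms$per_locus$ho <= 1))
  expect_true(all(ms$per_locus$he >= 0 & ms$per_locus$he <= 1))
  expect_true(all(ms$per_locus$p_hwe >= 0 & ms$per_locus$p_hwe <= 1))
  expect_equal(ms$panel$mean[ms$panel$stat == "ho"], mean(ms$per_locus$ho))
  expect_gt(ms$combined_exclusion, 0.9)
})
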