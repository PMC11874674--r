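test_that("IBD pair probabilities match hand-enumerated values", {
  p <- c("1" = 0.5, "2" = 0.5)
  # (A/A, A/A) at p = 0.5: enumerating parental/IBD configurations gives
  # P0 = 0.0625, P1 = 0.125, P2 = 0.25
  expect_equal(unname(ibd_pair_probs(c(1, 1), c(1, 1), p)),
               c(0.0625, 0.125, 0.25), tolerance = 1e-12)
  # P2 vanishes whenever the genotypes differ
  expect_equal(unname(ibd_pair_probs(c(1, 1), c(1, 2), p))[3L], 0)
  expect_equal(unname(ibd_pair_probs(c(1, 2), c(2, 1), p))[3L], 0.5)  # same unordered genotype
  expect_error(ibd_pair_probs(c(1, 3), c(1, 1), p), "absent")
})

test_that("pair probabilities normalise over all genotype pairs for k <= 4", {
  set.seed(2)
  for (k in 2:4) {
    p <- stats::setNames(as.numeric(stats::rgamma(k, 2)), seq_len(k))
    p <- p / sum(p)
    gs <- list()
    for (i in seq_len(k)) for (j in i:k) gs[[length(gs) + 1L]] <- c(i, j)
    tot <- c(0, 0, 0)
    sym <- TRUE
    for (g1 in gs) for (g2 in gs) {
      P <- ibd_pair_probs(g1, g2, p)
      tot <- tot + P
      Pr <- ibd_pair_probs(g2, g1, p)
      # UR/HS/FS probabilities are analytically symmetric in the pair
      if (max(abs(P - Pr)) > 1e-12) sym <- FALSE
    }
    expect_equal(unname(tot), c(1, 1, 1), tolerance = 1e-10)
    expect_true(sym)
  }
})

test_that("dyad log-likelihoods match closed forms and skip missing loci", {
  p <- c("1" = 0.5, "2" = 0.5)
  af <- make_freqs(list(L1 = p, L2 = p))
  gt <- multi_locus_gt(list(L1 = rbind(c(1, 1), c(1, 1)),
                            L2 = rbind(c(1, 2), c(NA, NA))))
  # L2 jointly missing -> only L1 contributes
  expect_equal(dyad_loglik(gt, "E1", "E2", "FS", af), log(0.140625), tolerance = 1e-12)
  # UR likelihood is the product of the genotype probabilities
  expect_equal(dyad_loglik(gt, "E1", "E2", "UR", af), log(0.25 * 0.25), tolerance = 1e-12)
  # symmetric in the pair
  for (h in c("UR", "HS", "FS", "PO"))
    expect_equal(dyad_loglik(gt, "E1", "E2", h, af), dyad_loglik(gt, "E2", "E1", h, af))
  gt_allmiss <- multi_locus_gt(list(L1 = rbind(c(1, 1), c(NA, NA)),
                                    L2 = rbind(c(NA, NA), c(1, 2))))
  expect_error(dyad_loglik(gt_allmiss, "E1", "E2", "FS", af), "no jointly informative")
})

test_that("simulated full sibs are likelier under FS than UR on average", {
  set.seed(31)
  pop <- build_population(population_model(test_panel(10L, 6L), n_adults = 0L))
  af <- make_freqs(pop$freqs)
  diff_fs <- replicate(40L, {
    dam <- lapply(pop$freqs, function(p) sort(sample(as.integer(names(p)), 2L,
                                                     replace = TRUE, prob = p)))
    sire <- lapply(pop$freqs, function(p) sort(sample(as.integer(names(p)), 2L,
                                                      replace = TRUE, prob = p)))
    off <- mate(dam, sire, 2L, pop$freqs)
    gt <- multi_locus_gt(off)
    dyad_loglik(gt, "E1", "E2", "FS", af) - dyad_loglik(gt, "E1", "E2", "UR", af)
  })
  expect_gt(mean(diff_fs), 0)
})

test_that("LR test rejects UR for identical multilocus genotypes with rare alleles", {
  freqs <- lapply(seq_len(17L), function(i)
    stats::setNames(c(0.05, 0.05, 0.45, 0.45), 1:4))
  names(freqs) <- paste0("L", seq_len(17L))
  af <- make_freqs(freqs)
  # both embryos homozygous for the rare allele everywhere
  calls <- lapply(freqs, function(p) rbind(c(1L, 1L), c(1L, 1L)))
  gt <- multi_locus_gt(calls)
  p <- lr_test(gt, "E1", "E2", "FS", "UR", af, n_sims = 2000L, seed = 3L)
  expect_lt(as.numeric(p), 0.05)
  expect_error(lr_test(gt, "E1", "E2", "FS", "FS", af), "must differ")
  expect_error(lr_test(gt, "E1", "E2", "FS", "UR", af, n_sims = 0L), "positive")
  expect_true(attr(lr_test(gt, "E1", "E2", "FS", "UR", af, n_sims = 50L, seed = 1L),
                   "low_precision"))
})

test_that("LR p-values are reproducible and order-independent via dyad substreams", {
  set.seed(12)
  pop <- build_population(population_model(test_panel(6L, 6L), n_adults = 30L))
  des <- mating_design(list(list(clutch_id = "C1", year = 2019L,
                                 matings = data.frame(dam = "F", sire = "M", n = 3L))))
  d <- generate_dataset(population_model(test_panel(6L, 6L), n_adults = 30L), des, seed = 4L)
  af <- extend_frequencies(allele_frequencies(d$gt), d$gt)
  d1 <- classify_dyads(d$gt, af, n_sims = 300L, seed = 7L)
  d2 <- classify_dyads(d$gt, af, n_sims = 300L, seed = 7L)
  expect_identical(d1, d2)
  # reversing embryo order leaves each dyad's p-value unchanged
  ids <- rev(d$gt$samples$sample_id)
  gt_rev <- subset_samples(d$gt, ids)
  d3 <- classify_dyads(gt_rev, af, n_sims = 300L, seed = 7L)
  key <- function(x) paste(pmin(x$id1, x$id2), pmax(x$id1, x$id2))
  m <- match(key(d1), key(d3))
  expect_equal(d1$p_second, d3$p_second[m])
})

test_that("dyad classification labels sibs, folds PO, and flags ties", {
  set.seed(21)
  panel <- test_panel(12L, 8L)
  des <- mating_design(list(
    list(clutch_id = "C1", year = 2019L,
         matings = data.frame(dam = "F1", sire = c("M1", "M2"), n = c(2L, 2L))),
    list(clutch_id = "C2", year = 2019L,
         matings = data.frame(dam = "F2", sire = "M3", n = 2L))))
  d <- generate_dataset(population_model(panel, n_adults = 60L), des, seed = 19L)
  af <- extend_frequencies(allele_frequencies(d$gt), d$gt)
  dy <- classify_dyads(d$gt, af, n_sims = 500L, seed = 2L)
  # within-clutch mode: no cross-clutch dyads
  expect_true(all(dy$clutch1 == dy$clutch2))
  expect_equal(nrow(dy), 6L + 1L)  # C(4,2) + C(2,2)
  # full sibs of C2 classified FS (PO folds into FS if it tops the likelihood)
  c2 <- dy[dy$clutch1 == "C2", ]
  expect_equal(c2$ml_label, "FS")
  # tie annotation has the "X or Y" shape exactly when p_second > 0.05
  tied <- !is.na(dy$p_second) & dy$p_second > 0.05
  expect_equal(grepl(" or ", dy$annotation), tied)
  # clutch of one embryo yields an empty dyad table
  solo <- subset_samples(d$gt, c("C2.A"))
  expect_equal(nrow(classify_dyads(solo, af)), 0L)
})
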