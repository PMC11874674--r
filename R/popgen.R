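#' Allele frequencies from a genotype table
#'
#' Empirical mode counts gene copies over non-missing calls in the chosen
#' subset (typically the adult reference sample). The `uniform_minimal` mode
#' gives every observed allele equal weight 1/N_A; it is the probability-model
#' counterpart of running sibship reconstruction with all allele frequencies
#' forced to a flat nominal value, which minimises presumptions of allele
#' sharing between inferred parents.
#'
#' @param gt a `genotype_table`
#' @param subset sample ids to count over (default: all adults, or everyone
#'   if no adults are present)
#' @param mode "empirical" or "uniform_minimal"
#' @return an `allele_freqs` object: list with `freqs` (per locus, named
#'   numeric summing to 1), `n_copies` (gene copies counted), `mode` and
#'   `empty_loci` (loci with zero non-missing calls, whose map is empty)
#' @export
allele_frequencies <- function(gt, subset = NULL, mode = c("empirical", "uniform_minimal")) {
  mode <- match.arg(mode)
  if (is.null(subset)) {
    subset <- gt$samples$sample_id[gt$samples$role == "adult"]
    if (!length(subset)) subset <- gt$samples$sample_id
  }
  if (!length(subset)) stop("empty subset")
  idx <- match(as.character(subset), gt$samples$sample_id)
  if (anyNA(idx)) stop("subset contains unknown sample ids")
  freqs <- list(); n_copies <- integer(length(gt$loci)); names(n_copies) <- gt$loci
  empty <- character(0)
  for (l in gt$loci) {
    m <- gt$calls[[l]][idx, , drop = FALSE]
    v <- as.vector(m[!is.na(m[, 1L]), , drop = FALSE])
    n_copies[[l]] <- length(v)
    if (!length(v)) {
      freqs[[l]] <- stats::setNames(numeric(0), character(0))
      empty <- c(empty, l)
      next
    }
    if (mode == "empirical") {
      tab <- table(v)
      freqs[[l]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    } else {
      a <- sort(unique(v))
      freqs[[l]] <- stats::setNames(rep(1 / length(a), length(a)), a)
    }
  }
  structure(list(freqs = freqs, n_copies = n_copies, mode = mode, empty_loci = empty),
            class = "allele_freqs")
}

#' Floor-extend allele frequencies with alleles seen only in embryos
#'
#' Alleles present in `gt` but absent from the frequency map get a floor
#' frequency 1/(2n+1), where n is the number of individuals behind the map;
#' each locus is then renormalised. Avoids zero likelihoods for embryo
#' alleles unseen in the adult reference sample.
#'
#' @param af an `allele_freqs`
#' @param gt a `genotype_table` whose observed alleles must be representable
#' @return an `allele_freqs`
#' @export
extend_frequencies <- function(af, gt) {
  for (l in intersect(names(af$freqs), gt$loci)) {
    p <- af$freqs[[l]]
    seen <- gt$alleles[[l]]
    new <- setdiff(as.character(seen), names(p))
    if (length(new)) {
      floor_p <- 1 / (max(af$n_copies[[l]], 2L) + 1)
      p <- c(p, stats::setNames(rep(floor_p, length(new)), new))
      p <- p / sum(p)
      af$freqs[[l]] <- p
    }
  }
  af
}

#' Observed and expected heterozygosity per locus
#'
#' He uses the small-sample (unbiased) estimator 2n/(2n-1) * (1 - sum p^2)
#' with n the number of diploid individuals scored at the locus; set
#' `unbiased = FALSE` for the uncorrected form.
#'
#' @param gt a `genotype_table`
#' @param subset sample ids (default adults, or all if no adults)
#' @param unbiased logical
#' @return data.frame with columns `locus`, `n`, `n_alleles`, `ho`, `he`;
#'   loci with fewer than two scored individuals get `NA` and are flagged in
#'   attribute "undefined_loci"
#' @export
heterozygosities <- function(gt, subset = NULL, unbiased = TRUE) {
  if (is.null(subset)) {
    subset <- gt$samples$sample_id[gt$samples$role == "adult"]
    if (!length(subset)) subset <- gt$samples$sample_id
  }
  idx <- match(as.character(subset), gt$samples$sample_id)
  if (anyNA(idx)) stop("subset contains unknown sample ids")
  undef <- character(0)
  rows <- lapply(gt$loci, function(l) {
    m <- gt$calls[[l]][idx, , drop = FALSE]
    m <- m[!is.na(m[, 1L]), , drop = FALSE]
    n <- nrow(m)
    if (n < 2L) {
      undef <<- c(undef, l)
      return(data.frame(locus = l, n = n, n_alleles = NA_integer_,
                        ho = NA_real_, he = NA_real_))
    }
    p <- as.numeric(table(as.vector(m))) / (2 * n)
    he <- 1 - sum(p^2)
    if (unbiased) he <- he * (2 * n) / (2 * n - 1)
    data.frame(locus = l, n = n, n_alleles = length(p),
               ho = mean(m[, 1L] != m[, 2L]), he = he)
  })
  out <- do.call(rbind, rows)
  attr(out, "undefined_loci") <- undef
  out
}

# log conditional probability (up to an additive constant in the allele
# counts) of a genotype count table under HWE: n_het*log2 - sum(log(n_gg!))
.hwe_log_table_prob <- function(pairs) {
  het <- pairs[, 1L] != pairs[, 2L]
  key <- paste(pairs[, 1L], pairs[, 2L])
  sum(het) * log(2) - sum(lgamma(table(key) + 1))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype table given the observed allele
#' counts. Biallelic loci are evaluated by complete enumeration over the
#' possible heterozygote counts; multiallelic loci by Monte-Carlo sampling of
#' i.i.d. genotype tables obtained by random pairing of the observed gene
#' copies (an exact draw from the null distribution). The p-value is the
#' null probability of tables no more probable than the observed one.
#'
#' @param gt a `genotype_table`
#' @param locus locus name
#' @param subset sample ids (default adults, or all)
#' @param mc_reps Monte-Carlo replicates for multiallelic loci
#' @param seed integer seed making the Monte-Carlo p-value reproducible
#' @return p-value in [0, 1], with attribute "method" ("enumeration",
#'   "monte_carlo" or "monomorphic")
#' @export
hwe_exact_test <- function(gt, locus, subset = NULL, mc_reps = 10000L, seed = 1L) {
  if (is.null(subset)) {
    subset <- gt$samples$sample_id[gt$samples$role == "adult"]
    if (!length(subset)) subset <- gt$samples$sample_id
  }
  m <- locus_calls(gt, locus, subset)
  m <- m[!is.na(m[, 1L]), , drop = FALSE]
  n <- nrow(m)
  if (n < 5L) stop("fewer than 5 scored individuals at ", locus)
  alleles <- sort(unique(as.vector(m)))
  if (length(alleles) < 2L)
    return(structure(1.0, method = "monomorphic"))
  obs <- .hwe_log_table_prob(m)
  tol <- 1e-9
  if (length(alleles) == 2L) {
    nA <- sum(m == alleles[1L])
    # tables indexed by heterozygote count h with h = nA (mod 2)
    hs <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
    lp <- vapply(hs, function(h) {
      naa <- (nA - h) / 2; nbb <- n - naa - h
      h * log(2) - (lgamma(naa + 1) + lgamma(h + 1) + lgamma(nbb + 1))
    }, 0)
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    p <- sum(pr[lp <= obs + tol])
    return(structure(min(1, p), method = "enumeration"))
  }
  copies <- as.vector(m)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(mc_reps)) {
    perm <- sample(copies)
    sim <- matrix(perm, ncol = 2L)
    sw <- sim[, 1L] > sim[, 2L]
    tmp <- sim[sw, 1L]; sim[sw, 1L] <- sim[sw, 2L]; sim[sw, 2L] <- tmp
    if (.hwe_log_table_prob(sim) <= obs + tol) hits <- hits + 1L
  }
  structure((hits + 1) / (mc_reps + 1), method = "monte_carlo")
}

# P(a random individual's genotype carries allele x) under HWE
.carry_prob <- function(p) 1 - (1 - p)^2

#' Exclusion probabilities of a marker panel
#'
#' `parent_pair` (the default; no candidate parents are sampled in a
#' progeny-array design): the probability that a random non-parental pair is
#' Mendelian-incompatible with a random offspring. `first_parent`: a random
#' individual excluded as a parent when no parent is known. `second_parent`:
#' a random individual excluded as the second parent when one true parent is
#' known. All are exact sums over genotype combinations under HWE.
#'
#' @param af an `allele_freqs`
#' @param form which exclusion probability
#' @return list with `per_locus` (named numeric; loci with a single allele
#'   give 0) and `combined` = 1 - prod(1 - P_l)
#' @export
exclusion_probability <- function(af, form = c("parent_pair", "first_parent", "second_parent")) {
  form <- match.arg(form)
  per <- vapply(names(af$freqs), function(l) {
    p <- af$freqs[[l]]
    if (length(p) < 2L) return(0)
    k <- length(p)
    i <- rep(seq_len(k), each = k); j <- rep(seq_len(k), k)
    keep <- i <= j
    i <- i[keep]; j <- j[keep]
    pO <- ifelse(i == j, p[i]^2, 2 * p[i] * p[j])       # offspring genotype under HWE
    if (form == "parent_pair") {
      ci <- .carry_prob(p[i]); cj <- .carry_prob(p[j])
      compat <- ifelse(i == j, ci^2, 2 * ci * cj - (2 * p[i] * p[j])^2)
      sum(pO * (1 - compat))
    } else if (form == "first_parent") {
      share <- ifelse(i == j, .carry_prob(p[i]), 1 - (1 - p[i] - p[j])^2)
      sum(pO * (1 - share))
    } else {
      # enumerate (mother genotype, maternal allele, paternal allele); a
      # candidate father is excluded iff he carries no allele that could be
      # the paternal contribution to the offspring given this mother
      tot <- 0
      for (a in seq_len(k)) for (b in a:k) {
        pm <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
        mgs <- if (a == b) a else c(a, b)
        for (o in seq_len(k)) {
          for (mg in mgs) {
            w <- pm * p[o] / length(mgs)
            # offspring {mg, o}: paternal allele may be o, or mg if the
            # mother also carries o (roles of the two alleles swappable)
            R <- if (o %in% c(a, b)) unique(c(o, mg)) else o
            tot <- tot + w * (1 - sum(p[R]))^2
          }
        }
      }
      tot
    }
  }, 0)
  list(per_locus = per, combined = 1 - prod(1 - per))
}

#' Haplotype diversity
#'
#' Hd = n/(n-1) * (1 - sum p_i^2) over haplotype frequencies; the probability
#' that two randomly drawn sequences differ, with small-sample correction.
#'
#' @param ht a `haplotype_table`, or a character vector of haplotype labels
#' @param subset optional sample ids to restrict to
#' @return Hd in [0, 1]
#' @export
haplotype_diversity <- function(ht, subset = NULL) {
  labs <- if (inherits(ht, "haplotype_table")) ht$haplotype_of else ht
  if (!is.null(subset)) labs <- labs[as.character(subset)]
  labs <- labs[!is.na(labs)]
  n <- length(labs)
  if (n < 2L) stop("haplotype diversity undefined for fewer than 2 samples")
  p <- as.numeric(table(labs)) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Marker panel summary table
#'
#' One row per locus (sample size, allele count, size range, Ho, He, HWE
#' p-value) plus panel means and standard errors (sd/sqrt(L) over L loci) and
#' the combined exclusion probability; the shape of a standard
#' marker-characteristics table.
#'
#' @param gt a `genotype_table`
#' @param subset reference sample ids (default adults)
#' @param mc_reps,seed passed to [hwe_exact_test()]
#' @param exclusion_form passed to [exclusion_probability()]
#' @return list with `per_locus` (data.frame), `panel` (means/SEs) and
#'   `combined_exclusion`
#' @export
marker_summary <- function(gt, subset = NULL, mc_reps = 10000L, seed = 1L,
                           exclusion_form = "parent_pair") {
  het <- heterozygosities(gt, subset)
  af <- allele_frequencies(gt, subset, mode = "empirical")
  size_rng <- t(vapply(gt$loci, function(l) {
    a <- as.integer(names(af$freqs[[l]]))
    if (!length(a)) c(NA_integer_, NA_integer_) else range(a)
  }, integer(2)))
  p_hwe <- vapply(seq_along(gt$loci), function(i) {
    l <- gt$loci[[i]]
    if (is.na(het$ho[i])) return(NA_real_)
    as.numeric(hwe_exact_test(gt, l, subset, mc_reps = mc_reps, seed = seed + i))
  }, 0)
  per <- data.frame(locus = gt$loci, n = het$n, n_alleles = het$n_alleles,
                    size_min = size_rng[, 1L], size_max = size_rng[, 2L],
                    ho = het$ho, he = het$he, p_hwe = p_hwe)
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  panel <- data.frame(
    stat = c("n_alleles", "ho", "he"),
    mean = c(mean(per$n_alleles, na.rm = TRUE), mean(per$ho, na.rm = TRUE),
             mean(per$he, na.rm = TRUE)),
    se = c(se(per$n_alleles), se(per$ho), se(per$he)))
  excl <- exclusion_probability(af, form = exclusion_form)
  list(per_locus = per, panel = panel, combined_exclusion = excl$combined)
}
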