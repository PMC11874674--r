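# shared fixtures and independent brute-force oracles

# single-locus genotype table from an n x 2 allele matrix (embryos, one clutch)
one_locus_gt <- function(calls, clutch = "C1", role = "embryo") {
  n <- nrow(calls)
  samples <- data.frame(sample_id = paste0("E", seq_len(n)),
                        clutch_id = if (role == "embryo") clutch else NA,
                        year = 2019L, role = role, stringsAsFactors = FALSE)
  genotype_table(samples, list(L1 = calls))
}

# multi-locus table: `calls` is a named list of n x 2 matrices
multi_locus_gt <- function(calls, clutch = "C1", role = "embryo") {
  n <- nrow(calls[[1L]])
  samples <- data.frame(sample_id = paste0("E", seq_len(n)),
                        clutch_id = if (role == "embryo") clutch else NA,
                        year = 2019L, role = role, stringsAsFactors = FALSE)
  genotype_table(samples, calls)
}

# allele_freqs object from a named list of named numeric vectors
make_freqs <- function(freqs, n = 81L) {
  structure(list(freqs = freqs,
                 n_copies = stats::setNames(rep(2L * n, length(freqs)), names(freqs)),
                 mode = "empirical", empty_loci = character(0)),
            class = "allele_freqs")
}

# ---- oracle: parent-pair exclusion by full enumeration ----------------------
# enumerates every (parent1, parent2, offspring) genotype combination at one
# locus and sums the probability that the offspring cannot be produced
oracle_exclusion <- function(p) {
  k <- length(p)
  gtypes <- list()
  for (i in seq_len(k)) for (j in i:k) gtypes[[length(gtypes) + 1L]] <- c(i, j)
  pg <- vapply(gtypes, function(g) if (g[1L] == g[2L]) p[g[1L]]^2 else 2 * p[g[1L]] * p[g[2L]], 0)
  can_make <- function(g1, g2, o) {
    for (a in g1) for (b in g2) if (all(sort(c(a, b)) == o)) return(TRUE)
    FALSE
  }
  excl <- 0
  for (oi in seq_along(gtypes)) {
    p_incomp <- 0
    for (i in seq_along(gtypes)) for (j in seq_along(gtypes)) {
      if (!can_make(gtypes[[i]], gtypes[[j]], gtypes[[oi]]))
        p_incomp <- p_incomp + pg[i] * pg[j]
    }
    excl <- excl + pg[oi] * p_incomp
  }
  excl
}

# ---- oracle: minimum parent count by exhaustive enumeration -----------------
# enumerates every embryo -> parent-pair assignment for P = 2, 3, ... and
# checks Mendelian feasibility by direct enumeration of parental genotypes
# over observed alleles plus an untransmitted wildcard (allele 0)
oracle_min_parents <- function(geno_list, n, p_max = 6L) {
  locus_feasible <- function(g, pairs) {
    scored <- !is.na(g[, 1L])
    if (!any(scored)) return(TRUE)
    parents <- sort(unique(as.vector(pairs[scored, , drop = FALSE])))
    alleles <- sort(unique(as.vector(g[scored, , drop = FALSE])))
    au <- c(0L, alleles)  # 0 = wildcard (transmitted to no sampled offspring)
    gset <- list()
    for (i in seq_along(au)) for (j in i:length(au))
      gset[[length(gset) + 1L]] <- c(au[i], au[j])
    ok_row <- function(gr, g1, g2) {
      for (a in g1) for (b in g2)
        if (a != 0L && b != 0L && all(sort(c(a, b)) == gr)) return(TRUE)
      FALSE
    }
    assigned <- vector("list", length(parents))
    dfs <- function(d) {
      if (d > length(parents)) return(TRUE)
      for (gp in gset) {
        assigned[[d]] <<- gp
        fail <- FALSE
        for (r in which(scored)) {
          i1 <- match(pairs[r, 1L], parents); i2 <- match(pairs[r, 2L], parents)
          if (i1 <= d && i2 <= d &&
              !ok_row(g[r, ], assigned[[i1]], assigned[[i2]])) { fail <- TRUE; break }
        }
        if (!fail && dfs(d + 1L)) return(TRUE)
      }
      FALSE
    }
    dfs(1L)
  }
  feasible <- function(pairs) {
    for (g in geno_list) if (!locus_feasible(g, pairs)) return(FALSE)
    TRUE
  }
  for (P in 2L:p_max) {
    prs <- utils::combn(P, 2L)
    npair <- ncol(prs)
    idx <- rep(1L, n)
    repeat {
      pairs <- t(prs[, idx, drop = FALSE])
      if (feasible(pairs)) return(P)
      j <- n
      while (j >= 1L && idx[j] == npair) { idx[j] <- 1L; j <- j - 1L }
      if (j < 1L) break
      idx[j] <- idx[j] + 1L
    }
  }
  NA_integer_
}

# quick equifrequent study-like panel for simulations in tests
test_panel <- function(n_loci = 10L, k = 8L) {
  lapply(seq_len(n_loci), function(i) locus_def(paste0("L", i), k, "equifrequent"))
}
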