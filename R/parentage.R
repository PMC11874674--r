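# ---- internal combinatorial machinery -------------------------------------
#
# A parent is represented by its per-locus "transmission set": the (at most
# two) alleles it passes to sampled offspring. A parent may additionally
# carry an untransmitted wildcard allele, so size-1 sets stand for genotypes
# (a, a) or (a, x) with x unobserved. An offspring genotype {u, v} is
# explained by parents with sets T1, T2 iff it can be split with one allele
# drawn from each set.

# all subsets of size 1 or 2 of an allele vector
.subsets12 <- function(a) {
  out <- lapply(a, function(x) x)
  if (length(a) >= 2L) {
    cmb <- utils::combn(a, 2L)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

# can every offspring row of g (m x 2, no NA) be split across T1 / T2?
.rows_split_ok <- function(g, T1, T2) {
  in11 <- g[, 1L] %in% T1; in12 <- g[, 2L] %in% T2
  in21 <- g[, 2L] %in% T1; in22 <- g[, 1L] %in% T2
  all((in11 & in12) | (in21 & in22))
}

# full-sib compatibility of a set of rows at one locus; returns FALSE, or a
# list of witness transmission-set pairs (possibly the sentinel "free" when
# the locus carries no data for these rows)
.locus_fs_witnesses <- function(g) {
  g <- g[!is.na(g[, 1L]), , drop = FALSE]
  if (!nrow(g)) return("free")
  a <- sort(unique(as.vector(g)))
  if (length(a) > 4L) return(FALSE)
  subs <- .subsets12(a)
  wit <- list()
  for (i in seq_along(subs)) for (j in i:length(subs)) {
    if (.rows_split_ok(g, subs[[i]], subs[[j]]))
      wit[[length(wit) + 1L]] <- list(subs[[i]], subs[[j]])
  }
  if (length(wit)) wit else FALSE
}

# fast boolean version with early exit
.locus_fs_ok <- function(g) {
  g <- g[!is.na(g[, 1L]), , drop = FALSE]
  if (!nrow(g)) return(TRUE)
  a <- sort(unique(as.vector(g)))
  if (length(a) > 4L) return(FALSE)
  subs <- .subsets12(a)
  for (i in seq_along(subs)) for (j in i:length(subs))
    if (.rows_split_ok(g, subs[[i]], subs[[j]])) return(TRUE)
  FALSE
}

.fs_ok_rows <- function(geno, rows) {
  for (g in geno) if (!.locus_fs_ok(g[rows, , drop = FALSE])) return(FALSE)
  TRUE
}

# necessary condition for one parent shared by the given rows: at each locus
# some <=2-allele set intersects every row's genotype
.cover_ok_rows <- function(geno, rows) {
  for (gl in geno) {
    g <- gl[rows, , drop = FALSE]
    g <- g[!is.na(g[, 1L]), , drop = FALSE]
    if (!nrow(g)) next
    a <- sort(unique(as.vector(g)))
    found <- FALSE
    for (S in .subsets12(a)) {
      if (all(g[, 1L] %in% S | g[, 2L] %in% S)) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# joint Mendelian feasibility of a full pedigree structure at one locus.
# g: n x 2 (NA = missing), pairs: n x 2 parent indices.
# Returns FALSE or a named list parent -> transmission set ("free" parents,
# with no scored offspring, are omitted).
.locus_pedigree_witness <- function(g, pairs) {
  scored <- !is.na(g[, 1L])
  if (!any(scored)) return(list())
  parents <- sort(unique(as.vector(pairs[scored, , drop = FALSE])))
  cand <- lapply(parents, function(q) {
    rows <- scored & (pairs[, 1L] == q | pairs[, 2L] == q)
    a <- sort(unique(as.vector(g[rows, , drop = FALSE])))
    .subsets12(a)
  })
  names(cand) <- as.character(parents)
  ord <- order(lengths(cand))
  row_par1 <- match(pairs[, 1L], parents)
  row_par2 <- match(pairs[, 2L], parents)

  check_partial <- function(assigned) {
    for (r in which(scored)) {
      T1 <- assigned[[row_par1[r]]]; T2 <- assigned[[row_par2[r]]]
      gr <- g[r, ]
      if (!is.null(T1) && !is.null(T2)) {
        if (!((gr[1L] %in% T1 && gr[2L] %in% T2) ||
              (gr[2L] %in% T1 && gr[1L] %in% T2))) return(FALSE)
      } else if (!is.null(T1)) {
        if (!any(gr %in% T1)) return(FALSE)
      } else if (!is.null(T2)) {
        if (!any(gr %in% T2)) return(FALSE)
      }
    }
    TRUE
  }

  assigned <- vector("list", length(parents))
  dfs <- function(d) {
    if (d > length(ord)) return(TRUE)
    q <- ord[d]
    for (Tq in cand[[q]]) {
      assigned[[q]] <<- Tq
      if (check_partial(assigned) && dfs(d + 1L)) return(TRUE)
    }
    assigned[q] <<- list(NULL)
    FALSE
  }
  if (!dfs(1L)) return(FALSE)
  stats::setNames(assigned, as.character(parents))
}

.pedigree_ok <- function(geno, pairs, witness = FALSE) {
  wit <- list()
  for (l in names(geno)) {
    w <- .locus_pedigree_witness(geno[[l]], pairs)
    if (isFALSE(w)) return(FALSE)
    wit[[l]] <- w
  }
  if (witness) wit else TRUE
}

# Exhaustive canonical DFS over assignments of units to parent pairs drawn
# from P abstract parents. unit_rows: list mapping unit -> embryo row
# indices (all members of a unit share both parents). Returns a list of
# n_units x 2 pair matrices; canonical labelling (new parent indices appear
# in order) makes solutions unique up to relabelling.
.enumerate_pairings <- function(geno, unit_rows, P, max_solutions = 200L) {
  nu <- length(unit_rows)
  pairs_units <- matrix(0L, nu, 2L)
  n_emb <- max(unlist(unit_rows))
  emb_pairs <- matrix(0L, n_emb, 2L)
  sols <- list()
  truncated <- FALSE

  dfs <- function(e, used) {
    if (length(sols) >= max_solutions) { truncated <<- TRUE; return() }
    if (e > nu) {
      if (.pedigree_ok(geno, emb_pairs)) sols[[length(sols) + 1L]] <<- pairs_units
      return()
    }
    cands <- list()
    if (used >= 2L) {
      cmb <- utils::combn(seq_len(used), 2L)
      cands <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    }
    if (used + 1L <= P)
      cands <- c(cands, lapply(seq_len(used), function(i) c(i, used + 1L)))
    if (used + 2L <= P)
      cands <- c(cands, list(c(used + 1L, used + 2L)))
    for (pr in cands) {
      pairs_units[e, ] <<- pr
      rows <- unit_rows[[e]]
      emb_pairs[rows, 1L] <<- pr[1L]; emb_pairs[rows, 2L] <<- pr[2L]
      new_used <- max(used, pr[2L])
      # prune: the full-sib family receiving this unit must stay compatible,
      # and each parent's whole offspring set must still be 2-allele coverable
      fam_rows <- which(emb_pairs[, 1L] == pr[1L] & emb_pairs[, 2L] == pr[2L] &
                          seq_len(n_emb) %in% unlist(unit_rows[seq_len(e)]))
      ok <- .fs_ok_rows(geno, fam_rows)
      if (ok) for (q in pr) {
        qr <- which((emb_pairs[, 1L] == q | emb_pairs[, 2L] == q) &
                      seq_len(n_emb) %in% unlist(unit_rows[seq_len(e)]))
        if (!.cover_ok_rows(geno, qr)) { ok <- FALSE; break }
      }
      if (ok) dfs(e + 1L, new_used)
      emb_pairs[rows, ] <<- 0L
    }
    pairs_units[e, ] <<- 0L
  }
  dfs(1L, 0L)
  structure(sols, truncated = truncated)
}

# per-locus genotype matrices for a set of embryo ids
.clutch_geno <- function(gt, ids) {
  g <- lapply(gt$loci, function(l) locus_calls(gt, l, ids))
  names(g) <- gt$loci
  g
}

# greedy agglomerative full-sib partition (deterministic)
.greedy_partition <- function(geno, n) {
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        u <- c(groups[[i]], groups[[j]])
        if (.fs_ok_rows(geno, u)) {
          groups[[i]] <- u
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups
}

# ---- exported operations ---------------------------------------------------

#' Full-sib compatibility of a set of embryos
#'
#' TRUE iff at every locus some parental pair of transmission sets (built
#' from observed offspring alleles, each parent allowed one untransmitted
#' wildcard allele) explains every member's genotype. Missing calls skip
#' that embryo at that locus. A single embryo is always compatible.
#'
#' @param gt a `genotype_table`
#' @param ids embryo sample ids
#' @return list with `ok` (logical) and `witnesses`: per locus, a list of
#'   compatible transmission-set pairs (or the sentinel "free" where the
#'   locus has no data)
#' @export
fs_compatible <- function(gt, ids) {
  if (!length(ids)) stop("empty embryo set")
  geno <- .clutch_geno(gt, ids)
  wit <- list()
  for (l in names(geno)) {
    w <- .locus_fs_witnesses(geno[[l]])
    if (isFALSE(w)) return(list(ok = FALSE, witnesses = NULL, failed_locus = l))
    wit[[l]] <- w
  }
  list(ok = TRUE, witnesses = wit)
}

#' Can two full-sib groups share exactly one parent?
#'
#' TRUE iff at every locus there is a transmission set {x, y} hitting every
#' member of both groups, such that each group retains a compatible second
#' parent. The witness shared sets per locus are returned.
#'
#' @param gt a `genotype_table`
#' @param idsA,idsB embryo ids of the two groups (each FS-compatible)
#' @return list with `ok` and `shared_witness` (per locus, list of allele
#'   sets the shared parent could transmit)
#' @export
shared_parent_compatible <- function(gt, idsA, idsB) {
  ids <- c(idsA, idsB)
  geno <- .clutch_geno(gt, ids)
  rowsA <- seq_along(idsA)
  rowsB <- length(idsA) + seq_along(idsB)
  pairs <- rbind(matrix(rep(c(1L, 2L), each = length(idsA)), ncol = 2L),
                 matrix(rep(c(1L, 3L), each = length(idsB)), ncol = 2L))
  wit <- list()
  for (l in names(geno)) {
    g <- geno[[l]]
    w <- .locus_pedigree_witness(g, pairs)
    if (isFALSE(w)) return(list(ok = FALSE, shared_witness = NULL, failed_locus = l))
    # collect all feasible shared sets (parent 1) at this locus
    scored <- !is.na(g[, 1L])
    if (!any(scored)) { wit[[l]] <- "free"; next }
    a <- sort(unique(as.vector(g[scored, , drop = FALSE])))
    ok_sets <- Filter(function(S) {
      gs <- g[scored, , drop = FALSE]
      if (!all(gs[, 1L] %in% S | gs[, 2L] %in% S)) return(FALSE)
      pr <- pairs
      !isFALSE(.locus_pedigree_witness_fixed(g, pr, S))
    }, .subsets12(a))
    wit[[l]] <- ok_sets
  }
  list(ok = TRUE, shared_witness = wit)
}

# pedigree witness with parent 1's transmission set fixed to S
.locus_pedigree_witness_fixed <- function(g, pairs, S) {
  scored <- !is.na(g[, 1L])
  if (!any(scored)) return(list())
  # rows where parent 1 participates must intersect S; then solve for others
  ok_rows <- function() {
    for (r in which(scored)) {
      if (1L %in% pairs[r, ] && !any(g[r, ] %in% S)) return(FALSE)
    }
    TRUE
  }
  if (!ok_rows()) return(FALSE)
  # reduce: remove parent 1 by restricting remaining parent of those rows
  parents <- sort(unique(as.vector(pairs[scored, , drop = FALSE])))
  others <- setdiff(parents, 1L)
  cand <- lapply(others, function(q) {
    rows <- scored & (pairs[, 1L] == q | pairs[, 2L] == q)
    a <- sort(unique(as.vector(g[rows, , drop = FALSE])))
    .subsets12(a)
  })
  names(cand) <- as.character(others)
  assigned <- stats::setNames(vector("list", length(others)), as.character(others))
  check <- function() {
    for (r in which(scored)) {
      p1 <- pairs[r, 1L]; p2 <- pairs[r, 2L]
      T1 <- if (p1 == 1L) S else assigned[[as.character(p1)]]
      T2 <- if (p2 == 1L) S else assigned[[as.character(p2)]]
      gr <- g[r, ]
      if (!is.null(T1) && !is.null(T2)) {
        if (!((gr[1L] %in% T1 && gr[2L] %in% T2) ||
              (gr[2L] %in% T1 && gr[1L] %in% T2))) return(FALSE)
      } else if (!is.null(T1) && !any(gr %in% T1)) return(FALSE)
      else if (!is.null(T2) && !any(gr %in% T2)) return(FALSE)
    }
    TRUE
  }
  dfs <- function(d) {
    if (d > length(others)) return(TRUE)
    q <- as.character(others[d])
    for (Tq in cand[[q]]) {
      assigned[[q]] <<- Tq
      if (check() && dfs(d + 1L)) return(TRUE)
    }
    assigned[q] <<- list(NULL)
    FALSE
  }
  if (dfs(1L)) list(shared = S) else FALSE
}

#' Minimum-parent parsimony reconstruction of a clutch
#'
#' Searches for the smallest number of parents whose genotypes can explain
#' every embryo in the clutch, jointly over all loci, allowing parents to be
#' shared between full-sib groups. For clutches up to `exact_cap` embryos the
#' search is an exhaustive branch-and-bound over embryo-to-parent-pair
#' assignments (canonical labelling, Mendelian pruning) and every minimal
#' solution is returned; larger clutches use a deterministic greedy full-sib
#' agglomeration followed by an exact parent-sharing search over the fixed
#' groups, flagged `exact = FALSE`.
#'
#' @param gt a `genotype_table`
#' @param ids embryo sample ids of one clutch (or a clutch object from
#'   [split_by_clutch()])
#' @param exact_cap largest clutch size searched exhaustively
#' @param max_solutions cap on recorded minimal solutions (sets `truncated`)
#' @param check_sensitivity if TRUE, also reports loci whose removal lowers
#'   the minimal parent count (assignments hinging on few allelic
#'   mismatches should be re-checked upstream, not silently absorbed)
#' @return a `parentage_solution`: list with `clutch_id`, `embryo_ids`,
#'   `n_parents_min`, `assignment` (primary solution: embryo -> (parentX,
#'   parentY) integer labels), `groups` (full-sib groups of the primary
#'   solution), `shared_links` (groups sharing one parent, with the parent
#'   label), `witness` (per locus, parent transmission sets), `alternates`
#'   (other minimal assignments), `exact`, `truncated`, `sensitive_loci`
#' @export
min_parent_search <- function(gt, ids, exact_cap = 12L, max_solutions = 200L,
                              check_sensitivity = FALSE) {
  clutch_id <- NA_character_
  if (is.list(ids) && !is.null(ids$embryo_ids)) {
    clutch_id <- ids$clutch_id
    ids <- ids$embryo_ids
  }
  ids <- as.character(ids)
  if (!length(ids)) stop("clutch of size 0")
  if (is.na(clutch_id)) {
    cid <- gt$samples$clutch_id[match(ids, gt$samples$sample_id)]
    if (length(unique(cid)) == 1L) clutch_id <- cid[1L]
  }
  geno <- .clutch_geno(gt, ids)
  n <- length(ids)
  lb <- 2L
  for (g in geno) {
    a <- unique(as.vector(g[!is.na(g[, 1L]), , drop = FALSE]))
    lb <- max(lb, as.integer(ceiling(length(a) / 2)))
  }
  exact <- n <= exact_cap
  if (exact) {
    unit_rows <- as.list(seq_len(n))
  } else {
    unit_rows <- .greedy_partition(geno, n)
    lb <- max(lb, 2L)
  }
  sols <- list(); truncated <- FALSE
  for (P in lb:(2L * n)) {
    res <- .enumerate_pairings(geno, unit_rows, P, max_solutions)
    if (length(res)) {
      sols <- res
      truncated <- attr(res, "truncated")
      n_min <- P
      break
    }
  }
  # expand unit-level pair matrices to embryo-level assignments
  expand <- function(pu) {
    m <- matrix(0L, n, 2L, dimnames = list(ids, c("parentX", "parentY")))
    for (u in seq_along(unit_rows)) m[unit_rows[[u]], ] <- rep(pu[u, ], each = length(unit_rows[[u]]))
    m
  }
  assigns <- lapply(sols, expand)
  primary <- assigns[[1L]]
  key <- paste(primary[, 1L], primary[, 2L])
  groups <- split(ids, factor(key, levels = unique(key)))
  names(groups) <- NULL
  gp <- do.call(rbind, lapply(groups, function(g) primary[match(g[1L], ids), ]))
  links <- list()
  if (length(groups) >= 2L) {
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      shared <- intersect(gp[i, ], gp[j, ])
      if (length(shared) == 1L)
        links[[length(links) + 1L]] <- data.frame(groupA = i, groupB = j, parent = shared)
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    data.frame(groupA = integer(0), groupB = integer(0), parent = integer(0))
  witness <- .pedigree_ok(geno, primary, witness = TRUE)
  sens <- character(0)
  if (check_sensitivity && length(gt$loci) > 1L) {
    for (l in gt$loci) {
      gt_drop <- gt
      gt_drop$loci <- setdiff(gt$loci, l)
      gt_drop$calls <- gt$calls[gt_drop$loci]
      gt_drop$alleles <- gt$alleles[gt_drop$loci]
      alt <- min_parent_search(gt_drop, ids, exact_cap = exact_cap,
                               max_solutions = 1L, check_sensitivity = FALSE)
      if (alt$n_parents_min < n_min) sens <- c(sens, l)
    }
  }
  structure(list(clutch_id = clutch_id, embryo_ids = ids,
                 n_parents_min = n_min, assignment = primary, groups = groups,
                 shared_links = links, witness = witness,
                 alternates = assigns[-1L], exact = exact,
                 truncated = isTRUE(truncated), sensitive_loci = sens),
            class = "parentage_solution")
}

#' @export
print.parentage_solution <- function(x, ...) {
  cat("parentage_solution", if (!is.na(x$clutch_id)) paste0("[", x$clutch_id, "]"),
      ":", length(x$embryo_ids), "embryos ->", x$n_parents_min, "parents,",
      length(x$groups), "full-sib group(s);",
      length(x$alternates), "alternate solution(s);",
      if (x$exact) "exact" else "heuristic", "\n")
  invisible(x)
}

#' Log-likelihood score of a sibship partition
#'
#' Sum over full-sib families of log sum over parental genotype pairs of
#' P(pair | freqs) * prod P(offspring | pair), with parents shared between
#' families collapsed into one variable (computed by variable elimination
#' over the parent-sharing graph). Three frequency modes: "empirical" (use
#' `af` as given), "uniform_minimal" (every observed allele weight 1/N_A;
#' the probability-model counterpart of flattening all frequencies to
#' minimise presumed allele sharing between inferred parents) and
#' "flat_unnormalized" (literal nominal weight per allele, reproducing the
#' input idiom of sibship software; not a probability, rankings only).
#'
#' @param gt a `genotype_table`
#' @param ids embryo ids, in the row order of `assignment`
#' @param assignment n x 2 integer matrix of parent labels (e.g. the
#'   `assignment` of a [min_parent_search()] solution)
#' @param af an `allele_freqs`, required for mode "empirical"
#' @param mode frequency mode
#' @param flat nominal weight for "flat_unnormalized"
#' @return log score; `-Inf` (with attribute "zero_likelihood") when a family
#'   has probability zero under the supplied frequencies
#' @export
partition_loglik <- function(gt, ids, assignment, af = NULL,
                             mode = c("uniform_minimal", "empirical", "flat_unnormalized"),
                             flat = 0.001) {
  mode <- match.arg(mode)
  ids <- as.character(ids)
  geno <- .clutch_geno(gt, ids)
  total <- 0
  for (l in gt$loci) {
    w <- switch(mode,
      uniform_minimal = {
        a <- gt$alleles[[l]]
        stats::setNames(rep(1 / length(a), length(a)), a)
      },
      empirical = {
        if (is.null(af)) stop("mode 'empirical' needs allele frequencies")
        af$freqs[[l]]
      },
      flat_unnormalized = {
        a <- gt$alleles[[l]]
        stats::setNames(rep(flat, length(a)), a)
      })
    if (!length(w)) next
    val <- .locus_partition_lik(geno[[l]], assignment, w)
    if (val$lik <= 0)
      return(structure(-Inf, zero_likelihood = l))
    total <- total + log(val$lik) + val$logc
  }
  total
}

# one-locus partition likelihood by variable elimination.
# g: n x 2 allele matrix; pairs: n x 2 parent labels; w: named allele weights
.locus_partition_lik <- function(g, pairs, w) {
  a <- as.integer(names(w))
  k <- length(a)
  gi <- rep(seq_len(k), each = k); gj <- rep(seq_len(k), k)
  keep <- gi <= gj
  gi <- gi[keep]; gj <- gj[keep]
  prior <- ifelse(gi == gj, w[gi] * w[gj], 2 * w[gi] * w[gj])
  ng <- length(prior)
  Tm <- matrix(0, ng, k)  # P(genotype transmits allele)
  Tm[cbind(seq_len(ng), gi)] <- Tm[cbind(seq_len(ng), gi)] + 0.5
  Tm[cbind(seq_len(ng), gj)] <- Tm[cbind(seq_len(ng), gj)] + 0.5
  amap <- stats::setNames(seq_len(k), a)

  scored <- !is.na(g[, 1L])
  fam_key <- paste(pairs[, 1L], pairs[, 2L])
  fams <- unique(fam_key)
  logc <- 0
  factors <- list()
  fam_parents <- lapply(fams, function(f) as.integer(strsplit(f, " ")[[1L]]))
  occ <- table(unlist(fam_parents))
  for (fi in seq_along(fams)) {
    pr <- fam_parents[[fi]]
    rows <- which(fam_key == fams[fi] & scored)
    M <- matrix(1, ng, ng)
    for (r in rows) {
      u <- amap[[as.character(g[r, 1L])]]
      v <- amap[[as.character(g[r, 2L])]]
      Pr <- outer(Tm[, u], Tm[, v])
      if (u != v) Pr <- Pr + outer(Tm[, v], Tm[, u])
      M <- M * Pr
    }
    mx <- max(M)
    if (mx > 0) { M <- M / mx; logc <- logc + log(mx) }
    shared1 <- occ[as.character(pr[1L])] > 1L
    shared2 <- occ[as.character(pr[2L])] > 1L
    if (!shared1 && !shared2) {
      factors[[length(factors) + 1L]] <- list(vars = integer(0),
                                              val = drop(prior %*% M %*% prior))
    } else if (shared1 && !shared2) {
      factors[[length(factors) + 1L]] <- list(vars = pr[1L], val = drop(M %*% prior))
    } else if (!shared1 && shared2) {
      factors[[length(factors) + 1L]] <- list(vars = pr[2L], val = drop(prior %*% M))
    } else {
      factors[[length(factors) + 1L]] <- list(vars = pr, val = M)
    }
  }
  shared_parents <- as.integer(names(occ)[occ > 1L])
  for (q in shared_parents)
    factors[[length(factors) + 1L]] <- list(vars = q, val = prior)
  # eliminate shared parents one at a time
  for (q in shared_parents) {
    idx <- which(vapply(factors, function(f) q %in% f$vars, TRUE))
    fs <- factors[idx]
    factors[idx] <- NULL
    others <- unique(unlist(lapply(fs, function(f) setdiff(f$vars, q))))
    if (length(others) > 2L)
      stop("parent-sharing structure too complex for exact scoring")
    if (length(others) == 0L) {
      v <- rep(1, ng)
      for (f in fs) v <- v * f$val
      mx <- max(v); if (mx > 0) { v <- v / mx; logc <- logc + log(mx) }
      factors[[length(factors) + 1L]] <- list(vars = integer(0), val = sum(v))
    } else if (length(others) == 1L) {
      Mq <- matrix(1, ng, ng)  # rows = q, cols = other
      for (f in fs) {
        if (length(f$vars) == 1L) Mq <- Mq * f$val
        else if (f$vars[1L] == q) Mq <- Mq * f$val
        else Mq <- Mq * t(f$val)
      }
      v <- colSums(Mq)
      mx <- max(v); if (mx > 0) { v <- v / mx; logc <- logc + log(mx) }
      factors[[length(factors) + 1L]] <- list(vars = others, val = v)
    } else {
      A <- matrix(1, ng, ng); B <- matrix(1, ng, ng); uq <- rep(1, ng)
      for (f in fs) {
        if (length(f$vars) == 1L) uq <- uq * f$val
        else {
          other <- setdiff(f$vars, q)
          Mf <- if (f$vars[1L] == q) f$val else t(f$val)
          if (other == others[1L]) A <- A * Mf else B <- B * Mf
        }
      }
      C <- t(A * uq) %*% B  # [others1, others2]
      mx <- max(C); if (mx > 0) { C <- C / mx; logc <- logc + log(mx) }
      factors[[length(factors) + 1L]] <- list(vars = others, val = C)
    }
  }
  lik <- 1
  for (f in factors) {
    if (length(f$vars)) stop("internal: unresolved factor")  # should not happen
    lik <- lik * f$val
  }
  list(lik = lik, logc = logc)
}

#' Scan for full-sib or half-sib dyads across clutches
#'
#' Pools embryos by sampling year and classifies every cross-clutch dyad
#' (delegating to [classify_dyads()]); reconstructed full sibs spread over
#' different host individuals would indicate one dam parasitising several
#' hosts.
#'
#' @param gt a `genotype_table` with at least 2 clutches
#' @param af an `allele_freqs`
#' @param n_sims,seed,alpha Monte-Carlo settings as in [classify_dyads()]
#' @return data.frame of cross-clutch dyads whose ML label is FS or HS
#'   (columns as [classify_dyads()] plus `year`); zero rows when no clutch
#'   pair exists
#' @export
cross_clutch_scan <- function(gt, af, n_sims = 1000L, seed = 1L, alpha = 0.05) {
  emb <- gt$samples[gt$samples$role == "embryo", , drop = FALSE]
  years <- unique(emb$year)
  out <- list()
  for (y in years) {
    ids <- emb$sample_id[emb$year == y]
    sub_ids <- c(ids, gt$samples$sample_id[gt$samples$role == "adult"])
    sub <- subset_samples(gt, sub_ids)
    d <- classify_dyads(sub, af, pooled = TRUE, n_sims = n_sims, seed = seed,
                        alpha = alpha)
    if (!nrow(d)) next
    d <- d[!is.na(d$ml_label) & d$clutch1 != d$clutch2 &
             d$ml_label %in% c("FS", "HS"), , drop = FALSE]
    if (nrow(d)) { d$year <- y; out[[length(out) + 1L]] <- d }
  }
  if (!length(out)) {
    empty <- .empty_dyads(); empty$year <- integer(0)
    return(empty)
  }
  do.call(rbind, out)
}
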