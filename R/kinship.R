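#' IBD-sharing coefficients of the four kinship hypotheses
#'
#' (k0, k1, k2) = probabilities that a dyad shares 0/1/2 alleles identical by
#' descent: unrelated (1,0,0), half sib (.5,.5,0), full sib (.25,.5,.25),
#' parent-offspring (0,1,0).
#' @return named list of length-3 numeric vectors
#' @export
kinship_hypotheses <- function() {
  list(UR = c(1, 0, 0), HS = c(0.5, 0.5, 0), FS = c(0.25, 0.5, 0.25), PO = c(0, 1, 0))
}

# Vectorised genotype-pair probabilities given m = 0, 1, 2 alleles IBD.
# a1 <= b1 and a2 <= b2 are character allele names indexing p (named freq
# vector summing to 1). Returns an n x 3 matrix (P0, P1, P2).
.ibd_probs_vec <- function(a1, b1, a2, b2, p) {
  pa1 <- p[a1]; pb1 <- p[b1]; pa2 <- p[a2]; pb2 <- p[b2]
  if (anyNA(pa1) || anyNA(pb1) || anyNA(pa2) || anyNA(pb2))
    stop("allele absent from frequency map")
  hom1 <- a1 == b1; hom2 <- a2 == b2
  pg1 <- ifelse(hom1, pa1^2, 2 * pa1 * pb1)
  pg2 <- ifelse(hom2, pa2^2, 2 * pa2 * pb2)
  P0 <- pg1 * pg2
  P2 <- ifelse(a1 == a2 & b1 == b2, pg1, 0)
  # transition: share one allele s of g1 (weight 1 if hom, 1/2 each if het),
  # draw the partner's other allele from the population
  trans <- function(s) ifelse(hom2,
                              ifelse(a2 == s, pa2, 0),
                              ifelse(a2 == s, pb2, 0) + ifelse(b2 == s, pa2, 0))
  Tv <- ifelse(hom1, trans(a1), 0.5 * trans(a1) + 0.5 * trans(b1))
  P1 <- pg1 * Tv
  cbind(P0 = unname(P0), P1 = unname(P1), P2 = unname(P2))
}

#' Genotype-pair probabilities under 0/1/2 alleles IBD at one locus
#'
#' The probability of the (unordered-genotype) pair given m alleles shared
#' identical by descent, under the supplied allele frequencies; the building
#' block of all k-coefficient kinship likelihoods.
#'
#' @param g1,g2 length-2 vectors of allele names/sizes (unordered)
#' @param p named numeric vector of allele frequencies at the locus
#' @return numeric c(P0, P1, P2)
#' @export
ibd_pair_probs <- function(g1, g2, p) {
  g1 <- sort(as.character(g1)); g2 <- sort(as.character(g2))
  drop(.ibd_probs_vec(g1[1L], g1[2L], g2[1L], g2[2L], p))
}

# per-locus sorted character genotypes of a pair, jointly non-missing loci only
.joint_calls <- function(gt, id1, id2) {
  out <- list()
  for (l in gt$loci) {
    g <- locus_calls(gt, l, c(id1, id2))
    if (anyNA(g)) next
    out[[l]] <- g
  }
  out
}

#' Log-likelihood of a dyad under a kinship hypothesis
#'
#' Sum over jointly non-missing loci of log(k0 P0 + k1 P1 + k2 P2), per-locus
#' IBD states independent given the k-coefficients.
#'
#' @param gt a `genotype_table`
#' @param id1,id2 sample ids
#' @param hypothesis "UR", "HS", "FS", "PO", or a length-3 k vector
#' @param af an `allele_freqs` (should cover embryo alleles; see
#'   [extend_frequencies()])
#' @return log-likelihood (scalar)
#' @export
dyad_loglik <- function(gt, id1, id2, hypothesis, af) {
  k <- if (is.character(hypothesis)) kinship_hypotheses()[[hypothesis]] else hypothesis
  if (is.null(k) || length(k) != 3L) stop("unknown hypothesis")
  jc <- .joint_calls(gt, id1, id2)
  if (!length(jc)) stop("no jointly informative loci for ", id1, " and ", id2)
  ll <- 0
  for (l in names(jc)) {
    g <- jc[[l]]
    P <- ibd_pair_probs(g[1L, ], g[2L, ], af$freqs[[l]])
    ll <- ll + log(sum(k * P))
  }
  ll
}

# simulate n dyads at the given loci under k; returns n-vector of
# LR = loglik(k_put) - loglik(k_alt)
.simulate_lr <- function(k_sim, k_put, k_alt, af, loci, n) {
  lr <- numeric(n)
  for (l in loci) {
    p <- af$freqs[[l]]
    nm <- names(p)
    m <- sample.int(3L, n, replace = TRUE, prob = k_sim) - 1L
    d1 <- nm[sample.int(length(p), n, replace = TRUE, prob = p)]
    d2 <- nm[sample.int(length(p), n, replace = TRUE, prob = p)]
    d3 <- nm[sample.int(length(p), n, replace = TRUE, prob = p)]
    d4 <- nm[sample.int(length(p), n, replace = TRUE, prob = p)]
    # m = 0: two independent genotypes; m = 1: shared allele d1 plus d2/d3;
    # m = 2: one genotype (d1, d2) copied to both
    a1 <- ifelse(m == 0L, d1, d1)
    b1 <- ifelse(m == 0L, d2, ifelse(m == 1L, d2, d2))
    a2 <- ifelse(m == 0L, d3, ifelse(m == 1L, d1, d1))
    b2 <- ifelse(m == 0L, d4, ifelse(m == 1L, d3, d2))
    sw1 <- a1 > b1; tmp <- a1[sw1]; a1[sw1] <- b1[sw1]; b1[sw1] <- tmp
    sw2 <- a2 > b2; tmp <- a2[sw2]; a2[sw2] <- b2[sw2]; b2[sw2] <- tmp
    P <- .ibd_probs_vec(a1, b1, a2, b2, p)
    lr <- lr + log(P %*% k_put) - log(P %*% k_alt)
  }
  lr
}

#' Monte-Carlo likelihood-ratio test between two kinship hypotheses
#'
#' Simulates `n_sims` dyads under the alternative hypothesis, at the pair's
#' jointly non-missing loci (so the observed missing-data pattern is
#' respected), and reports the fraction of simulated dyads whose likelihood
#' ratio LR(putative vs alternative) is at least the observed one. A small
#' p-value rejects the alternative in favour of the putative relationship.
#'
#' @param gt a `genotype_table`
#' @param id1,id2 sample ids
#' @param putative,alternative distinct hypothesis labels ("UR","HS","FS","PO")
#' @param af an `allele_freqs`
#' @param n_sims simulated dyads (>= 1; < 100 sets a low-precision flag)
#' @param seed integer RNG seed
#' @return p-value with attributes "lr_obs" and "low_precision"
#' @export
lr_test <- function(gt, id1, id2, putative, alternative, af, n_sims = 10000L, seed = 1L) {
  if (identical(putative, alternative)) stop("putative and alternative must differ")
  if (n_sims < 1L) stop("n_sims must be positive")
  hyp <- kinship_hypotheses()
  k_put <- hyp[[putative]]; k_alt <- hyp[[alternative]]
  if (is.null(k_put) || is.null(k_alt)) stop("unknown hypothesis label")
  obs <- dyad_loglik(gt, id1, id2, putative, af) -
    dyad_loglik(gt, id1, id2, alternative, af)
  loci <- names(.joint_calls(gt, id1, id2))
  set.seed(seed)
  sim <- .simulate_lr(k_alt, k_put, k_alt, af, loci, n_sims)
  p <- mean(sim >= obs - 1e-9)
  structure(p, lr_obs = obs, low_precision = n_sims < 100L)
}

# deterministic per-dyad seed derived from the master seed and the pair ids,
# so batch order never changes results
.dyad_seed <- function(seed, id1, id2) {
  s <- paste(sort(c(id1, id2)), collapse = "|")
  h <- sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Maximum-likelihood kinship classification of embryo dyads
#'
#' For each within-clutch pair (or every pair across clutches in pooled
#' mode): the log-likelihood of UR/HS/FS/PO, the ML label with PO folded into
#' FS (both members are embryos, so a parent-offspring dyad is not a
#' meaningful result and is reported as full sib), and a likelihood-ratio
#' test of the ML label against the runner-up. When the runner-up cannot be
#' rejected at `alpha`, the dyad is annotated "X or Y".
#'
#' @param gt a `genotype_table` (embryos are classified)
#' @param af an `allele_freqs`
#' @param pooled if TRUE, all embryo pairs; if FALSE (default), within-clutch
#' @param n_sims,seed Monte-Carlo settings; per-dyad seeds are derived from
#'   `seed` and the pair ids
#' @param alpha tie-reporting threshold
#' @return data.frame, one row per dyad: ids, clutches, per-hypothesis
#'   log-likelihoods, `ml_label` (folded), `po_folded`, `second`, `p_second`,
#'   `annotation`, `error` (NA unless the dyad failed, in which case the
#'   message is recorded and the batch continues)
#' @export
classify_dyads <- function(gt, af, pooled = FALSE, n_sims = 10000L, seed = 1L,
                           alpha = 0.05) {
  emb <- gt$samples[gt$samples$role == "embryo", , drop = FALSE]
  if (nrow(emb) < 2L)
    return(.empty_dyads())
  pairs <- utils::combn(emb$sample_id, 2L)
  cl <- stats::setNames(emb$clutch_id, emb$sample_id)
  if (!pooled) {
    keep <- cl[pairs[1L, ]] == cl[pairs[2L, ]] & !is.na(cl[pairs[1L, ]])
    pairs <- pairs[, keep, drop = FALSE]
  }
  if (!ncol(pairs)) return(.empty_dyads())
  hyp_names <- names(kinship_hypotheses())
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    id1 <- pairs[1L, i]; id2 <- pairs[2L, i]
    res <- try({
      ll <- vapply(hyp_names, function(h) dyad_loglik(gt, id1, id2, h, af), 0)
      ord <- order(ll, decreasing = TRUE)
      raw_ml <- hyp_names[ord[1L]]
      fold <- function(h) if (h == "PO") "FS" else h
      ml <- fold(raw_ml)
      # runner-up: best hypothesis whose folded label differs from ml
      folded <- vapply(hyp_names[ord], fold, "")
      second <- hyp_names[ord][which(folded != ml)[1L]]
      p2 <- as.numeric(lr_test(gt, id1, id2, ml, second, af, n_sims = n_sims,
                               seed = .dyad_seed(seed, id1, id2)))
      ann <- if (p2 > alpha) paste(ml, "or", fold(second)) else ml
      data.frame(id1 = id1, id2 = id2,
                 clutch1 = unname(cl[id1]), clutch2 = unname(cl[id2]),
                 ll_UR = ll[["UR"]], ll_HS = ll[["HS"]], ll_FS = ll[["FS"]],
                 ll_PO = ll[["PO"]], ml_label = ml, po_folded = raw_ml == "PO",
                 second = fold(second), p_second = p2, annotation = ann,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, silent = TRUE)
    if (inherits(res, "try-error"))
      data.frame(id1 = id1, id2 = id2,
                 clutch1 = unname(cl[id1]), clutch2 = unname(cl[id2]),
                 ll_UR = NA_real_, ll_HS = NA_real_, ll_FS = NA_real_,
                 ll_PO = NA_real_, ml_label = NA_character_, po_folded = NA,
                 second = NA_character_, p_second = NA_real_,
                 annotation = NA_character_,
                 error = conditionMessage(attr(res, "condition")),
                 stringsAsFactors = FALSE)
    else res
  })
  do.call(rbind, rows)
}

.empty_dyads <- function() {
  data.frame(id1 = character(0), id2 = character(0), clutch1 = character(0),
             clutch2 = character(0), ll_UR = numeric(0), ll_HS = numeric(0),
             ll_FS = numeric(0), ll_PO = numeric(0), ml_label = character(0),
             po_folded = logical(0), second = character(0),
             p_second = numeric(0), annotation = character(0),
             error = character(0), stringsAsFactors = FALSE)
}
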