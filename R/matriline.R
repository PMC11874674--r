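#' Matriline lower bound on the number of dams
#'
#' The number of distinct mitochondrial haplotypes among a clutch's embryos.
#' Haplotypes are maternally inherited, so any valid sexed parentage needs at
#' least this many dams; embryos without sequence data contribute nothing.
#'
#' @param embryo_ids embryo sample ids of the clutch
#' @param ht a `haplotype_table`
#' @return integer (0 when no embryo has a haplotype)
#' @export
matriline_lower_bound <- function(embryo_ids, ht) {
  h <- ht$haplotype_of[as.character(embryo_ids)]
  length(unique(h[!is.na(h)]))
}

#' Resolve dams versus sires with mitochondrial haplotypes
#'
#' Microsatellite parsimony alone cannot tell which abstract parent of a
#' full-sib group is the dam. Haplotype classes (matrilines) resolve this:
#' half sibs with different haplotypes must have different mothers and share
#' their father, so a parent shared between groups of different haplotypes
#' is a sire. A parent shared between same-haplotype groups is ambiguous;
#' the parsimony tie-break prefers the fewer-dams reading (identical
#' maternal haplotypes are positive evidence of one mother, whereas two
#' mothers sharing a haplotype requires an extra coincidence) and records
#' the alternative. A full-sib group spanning two haplotypes is reported as
#' a conflict, never silently repaired.
#'
#' @param sol a `parentage_solution`
#' @param ht a `haplotype_table` (embryos absent from it constrain nothing)
#' @return a `sexed_parentage`: list with `clutch_id`, `n_embryos`,
#'   `n_parents`, `n_dams`, `n_sires`, `dam_of` / `sire_of` (embryo ->
#'   "D1".../"S1..." labels), `sharing` (which parent label is shared across
#'   groups, or NA), `ambiguous` (logical), `alternatives` (list of
#'   alternative (n_dams, n_sires) splits), `conflicts` (character),
#'   `unsexed` (TRUE when no embryo carries a haplotype)
#' @export
resolve_parent_sexes <- function(sol, ht) {
  ids <- sol$embryo_ids
  haps <- ht$haplotype_of[ids]
  names(haps) <- ids
  groups <- sol$groups
  m <- length(groups)
  gp <- do.call(rbind, lapply(groups, function(g) sol$assignment[match(g[1L], ids), ]))
  conflicts <- character(0)

  group_hap <- vapply(groups, function(g) {
    h <- unique(stats::na.omit(haps[g]))
    if (length(h) > 1L) {
      conflicts <<- c(conflicts,
                      paste0("full-sib group {", paste(g, collapse = ","),
                             "} spans haplotypes ", paste(h, collapse = "/")))
      return(h[1L])
    }
    if (length(h)) h else NA_character_
  }, "")

  unsexed <- all(is.na(haps))
  parents <- sort(unique(as.vector(gp)))
  occ <- vapply(parents, function(q) sum(gp == q), 0L)
  sex <- stats::setNames(rep(NA_character_, length(parents)), parents)
  ambiguous <- unsexed
  alternatives <- list()

  # pass 1: shared parents constrained by the haplotypes of their groups
  for (qi in seq_along(parents)) {
    q <- parents[qi]
    if (occ[qi] < 2L) next
    gs <- which(gp[, 1L] == q | gp[, 2L] == q)
    hs <- unique(stats::na.omit(group_hap[gs]))
    if (length(hs) >= 2L) {
      sex[qi] <- "sire"
    } else {
      # same (or unknown) haplotype on every linked group: prefer the
      # fewer-dams reading (shared parent = dam), keep the alternative
      sex[qi] <- "dam"
      ambiguous <- TRUE
    }
  }
  # pass 2: within each group the two parents have opposite sexes
  repeat {
    changed <- FALSE
    for (gi in seq_len(m)) {
      q1 <- match(gp[gi, 1L], parents); q2 <- match(gp[gi, 2L], parents)
      s1 <- sex[q1]; s2 <- sex[q2]
      if (!is.na(s1) && !is.na(s2)) {
        if (s1 == s2)
          conflicts <- c(conflicts,
                         paste0("group ", gi, ": both parents constrained to ", s1))
        next
      }
      if (!is.na(s1) && is.na(s2)) { sex[q2] <- setdiff(c("dam", "sire"), s1); changed <- TRUE }
      if (is.na(s1) && !is.na(s2)) { sex[q1] <- setdiff(c("dam", "sire"), s2); changed <- TRUE }
    }
    if (!changed) break
  }
  # pass 3: unconstrained parent pairs (independent monogamous groups):
  # call the first slot the dam; with no haplotype the labelling is arbitrary
  for (gi in seq_len(m)) {
    q1 <- match(gp[gi, 1L], parents); q2 <- match(gp[gi, 2L], parents)
    if (is.na(sex[q1]) && is.na(sex[q2])) { sex[q1] <- "dam"; sex[q2] <- "sire" }
    else if (is.na(sex[q1])) sex[q1] <- setdiff(c("dam", "sire"), sex[q2])
    else if (is.na(sex[q2])) sex[q2] <- setdiff(c("dam", "sire"), sex[q1])
  }

  n_dams <- sum(sex == "dam"); n_sires <- sum(sex == "sire")
  lb <- matriline_lower_bound(ids, ht)
  if (n_dams < lb)
    conflicts <- c(conflicts, paste0("dam count ", n_dams,
                                     " below matriline lower bound ", lb))
  if (ambiguous && !unsexed) {
    # swapping the ambiguous shared parent's sex gives the alternative split
    n_sh_amb <- sum(occ >= 2L & sex == "dam")
    if (n_sh_amb > 0L)
      alternatives <- list(c(n_dams = n_dams + n_sh_amb, n_sires = n_sires - n_sh_amb))
  }
  dam_lab <- stats::setNames(paste0("D", seq_len(max(n_dams, 1L))), parents[sex == "dam"])
  sire_lab <- stats::setNames(paste0("S", seq_len(max(n_sires, 1L))), parents[sex == "sire"])
  lab_of <- stats::setNames(rep(NA_character_, length(parents)), parents)
  lab_of[names(dam_lab)] <- dam_lab
  lab_of[names(sire_lab)] <- sire_lab
  per_embryo <- t(vapply(ids, function(e) {
    pr <- as.character(sol$assignment[match(e, ids), ])
    labs <- lab_of[pr]
    c(dam = labs[which(sex[match(pr, parents)] == "dam")][1L],
      sire = labs[which(sex[match(pr, parents)] == "sire")][1L])
  }, c(dam = "", sire = "")))
  sharing <- if (any(occ >= 2L)) unname(lab_of[match(parents[occ >= 2L], parents)]) else NA_character_

  structure(list(clutch_id = sol$clutch_id, n_embryos = length(ids),
                 n_parents = sol$n_parents_min,
                 n_dams = n_dams, n_sires = n_sires,
                 dam_of = stats::setNames(per_embryo[, "dam"], ids),
                 sire_of = stats::setNames(per_embryo[, "sire"], ids),
                 sharing = sharing, ambiguous = ambiguous,
                 alternatives = alternatives, conflicts = conflicts,
                 unsexed = unsexed,
                 matriline_bound = lb,
                 n_alternate_partitions = length(sol$alternates),
                 exact = sol$exact),
            class = "sexed_parentage")
}

#' @export
print.sexed_parentage <- function(x, ...) {
  cat("sexed_parentage", if (!is.na(x$clutch_id)) paste0("[", x$clutch_id, "]"), ":",
      x$n_embryos, "embryos,", x$n_dams, "dam(s) x", x$n_sires, "sire(s)",
      if (x$ambiguous) "(ambiguous)" else "",
      if (length(x$conflicts)) paste0("; CONFLICTS: ", length(x$conflicts)) else "", "\n")
  invisible(x)
}
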