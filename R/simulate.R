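#' Define a microsatellite locus for simulation
#'
#' Frequency schemes: "equifrequent"; "target_He" (one major allele plus
#' equifrequent minors, with the major frequency solved in closed form so
#' that 1 - sum p^2 hits the target gene diversity; monotone and
#' reproducible); "dirichlet" (frequencies drawn once from a symmetric
#' Dirichlet(alpha) when the population is built).
#'
#' @param name locus name
#' @param n_alleles number of alleles (>= 2)
#' @param scheme frequency scheme
#' @param he target gene diversity for scheme "target_He"
#' @param alpha Dirichlet concentration for scheme "dirichlet"
#' @param size_range bp range the allele sizes are spread over
#' @return a `locus_def` list
#' @export
locus_def <- function(name, n_alleles, scheme = c("equifrequent", "target_He", "dirichlet"),
                      he = NULL, alpha = 1, size_range = NULL) {
  scheme <- match.arg(scheme)
  if (n_alleles < 2L) stop("n_alleles must be >= 2")
  if (scheme == "target_He") {
    if (is.null(he)) stop("scheme 'target_He' needs a target he")
    if (he >= 1 - 1 / n_alleles + 1e-12 || he <= 0)
      stop("target He ", he, " infeasible for ", n_alleles, " alleles (max ",
           round(1 - 1 / n_alleles, 4), ")")
  }
  if (is.null(size_range)) size_range <- c(100L, 100L + 2L * (n_alleles - 1L))
  list(name = name, n_alleles = n_alleles, scheme = scheme, he = he,
       alpha = alpha, size_range = size_range)
}

# closed-form major-allele frequency: k alleles, minors equifrequent,
# sum p^2 = M^2 + (1-M)^2/(k-1) = 1 - he; take the root with M >= 1/k
.solve_major <- function(k, he) {
  S <- 1 - he
  a <- k / (k - 1); b <- -2 / (k - 1); cc <- 1 / (k - 1) - S
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("target He infeasible")
  M <- (-b + sqrt(disc)) / (2 * a)
  if (M > 1) stop("target He infeasible")
  M
}

#' Define the population model for the clutch simulator
#'
#' @param loci list of [locus_def()]s
#' @param n_haplotypes mitochondrial haplotype pool size
#' @param hd target haplotype diversity of the pool (gene-diversity scale,
#'   major-plus-equifrequent-minors construction). The default pool of 13
#'   haplotypes at Hd 0.89 mirrors a high-diversity control-region sample in
#'   which different females are very likely to carry different haplotypes.
#' @param n_adults size of the adult reference sample drawn alongside each
#'   dataset
#' @return a `population_model` list
#' @export
population_model <- function(loci, n_haplotypes = 13L, hd = 0.89, n_adults = 81L) {
  stopifnot(length(loci) >= 1L, n_haplotypes >= 1L)
  if (n_haplotypes > 1L && (hd >= 1 - 1 / n_haplotypes + 1e-12 || hd <= 0))
    stop("target Hd infeasible for ", n_haplotypes, " haplotypes")
  list(loci = loci, n_haplotypes = n_haplotypes, hd = hd, n_adults = n_adults)
}

#' Realise allele frequencies and the haplotype pool of a population model
#'
#' Deterministic for the equifrequent and target_He schemes; Dirichlet draws
#' use the current RNG state.
#'
#' @param model a [population_model()]
#' @return list with `freqs` (per locus, named by allele size), `mt_pool`
#'   (haplotype label -> frequency)
#' @export
build_population <- function(model) {
  freqs <- lapply(model$loci, function(ld) {
    k <- ld$n_alleles
    sizes <- round(seq(ld$size_range[1L], ld$size_range[2L], length.out = k))
    sizes <- sizes + cumsum(c(0L, as.integer(diff(sizes) == 0L)))  # ensure distinct
    p <- switch(ld$scheme,
      equifrequent = rep(1 / k, k),
      target_He = { M <- .solve_major(k, ld$he); c(M, rep((1 - M) / (k - 1), k - 1L)) },
      dirichlet = { x <- stats::rgamma(k, ld$alpha); x / sum(x) })
    stats::setNames(p, sizes)
  })
  names(freqs) <- vapply(model$loci, `[[`, "", "name")
  kh <- model$n_haplotypes
  ph <- if (kh == 1L) 1 else {
    M <- .solve_major(kh, model$hd)
    c(M, rep((1 - M) / (kh - 1L), kh - 1L))
  }
  list(freqs = freqs, mt_pool = stats::setNames(ph, paste0("H", seq_len(kh))))
}

#' Define a mating design
#'
#' @param clutches list; each element a list with `clutch_id`, optional
#'   `year` and `host_species`, and `matings`: a data.frame with columns
#'   `dam`, `sire`, `n` (offspring per pairing). Dam/sire ids may repeat
#'   within and across clutches.
#' @param max_clutch_size guard on total embryos per clutch
#' @return a `mating_design` list
#' @export
mating_design <- function(clutches, max_clutch_size = 14L) {
  for (cl in clutches) {
    stopifnot(!is.null(cl$clutch_id), is.data.frame(cl$matings),
              all(c("dam", "sire", "n") %in% names(cl$matings)),
              all(cl$matings$n >= 1L))
    if (sum(cl$matings$n) > max_clutch_size)
      stop("clutch ", cl$clutch_id, " exceeds maximum size ", max_clutch_size)
  }
  list(clutches = clutches, max_clutch_size = max_clutch_size)
}

#' Genotyping error model
#' @param dropout_rate probability a heterozygous call loses one allele and
#'   is scored homozygous for the other
#' @param mistype_rate probability an allele call is replaced by another
#'   allele of the locus
#' @param missing_rate probability a call is lost entirely
#' @return an `error_model` list (defaults all 0)
#' @export
error_model <- function(dropout_rate = 0, mistype_rate = 0, missing_rate = 0) {
  stopifnot(dropout_rate >= 0, dropout_rate <= 1, mistype_rate >= 0,
            mistype_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  list(dropout_rate = dropout_rate, mistype_rate = mistype_rate,
       missing_rate = missing_rate)
}

# draw n HWE genotypes at one locus; returns n x 2 canonical matrix
.draw_genotypes <- function(p, n) {
  sizes <- as.integer(names(p))
  a <- sizes[sample.int(length(p), n, replace = TRUE, prob = p)]
  b <- sizes[sample.int(length(p), n, replace = TRUE, prob = p)]
  cbind(pmin(a, b), pmax(a, b))
}

#' Mendelian cross of one parent pair
#'
#' Each embryo receives one uniformly chosen allele per parent per locus;
#' genotyping errors are applied after meiosis (dropout makes a heterozygote
#' homozygous for the remaining allele, mistypes substitute a random other
#' allele of the locus, missing drops the call).
#'
#' @param dam,sire named lists of length-2 genotype vectors per locus
#' @param n number of offspring (>= 1)
#' @param freqs per-locus named allele frequencies (defines the allele pool
#'   mistypes are drawn from)
#' @param error an [error_model()]
#' @return list per locus of n x 2 canonical genotype matrices
#' @export
mate <- function(dam, sire, n, freqs, error = error_model()) {
  stopifnot(n >= 1L)
  out <- list()
  for (l in names(freqs)) {
    a <- dam[[l]][sample.int(2L, n, replace = TRUE)]
    b <- sire[[l]][sample.int(2L, n, replace = TRUE)]
    g <- cbind(a, b)
    if (error$mistype_rate > 0) {
      sizes <- as.integer(names(freqs[[l]]))
      hit <- matrix(stats::runif(2L * n) < error$mistype_rate, n, 2L)
      if (any(hit)) {
        repl <- sample(sizes, sum(hit), replace = TRUE)
        g[hit] <- repl
      }
    }
    if (error$dropout_rate > 0) {
      het <- g[, 1L] != g[, 2L]
      drop1 <- het & (stats::runif(n) < error$dropout_rate)
      side <- stats::runif(n) < 0.5
      g[drop1 & side, 1L] <- g[drop1 & side, 2L]
      g[drop1 & !side, 2L] <- g[drop1 & !side, 1L]
    }
    if (error$missing_rate > 0) {
      gone <- stats::runif(n) < error$missing_rate
      g[gone, ] <- NA_integer_
    }
    out[[l]] <- cbind(pmin(g[, 1L], g[, 2L]), pmax(g[, 1L], g[, 2L]))
  }
  out
}

# classify a clutch's design into its true mating pattern
.design_pattern <- function(matings) {
  nd <- length(unique(matings$dam)); ns <- length(unique(matings$sire))
  shared <- any(duplicated(matings$dam)) || any(duplicated(matings$sire))
  if (nd == 1L && ns == 1L) "monogamous"
  else if (nd == 1L) "polyandrous"
  else if (ns == 1L) "polygynous"
  else if (shared) "polygynandrous"
  else "two_pairs"
}

#' Generate a synthetic genotype + haplotype dataset with ground truth
#'
#' Parents are drawn under HWE from the realised population frequencies;
#' dams receive mitochondrial haplotypes from the pool; embryos inherit
#' their dam's haplotype exactly; an adult reference sample is drawn from
#' the same population. Deterministic under `seed`.
#'
#' @param model a [population_model()]
#' @param design a [mating_design()]
#' @param error an [error_model()] (applied to embryos only)
#' @param seed integer seed
#' @return list with `gt` (a `genotype_table` of embryos + adults), `ht`
#'   (a `haplotype_table` for all embryos), `truth` (list: `parents`
#'   genotypes, `dam_haplotypes`, `pedigree` data.frame embryo -> dam/sire,
#'   `clutches` data.frame with true n_dams/n_sires/pattern), `freqs`
#'   (realised population frequencies)
#' @export
generate_dataset <- function(model, design, error = error_model(), seed = 1L) {
  set.seed(seed)
  pop <- build_population(model)
  loci <- names(pop$freqs)
  dam_ids <- unique(unlist(lapply(design$clutches, function(cl) cl$matings$dam)))
  sire_ids <- unique(unlist(lapply(design$clutches, function(cl) cl$matings$sire)))
  draw_parent <- function() {
    g <- lapply(pop$freqs, function(p) drop(.draw_genotypes(p, 1L)))
    names(g) <- loci
    g
  }
  parents <- c(lapply(dam_ids, function(i) draw_parent()),
               lapply(sire_ids, function(i) draw_parent()))
  names(parents) <- c(dam_ids, sire_ids)
  dam_haps <- stats::setNames(
    names(pop$mt_pool)[sample.int(length(pop$mt_pool), length(dam_ids),
                                  replace = TRUE, prob = pop$mt_pool)],
    dam_ids)

  samples <- list(); calls <- stats::setNames(lapply(loci, function(l) NULL), loci)
  ped <- list(); clutch_truth <- list()
  hap_of <- character(0)
  for (cl in design$clutches) {
    letters_pool <- c(LETTERS, paste0(LETTERS, rep(LETTERS, each = 26L)))
    e_i <- 0L
    for (mi in seq_len(nrow(cl$matings))) {
      mm <- cl$matings[mi, ]
      off <- mate(parents[[mm$dam]], parents[[mm$sire]], mm$n, pop$freqs, error)
      ids <- paste0(cl$clutch_id, ".", letters_pool[e_i + seq_len(mm$n)])
      e_i <- e_i + mm$n
      samples[[length(samples) + 1L]] <- data.frame(
        sample_id = ids, clutch_id = cl$clutch_id,
        year = if (is.null(cl$year)) NA_integer_ else cl$year, role = "embryo",
        host_species = if (is.null(cl$host_species)) NA_character_ else cl$host_species,
        stringsAsFactors = FALSE)
      for (l in loci) calls[[l]] <- rbind(calls[[l]], off[[l]])
      ped[[length(ped) + 1L]] <- data.frame(embryo_id = ids, clutch_id = cl$clutch_id,
                                            dam = mm$dam, sire = mm$sire,
                                            stringsAsFactors = FALSE)
      hap_of <- c(hap_of, stats::setNames(rep(dam_haps[[mm$dam]], mm$n), ids))
    }
    clutch_truth[[length(clutch_truth) + 1L]] <- data.frame(
      clutch_id = cl$clutch_id,
      n_embryos = sum(cl$matings$n),
      n_dams = length(unique(cl$matings$dam)),
      n_sires = length(unique(cl$matings$sire)),
      n_parents = length(unique(cl$matings$dam)) + length(unique(cl$matings$sire)),
      pattern = .design_pattern(cl$matings), stringsAsFactors = FALSE)
  }
  if (model$n_adults > 0L) {
    aid <- sprintf("AD%03d", seq_len(model$n_adults))
    samples[[length(samples) + 1L]] <- data.frame(
      sample_id = aid, clutch_id = NA_character_, year = NA_integer_,
      role = "adult", host_species = NA_character_, stringsAsFactors = FALSE)
    for (l in loci) calls[[l]] <- rbind(calls[[l]], .draw_genotypes(pop$freqs[[l]],
                                                                    model$n_adults))
  }
  gt <- genotype_table(do.call(rbind, samples), calls)
  truth <- list(parents = parents, dam_haplotypes = dam_haps,
                pedigree = do.call(rbind, ped),
                clutches = do.call(rbind, clutch_truth))
  list(gt = gt, ht = haplotype_table(hap_of), truth = truth, freqs = pop$freqs)
}

#' Render a haplotype table as an aligned FASTA-style alignment
#'
#' Builds one random reference sequence and gives each haplotype label its
#' own set of diagnostic substitutions; optionally injects gap/N columns so
#' that column stripping is exercised. Sample sequences are their
#' haplotype's sequence. Uses the current RNG state.
#'
#' @param ht a `haplotype_table`
#' @param length sequence length before stripping (bp)
#' @param n_noise_cols columns given a gap or N in one random sequence
#' @return a `haplotype_alignment`
#' @export
haplotypes_to_alignment <- function(ht, length = 596L, n_noise_cols = 0L) {
  labs <- sort(unique(ht$haplotype_of))
  base <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  var_sites <- sample.int(length, max(2L * length(labs), 8L))
  seqs <- lapply(seq_along(labs), function(i) {
    s <- base
    # give haplotype i substitutions at its own subset of the variable sites
    mine <- var_sites[seq_along(var_sites) %% length(labs) + 1L == i]
    for (pos in mine) s[pos] <- setdiff(c("A", "C", "G", "T"), s[pos])[sample.int(3L, 1L)]
    s
  })
  names(seqs) <- labs
  out <- vapply(ht$haplotype_of, function(h) paste(seqs[[h]], collapse = ""), "")
  if (n_noise_cols > 0L && base::length(out) > 0L) {
    cols <- sample.int(length, n_noise_cols)
    for (ci in cols) {
      r <- sample.int(base::length(out), 1L)
      substr(out[r], ci, ci) <- sample(c("-", "N"), 1L)
    }
  }
  haplotype_alignment(out)
}
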