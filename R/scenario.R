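#' Classify a sexed parentage into a mating pattern
#'
#' Patterns follow the standard progeny-array logic: (1 dam, 1 sire) =
#' monogamous; (1, >=2) = polyandrous; (>=2, 1) = polygynous; (2, 2) with
#' disjoint pairs = two monogamous pairs; (2, 2) with any shared parent =
#' polygynandrous. The intrusion-scenario index maps monogamy to scenario 1
#' (pair, or one pair monopolising a spawning group), polyandry to 2,
#' polygyny to 3 and any multi-dam-multi-sire pattern to 4.
#'
#' @param sp a `sexed_parentage`
#' @return a `mating_scenario`: list with `pattern`, `inference`,
#'   `intro_scenario`, `secondary` (alternative pattern when the sexing was
#'   ambiguous, else NA)
#' @export
classify_scenario <- function(sp) {
  stopifnot(inherits(sp, "sexed_parentage"))
  if (sp$unsexed && sp$n_parents > 2L)
    stop("cannot classify: no haplotype data to sex ", sp$n_parents, " parents")
  pat <- function(nd, ns, shared) {
    if (nd == 1L && ns == 1L) "monogamous"
    else if (nd == 1L && ns >= 2L) "polyandrous"
    else if (nd >= 2L && ns == 1L) "polygynous"
    else if (shared) "polygynandrous"
    else "two_pairs"
  }
  shared <- !all(is.na(sp$sharing))
  pattern <- pat(sp$n_dams, sp$n_sires, shared)
  inference <- switch(pattern,
    monogamous = "Pair spawning, or one reproducing pair in the spawning group",
    polyandrous = "Spawning group",
    polygynous = "Spawning group",
    two_pairs = "Spawning group, or consecutive pair spawning",
    polygynandrous = "Spawning group")
  intro <- switch(pattern, monogamous = 1L, polyandrous = 2L, polygynous = 3L, 4L)
  secondary <- NA_character_
  if (sp$ambiguous && length(sp$alternatives)) {
    alt <- sp$alternatives[[1L]]
    secondary <- pat(alt[["n_dams"]], alt[["n_sires"]], shared)
  }
  structure(list(pattern = pattern, inference = inference,
                 intro_scenario = intro, secondary = secondary),
            class = "mating_scenario")
}

#' Dataset-level parentage summary
#'
#' Multiple parentage is only testable in clutches with three or more
#' embryos (any two embryo genotypes can always be explained by a single
#' parent pair), so clutches of 1-2 embryos are reported "untestable", never
#' "monogamous".
#'
#' @param sexed list of `sexed_parentage` objects (one per analysed clutch)
#' @param clutch_sizes named integer vector: embryos per clutch for the
#'   whole dataset, including untestable clutches
#' @param screening optional c(screened = , parasitised = ) host counts;
#'   prevalence is rounded to the nearest integer percent
#' @return a `dataset_summary` list: `n_clutches`, `n_testable`,
#'   `testable_median`, `testable_range`, `pattern_counts`, `n_multi_parent`,
#'   `fraction_multi_parent` (NA-flagged when no clutch is testable),
#'   `prevalence_pct`
#' @export
summarize_dataset <- function(sexed, clutch_sizes, screening = NULL) {
  if (!length(sexed) && !length(clutch_sizes)) stop("no clutches")
  testable <- clutch_sizes[clutch_sizes >= 3L]
  patterns <- c("monogamous", "polyandrous", "polygynous", "two_pairs", "polygynandrous")
  counts <- stats::setNames(integer(length(patterns)), patterns)
  n_multi <- 0L
  for (sp in sexed) {
    if (sp$n_embryos < 3L) next
    if (sp$n_parents > 2L) n_multi <- n_multi + 1L
    sc <- tryCatch(classify_scenario(sp), error = function(e) NULL)
    if (!is.null(sc)) counts[[sc$pattern]] <- counts[[sc$pattern]] + 1L
  }
  frac <- if (length(testable)) n_multi / length(testable) else NA_real_
  prev <- if (!is.null(screening))
    as.integer(round(100 * screening[["parasitised"]] / screening[["screened"]]))
  else NA_integer_
  structure(list(
    n_clutches = length(clutch_sizes),
    n_testable = length(testable),
    testable_median = if (length(testable)) stats::median(as.numeric(testable)) else NA_real_,
    testable_range = if (length(testable)) range(testable) else c(NA_integer_, NA_integer_),
    pattern_counts = counts,
    n_multi_parent = n_multi,
    fraction_multi_parent = frac,
    prevalence_pct = prev), class = "dataset_summary")
}

#' Write deterministic report files
#'
#' Emits `clutch_parentage.tsv` (one row per embryo: clutch, embryo, dam and
#' sire labels), `pattern_counts.tsv` (one row per mating pattern) and
#' `summary.txt`. Byte-identical output for identical inputs.
#'
#' @param summary a `dataset_summary`
#' @param sexed list of `sexed_parentage`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
render_report <- function(summary, sexed, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  p1 <- file.path(out_dir, "clutch_parentage.tsv")
  rows <- lapply(sexed, function(sp) {
    data.frame(clutch_id = sp$clutch_id, embryo_id = names(sp$dam_of),
               dam = unname(sp$dam_of), sire = unname(sp$sire_of),
               n_parents = sp$n_parents, ambiguous = sp$ambiguous,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(clutch_id = character(0), embryo_id = character(0),
               dam = character(0), sire = character(0),
               n_parents = integer(0), ambiguous = logical(0))
  utils::write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "pattern_counts.tsv")
  pc <- data.frame(pattern = names(summary$pattern_counts),
                   n_clutches = as.integer(summary$pattern_counts))
  utils::write.table(pc, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- file.path(out_dir, "summary.txt")
  lines <- c(
    sprintf("clutches: %d (testable, >=3 embryos: %d)", summary$n_clutches, summary$n_testable),
    sprintf("testable clutch size: median %s, range %s-%s",
            format(summary$testable_median), summary$testable_range[1L],
            summary$testable_range[2L]),
    sprintf("multi-parent clutches: %d of %d testable (%s)",
            summary$n_multi_parent, summary$n_testable,
            if (is.na(summary$fraction_multi_parent)) "undefined"
            else sprintf("%.0f%%", 100 * summary$fraction_multi_parent)),
    if (!is.na(summary$prevalence_pct))
      sprintf("parasitism prevalence: %d%%", summary$prevalence_pct))
  writeLines(lines, p3)
  invisible(c(p1, p2, p3))
}

#' Run the full parentage pipeline on a dataset
#'
#' Splits embryos into clutches, reconstructs the minimum-parent solution
#' per clutch, overlays haplotypes to sex the parents, classifies mating
#' scenarios and summarises the dataset. Deterministic given the inputs.
#'
#' @param gt a `genotype_table`
#' @param ht a `haplotype_table` (may cover only some embryos)
#' @param screening optional host screening counts for prevalence
#' @param exact_cap passed to [min_parent_search()]
#' @return list with `solutions`, `sexed`, `scenarios` (per testable clutch),
#'   `summary`, `clutch_sizes`
#' @export
run_pipeline <- function(gt, ht, screening = NULL, exact_cap = 12L) {
  clutches <- split_by_clutch(gt)
  sizes <- vapply(clutches, function(cl) length(cl$embryo_ids), 0L)
  solutions <- lapply(clutches, function(cl) min_parent_search(gt, cl, exact_cap = exact_cap))
  sexed <- lapply(solutions, resolve_parent_sexes, ht = ht)
  scenarios <- lapply(sexed[vapply(sexed, function(s) s$n_embryos >= 3L, TRUE)],
                      function(s) tryCatch(classify_scenario(s), error = function(e) NULL))
  summary <- summarize_dataset(sexed, sizes, screening)
  list(solutions = solutions, sexed = sexed, scenarios = scenarios,
       summary = summary, clutch_sizes = sizes)
}
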