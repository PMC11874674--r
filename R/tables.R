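#' The published 17-locus marker panel characteristics
#'
#' The printed characteristics of the Smu microsatellite panel developed for
#' cuckoo catfish parentage: per locus the reference sample size, allele
#' count, fragment size range (bp), observed and expected heterozygosity and
#' the published HWE p-value. Shipped as a plain-text fixture; used to
#' parameterise simulations and as the input for panel-level summaries.
#'
#' @return data.frame with columns `locus`, `motif`, `n`, `n_alleles`,
#'   `size_min`, `size_max`, `ho`, `he`, `p_hwe`, `multiplex`
#' @export
panel_table <- function() {
  utils::read.csv(system.file("extdata", "marker_panel.csv", package = "clutchkin",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

#' The roster of examined cuckoo catfish clutches
#'
#' Year, host species and embryo count of the 13 clutches with three or more
#' embryos in which multiple parentage is testable.
#'
#' @return data.frame with columns `clutch_id`, `year`, `host_species`,
#'   `n_embryos`
#' @export
clutch_table <- function() {
  utils::read.csv(system.file("extdata", "clutch_roster.csv", package = "clutchkin",
                              mustWork = TRUE), stringsAsFactors = FALSE)
}

#' Host screening counts behind the prevalence estimate
#' @return named vector c(screened, parasitised)
#' @export
screening_counts <- function() c(screened = 429L, parasitised = 24L)

#' Simulation panel mirroring the published marker characteristics
#'
#' One [locus_def()] per published locus, with its allele count, size range
#' and a target-He frequency scheme hitting the printed expected
#' heterozygosity (capped just under the equifrequent maximum where the
#' printed value is infeasible for the allele count).
#'
#' @return list of [locus_def()]s
#' @export
table1_panel <- function() {
  tab <- panel_table()
  lapply(seq_len(nrow(tab)), function(i) {
    k <- tab$n_alleles[i]
    he <- min(tab$he[i], 1 - 1 / k - 1e-3)
    locus_def(tab$locus[i], k, scheme = "target_He", he = he,
              size_range = c(tab$size_min[i], tab$size_max[i]))
  })
}

#' The study-shaped mating design
#'
#' The 13 testable clutches with their published sizes and reconstructed
#' mating patterns (7 monogamous; 1 polyandrous split 2+1; 2 clutches of two
#' monogamous pairs split evenly; 2 polygynous with one shared sire; 1
#' polygynandrous with one dam and one sire each mating twice), plus
#' optionally the 11 small clutches of 1-2 embryos in which multiple
#' parentage is untestable. Every clutch has its own parents (no cross-clutch
#' sharing) unless `cross_clutch_dam` adds one dam parasitising two hosts.
#'
#' @param include_small include the 11 untestable clutches (24 in total)
#' @param cross_clutch_dam if TRUE, the dams of the first two monogamous
#'   clutches are the same female
#' @return a [mating_design()]
#' @export
study_design <- function(include_small = TRUE, cross_clutch_dam = FALSE) {
  m1 <- function(d, s, n) data.frame(dam = d, sire = s, n = n)
  cl <- function(id, year, host, matings)
    list(clutch_id = id, year = year, host_species = host, matings = matings)
  mono <- list(
    cl("19.GP01", 2019L, "G. pfefferi", m1("F01", "M01", 4L)),
    cl("19.SD01", 2019L, "S. diagramma", m1("F02", "M02", 3L)),
    cl("19.SD03", 2019L, "S. diagramma", m1("F03", "M03", 3L)),
    cl("22.SH01", 2022L, "S. horei", m1("F04", "M04", 8L)),
    cl("22.SH03", 2022L, "S. horei", m1("F05", "M05", 7L)),
    cl("22.SH04", 2022L, "S. horei", m1("F06", "M06", 5L)),
    cl("22.SH05", 2022L, "S. horei", m1("F07", "M07", 6L)))
  if (cross_clutch_dam) mono[[2L]]$matings$dam <- "F01"
  other <- list(
    # polyandrous: one dam, two sires
    cl("19.SH01", 2019L, "S. horei", data.frame(dam = "F08", sire = c("M08", "M09"),
                                                n = c(2L, 1L))),
    # two monogamous pairs
    cl("19.GP02", 2019L, "G. pfefferi", data.frame(dam = c("F09", "F10"),
                                                   sire = c("M10", "M11"), n = c(7L, 7L))),
    cl("19.SD05", 2019L, "S. diagramma", data.frame(dam = c("F11", "F12"),
                                                    sire = c("M12", "M13"), n = c(4L, 4L))),
    # polygynous: two dams sharing one sire
    cl("19.SD02", 2019L, "S. diagramma", data.frame(dam = c("F13", "F14"),
                                                    sire = "M14", n = c(3L, 2L))),
    cl("22.SH02", 2022L, "S. horei", data.frame(dam = c("F15", "F16"),
                                                sire = "M15", n = c(4L, 3L))),
    # polygynandrous: d1 x s1, d1 x s2, d2 x s2
    cl("19.SD04", 2019L, "S. diagramma", data.frame(dam = c("F17", "F17", "F18"),
                                                    sire = c("M16", "M17", "M17"),
                                                    n = c(2L, 2L, 1L))))
  small <- list()
  if (include_small) {
    sizes <- c(rep(1L, 7L), rep(2L, 4L))
    small <- lapply(seq_along(sizes), function(i)
      cl(sprintf("19.XX%02d", i), 2019L, "mixed hosts",
         m1(sprintf("F%02d", 18L + i), sprintf("M%02d", 17L + i), sizes[i])))
  }
  mating_design(c(mono, other, small))
}
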