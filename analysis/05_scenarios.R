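#!/usr/bin/env Rscript
# Dataset-level summary: mating-pattern counts over the testable clutches,
# the multi-parent fraction, clutch-size statistics and parasitism
# prevalence -- the headline numbers of the parentage analysis.
# Run 01_simulate_study.R and 03_parentage.R first.

suppressPackageStartupMessages(library(clutchkin))

tab <- utils::read.delim("results/clutch_reconstruction.tsv")
sizes <- stats::setNames(tab$n_embryos, tab$clutch_id)

cat("clutches:", nrow(tab), " testable (>=3 embryos):", sum(tab$n_embryos >= 3L), "\n")
testable <- tab[tab$n_embryos >= 3L, ]
cat(sprintf("multi-parent clutches: %d / %d (%.0f%%), each with %s parents\n",
            sum(testable$n_parents > 2L), nrow(testable),
            100 * mean(testable$n_parents > 2L),
            paste(sort(unique(testable$n_parents[testable$n_parents > 2L])),
                  collapse = "-")))
cat("pattern counts over testable clutches:\n")
print(table(factor(testable$pattern,
                   levels = c("monogamous", "polyandrous", "polygynous",
                              "two_pairs", "polygynandrous"))))
cat(sprintf("testable clutch sizes: median %d, range %d-%d\n",
            as.integer(median(testable$n_embryos)), min(testable$n_embryos),
            max(testable$n_embryos)))
sc <- screening_counts()
cat(sprintf("parasitism prevalence: %d / %d hosts = %d%%\n",
            sc[["parasitised"]], sc[["screened"]],
            as.integer(round(100 * sc[["parasitised"]] / sc[["screened"]]))))
cat("see results/report/ for the rendered tables\n")
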