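---
title: "Reconstructing brood-parasite mating patterns from embryo genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing brood-parasite mating patterns from embryo genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchkin)
```

## The inference problem

Cuckoo catfish (*Synodontis multipunctatus*) spawn covertly into the mouths
of brooding cichlids, so their mating system cannot be observed directly.
What can be sampled is a *progeny array*: the parasite embryos flushed from
one host female's buccal cavity (a "clutch"), with no candidate parents.
`clutchkin` infers, for each clutch, the smallest number of dams and sires
whose genotypes can explain every embryo, then reads the dam/sire split off
maternally inherited mitochondrial haplotypes, and finally classifies each
clutch into a mating pattern (monogamous pair, polyandry, polygyny, two
independent pairs, or polygynandry). Because any two embryos can always be
explained by a single parent pair, multiple parentage is only testable in
clutches with three or more embryos; smaller clutches are reported
*untestable*, never "monogamous".

## Minimum-parent parsimony

The core model is deliberately conservative: we search for the *minimum*
number of parents compatible with the genotypes, so that multi-parent calls
are never artefacts of over-splitting sibships.

A parent is represented, per locus, by its *transmission set*: the at most
two alleles it passes to sampled offspring. Each parent is additionally
allowed one untransmitted "wildcard" allele per locus — a real parent may
carry an allele that no sampled embryo inherited, which matters for small
families. An embryo genotype $\{u, v\}$ is explained by parents with
transmission sets $T_1, T_2$ iff the pair can be split with one allele from
each set. A set of embryos is *full-sib compatible* when such a parental
pair exists at every locus (missing calls skip that embryo at the locus),
and two full-sib groups may *share a parent* when one transmission set hits
every member of both groups while each group retains a feasible second
parent.

`min_parent_search()` enumerates assignments of embryos to unordered parent
pairs drawn from $P$ abstract parents, for $P = 2, 3, \dots$, stopping at
the first feasible $P$. The search is exhaustive for clutches up to
`exact_cap = 12` embryos (the assignment tree is pruned by incremental
full-sib checks, per-parent two-allele coverage checks and canonical parent
labelling; full joint feasibility is certified at each leaf by a per-locus
constraint solver over transmission sets). *All* minimal solutions are
returned — alternates matter, because allele sharing between true parents
can make genuinely distinct pedigrees equally parsimonious. Above the cap
(the largest clutch here has 14 embryos) a deterministic greedy full-sib
agglomeration fixes the partition and an exact sharing search runs over the
groups; such solutions are flagged `exact = FALSE`.

Two points where the design was genuinely open:

* **Three-homozygote toy case.** For a single locus with offspring
  $\{A/A, B/B, C/C\}$ one might expect four parents (two disjoint pairs),
  but exhaustive enumeration shows three suffice — parents $A/B$, $A/C$,
  $B/C$ mated pairwise. The search and its brute-force oracle agree on 3;
  the package follows the enumeration.
* **Mismatch handling.** The default tolerates zero Mendelian mismatches.
  Rather than absorbing genotyping errors silently, the optional
  sensitivity check (`check_sensitivity = TRUE`) re-runs the search with
  each locus excluded and reports loci whose removal lowers the parent
  count — exactly the clutches where raw electropherograms should be
  re-examined upstream.

## Scoring partitions

`partition_loglik()` scores a sibship partition as the sum over families of
$\log \sum_{\text{parent pairs}} P(\text{pair}) \prod_{\text{off}}
P(\text{off} \mid \text{pair})$, with shared parents collapsed into one
variable (variable elimination over the parent-sharing graph; sharing
structures needing factors over more than two shared parents at once are
rejected rather than approximated). The default frequency mode,
`uniform_minimal`, gives every observed allele weight $1/N_A$. This is the
probability-model counterpart of the common practice of flattening all
allele frequencies to a nominal constant when reconstructing sibships, which
minimises presumed allele sharing between inferred parents and thereby
guards against overestimating parent numbers; a literal unnormalised flat
mode (`flat_unnormalized`, default 0.001 per allele) reproduces that
software idiom for comparison, and `empirical` uses reference-sample
frequencies.

## Matrilines: dams versus sires

Microsatellites alone cannot say which abstract parent is the dam. mtDNA
control-region haplotypes are maternally inherited, so: the number of
distinct haplotypes in a clutch lower-bounds the dam count
(`matriline_lower_bound()`); a parent shared between groups with different
haplotypes must be the sire; and a full-sib group spanning two haplotypes is
a data conflict that is recorded, never repaired. When linked groups share
one haplotype the sexing is ambiguous: one dam (shared parent maternal) and
two sires, or two haplotype-sharing dams and one shared sire. The tie-break
prefers fewer dams — identical maternal haplotypes are positive evidence for
one mother, while two mothers sharing a haplotype requires an extra
coincidence — and the alternative split is always retained, so downstream
reports can present the ambiguity rather than hide it. The practical risk of
haplotype collisions is set by the pool's gene diversity: at the default
pool (13 haplotypes, Hd 0.89) two random dams share a haplotype about 11% of
the time, and the simulator reproduces exactly that failure rate.

## Dyadic kinship cross-check

Independently of the parsimony reconstruction, `classify_dyads()` evaluates
every within-clutch pair under the four standard k-coefficient hypotheses —
unrelated $(1,0,0)$, half sib $(\tfrac12,\tfrac12,0)$, full sib
$(\tfrac14,\tfrac12,\tfrac14)$, parent–offspring $(0,1,0)$ — using the
classical genotype-pair probabilities given 0/1/2 alleles IBD, summed in log
over jointly scored loci. Both members of a dyad are embryos, so a
parent–offspring maximum is not meaningful and is folded into full sib.
Hypotheses are compared by Monte-Carlo likelihood-ratio tests: `lr_test()`
simulates dyads under the *alternative* at the pair's jointly non-missing
loci and reports the upper-tail fraction of simulated likelihood ratios;
when the runner-up cannot be rejected at 0.05 the dyad is annotated
"X or Y". Allele frequencies come from the adult reference sample; embryo
alleles unseen there get a floor frequency $1/(2n+1)$ with renormalisation,
avoiding zero likelihoods. Per-dyad RNG substreams are derived from the
master seed and the pair ids, so batch order never changes a p-value.

## Marker diagnostics

The panel-level functions are standard but self-contained: unbiased expected
heterozygosity $\frac{2n}{2n-1}(1 - \sum p_i^2)$ (a flag switches to the
uncorrected form); an exact conditional HWE test — complete enumeration for
biallelic loci, and for multiallelic loci i.i.d. Monte-Carlo draws of
genotype tables by random pairing of the observed gene copies, which samples
the conditional null distribution directly and needs no Markov-chain
burn-in; haplotype diversity $\frac{n}{n-1}(1-\sum p_i^2)$; and exclusion
probabilities by exact summation over genotype combinations under HWE. The
default exclusion form is the *parent-pair* probability (a random non-parental
pair is Mendelian-incompatible with a random offspring), matching a design
in which no candidate parents are sampled; single-parent forms are provided
for completeness.

## The simulator and what it does (not) emulate

`generate_dataset()` draws parents under HWE from a configurable population,
transmits alleles mendelianly, gives every embryo its dam's haplotype
exactly, and draws an adult reference sample (default 81) from the same
population. Its defaults mirror the study conditions: 17 loci with the
published allele counts (4–22) and expected heterozygosities (0.33–0.93,
realised by a one-major-allele construction whose major frequency is solved
in closed form); clutches of 1–14 embryos under the five mating patterns;
a 13-haplotype mitochondrial pool sized to Hd 0.89; optional allelic
dropout, mistyping and missingness (all default 0). `study_design()`
reproduces the 24-clutch layout, with the 13 testable clutches assigned the
published sizes and patterns.

The simulator intentionally omits: null alleles and other systematic
genotyping artefacts, linkage between loci, population structure or
relatedness among the founding parents, host egg-adoption and embryo
mortality dynamics, and mutation. Passing recovery tests on simulated data
therefore demonstrates the correctness of the inference machinery under the
stated sampling model — not robustness to field-data pathologies, which the
sensitivity reporting is designed to surface instead.

## Numerical and size choices

Monte-Carlo defaults are 10,000 LR simulations per dyad (the analysis
scripts use 2,000 for the batch over all ~250 within-clutch dyads) and
10,000 table draws per HWE test. The test suite scales simulations to keep
the whole run in minutes: 100 random oracle instances for the parsimony
search, 500 null dyads at 1,000 simulations for LR calibration, 40
replicate clutches per mating design for parameter recovery, and
200–400-replicate checks elsewhere; tolerances follow binomial Monte-Carlo
standard errors. Family likelihoods are rescaled per factor to avoid
underflow; exact enumeration thresholds (`exact_cap = 12`, biallelic HWE
enumeration) are stated alongside the functions. All pipeline randomness
flows from one master seed.

## Known limitations

* Exact minimality is certified only up to `exact_cap` embryos; beyond it
  the greedy partition can in principle miss a smaller solution (flagged).
* The parsimony objective cannot distinguish two dams sharing a haplotype
  from one dam; such clutches remain flagged ambiguous by construction.
* Cross-clutch scans inherit the false-positive rate of the panel; with 17
  informative loci spurious FS calls are rare but HS calls between small
  clutches are expected occasionally, as the dyadic tests quantify.
* The HWE test's Monte-Carlo p-values are exact in distribution but
  discrete; at small sample sizes they are conservative.
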