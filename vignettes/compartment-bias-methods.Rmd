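---
title: "Methods: Monte Carlo-Wilcoxon bias tests and isochore compartment-bias analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MCW bias tests and compartment-bias analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartmentBias)
```

# Overview

This package tests whether quantitative differences between two
conditions are *concertedly biased in one direction*, and applies that
machinery to a specific genomic question: do exposure-induced expression
changes point opposite ways in heterochromatin-like (AT-rich) versus
euchromatin-like (GC-rich) genomic compartments? Isochores — long
stretches of relatively homogeneous base composition — serve as the
compartment proxy, classified from AT-rich to GC-rich as L1, L2, H1, H2,
H3.

# The MCW test family

All three tests share two ingredients: a **bias index** (BI) in
[-1, 1] built from signed ranks, and a **rearrangement null**.

**Signed ranking.** Differences equal to zero receive rank 0. Nonzero
differences are ranked ascending by absolute value starting at 1; tied
absolute values all receive the minimum of their would-be ranks; each
rank carries its difference's sign. The min-tie rule makes the index
slightly conservative under heavy ties (tied blocks contribute less than
mid-ranks would), which is deliberate: the same data enter the null, so
p-values remain exact.

**uMCW (unmatched measures).** All cross-set pairs a_i − b_j are formed
— the Cartesian product is the only reading under which "all possible
pairs" defines a unique universe and the normalizer is well defined —
and signed-ranked. BI is the signed-rank sum divided by the sum of
absolute ranks, its value if every a exceeded every b. Only the a−b
subtraction direction is computed; the b−a direction is its exact
negation and adds nothing. The null rearranges which measures belong to
which set: all C(n_a+n_b, n_a) assortments when that count is below the
`maxRearrangements` budget (strictly below — at equality the test takes
the Monte-Carlo path), otherwise `maxRearrangements` uniform draws with
replacement.

**mbMCW (matched pairs).** Per-pair differences (first − second) from
both sets are pooled and ranked *jointly*, because the statistic
compares signed-rank sums across the sets on a common scale. BI =
(S_x − S_y)/M where M is S_x − S_y in the most extreme configuration —
x's pairs holding the largest ranks, all positive, y's the rest, all
negative — which works out to the sum of all absolute ranks. That shared
normalizer makes swap antisymmetry (BI(x,y) = −BI(y,x)) exact by
construction even for unequal set sizes. The null permutes the
pair-to-set assignment; ranks never need recomputing because the pooled
difference multiset is permutation-invariant.

**bMCW (biased measures).** Input is a set of per-element bias measures
(in the genomic application, per-gene uMCW BIs) and designated subsets.
The whole-set index wBI divides the signed-rank sum by the sum of
absolute ranks; its null flips every rank's sign independently (2^N
configurations enumerated when below budget; sign flips on zero ranks
are no-ops, so the enumeration over-counts configurations harmlessly —
proportions are unchanged). Each subset index sBI divides the subset's
signed-rank sum by the sum of the |S| *largest* absolute ranks — its
value had the subset held the most positive measures in the whole set —
and its null draws random same-size memberships. A consequence worth
noting: with all-positive but distinct measures, wBI is 1 but a subset's
sBI is below 1 unless the subset actually holds the top ranks; all
subsets reach 1 only when the positive measures tie.

**P-values.** P_upper and P_lower are the proportions of null BIs at
least as high / as low as the observed one. Ties (within 1e-9, separating
genuine rational-arithmetic ties from floating-point noise) count toward
both tails, so P_upper + P_lower ≥ 1 and each tail is individually
valid. Monte-Carlo proportions are reported raw, without +1 smoothing; a
zero proportion means "below 1/maxRearrangements". Every Monte-Carlo
draw flows from the seed in `mcwConfig`, and the caller's RNG state is
saved and restored, so results are reproducible and side-effect free.

`maxRearrangements` defaults to 10,000. With five replicates per group —
the design all per-gene tests use — C(10,5) = 252, so every per-gene
null is exact and the Monte-Carlo path only engages for larger
phenotype or subset tests.

# Isochore segmentation and gene assignment

Chromosomes are tiled with non-overlapping 100-kb windows; GC is
computed over non-N bases (the alternative — counting N in the
denominator — would drag gap-adjacent windows toward L1 for no
biological reason). Class boundaries are 37/41/46/53 %GC with
lower-inclusive half-open intervals; the boundary convention is
arbitrary but immaterial, since a window sitting exactly on a boundary
is measure-zero in practice and every downstream analysis only needs a
consistent partition. Windows with more than 50% N are assembly-gap
windows: unclassified, excluded, and run-breaking, because composition
is undefined over gaps. Terminal sub-100-kb windows are classified
normally but flagged. Juxtaposed same-class windows merge into
isochores with non-N-weighted mean GC.

Genes (full annotation span, introns included) are assigned to the
single isochore with the largest base-pair overlap; ties go to the
lower start coordinate — a deterministic rule that avoids double
counting in class partitions. Genes overlapping no classified isochore
remain unassigned: they stay in whole-transcriptome tests but join no
class subset.

Relative gene fractions per class are log10((x/n)/(X/N)); classes empty
in the subset yield −Inf as an explicit sentinel rather than an error,
since emptiness is informative.

# Expression statistics

A gene is expressed in a contrast when ≥ 2 reads map to it in ≥ 2 of
the contrast's samples; cpm normalization runs *after* this filter, over
the genes present at that stage, so each sample column of the working
table sums to one million. Per-gene uMCW tests take exposure as the
first set, so positive BI means higher expression under exposure. Genes
on the mitochondrial genome, the Y chromosome, and unassembled segments
are excluded so both sexes are comparable. The 0–1 rescaling used for
visualization maps constant genes to all zeros (a guard against
division by zero; it affects no statistic).

Because cpm is compositional, a fold change planted uniformly across
*all* genes is invisible after normalization — library totals absorb
it. The planted dichotomy (AT classes down, GC classes up) is
approximately balanced and survives normalization; this is worth
remembering when interpreting whole-transcriptome wBIs.

# Pre-ranked enrichment

Genes are ranked by BI, descending, ties broken by gene id for strict
determinism. The running score adds |stat|/Σ_set|stat| at members
(weight exponent 1, the classic weighted statistic) and subtracts
1/(N − N_set) elsewhere; ES is the maximal-magnitude deviation. Sets are
intersected with the ranked universe first, then kept when 15 ≤ size
< 500. The null permutes set membership — equivalent to permuting gene
ranks for a fixed set and much cheaper; p is the proportion of same-sign
null scores at least as extreme (floored at 1/nPerm so no set reports
p = 0 from a finite null), and NES divides ES by the mean |null ES| of
the same sign.

# Compartment bias and the dichotomy call

For each contrast, one bMCW test takes the per-gene BIs as measures and
the isochore classes, chromosomes and (optionally) individual isochores
as subsets. Individual isochores are only tested when named explicitly
or when they hold at least a minimum number of genes, to bound the
multiple-testing surface.

The dichotomy caller formalizes a qualitative pattern: "present" iff
the mean class sBI of {L1, L2} and of {H2, H3} have opposite signs and
each side has at least one class with min(P_upper, P_lower) < α
(default 0.05). H1, the intermediate class, carries no constraint. The
direction label (`present_GC_up` / `present_AT_up`) names the side with
positive bias. Requiring significance on *both* sides keeps the
false-positive rate at or below the nominal α in null simulations.

# The synthetic-data generator

The generator emulates the study conditions — 2 sexes × 2 tissues × 5
groups (DMSO control plus four exposures) × 5 replicates, 100 RNA
samples — and plants known structure:

- **Genome**: per chromosome, fixed-length blocks at GC targets
  30/39/43/50/60%, one block per class, plus an all-N gap block on
  chromosome 1. At 100-kb scale the realized window GC sits within a few
  tenths of a percent of target (binomial sampling), comfortably inside
  the ±1% placement tolerance. Default scale (3 chromosomes, 200-kb
  blocks) keeps a full pipeline run in seconds.
- **Genes**: non-overlapping spans placed wholly inside single blocks so
  each gene's true class is unambiguous; recorded in the truth table.
- **Counts**: negative binomial around class-shifted means — the
  standard noise model for bulk RNA-seq replicates — with dispersion 0.1
  and per-gene log-normal baselines around 100 counts. Exposure samples
  of a gene are shifted by 2^(planted log2 fold change of its class);
  defaults plant nothing (a null genome) and analyses opt into shifts.
- **Gene sets**: sizes spanning both tails of the 15/500 filter; a
  fraction are class-skewed (8× sampling weight for one class),
  emulating compartment-biased functional terms.
- **Phenotypes**: Gaussian traits with standardized group effects,
  pre/post fasting pairs with a common weight drop, and a log-normal
  plasma panel in which out-of-range values cluster in a few
  boundary-prone metabolites (as in real panels, where some analytes sit
  near the standard curve edge) so that complete-case metabolites exist
  for the PCA.

What the generator does **not** emulate: exon/intron gene structure,
sequence composition beyond GC, library-size variation beyond the
compositional effect, correlated gene modules, batch effects, or any
covariance between phenotypes and expression. Passing recovery tests
therefore demonstrates that the statistics detect the structure they
target at realistic noise levels — not that real tissues contain that
structure.

# Phenotype analyses

Body weight is normalized by days of age; glucose, tissue weights and
plasma metabolites additionally by body weight, matching the unit
chains g/days-old and (pg/mL)/g/days-old. Matched pairs are always
(later − earlier): post − pre for fasting, exit − entry for cage
consumption, so "exposure loses more weight" reads as a negative mbMCW
BI. Plasma values outside the standard curve, or non-extrapolable, are
zeroed. The metabolite PCA uses complete-case metabolites (valid for
every mouse of the sex under analysis), centering, and — by default —
unit-variance scaling, since concentrations span orders of magnitude;
both modes are exposed because the choice is a genuine judgment call.
Component signs follow a fixed convention (largest-magnitude loading
positive) so outputs are bit-reproducible. Dose arithmetic converts a
drinking-water concentration to mg/kg/day using the tributyltin cation
mass (290.06 g/mol) by default; the chloride salt (325.5) is a
parameter away and yields the same one-significant-figure dose.

# Numerical and design choices

- Coordinates are 1-based closed inside GRanges (the Bioconductor
  convention) and 0-based half-open in BED output and window tables.
- Exact-path enumeration caches index-subset matrices, shared across
  the thousands of per-gene tests of a contrast.
- Problem sizes in the validation suite — 100–500 genes per replicate,
  100 replicates for recovery/false-positive rates, 500 sets for
  calibration — were chosen as the smallest scales at which the binomial
  error bands in the acceptance properties are meaningful.
- The cross-contrast aggregation of enrichment results (e.g. "most
  extreme p across contrasts") is left to the user: the package emits
  per-contrast tables and prescribes no aggregation rule.

# Known limitations

- The uMCW "all possible disjoint pairs" reading (full Cartesian
  product) and the mbMCW normalizer are interpretations validated by
  internal symmetry properties, not against an external reference
  implementation.
- Min-tie ranking makes BIs of heavily tied data non-comparable in
  magnitude to mid-rank-based statistics, though p-values remain valid.
- Per-gene tests are marginal: no shrinkage or dispersion sharing across
  genes, by design — the method is rank-based and model-free.
- The dichotomy caller summarizes four class-level tests; it does not
  correct across contrasts.
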