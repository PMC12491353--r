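---
title: "Models and methods behind ystrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ystrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpop)
```

ystrpop analyses Y-chromosomal short tandem repeat (Y-STR) haplotypes of the
kind produced by the 17-locus Yfiler multiplex: one row per male, one repeat
count per locus, with DYS385 reported as an unordered pair and occasional
partial-repeat ("microvariant") alleles such as 17.2 at DYS458. This vignette
records the statistical models, the numerical conventions, and the design
decisions taken where the methodology left genuine choices open.

## Data model

A haplotype table is an ordinary tibble (`sample_id`, `population`, then one
numeric column per panel position). Three conventions apply throughout:

* **DYS385 is stored sorted ascending.** The assay cannot phase the two
  copies, so `(17, 13)` and `(13, 17)` are the same observation; sorting
  makes every downstream computation deterministic.
* **DYS389II is stored raw.** The familiar allele-frequency display
  subtracts DYS389I from DYS389II (the DYS389II amplicon contains the
  DYS389I repeat stretch); `encode_dys389ii()` provides that view, guarded
  by a state flag so the transform is idempotent. Distances default to the
  raw value — the encoding is a reporting convention, not a different
  measurement — but every distance function exposes a switch because
  published matrices do not always say which convention they used.
* **Missing is missing.** The input sentinel `99` and empty cells both map
  to one missing state (`NA`). Missing calls stay inside haplotype keys as
  their own symbol (so diversity statistics remain well defined on
  incomplete data), contribute zero to pairwise distances (pairwise
  deletion), and are excluded locus-wise from network medians.

## Forensic summary statistics

With haplotype counting frequencies $p_i$ and sample size $n$:

* haplotype diversity $HD = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ (Nei),
* haplotype match probability $HMP = 1 - HD$,
* match probability $MP = \sum_i p_i^2$ (also per locus on allele
  frequencies, with power of discrimination $PD = 1 - MP$),
* discrimination capacity $DC = h/n$ for $h$ distinct haplotypes,
* fraction of unique haplotypes $FUH = 100\,s/h$ for $s$ singletons.

$FUH$ has competing definitions in the applied literature ($s/h$, $s/n$,
$h/n$); ystrpop reports $100\,s/h$ and exposes $s$, $h$ and $n$ so any ratio
can be formed. The frequency of the most common haplotype is likewise
reported under both the count/$n$ and count/$h$ conventions, labelled.
Per-locus gene diversity is available biased ($1-\sum p_i^2$) and unbiased
($\tfrac{n}{n-1}$-corrected); the over-loci mean and SD default to the
unbiased form with the sample SD. Percentage *displays* of haplogroup
composition truncate (rather than round) at two decimals, the convention
used in forensic reports (`76/128` displays as `59.37`).

## Distances, pairwise differences and AMOVA $R_{ST}$

The microsatellite distance between two haplotypes is the sum over loci of
squared repeat-count differences, DYS385 contributing its two sorted
positions. Microvariants enter at face value by default (17.2 vs 17
contributes $0.04$); a switch rounds first. For populations $X, Y$,
$\Pi_X$ is the mean distance over unordered within-population pairs,
$\Pi_{XY}$ the mean over all $n_X n_Y$ cross pairs, and the corrected
between-population distance is $\Pi_{XY} - (\Pi_X + \Pi_Y)/2$.

Pairwise $R_{ST}$ comes from a two-level analysis of molecular variance on
the same distances: with $N = n_A + n_B$ and $P = 2$,
$SSD_{total} = \frac{1}{N}\sum_{i<j} d_{ij}$,
$SSD_{within} = \sum_p \frac{1}{n_p}\sum_{i<j \in p} d_{ij}$, mean squares
on $P-1$ and $N-P$ degrees of freedom,
$n_c = (N - \sum_p n_p^2/N)/(P-1)$, $\sigma^2_w = MS_{within}$,
$\sigma^2_a = (MS_{among} - MS_{within})/n_c$, and
$R_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Negative estimates are
reported as computed — the estimator is unbiased, not non-negative; two
identical groups of size $n$ land at exactly $-1/(n-1)$ — and a zero total
variance is flagged rather than returned as NaN. Note that duplicating a
population gives $\Pi_{XY} = (1 - 1/n)\,\Pi_X$, not $\Pi_X$: the cross
average includes each profile paired with its own copy at distance zero.
Both effects vanish as $n$ grows.

## Ordination

Classical (Torgerson) scaling eigendecomposes $-\tfrac12 J D^2 J$ via
`stats::cmdscale()`; Euclidean-embeddable matrices are inverted to machine
precision at the embedding dimension. Nonmetric scaling minimizes Kruskal's
stress-1 with monotone regression on dissimilarity ranks via
`MASS::isoMDS()`, initialized from the classical solution so the fit is
deterministic; stress is reported $\times 100$. The wrapper recomputes
stress-1 independently (isotonic regression via `stats::isoreg`) to judge
convergence — `isoMDS` does not expose an iteration count, so `iterations`
is `NA` for nonmetric fits and `converged` means the final stress did not
exceed that of the initial configuration. Axes are centered and carry a
deterministic sign convention (first nonzero coordinate positive). Distance
matrices with small negative entries (as pairwise $R_{ST}$ can produce) are
floored at zero with a message before ordination.

Agglomerative clustering defaults to UPGMA (`stats::hclust`, average
linkage; complete and Ward available). Heights are exposed as ultrametric
node depths — half the merge distance — matching the Newick export through
`ape`, so two leaves at distance $d$ merge at height $d/2$.

## Median-joining networks

Preprocessing follows the standard conventions for STR network input:
microvariants are rounded to the nearest integer (half away from zero), the
constitutively duplicated DYS385 a/b pair is excluded, missing calls are
excluded locus-wise, and identical reduced haplotypes collapse into one node
with a multiplicity. Loci are treated as multistate ordered characters with
step distance $\sum_l |a_l - b_l|$ and uniform weights.

The network construction iterates: build the $\varepsilon$-relaxed minimum
spanning network (the union of all minimum spanning trees, plus every edge
within $\varepsilon$ of the weight at which its endpoints first connect
under grouped Kruskal processing); form the locus-wise median of every
connected triple (the lower median when values disagree, the majority value
when one of the three is missing); and admit a median vector only while it
lowers the connection cost — the MST length — of the node set (cost ties
are admitted when $\varepsilon > 0$, and a generation cap guards
termination). Median nodes that stop paying for themselves are pruned until
a fixpoint. All tie-breaks are lexicographic on haplotype vectors, so the
result is deterministic and independent of input order. On small fixtures
the construction provably reaches the brute-force Steiner minimum (the test
suite enumerates lattice candidates exhaustively); in general the total
cost never exceeds the MST over observed haplotypes. $\varepsilon$ defaults
to 0, the customary setting when no relaxation is requested.

## Allelic richness by rarefaction

For allele counts $N_{ij}$ (allele $i$, population $j$) with totals $N_j$,
the expected number of distinct alleles in a standardized subsample of $g$
gene copies is
$\hat\alpha_g = \sum_i \left[1 - \binom{N_j - N_{ij}}{g}\middle/\binom{N_j}{g}\right]$,
and the expected number of private alleles multiplies each term by the
probability that the allele is absent from every other population's size-$g$
subsample. Binomial ratios are evaluated in log-gamma arithmetic. The grid
of $g$ runs from 2 to the smallest per-locus population total; males are
haploid at these loci, so one allele is one gene copy and DYS385
contributes its two copies to its own pooled spectrum.

## Ancestry variability: $F_{ST}/F_{ST}^{max}$

Treating each individual's membership-coefficient vector (a row of a
STRUCTURE-style Q matrix) as an allele-frequency vector, the variability of
a population's rows is
$F_{ST} = \bigl(\overline{\sum_k q_{ik}^2} - \sum_k \bar p_k^2\bigr)/\bigl(1 - \sum_k \bar p_k^2\bigr)$.
Because $F_{ST}$ is bounded by a function of the mean membership vector, it
is normalized by the maximum attainable over all row-stochastic matrices
with the same column means. That maximum concentrates rows on vertices:
$\lfloor I\bar p_k\rfloor$ rows sit at vertex $k$ and the fractional
remainders are packed into as few mixed rows as possible; the packing
maximizing the sum of squares is found by pouring the remainders in every
order of the nonzero fractional masses (at most $7!$ orders are tried;
beyond that the descending order is used). The test suite verifies this
closed form against exact vertex enumeration of the transportation polytope
for small instances. Degenerate cases ($\bar p$ at a vertex, or all rows
identical) define the ratio as 0 with a flag. Bootstrap uncertainty
resamples rows with replacement within each population (default $B = 100$,
seeded); group differences are compared with the tie-corrected
Kruskal–Wallis rank test. The STRUCTURE inference itself is out of scope:
Q matrices are consumed as input or simulated.

## Haplogroup prediction

A naive-Bayes classifier over per-haplogroup, per-locus allele frequencies:
$P(g \mid \text{profile}) \propto \pi_g \prod_l P(a_l \mid g, l)$ in log
space, with additive pseudocount smoothing
$P(a \mid g, l) = (c_{agl} + \alpha)/(n_{gl} + \alpha V_l)$, $V_l$ the locus
vocabulary size and $\alpha = 0.5$ (a Jeffreys-style default, stated in the
model object). Missing loci are skipped; ties break alphabetically; a
profile missing every locus gets the uniform posterior with a flag. The
package ships no reference panel — published predictors do not publish
their training data — so references are user-supplied (or simulated), and
no claim is made of matching any online predictor's assignments.

## The synthetic-data generator

`simulate_haplotypes()` emulates the structure these analyses assume: each
individual draws a founder lineage, copies its founder haplotype, and
accumulates symmetric single-step mutations (the stepwise mutation model,
under which the squared-difference distance behind $R_{ST}$ is the natural
estimator). Defaults mirror an Arabian-peninsula-style sample: $n = 128$ in
one population; two dominant founder lineages at 59% and 21% plus a 20%
residual class; a microvariant rule adding $+0.2$ at DYS458 to every
chromosome of the dominant lineage, reproducing the concentration of
DYS458 partial repeats in one lineage; mutation rate
$\mu = 2\times10^{-3}$ per locus per generation, the canonical average
Y-STR rate; and a per-individual generational depth drawn geometric with
mean 200 — a timescale of a few thousand years, consistent with the recent
star-like expansions such samples show, and producing the high
discrimination capacity typical of Yfiler data. Founder haplotypes start
from a plausible modal Yfiler haplotype separated by multi-locus offsets;
they are configuration constants, not biological claims. Multi-population
scenarios first drift each population's founder copies apart for a
configurable number of generations.

What the generator does *not* emulate: multi-step mutations, locus-specific
mutation rates, allele-range constraints, genotyping error, and population
growth curves. Passing tests therefore demonstrate correctness of the
estimators under the stepwise model, not robustness to every feature of
real data.

One experimental-design note: in the divergence-ordering experiment (two
populations at founder-drift depths 0, 20 and 80 generations), the default
three-lineage mixture is deliberately replaced by a single founder lineage.
A shared lineage mixture inflates the within-population variance by the
squared distance between founder haplotypes, which swamps the shallow
between-population signal; a single lineage isolates exactly the drift the
experiment varies.

## Numerical and testing choices

Problem sizes in the test suite are the package's own choices: Monte-Carlo
rarefaction oracles run at $10^4$ resamples (3-standard-error agreement),
exact Steiner and transportation-polytope oracles run on instances small
enough to enumerate exhaustively ($\le 5$ haplotypes $\times \le 4$ loci;
$I \le 6$, $K \le 3$), and simulation-based property checks use 10 seeded
replicates of 40–128 individuals. Tolerances: simplex row sums to $10^{-6}$
(renormalized), SSD additivity to $10^{-9}$, closed-form $F_{ST}^{max}$ to
$10^{-6}$.

## Known limitations

* The published per-locus regression values (e.g. a DYS458 match
  probability of 0.138672 and a within-population average pairwise
  difference of 205.13314) require the study's full haplotype deposit,
  which is distributed through a supplementary archive and a YHRD
  accession; the corresponding regression test states this and fails until
  a local copy is supplied at `inst/extdata/yemen_yfiler_haplotypes.tsv`.
* Cross-population figures built on dozens of external published datasets
  (52-population distance matrices, their MDS stress, STRUCTURE runs) are
  supported as computations on user-assembled tables but are not
  reproduced from scratch.
* AMOVA significance permutations, multi-level AMOVA, maximum-parsimony
  network post-processing, rho-based dating, and STRUCTURE/CLUMPP/Distruct
  processing are out of scope.
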