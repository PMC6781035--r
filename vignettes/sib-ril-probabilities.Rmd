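---
title: "Exact multilocus probabilities in sibling-mated RILs: model, solver, and imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact multilocus probabilities in sibling-mated RILs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibril)
```

## The problem

A two-way recombinant inbred line (RIL) is produced by crossing two
homozygous founders, then inbreeding until every locus is fixed.  Under
*sibling mating* (SIB RILs) a brother and a sister are crossed at each
generation, as in mouse and other animal panels where selfing is impossible.
The fixed line is a mosaic of the founder genomes; quantitative work with
such panels (map construction, QTL likelihoods, imputation) needs the
probability of every multilocus genotype of the fixed line, given the
meiotic recombination fractions between the loci.

Fixation takes, formally, infinitely many generations, so these
probabilities cannot be obtained by iterating a finite recursion.  For two
and three loci the classical closed form is the Haldane–Waddington relation

$$R \;=\; \frac{4r}{1 + 6r},$$

where $r$ is the per-meiosis recombination fraction of a locus pair and $R$
the probability that the fixed line is recombinant for that pair.  `sibril`
implements a self-consistency method that extends exact computation to an
arbitrary number $L$ of linked loci, and to different female and male
recombination rates.

## IBD index lists and their symmetry classes

Label the four F1 chromosomes 0, 1 (the female's homologues) and 2, 3 (the
male's).  The material of the fixed line traces back, locus by locus, to
exactly one F1 chromosome; an *IBD index list* $u = (i_1, \dots, i_L)$,
$i_\ell \in \{0,1,2,3\}$, records these origins, and $Q(u)$ is its
probability.  The $4^L$ probabilities $Q$ are highly redundant: swapping the
two homologues within a sex cannot change any probability, and when female
and male meioses are statistically identical the two sexes can be swapped as
well.  These relabelings form a group of 8 permutations (4 in the
sex-dependent case); `ibd_classes()` partitions the $4^L$ lists into orbits
by explicit enumeration and keeps one lexicographically minimal
representative per orbit, with the orbit size as its weight.  In the
equal-sex mode the number of classes is $2^{L-2}(2^{L-1}+1)$ — 1, 3, 10, 36,
136, … — which the enumeration reproduces for every $L$ tested (a brute-force
orbit partition provides an independent check in the test suite).

Computing weights as true orbit sizes, rather than via the 4-vs-8 shortcut
valid in the equal-sex mode, means the sex-dependent mode (weights 2 and 4)
needs no special casing.

## Self-consistency

Decomposing the inheritance over the next generation gives, for every $u$,

$$Q(u) \;=\; \sum_v T[u \to v]\, Q(v),$$

where $v$ runs over the lists reachable in one generation and $T$ is built
from per-meiosis factors: each chromosome $j$ of the next generation is the
product of one meiosis (0 and 2 are female-meiosis products, 1 and 3
male-meiosis products); the loci assigned to $j$ contribute $\tfrac12$ for
the first locus and, for each successive pair, the probability $r_{l,l'}$ or
$1 - r_{l,l'}$ that the interval is, or is not, recombinant — "recombinant"
meaning that the origins $u_l$ and $u_{l'}$ differ.  Because the process
from the next generation to fixation is statistically identical to the
original one, the same $Q$ appears on both sides, closing the infinite
process into a finite linear system.

The homogeneous system is rank-deficient by exactly one: summed over all
origins $u$, the transition probabilities into any fixed target $v$ equal 1,
so the sum of all equations vanishes identically.  (This summed-over-origins
direction is the stochasticity property that matters; the transition matrix
is *not* row-stochastic away from $r = \tfrac12$, as the two-locus entries
$(1-r)/2, \tfrac14, \tfrac14, (1-r)/2$ show.)  One homogeneous equation —
by default the last in lexicographic order, but the solution is invariant to
the choice, which the tests verify — is therefore replaced by the
normalization $\sum_u Q(u) = 1$, whose coefficients on the representatives
are the orbit weights.

`build_reduced_system()` assembles the reduced system with every reachable
$Q(v)$ mapped to its canonical representative, and `solve_Q()` solves it.
Numerical choices:

* **Exact rationals.**  When every rate is a small exact fraction and the
  system has at most 64 unknowns ($L \le 4$ equal-sex), the build and solve
  run in exact rational arithmetic (numerator/denominator pairs held in
  doubles, reduced at every step; an operation that would leave the
  exactly-representable range falls back to floating point).  Two-locus
  results such as $Q(0,0) = 1/(4+24r)$ are then reproduced bit-exactly.
* **Floating point.**  Otherwise a dense LU solve is used up to 2500
  unknowns and a sparse direct solve above.  The dense threshold is
  deliberately high: each self-consistency row has up to $2^L$ structural
  nonzeros and sparse LU fills in heavily, so dense LAPACK is an order of
  magnitude faster at a few thousand unknowns.
* **Degenerate inputs.**  Coincident loci ($r = 0$ between distinct
  markers in larger maps) can make the system singular; the solver reports
  this with guidance to merge the loci rather than guessing.
* **Residuals.**  `residual_check()` re-evaluates every self-consistency
  equation — including the dropped one — through the scalar
  transition-probability path, independent of the vectorized builder, plus
  the normalization; exact solves return exactly 0 and float solves stay
  below $10^{-10}$ for the sizes exercised by default.

Problem sizes: the class count grows like $4^L/8$ and the build like
$16^L$.  Systems up to $L = 6$ (528 unknowns) solve in seconds and are part
of the default test run; $L = 7$ (2080) takes a few seconds, $L = 8$ (8256)
about a minute, and those sizes are supported but not exercised by default.
$L$ is capped at 10.

## Rates, maps, and the sex-dependent mode

`recomb_model()` accepts either map positions in cM (all pairwise fractions
then derive from the Haldane map function $r = (1 - e^{-2d/100})/2$, which
makes them no-interference consistent, including non-adjacent pairs), a full
pairwise matrix (validated for symmetry and range; accepted with a warning
when it violates no-interference additivity, since the linear algebra is
well defined regardless), or adjacent fractions (non-adjacent entries filled
by $r_{ac} = r_{ab} + r_{bc} - 2 r_{ab} r_{bc}$).  Female and male rates may
differ (`rf`, `rm`); the symmetry group then loses the sex swap and the
class count roughly doubles.  The per-meiosis factor isolates where an
interference model would plug in, but only the no-interference model is
implemented.

A classical check the package reproduces: with sex-dependent rates the
two-locus RIL recombination fraction is
$R = 2(r^f + r^m) / (3(r^f + r^m) + 1)$, which depends on the two rates
only through their mean — so the Haldane–Waddington relation survives
sex-dependence if $r$ is read as the sex-averaged rate — even though the
individual $Q$'s are asymmetric in $r^f$ and $r^m$.

## Genotype probabilities

Founder-1 alleles (written A) sit on chromosomes 0 and 2, founder-2 alleles
(a) on 1 and 3.  A genotype $G = (\alpha_1, \dots, \alpha_L)$ is therefore
compatible with exactly $2^L$ index lists, and
$P(G) = \sum_{u \,\text{compatible}} Q(u)$, evaluated by canonical lookup
per compatible list ($2^L$ terms) rather than by expanding $Q$ to the full
$4^L$ table — both are feasible up to $L = 10$, but the lookup keeps memory
predictable.  `genotype_distribution()` tabulates all $2^L$ genotypes;
complementary genotypes always have equal probability and the table sums
to 1.  `pairwise_R()` marginalizes an $L$-locus solution to any locus pair;
with map-derived rates this equals `hw_R()` at the pairwise fraction for
*all* pairs, adjacent or not, which the tests assert to $10^{-10}$ — a
strong end-to-end consistency check between the combinatorics, the builder,
and the solver.

## The forward simulator

`simulate_population()` is an independent Monte Carlo route to the same
quantities: it tracks the four chromosomes of a sibling pair as sequences of
F1 labels, produces gametes marker-by-marker (first locus a fair coin
between the homologues, then an independent source switch per interval with
the interval's recombination fraction — exactly equivalent, at the markers,
to continuous crossover positions under no interference), and iterates
until *IBD* fixation, i.e. all four chromosomes identical at every locus.
IBD fixation is stricter than allelic fixation, and is the event the $Q$'s
describe.  Fixation is almost sure, so the default 500-generation cap only
triggers a warning and the simulation continues; typical fixation times are
a few tens of generations.

What the generator emulates — and does not: Mendelian segregation without
bias, no interference, no selection or segregation distortion, fully
informative biallelic markers, complete fixation (no residual
heterozygosity).  Agreement between simulation and the exact solver
(200,000 replicates at $L = 3$ stay within 4 standard errors per genotype)
validates the algebra under the model's own assumptions; it cannot speak to
interference or distortion in real data.

## Imputation of missing calls

Given a genotype matrix with missing calls and the marker map,
`impute_matrix()` processes each individual's maximal runs of missing
markers:

* one flanking call only (run touches a chromosome end): copy it across;
* two concordant flanks: fill with the shared call;
* two discordant flanks: compute the exact genotype distribution of the
  flanks-plus-block loci and take the maximum-probability genotype
  compatible with both flank calls.  Selecting the compatible joint argmax
  is equivalent to the conditional (posterior) argmax given the flanks,
  since the conditioning event is the same for all candidates.

Exact ties (e.g. a single missing marker exactly halfway between discordant
flanks) resolve deterministically toward the left flank.  Blocks whose
flanks-plus-interior exceed `max_block_loci` (default 8) are split at the
genetic midpoint of the flanked interval, each side copying its nearer
flank.  The default cap reflects measured solver cost — 9- and 10-locus
blocks would need systems of 32,896 and 131,328 unknowns, far beyond what
per-block solves can afford — and `benchmark_impute()` lowers it to 6 so
that a full benchmark (100 individuals × 100 markers × 6 fractions × 10
replicates) runs in about three minutes; at 70% missing data the measured
error difference between caps 6 and 7 is well inside the
replicate-to-replicate spread.  Heterozygous or non-parental input tokens
are coerced to missing on read, matching the usual practice of treating
residual heterozygosity in nearly-fixed lines as missing data.

Masking for benchmarks (`mask_genotypes()`) selects an exact count of cells
uniformly without replacement at the matrix level, so a "30% missing"
replicate masks exactly 30% of calls.  On the standard design (100
individuals, 100 markers on 150 cM) the mean error rate increases with the
missing fraction and stays far below the 0.5 coin-flip baseline — a few
percent at 10% missing, below 10% at 70% missing, as computed by the test
suite.

## Known limitations

* Only 2-way SIB RILs: no $2^k$-way funnels, advanced intercross,
  MAGIC/NAM designs, and no finite-generation residual heterozygosity.
* No crossover interference model (the per-meiosis factor is the hook).
* One linkage group per model; unlinked groups factorize exactly
  ($r = \tfrac12$ gives independent uniform factors), so multi-chromosome
  data are handled per group.
* Exact rational solving is limited to small systems and rates expressible
  as small fractions; everything else is double precision with residuals
  reported.

## A worked session

```{r example, eval = FALSE}
m <- recomb_model(r = 1/4)
sol <- solve_Q(m)
sol$Q                      # 1/10, 1/20, 1/20 (exact)
genotype_distribution(sol) # AA/aa: 0.3, Aa/aA: 0.2
pairwise_R(sol, 1, 2)      # 0.4 = 4r/(1+6r)

m3 <- recomb_model(map = c(0, 20, 50))
sol3 <- solve_Q(m3)
residual_check(sol3)

pop <- simulate_population(200, m3, seed = 1)
masked <- mask_genotypes(pop, 0.2, seed = 2)
imputed <- impute_matrix(masked$genotypes, m3)
imputation_error(imputed, pop, masked$mask)
```
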