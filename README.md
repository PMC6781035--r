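# sibril

Exact multilocus genotype and identity-by-descent (IBD) probabilities in
2-way **sibling-mated recombinant inbred lines** (SIB RILs), for arbitrary
numbers of linked loci and optionally sex-dependent recombination rates —
with a forward pedigree simulator and an exact-probability imputation
routine for missing genotype calls.

## Who this is for

Quantitative and population geneticists working with sibling-mated RIL
panels (e.g. mouse panels, where selfing is impossible).  Genetic-map
construction, QTL likelihoods and imputation all need the expected
frequencies of multilocus genotypes in the fixed lines; for SIB RILs the
classical results stop at three loci.

## The method

Label the four F1 chromosomes 0, 1 (female homologues) and 2, 3 (male
homologues).  The fixed line inherits, at each locus ℓ, IBD from exactly one
F1 chromosome; `Q(i₁,…,i_L)` is the probability of a given origin list.
Decomposing over the next generation gives the self-consistent system

    Q(u) = Σ_v T[u → v] Q(v),

with transition probabilities `T` built from per-meiosis factors under the
Haldane (no-interference) model.  Because the process from the next
generation to fixation is statistically the same process, the equations
close the formally infinite inbreeding into a finite linear system.  The
4^L unknowns reduce to their equivalence classes under chromosome
relabeling (≈ 4^L/8 classes), one dependent equation is replaced by the
normalization Σ Q = 1, and the system is solved — in exact rational
arithmetic for small systems, numerically otherwise.  The 2^L genotype
probabilities follow by summing Q over compatible origin lists (A-alleles
live on chromosomes 0 and 2, a-alleles on 1 and 3).  Marginalizing any
solution to a locus pair recovers the Haldane–Waddington relation
`R = 4r/(1+6r)`; with sex-dependent rates the package derives
`R = 2(r^f+r^m)/(3(r^f+r^m)+1)`, i.e. the classical relation evaluated at
the sex-averaged rate.

## A worked example

```r
library(sibril)
m <- recomb_model(r = 1/4)   # two loci, recombination fraction 1/4
sol <- solve_Q(m)
sol
#> IBD probabilities: 3 classes, L = 2, equal-sex mode, rational arithmetic
#>  index_list weight    Q Q_num Q_den
#>         0,0      4 0.10     1    10
#>         0,1      4 0.05     1    20
#>         0,2      8 0.05     1    20
#> max self-consistency residual: 0
```

The three non-equivalent IBD probabilities are exact rationals:
`Q(0,0) = 1/10` (both loci trace to the same female homologue — weight 4,
as its orbit under relabeling has 4 members), and `Q(0,1) = Q(0,2) = 1/20`.
From these, the genotype distribution and the RIL recombination fraction:

```r
genotype_distribution(sol)
#>   genotype probability num den
#> 1       AA         0.3   3  10
#> 2       Aa         0.2   1   5
#> 3       aA         0.2   1   5
#> 4       aa         0.3   3  10
pairwise_R(sol, 1, 2)
#> [1] 0.4
```

`R = 0.4 = 4r/(1+6r)` at `r = 1/4`: the two recombinant genotypes carry
`R/2 = 0.2` each.  The same machinery runs for many loci (`recomb_model(map
= c(0, 20, 50, ...))`, positions in cM) and for sex-dependent rates
(`recomb_model(rf = 0.1, rm = 0.3)`).

Simulation and imputation:

```r
m3  <- recomb_model(map = c(0, 20, 50))
pop <- simulate_population(200, m3, seed = 1)      # forward pedigree MC
masked  <- mask_genotypes(pop, 0.2, seed = 2)
imputed <- impute_matrix(masked$genotypes, m3)     # exact-probability fill
imputation_error(imputed, pop, masked$mask)
```

A thin command-line wrapper with subcommands `enumerate`, `solve`,
`genotype-probs`, `simulate`, `impute` and `benchmark-impute` is installed
as `exec/sibril`.

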