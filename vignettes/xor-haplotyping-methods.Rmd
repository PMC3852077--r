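---
title: "Phasing xor-genotypes by sparse dictionary selection: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing xor-genotypes by sparse dictionary selection: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xhsd)
```

## The inference problem

An xor-genotype records, per SNP locus, only whether an individual is
heterozygous there: `x = h1 ⊕ h2` for the two unobserved haplotypes. Two
layers of information are lost relative to regular genotypes: the phase of
the heterozygous loci (as in ordinary phasing) *and* the allele carried at
every homozygous locus. Consequently every binary vector `z` is a valid
partner for every xor-genotype (`h2 = x ⊕ z`), and a population-level
principle is needed to pick among the `2^L` per-individual possibilities.
`xhsd` uses maximum parsimony: explain all `N` individuals with the fewest
distinct haplotypes. This presumes the population shares haplotypes — true
for regions of appreciable linkage disequilibrium, and increasingly violated
as diversity grows (see *Limitations*).

## Greedy dictionary selection

The candidate set is the implicit ordered family of all `2^L` binary
columns; column `k` is the binary expansion of `k − 1` with SNP 1 as the
least-significant bit. The ordering is part of the method's contract — gain
traces and tie-breaks are stated in terms of it — and the set is never
materialized as a matrix.

Starting from an empty dictionary `D`, each iteration scores every
candidate column `j ∉ D` by the population fitness of `D ∪ {j}` and adds
the maximizer, stopping when each individual is exactly reconstructed by
one dictionary column doubled or the XOR of two columns. Per-individual
multiplicities always total 2: the degenerate "one column, multiplicity 1"
reading is excluded, since an xor-genotype is the composition of exactly
two (possibly identical) haplotypes.

Two fitness modes are implemented:

* **indicator** (default): `F_i(D) = ‖x_i‖² · 1[x_i exactly
  reconstructable from D]`. This is the mode whose gain sequence matches
  the method's published hand trace on the three-individual example
  (gains 0.33/0.66 at the second iteration, 1.33 at the third); the
  package's reference values are all computed in this mode.
* **residual**: the literal variance-reduction reading
  `F_i(D) = ‖x_i‖² − min_A L_i(A)`, floored at zero so that distant
  reconstructions cannot push an individual's fitness negative.

Termination is decided by "all best residuals are zero on observed loci",
not by fitness equality: an all-homozygous xor-genotype has norm 0 and
would otherwise be indistinguishable from an unexplained record. For
pure-xor data convergence is guaranteed (any column's partner explains an
individual), with at most `N + 1` iterations; a defensive error triggers
beyond `2^L` iterations.

**Tie-breaking.** Equal maximal gains are resolved to the lowest column
index by default — deterministic, auditable, and consistent with the
published trace at the iteration where two candidates tie at 4/3. A seeded
random mode mirrors assay-style arbitrary choices among equal maxima.

**Zero-marginal-gain steps.** When regular genotypes are present, a
situation arises that pure-xor data never produces: no single added column
can complete any unexplained individual (a regular genotype needs *both*
members of a compatible pair in the dictionary, and columns arrive one at a
time). In that situation the selection falls back, in order, to (i)
candidates that are a compatible half of some unexplained regular genotype,
weighted by the individuals' contribution, (ii) the residual-mode variance
reduction, (iii) the lowest index. The fallback is the package's own
termination device: it guarantees each unexplained regular genotype is
completed within two selections, bounding the dictionary at `2N + 2`
columns for mixed populations. Without it, a flat gain vector would be
resolved by the lowest-index rule alone and the dictionary could fill with
unusable columns.

**Final assignments.** At convergence each individual is assigned the
support minimizing its residual, ties to the lexicographically smallest
sorted support. This re-derivation (rather than freezing the pair at the
iteration where the individual first became explained) makes assignments a
deterministic function of the final dictionary.

## Regular genotypes and the bit-flip degree of freedom

Inverting any locus subset across *all* haplotypes preserves every
xor-genotype, so a solution is one of up to `2^L − 1` flip-equivalent sets.
A locus is pinned once the allele of any individual homozygous there is
known, which is what regular genotypes provide.

The informative-set search (`mti()`) finds the smallest set of individuals
whose heterozygous-locus sets have empty intersection — their regular
genotypes then reveal a homozygous allele at every locus. The search is
exhaustive over subset sizes 1–4 by default (reported set sizes are
typically ≤ 3, so exact search is cheap; the cap is configurable up to
`N`), with a greedy intersection-reduction fallback beyond the cap. The
original minimum-tree-intersection formulation is defined on
perfect-phylogeny trees; only its empty-intersection property is used
here, so the search is implemented directly on that criterion.

Two resolution pathways exist:

* **pre** (default): the selected individuals' xor-genotypes are replaced
  by their regular genotypes *before* fitting. A bias `b = 4` multiplies
  their fitness so the dictionary preferentially grows with columns
  compatible with the known genotypes. The default follows the observation
  that constraining the search beats post-hoc correction; the bias value
  is the one reported to work well empirically, roughly matching the
  homozygous-site information advantage of a regular genotype.
* **post**: the model is fitted on xor data alone; afterwards each locus
  collects votes from genotyped individuals homozygous there (allele 0 for
  genotype 0, allele 1 for genotype 2) and flips on a majority, ties
  keeping the unflipped state with a warning. Votes can conflict because
  different individuals' inferred pairs need not be mutually consistent at
  a locus; majority-with-logged-ties is deterministic and auditable.

Per-locus status is reported as `forced` (anchored or unanimous), `voted`
(majority with disagreement), or `unresolved`; unresolved loci carry the
`XFLIP` FILTER flag in the VCF export.

## Long sequences: entropy partition and ligation

Candidate enumeration is exponential in `L`, so sequences longer than
`W = 8` SNPs (the default block cap; 256 candidates per block) are split
into contiguous blocks by dynamic programming over ending loci:
`E*(m) = min_l E*(l−1) + E(l, m)` with block width ≤ `W`, where `E(l, m)`
is the Shannon entropy (natural log; the base is irrelevant to the argmin
but fixed for reproducibility) of the haplotype usage frequencies obtained
by solving the block greedily. The DP requires `O(L·W)` block solves,
cached by `(l, m)`. Ties prefer the smallest block start. When regular
genotypes are present the block solves score the same mixed population as
the final solve, so the partition reflects the data actually fitted.

Ligation is a design gap in the source method (the partition–ligation
citation does not specify the joining step), so the package's rule is its
own and clearly labelled: blocks are stitched left to right; at each
junction an individual's block pair joins straight or crossed, preferring
joins whose two resulting prefixes already exist in the running prefix set
(both known > one > none; remaining ties join straight), processing
individuals in input order. This greedily minimizes the accumulated number
of distinct full-length haplotypes. Every join choice reconstructs the
individual's xor-genotype exactly, so ligation affects parsimony and
phase, never correctness of the reconstruction. An exhaustive-join mode
(feasible for ≤ 12 junction choices) serves as the test oracle.

## Missing data and typing errors

Missing sites are masks, never sentinel values: norms, distances and
compatibility checks run over observed loci only, and a fully missing
record is vacuously explained. With `weight_missing = TRUE` each
individual's fitness is multiplied by `w = (number of observed loci)²`, a
nondecreasing function of information content that de-prioritizes heavily
missing records; it is off by default because it only changes behavior
under missingness. Typing errors need no special machinery at fit time —
an erroneous xor-genotype is still a valid binary vector and is phased
exactly as observed; errors surface in the evaluation metrics instead.

## Evaluation metrics

* `P_e` (pair error): fraction of individuals whose inferred unordered pair
  differs from the truth anywhere — a single flipped SNP counts.
* `swr` (switch error rate): `Σ miss_het / Σ (χ_i / 2)`, where `χ_i` is the
  truth heterozygous-locus count and `miss_het` is the smaller, over the
  two pair orientations, of the count of heterozygous loci with the wrong
  allele. The orientation-minimizing reading guarantees `swr ≤ 1` and
  matches a worst-case-switches normalizer; a consecutive-switch count is
  a reasonable alternative reading that is deliberately not the default.
* `err_p` (prediction error): wrongly predicted hidden-homozygous alleles
  over `Σ (L − χ_i)`.
* `ρ` (diversity ratio): distinct haplotypes in use over `N`.

Truth-missing loci are excluded from all numerators and denominators; empty
denominators define the rate as 0. For xor-only benchmarking,
`best_flip_evaluate()` searches the flip subset bringing the inference
closest to the truth (total mis-inferred loci, then mis-paired
individuals), exhaustively for `L ≤ 16` and by seeded coordinate descent
with restarts beyond.

## The synthetic-population generator

`gen_pool()` draws per-site minor-allele probabilities uniformly in
[0.1, 0.9] (so no site is monomorphic in expectation), samples `K` distinct
haplotypes sitewise, and applies `r` random crossover events between pool
members to emulate recombination-driven mosaicism. `gen_population()`
draws pool weights from a symmetric Dirichlet(α) (α = 1 default; smaller α
concentrates usage, `Inf` gives uniform pairing) and pairs two independent
draws per individual. `inject_missing()` and `inject_errors()` add
independent Bernoulli masks and fair re-typing errors (expected changed-bit
fraction `P_err / 2`).

The generator reproduces the structural features the method depends on —
shared haplotypes, random pairing, configurable diversity, missingness and
noise — but not coalescent fine structure: no mutation genealogy, no
site-frequency spectrum, no linkage-decay profile. Passing tests therefore
demonstrate correctness of the machinery and behavior under the modeled
regimes, not calibrated error rates on real cohorts. The allele-frequency
bounds and the Dirichlet pairing are the package's own choices where the
source material leaves them open.

## Exact-recovery conditions used by the tests

The test suite asserts perfect recovery (`P_e = swr = 0`) on instances
satisfying, a priori: (i) every pool haplotype is used at least twice;
(ii) all pairwise pool XORs are distinct and each occurs among the
observed xor-genotypes; (iii) every all-homozygous individual is among the
genotyped set (repeated informative-set runs select them first, since
their heterozygous-locus sets are empty); (iv) the heterozygous-locus sets
have empty global intersection. Under (ii), any exact explanation with `K`
columns must satisfy `w_a ⊕ w_b = a ⊕ b` for every realized pair, forcing
`w_c = c ⊕ s` for a single flip `s` — the pool up to a global flip — and
(iii)–(iv) anchor `s = 0`. The remaining gap is whether the greedy search
*attains* the minimum `K`: that is not a theorem (a "chord" column
completing a whole pair class can tie ahead of a pool column), so the
tests require attainment on the majority of replicates and assert exact
recovery conditional on it, alongside a nonincreasing median pair error
as `N` grows under full genotyping.

## Numerical and problem-size choices

Gain comparisons use an absolute tolerance of `1e-9` (all fitness values
are small rational numbers at test scale); frequency vectors must sum to 1
within `1e-9`; the DP tie rule and all lexicographic tie-breaks are exact
integer comparisons. Candidate enumeration is capped at `L ≤ 16` per
solve (the partition default keeps blocks at 8). Test and example sizes —
populations of 3–50 individuals, 3–30 SNPs, pools of 3–29 haplotypes,
20-replicate simulation batches — are chosen so every property that has an
exhaustive oracle (support enumeration, subset-minimum dictionaries,
tiling enumeration, flip enumeration, join enumeration) can be checked
against it directly.

## Limitations

* Greedy selection carries no optimality guarantee here — the XOR
  composition breaks the submodularity arguments available for regular
  genotypes — and can overshoot the parsimony minimum.
* Maximum parsimony itself misleads on low-LD, high-diversity regions:
  the method will report a diversity ratio well below the truth there.
* Biallelic SNPs only; no multi-allelic sites, no cross-chromosome phase
  sets, no imputation of missing sites (though the inferred pairs type
  them implicitly).
* The ligation rule is a heuristic; pathological junction patterns can
  yield more distinct haplotypes than an exhaustive join would.
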