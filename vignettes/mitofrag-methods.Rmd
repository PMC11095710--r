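---
title: "Models and methods in mitofrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mitofrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mitofrag` studies the evolution of mitochondrial genome fragmentation —
the breakup of the ancestrally single circular mitochondrial chromosome
into multiple minicircles, as seen in parasitic lice — on a dated
phylogeny. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic benchmarks do and do not
establish. Everything quantitative stated here is computed by the test
suite or by `scripts/acceptance.R`; the vignette itself reports no numbers
beyond those.

## The discrete-trait models

Fragmentation state is coded 0 (single chromosome) and 1 (fragmented). On
a dated tree it evolves as a two-state continuous-time Markov chain with
rate matrix

```
Q = [ -q01   q01 ]
    [  q10  -q10 ]        (rates per million years)
```

Three model classes are fitted by maximum likelihood with Felsenstein
pruning: **ER** (`q01 = q10`, one free rate), **ARD** (two free rates),
and **USR**, the irreversible model with `q10 = 0` that encodes the common
assumption that fragmentation is not undone. The 2×2 transition
probabilities have a closed form, so no matrix exponential is needed, and
`P(0) = I` makes zero-length branches (including arbitrary resolutions of
multifurcations) exact rather than degenerate.

Numerical choices: optimization is on the log-rate scale (rates bounded to
`[1e-9, 1e3]`); the one-parameter models use golden-section search with
relative tolerance `1e-10` plus bracket polishing, ARD uses L-BFGS-B from
five deterministic starts including near-boundary ones, which also
guarantees the nesting inequality `logL(ARD) >= logL(ER), logL(USR)` up to
optimizer tolerance. The root prior is flat `(0.5, 0.5)` by default,
matching the usual default of discrete-trait reconstruction functions; a
stationary prior is available. Likelihood partials are renormalized during
the post-order pass, so trees with hundreds of tips do not underflow.

Model comparison uses `AIC = 2k − 2 logL` and
`AICc = AIC + 2k(k+1)/(n−k−1)` with `n` equal to the number of tips.
Free-parameter counts are 1 (ER), 2 (ARD) and 1 (USR). Published analyses
sometimes count the structurally fixed USR rate as a parameter; the
`compat_k = TRUE` flag reproduces that `k = 2` convention. Akaike weights
are normalized over whatever model set the user declares — note that
weights depend on that set, and printed weights from other sources may not
be recoverable from pairwise AICc differences alone; `mitofrag` reports
weights over `{ER, ARD, USR}` and makes no attempt to match weights whose
normalization set is unknown.

Ancestral states are reconstructed three ways: **marginal probabilities**
by the re-rooting method (outside-subtree partials propagated preorder and
combined with the pruning partials; rows sum to one by construction);
**stochastic character mapping** by exact backward filtering / forward
sampling — node states are drawn from their joint conditional distribution
given the tips, then within-branch histories are sampled conditional on
both endpoints by uniformization (no rejection sampling, so irreversible
models cannot stall, and no sampled USR map ever contains a 1→0
transition); and **Fitch parsimony** with the up-pass/down-pass rules,
whose per-node state sets equal the exhaustive most-parsimonious-
reconstruction sets (verified against full enumeration in the tests).

## Phylogenetic signal: the D statistic

For a binary trait the package computes the Fritz–Purvis `D`. The observed
quantity `d_obs` is the sum over internal nodes of the absolute difference
between the two daughter values, where node values are obtained by
equal-weights averaging of daughter values in a post-order pass from the
0/1 tips. Two nulls with matched prevalence are simulated: tip-label
permutation ("no phylogenetic structure") and a Brownian trait thresholded
at the observed prevalence. Then

```
D = (d_obs − mean d_Brownian) / (mean d_random − mean d_Brownian)
```

so a random trait has expectation near 1 and a threshold-Brownian trait
near 0. `p_random` and `p_brownian` are the fractions of null draws with
`d <= d_obs`. Multifurcations are resolved arbitrarily with zero-length
branches (the down-pass assumes bifurcations); a constant trait or a star
tree is an error, since the statistic is undefined there. Brownian tip
draws use the Cholesky factor of the tree covariance with a `1e-10`
diagonal inflation to tolerate semidefiniteness from zero-length edges.

## Matched pairs and the sign test

The published analyses contrast fragmented against non-fragmented lineages
in phylogenetically independent matched pairs. Because the original pair
choice was partly manual, `mitofrag` defines a deterministic formalization:
a post-order greedy scan selects minimal clades containing both states and
not overlapping any previously selected clade; each clade yields one pair,
and consuming the clade makes all tip-to-MRCA paths edge-disjoint across
pairs (verified by brute force in the tests). Within a clade side, the
representative is the tip with the median tip-to-MRCA path length
(branch-length mode; lower median on even counts) or the tip with the
annotated-gene count nearest the opposing member (rearrangement mode; when
both sides hold several tips the smaller side is fixed first by its median
gene count). All ties break to the lexicographically smallest label, so
the pair set is reproducible.

The default sign test is the normal approximation **without** continuity
correction, `z = (k − n/2)/√(n/4)` with a two-tailed normal p — this is
the variant consistent with the published p-values for 14 and 13 wins of
19 pairs, which the exact binomial (also reported) does not reproduce.
Ties are dropped from `n`, the standard convention.

## Gene-order rearrangement

A genome's structure is summarized by its gene boundaries: unordered pairs
of gene names for consecutive genes, including the wrap-around boundary on
circular chromosomes. Unsigned, unordered boundaries are the default —
they match manual boundary matching on gene identity and are invariant to
the rotation and global flip of a circle; an orientation-aware mode
(ordered, signed pairs after canonical rotation starting at `cox1`) is
available where strand information matters.

Ancestral boundary sets are reconstructed by treating each observed
boundary as an independent binary character under Fitch parsimony and then
filtering each node's candidate set (boundaries whose MPR set includes
"present") to a structurally consistent subset: each gene may neighbour at
most two others (at most one per gene end in oriented mode), selected
greedily in descending tip support with lexicographic tie-breaks. On small
instances this equals an exhaustive minimum-change reconstruction under
the same filter (tested). Treating boundaries independently is a
deliberate simplification — it does not model rearrangement mechanisms and
can propose boundary sets no single circular order realizes; it serves
here as a transparent, testable stand-in for black-box ancestral gene-order
tools, sufficient for the shared-boundary score.

The rearrangement score of a tip against an ancestor is `B/G`: boundaries
shared with the ancestor over the tip's own annotated gene count (so
missing annotations shrink the denominator of the same taxon, not its
partner's). A fission of a circular chromosome removes exactly two
ancestral boundaries and creates two new ones, so a single fission drops
the score by `2/G` — an exactly assertable invariant. In pair contrasts
the member with the **lower** score is the more rearranged one.

## Assembly diagnostics

Read-based assemblies cannot prove a molecule is circular; the package
implements the splice-and-remap heuristic used for "circular-mapping"
calls. If a contig's first and last `k` bases match exactly
(`k` scanned from 40 down to 10), one copy is trimmed; the sequence is
then rotated by half its length so the original ends become adjacent in
the middle, and reads are re-mapped to this spliced sequence (ungapped,
both strands, at least 95% identity, seeded on an exact 25-bp read
prefix). The **connectivity** at a position is the number of aligned reads
covering it with at least 20 aligned bases on each side; a contig is
called circular when the minimum connectivity within ±20 bp of the splice
is at least a quarter of the median whole-contig coverage. The original
method's exact weighting of similarity, coverage and alignment score is
not published, so this is a documented surrogate with every constant
configurable (`k_max`, `k_min`, identity, flank, seed width, ratio), not a
byte-compatible clone. Paired-end information is not used for the call;
single spanning reads suffice at minicircle scale.

Mononucleotide repeats are maximal single-base runs of at least 18 bp
(1-based coordinates). Shared inter-contig sequence is any maximal exact
segment strictly longer than 150 bp (one read length), found by anchoring
`min_len + 1`-mers on diagonals, so nothing above the threshold can be
missed; both strands are searched.

## Base composition

AT% is `100·(A+T)/(A+C+G+T)` with ambiguity codes excluded from numerator
and denominator. Partitions per sample: all sites, concatenated coding
sequence, the three codon positions, and fourfold degenerate sites —
third positions whose four completions encode the same amino acid, derived
directly from the genetic code table (NCBI table 5, invertebrate
mitochondrial, by default; under it `AGN` is a serine family and hence
fourfold, unlike the standard code). Coding AT% is exactly the
gene-length-weighted mean of per-gene AT%, an identity the tests assert.

Group comparisons use a phylogenetic ANOVA: the classical one-way F
statistic, with a null distribution from Brownian simulations on the tree
(rate set to the mean squared independent contrast of the data) holding
group labels fixed, and an add-one-smoothed upper-tail p-value.
Regressions use GLS with covariance from shared branch lengths, written in
closed form (Cholesky whitening); Pagel's λ scales the off-diagonal
covariance and is estimated by profile maximum likelihood restricted to
`[0, 1]` with explicit boundary checks — this avoids the unconstrained-λ
convergence failures of generic mixed-model routines, and at fixed λ the
fit agrees with an independent GLS implementation to numerical precision
(tested). Slope inference uses the t distribution with `n − 2` residual
degrees of freedom.

## The synthetic-data generator

The generator produces study-shaped data with recorded truth:

- **Trees**: forward birth–death simulation from two crown lineages,
  stopped when the surviving-lineage count first reaches `n`, plus one
  final exponential waiting period, so pure-birth crown heights have the
  Yule expectation `Σ_{k=2..n} 1/(b·k)` (tested against 500 replicates).
  Extinct subtrees are pruned; histories that die out are resimulated.
  With extinction this is simple sampling rather than a general sampling
  approach; for the benchmark regimes used here (low relative extinction)
  the difference is immaterial.
- **Traits**: exact jump sampling of the two-state chain along each branch
  (preorder), recording every jump — the full painting is what lets
  branch-rate and event-rate multipliers act on fragmented *segments*
  rather than on whole branches, and is the ground truth against which
  stochastic-map transition counts are scored.
- **Branch lengths**: time × base rate, with fragmented segments
  multiplied by `multiplier`, optionally jittered by mean-one lognormal
  noise (`sigma`, default 0.2 in the pipelines) standing in for
  finite-alignment estimation error. It does not simulate sequences or
  alignment artifacts.
- **Gene orders**: Poisson events along branches — block moves of 1–3
  genes (tRNA-scale mobility dominates real rearrangements) with random
  orientation and destination, and fissions of circular chromosomes at two
  random boundaries; gene content is conserved, fissions of single-gene
  circles are never emitted. Event rates are multiplied by
  `frag_multiplier` on fragmented segments.
- **Reads**: uniform start positions on the circle (spanning the origin),
  both strands, independent per-base substitution errors, constant
  quality; 150 bp defaults match short-read platforms. No indels, no
  quality gradients, no coverage bias.

Default rates in the CLI pipeline (`q01 = q10 = 0.01` per My on ~100-My
trees, base substitution rate 0.01/site/My, rearrangement 0.02 and fission
0.005 events/My) are chosen to produce a handful of fragmentation
transitions and visibly rearranged tip genomes on a 90-taxon tree — the
shape of the empirical study — without saturating either signal.

## Benchmark design and problem sizes

The acceptance suite ties every estimator to an independent oracle or a
known truth: pruning and Fitch to exhaustive enumeration (≤ 12 tips);
marginals to brute-force conditionals; ER rate recovery on 500-tip trees
(median relative error under 25%); stochastic-map 5–95% transition-count
intervals covering the simulated truth (≥ 85% of replicates);
D statistic means within 0.15 of its 1/0 fixed points on 128-tip trees;
pair disjointness by exhaustive path intersection on fuzzed trees;
sign-test type-I error inside a 99% binomial band around 0.05 under
multiplier-1 pipelines and ≥ 80% power at multiplier 2 with `sigma = 0.2`
on trees yielding roughly 15–20 pairs; ancestral adjacencies equal to the
exhaustive oracle (≤ 6 genes, ≤ 6 taxa); circularity sensitivity ≥ 0.95
with no false positives on 100 + 100 molecules of 2–3.2 kb at 50× coverage
and 1% error; the fourfold classifier equal to a hand-enumerated code
table; and PGLS slope recovery with near-nominal 3-SE coverage plus
`λ ≤ 0.1` under white-noise residuals. These sizes keep the whole suite
within a few minutes on one CPU while leaving each check statistically
sharp.

Two benchmark conditions deserve comment. The rearrangement-contrast
benchmark evolves the trait **irreversibly** (`q10 = 0`): under freely
reversible histories many fragmented tips have only just become
fragmented, so their gene orders have had no time to diverge and the
contrast is genuinely diluted — the irreversible regime is also the one
the empirical analyses assume for fragmentation. And the sign-test type-I
benchmark uses the realized mixture of pair counts produced by the
selection algorithm; the normal-approximation sign test is slightly
conservative at small `n`, which is visible in, and absorbed by, the 99%
band.

## Known limitations

- The Mk machinery is strictly two-state; no hidden-rate or multi-state
  models, and no rate-shift (BAMM-style) analyses.
- Branch lengths are generated, not estimated from sequences; conclusions
  about alignment-based estimation error rest on the lognormal stand-in.
- The adjacency reconstruction is per-boundary parsimony, not a
  rearrangement-event model; it cannot infer event sequences or
  breakpoint/DCJ distances.
- The circularity caller assumes uniform-ish coverage and unique junction
  context; long repeats spanning a junction can defeat any read-length
  method, which is precisely why inter-contig shared-sequence scanning is
  provided alongside it.
- D-statistic p-values are Monte-Carlo; at the default 1000 simulations
  their resolution is 0.001.
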