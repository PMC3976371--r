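---
title: "Partitioned RAD analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned RAD analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radpartition)
```

This vignette explains the models behind `radpartition`, the parameters that
matter and their defaults, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely open.

## From reads to loci

RAD-Seq produces fixed-length reads adjacent to restriction-enzyme cut sites.
The expected number of cut sites under an independent-base genome model is
`genome_length * prod(p_motif)`, where each motif position contributes
`gc/2` (C or G) or `(1-gc)/2` (A or T). For a 500-Mb genome at 40% GC, the
6-bp PstI site CTGCAG is expected 72,000 times, while an 8-bp cutter such as
SbfI yields roughly 25-fold fewer sites — enzyme choice sets the marker
density.

**Quality handling.** Bases below Phred 20 are masked to `N`; reads whose
post-masking `N` fraction strictly exceeds 5% are dropped
(`mask_low_quality_reads()`). Both thresholds are conventional for this kind
of pipeline and configurable.

**Within-individual clustering.** Reads are clustered greedily against
centroids at 88% ungapped identity, testing the reverse complement as well
since reads come off either strand. Unique reads are seeded in order of
multiplicity (ties broken lexicographically), which makes the clustering
deterministic. Indel-aware alignment is deliberately out of scope: reads are
fixed-length, and the ungapped Hamming identity keeps the operation exact and
testable. Stacks below depth 6 are discarded; shallow stacks cannot separate
heterozygosity from error.

**Error and heterozygosity.** The per-base sequencing error rate
$\epsilon$ and per-site heterozygosity $H$ are estimated jointly by
maximizing, over all stack columns, the mixture likelihood

$$\prod_{\text{columns}} \left[(1-H)\,P_{\text{hom}}(\text{counts}\mid\epsilon)
  + H\,P_{\text{het}}(\text{counts}\mid\epsilon)\right],$$

where the homozygote term is a multinomial with the most frequent base as
truth (errors uniform over the other three bases) and the heterozygote term
assumes equal dosage of the two most frequent bases. Columns are pooled
across stacks and depths; this pooling is a documented choice — conditioning
on per-column depth gives the same maximizer for these models. Columns are
aggregated by their sorted count pattern, so the optimization (bounded
Nelder–Mead-free `nlminb` over $(\epsilon, H) \in [10^{-9}, 0.499]^2$) is
fast at any data size. Boundary estimates are clamped to $10^{-9}$ downstream
to avoid $\log 0$.

At the defaults used in testing (depth 20, 2,000 columns), $\epsilon = 0.01$
is recovered within a few percent; $H = 0.005$ corresponds to only ~10
heterozygous sites in such a dataset, so individual estimates scatter around
the truth with ~30% sampling noise — the tests therefore assert recovery of
the median over replicate datasets.

**Consensus calling.** Per column the posterior over ten genotypes (4
homozygotes at prior $(1-H)/4$, 6 unordered heterozygote pairs at prior
$H/6$) is computed from the same multinomial models; the argmax genotype is
called only when its posterior reaches 0.95, otherwise the site is `N`.
Heterozygous calls become IUPAC two-fold codes. Loci with more than 3
heterozygous sites, or whose heterozygous sites phase into more than 2
read-supported haplotypes, are flagged as putative paralogs and excluded —
a diploid cannot carry three haplotypes at one locus.

**Across-individual clustering and filters.** Consensus sequences cluster at
the same 88% identity; clusters with two sequences from one individual are
paralogous and dropped, as are clusters with fewer than 4 (or, stricter, 10)
individuals, loci where any column is heterozygous in more than 2
individuals, and loci with more than 10 variable sites. All sampled
individuals count toward the shared-heterozygote rule, including any
outgroup. Variable-site counting expands IUPAC codes into their constituent
bases and ignores `N`/`-`.

## The likelihood engine

Site likelihoods use the general time-reversible model with 4 discrete gamma
rate categories (equal weights, category rates by the mean-of-quantile
method). `N`, `-`, and IUPAC codes enter as partial states. Columns missing
in every taxon are excluded. The numerical core is `phangorn` (Felsenstein
pruning in C); the package's contribution is the surface and the
verification: the test suite carries an independent exhaustive-enumeration
oracle (own rate matrix, own symmetrized eigendecomposition, own gamma
discretization) and requires agreement to $10^{-8}$ on random instances, plus
closed-form checks (zero-branch identity, two-taxon Jukes–Cantor) and the
pulley-principle invariance under re-rooting.

Branch lengths are optimized per branch to within $10^{-3}$ log-likelihood
units (the underlying optimizer's tolerance is relative to $|\ln L|$ and is
converted internally) and clamped to $[10^{-8}, 10]$ substitutions/site.
Two-taxon alignments have a single free path length, optimized directly by
golden-section search. Tree search is NNI hill climbing: evaluate all unique
1-step neighbors with re-optimized branch lengths, take the best strictly
improving move, stop at a local optimum — adequate for the shallow,
strong-signal matrices this package targets, and deterministic. Bootstrap
supports resample columns with replacement and re-run the climb from a
neighbor-joining start; supports from this engine are comparable across
datasets analyzed by the same engine, which is how they are used (genic vs
non-genic comparisons), not as substitutes for a full ML-search bootstrap.

Fitch parsimony treats ambiguity codes as state sets; the consistency index
divides the sum over sites of the minimum conceivable changes by the Fitch
length. The minimum-change count per site uses fully resolved states only
(dropping ambiguous cells), which guarantees CI ≤ 1 against the set-based
Fitch length; matrices requiring zero steps report CI = 1 with a message.

## The partitioned RAD analysis

Concatenation can mask alternative topologies that many loci support. The
analysis makes such hidden support visible:

1. **Pool.** All unique 1-step NNI neighbors of the optimal tree — an
   unrooted binary tree on $n$ taxa has exactly $2(n-3)$ — plus unique
   2-step neighbors (neighbors of neighbors, excluding the optimal and
   1-step sets) sampled uniformly without replacement under a seed, until the
   requested pool size is reached. Topologies are identified by a canonical
   string over their non-trivial bipartitions, so deduplication is exact.
2. **Prune.** Each locus covers a subset of taxa; the pool is restricted to
   that subset (suppressed degree-2 vertices sum their branch lengths) and
   deduplicated, keeping an index from every pool tree to its pruned
   representative.
3. **Score.** Every unique pruned tree is evaluated against the locus. Branch
   lengths may be re-optimized per tree (`optimize = TRUE`) or taken from the
   pool as-is — at 50-bp locus length the fixed-length evaluation is an
   order of magnitude faster and preserves the ranking signal.
4. **Count.** A locus *favors* the trees within `ll_window = 2.0`
   log-likelihood units of its best tree and *disfavors* those within 2.0 of
   its worst (boundaries inclusive); every pool tree inherits its pruned
   representative's status. Loci enter only with ≥ `min_individuals = 4`
   individuals, ≥ 1 parsimony-informative site, ≥ `min_trees = 20` unique
   pruned trees, and a per-locus log-likelihood range ≥ `min_ll_range = 4.0`.
   Keeping the range above twice the window ensures no locus favors and
   disfavors the same tree.
5. **Regress.** Favoring counts are regressed on each tree's total-data
   log-likelihood (branch lengths re-optimized per tree on the concatenated
   supermatrix), each tree an independent point; trees above the 95%
   prediction interval have more supporting loci than their likelihood
   predicts. Only the upper side is flagged; the lower bound is reported.
   Poorly supported likelihood islands may be removed before the regression
   via a user-chosen cut (`ll_cut`) — chosen by inspecting the likelihood
   profile, never auto-detected, because the cut encodes a biological
   judgment about which topologies are plausible at all.

**Why the prediction interval, and when does it fire?** If the candidate
trees draw from one likelihood distribution, favoring counts are linear in
total log-likelihood; the slope is set by the typical per-locus
log-likelihood gap of the data. A coherent minority of conflicting loci
raises a tree's count *and* its total likelihood, moving it roughly along
that line. The tree escapes above the interval only when its extra favoring
loci are cheap in likelihood — coherent in direction but individually weak,
exactly the signature of a recent hybrid divergence shared by a fraction of
the genome against a deeper backbone signal. The package's detection
experiment (in the test suite) is built on this geometry: a 10-taxon species
tree, a 31-tree pool, 250 loci of 50 bp, gene-tree noise in the backbone
(40% of loci switch to a random 1-step neighbor, a cheap stand-in for
lineage sorting), and 30% of loci from one 2-step alternative whose internal
edges are halved. Under these conditions the alternative is flagged in 19 of
20 seeded runs, while without conflicting loci the generating topology holds
the top count and stays inside the interval. Conversely, when every locus
derives from one deep, complete-signal topology, the optimal tree itself
shows "excess" support — a reminder that the method reads *relative*
support structure and its null model is a noisy, partially informative locus
pool, not a clean simulation.

## The genic/non-genic informativeness comparison

Loci with a BLAST hit below an E-value cutoff (1e-15 by default; hits are
consumed from standard 12-column tabular files, never computed here) form the
"EST" set; loci with no hit at any E-value form the comparison pool; loci
with only weak hits belong to neither. For the observed set and each of
`n_replicates = 100` equal-sized random subsamples from the comparison pool
(drawn within an aligned-length window, 50–55 bp by default, so length does
not confound), the statistic bundle is computed on that dataset's own ML
tree: parsimony steps, variable and parsimony-informative counts, CI, aligned
length, missing proportion (`N` or `-`), the proportion of total branch
length in terminal branches, and mean bootstrap. Two-tailed resampling
p-values double the fraction of null values strictly more extreme than the
observed value in the direction away from the null mean; with zero more
extreme values the result is a bound at the test's resolution (`< 2/R`;
configurable to a one-sided `1/R`). The calibration test draws the observed
statistic from the null and confirms the p < 0.05 rate stays near nominal.

## The synthetic-data generator

The generator emulates: a uniform-topology species tree with exponential
branch lengths rescaled to a target mean root-to-tip depth
(substitutions/site); GTR+GAMMA locus alignments (sites assigned to discrete
gamma categories); restriction-site dropout as branch-wise loss events
(probability $1 - e^{-\text{rate} \cdot \text{length}}$ per branch) inherited
by all descendant tips, so missingness is phylogenetically structured;
independent per-(taxon, locus) coverage thinning; diploid read stacks
(Poisson depth, allele coin-flip, uniform base errors at rate $\epsilon$);
and technical-replicate pairs as two independent thinnings of one locus set,
with expected shared/union overlap $r_a r_b / (r_a + r_b - r_a r_b)$ — at
$r_a = r_b \approx 0.71$ this sits at the 0.55 overlap typical of replicate
sequencing runs. Defaults (20 taxa, 1,000 loci of 50 bp, depth 0.05,
dropout rate 5, coverage retention 0.75, read depth 20,
$\epsilon = H = 0.005$) emulate a shallow radiation sequenced at moderate
coverage with a roughly 60%-complete matrix.

It does **not** emulate: indels or alignment error (clustering and
downstream handling are deliberately ungapped), coalescent gene-tree
heterogeneity beyond the simple per-locus topology switch, base-composition
or rate variation among loci, paralogy, or quality-score structure along
reads (simulated qualities are constant). Tests passing on these data
therefore validate the machinery — estimators, filters, counting, the
regression — under the stated generative model; they do not certify
performance on real data with alignment error or deep coalescent conflict.

## Numerical choices and degenerate inputs

* Likelihood: all-missing columns excluded; anything else is a partial
  state. Branch clamp $[10^{-8}, 10]$; zero-length trees evaluate to the
  stationary distribution.
* Consensus: depth-0 columns are `N`; plurality consensus breaks ties
  alphabetically (documented, deterministic).
* Jaccard distances: taxa without loci, or pairs sharing no scored loci, get
  distance 1 with a warning.
* Empty locus sets concatenate to a 0-column matrix with completeness
  reported as 1.0 under a warning.
* The resampling test reports `p = 1` for a zero-variance null equal to the
  observation, and a resolution bound when no null value is more extreme.
* All randomness flows through per-call seeds (`with_seed` restores the
  caller's RNG state), so every simulated artifact is reproducible from its
  seed and identical seeds give identical pools, subsamples, and bootstrap
  supports.

## Problem sizes used in testing

The suite runs end to end in minutes on one core by scaling the experiments:
likelihood-oracle instances at ≤ 6 taxa and ≤ 6 sites (exhaustive
enumeration); prediction-interval coverage at 200 trees × 1,000 replicates;
the detection experiment at 10 taxa, 31 pool trees, 250 × 50 bp loci, 20
seeds; parameter recovery at 2,000 stack columns and a 10,000-site pairwise
alignment; the informativeness comparison at 8 taxa with 50 null replicates
per run; bootstrap checks at 6 taxa with 10–20 replicates. These sizes are
the package's chosen desk-scale study conditions; the same functions run
unchanged at the 20-taxon, 27,000-locus scale of a full RAD study.

## Known limitations

* The NNI hill climb can stop at local optima on flat likelihood surfaces;
  it is not a replacement for a full ML search program on hard datasets.
* Fixed-length, ungapped loci are assumed throughout; data requiring
  within-locus realignment must be aligned upstream.
* One substitution model is shared by all loci (per-locus branch lengths are
  re-optimized); partitioned model parameters are out of scope.
* The haplotype counter phases only the called heterozygous sites by read
  co-occurrence; it is a paralog screen, not a phasing method.
* Polyploid genotype models are not implemented (two-allele diploid only).
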