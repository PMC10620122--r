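---
title: "Identifying personalized driver gene sets by network propagation and genetic algorithm search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying personalized driver gene sets by network propagation and genetic algorithm search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gadriver)
```

## The problem

Tumors of the same type differ widely in which genes are genetically
altered and in which transcriptional programs are dysregulated. Most
driver-gene catalogs are built at the cohort level, yet any one patient
carries only a handful of the recurrent drivers plus a private set of
alterations. `gadriver` asks the per-individual question: *which subset of
this patient's copy-number-altered and mutated genes best explains this
patient's hallmark-level transcriptional dysregulation?*

The answer is framed as an optimization. An individual's candidate driver
genes are screened from their altered genes; every subset of candidates is
scored by how well the subset's *propagated* influence over a protein
interaction network reproduces the individual's observed hallmark
dysregulation; and a genetic algorithm searches the subsets for the best
score.

## The model, step by step

**Co-expression-weighted network.** Each protein interaction between genes
measured in the cohort is weighted by the absolute Pearson correlation of
the two genes' expression across the tumor samples, so that edges between
co-regulated genes carry more transition probability. The maximum connected
component is kept, and the weights are column-normalized into a transfer
matrix $W$ whose every column sums to one.

**Random walk with restart (RWR).** The influence of a seed gene set $S$
over the network is the stationary vector of

$$P_{t+1} = (1 - r)\,W P_t + r P_0,$$

with restart probability $r = 0.3$ and $P_0$ placing uniform mass $1/|S|$
on the seeds. Iteration stops when
$\max_i |P_{t+1,i} - P_{t,i}| < 10^{-10}$. Because $W$ is
column-stochastic the total mass stays exactly one at every step, and
because the fixed point is linear in $P_0$, the stationary vector of a
multi-seed walk equals the mean of the single-seed stationary vectors —
the package exploits this to precompute one profile per candidate gene and
score arbitrary subsets by averaging columns. A dense linear solve
$P_\infty = r (I - (1-r)W)^{-1} P_0$ serves as an independent oracle in
the tests.

**Dysfunctional hallmarks.** Per individual, each gene's log2 fold change
is its tumor expression minus the mean of the normal samples. Hallmark
gene sets with a gene-permutation GSEA $p \le 0.05$ on that fold-change
ranking (either direction of enrichment) are the individual's
dysfunctional hallmarks; at least three are required so a correlation over
them is meaningful.

**Fitness of a candidate subset.** The subset's RWR stationary vector is
scored against each dysfunctional hallmark by single-sample GSEA
(*Dscores*); the fold-change vector is scored the same way (*Escores*).
Fitness is the Pearson correlation between Dscores and Escores across the
dysfunctional hallmarks; its significance is the usual two-sided $t$ test
of `cor.test`. The empty subset and subsets with constant Dscores receive
a sentinel fitness of $-2$.

**Candidate screening.** An altered gene enters the candidate list only if
the GSEA of its own single-seed RWR ranking is significant
($p \le 0.05$) for at least one hallmark — genes whose propagation touches
no hallmark cannot contribute a signal the fitness can see.

**Genetic algorithm.** Subsets are binary chromosomes over the $L$
candidates. The population (size $N = \mathrm{clamp}(2L, 40, 200)$) is
initialized Bernoulli(0.5), then evolved by tournament selection of 3,
uniform crossover applied to a fraction 0.9 of shuffled pairs, per-bit
mutation at 0.01, and an elitist copy of the best-ever chromosome, for up
to $G = \mathrm{clamp}(5L, 50, 500)$ generations with early stop after 30
stagnant generations. Ties in fitness resolve toward smaller subsets, then
lexicographically, making results reproducible bit-for-bit. For
$L \le 12$ an exhaustive enumeration of all $2^L - 1$ nonempty subsets is
available and is used by the tests as the optimality oracle.

**Reporting.** For each selected driver alone, hallmarks with
$p \le 0.05$ **and** positive normalized enrichment score form the
driver-to-hallmark network; each edge carries the intersection of the
hallmark's expression-side and propagation-side leading edges (its core
enrichment genes). The cumulative-contribution curve re-evaluates fitness
on growing prefixes of the driver set, ordered by single-gene fitness.

## Enrichment internals

GSEA is the classic weighted Kolmogorov–Smirnov running sum: sorted by
score descending (ties broken by gene id), in-set genes add
$|s|^w / \sum_{hits} |s|^w$ (default $w = 1$) and others subtract
$1/(n - k)$; the enrichment score is the extremum of largest magnitude
(exact ties resolve to the positive side). The implementation computes the
curve's extrema in closed form from the in-set positions, which the test
suite checks against a brute-force walk of the whole curve.

Significance uses a gene-label permutation null — the natural choice when
the ranking is a single per-individual vector and no phenotype labels
exist. The $p$ value is the add-one-smoothed fraction of same-sign
permutation scores at least as extreme, so $p \in (0, 1]$ and is never
exactly zero; NES divides the observed score by the mean magnitude of
same-sign permutation scores. Sets of equal size share one null
distribution per ranking (the null depends only on size), which keeps a
50-hallmark scan at 1000 permutations fast and makes results independent
of set order.

ssGSEA follows the single-sample cumulative-difference form: the score is
the sum over all ranks of the weighted in-set ECDF minus the out-of-set
ECDF. In-set steps are weighted by $(n - i + 1)^\alpha$ at rank $i$ with
$\alpha = 0.25$. Rank-based weights were chosen over $|score|^\alpha$
deliberately: fold changes can be negative, and magnitude weights would
give strongly *down*-regulated genes the same pull as up-regulated ones,
whereas rank weights are monotone in the ranking, which is the property
the monotonicity tests assert. Scores are reported unnormalized because
only their correlation across hallmarks within one individual is ever
consumed. With $\alpha = 0$ the score reduces to the unweighted
Kolmogorov–Smirnov cumulative sum, which is how the tests pin it to a
hand-enumerated oracle.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `restart` | 0.3 | RWR restart probability; higher keeps mass nearer the seeds |
| `tol` | 1e-10 | RWR convergence threshold (max absolute change) |
| `n_perm` | 1000 | GSEA permutations; the p-value floor is ~1/(n_perm+1) |
| `p_threshold` | 0.05 | significance cutoff, boundary inclusive, no multiplicity correction across the 50 hallmarks |
| `alpha` | 0.25 | ssGSEA rank-weight exponent |
| `weight_exp` | 1 | GSEA hit-weight exponent |
| `crossover_prob` | 0.9 | fraction of selected pairs recombined |
| `mutation_prob` | 0.01 | per-bit flip probability |
| `tournament_k` | 3 | tournament size |

Nominal (uncorrected) $p \le 0.05$ is used at all three decision points —
dysfunctional hallmarks, candidate screening, driver-hallmark edges —
matching how such thresholds are conventionally applied in this kind of
per-individual analysis; the threshold is configurable.

## The synthetic cohort and what it does (not) show

`generate_fixture()` builds a self-contained cohort in which the truth is
known: a connected preferential-attachment graph of 500 genes (~2000
edges); 30 hallmark sets formed as unions of one-hop neighborhoods of
randomly drawn centers; per individual, 3 planted drivers (centers of
distinct hallmarks) and 10 random passenger alterations, each emitted as
a high-level copy-number call or a mutation row; and expression in which
tumors deviate from a shared baseline by the planted drivers' own RWR
profile.

Three generator choices deserve explanation:

* **The planted signal spans the whole network.** The drivers' stationary
  profile is max-normalized, flattened with a quarter power (diffusion
  profiles decay over orders of magnitude; flattening brings neighborhood
  genes above the noise floor), scaled by `effect_size`, and added to
  every gene's baseline. Restricting the signal to hallmark members was
  tried and rejected: single-sample enrichment is rank-based, and zeroing
  the non-members makes their fold-change ranks pure noise while their
  diffusion ranks stay systematic, which caps the true subset's fitness
  near 0.75 and invites the search to pad the set with passengers. With a
  monotone network-wide signal, the noiseless Escores equal the truth's
  Dscores exactly and recovery becomes a sharp test of the
  implementation.
* **Noise is smoothed one step over the graph.** Interacting genes
  co-vary across samples, so the $|PCC|$ edge weights the pipeline
  estimates reflect actual co-expression rather than pure sampling noise
  — the same assumption the method itself makes about real tumors.
* **Effect and noise defaults** (`effect_size = 6`, `noise_sd = 0.15` on
  the log2 scale) encode a strong lesion — e.g. a high-level
  amplification — measured on a quiet platform. They were fixed by
  probing the fitness landscape (the truth subset's fitness versus the
  exhaustive optimum) during generator design and are deliberately
  favorable: the recovery experiment validates the pipeline's
  correctness under the model's own assumptions, not its power on real,
  noisier data.

Because the generative model *is* the method's model, passing the
recovery test says the implementation is faithful; it says nothing about
how often biological drivers act through propagation-visible expression
shifts, about batch effects, mutation-type differences, or hallmark sets
that overlap as heavily as the real MSigDB collection does.

## Numerical and degenerate-input conventions

* Edges are dropped when an endpoint is missing from the expression
  matrix, when either gene has zero variance (correlation undefined), or
  when $|PCC| \le 10^{-12}$; a node left with no positive incident weight
  is an error rather than a silently dangling column.
* Component-size ties in `largest_component` go to the component holding
  the lexicographically smallest gene id.
* Seeds absent from the network are dropped with a message provided one
  seed remains; an all-absent seed set is an error.
* All rankings break score ties by gene id, so every stage is
  deterministic given its seed; per-stage seeds derive from the root seed
  so changing one stage's settings does not shift another's random
  stream.
* Problem sizes in the tests — 500-gene cohorts, 1000-trial null
  calibrations, $L = 8$ exhaustive oracles — were chosen so the whole
  suite completes in minutes on a single core while still exercising
  every claim; they are stated in the tests themselves.

## Known limitations

* On fitness landscapes with no structure (Escores unrelated to any
  subset's propagation), the genetic algorithm with the standard operator
  rates can converge to a local optimum; with planted structure it
  matches the exhaustive optimum across seeds, and the exhaustive mode is
  the safe choice whenever $L \le 12$.
* The method inherits single-sample GSEA's insensitivity to hallmark
  overlap: heavily overlapping gene sets yield correlated score vectors
  and can make distinct driver subsets nearly indistinguishable.
* The network is static and undirected; context-specific or directed
  regulatory structure is out of scope.

## A worked example

```{r example, eval = FALSE}
library(gadriver)

fix <- generate_fixture(n_individuals = 4, seed = 61)
cohort <- run_pipeline(fix$expr, fix$edges, fix$hallmarks,
                       fix$cna, fix$maf,
                       pipeline_config(seed = 7), outdir = "results")
cohort_summary(cohort)
jaccard(cohort$results$ind01$driver_genes, fix$truth$ind01)
```

The summary table reports, per individual, the candidate count, the
selected driver genes, the fitness (PCC), its `cor.test` p-value, and the
number of dysfunctional hallmarks; `results/` holds per-individual JSON,
the cohort TSV, the assembled driver-hallmark edge list, and a manifest
with every parameter and seed.
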