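# gadriver

Personalized cancer driver gene sets by coupling random walk with restart
on a co-expression-weighted protein interaction network with a genetic
algorithm search.

## What problem this solves

Cancer cohorts are genetically heterogeneous: two patients with the same
tumor type rarely share the same altered genes, and cohort-level driver
catalogs say little about which of *this* patient's alterations actually
drive *this* patient's transcriptional dysregulation. `gadriver` answers
the per-individual question: among the genes with high-level copy-number
alterations or somatic mutations in one individual, which subset best
explains that individual's dysregulated cancer hallmarks?

It is aimed at computational biologists working with matched expression,
copy-number, and mutation profiles (e.g. TCGA-style cohorts) plus a
protein interaction network and a hallmark gene set collection (GMT).

## The method

For each individual:

1. **Dysfunctional hallmarks.** Log2 fold changes against the mean of the
   normal samples are ranked and each hallmark gene set is tested by
   permutation GSEA; hallmarks with *p* ≤ 0.05 are the individual's
   dysfunctional hallmarks (at least 3 required).
2. **Network propagation.** A transfer matrix *W* is built from the
   interaction network, each edge weighted by |PCC| of its genes'
   expression across the tumor cohort, columns normalized to sum to 1 on
   the maximum connected component. A seed set *S* propagates by random
   walk with restart,

   P<sub>t+1</sub> = (1 − r) W P<sub>t</sub> + r P<sub>0</sub>,

   with r = 0.3, P<sub>0</sub> uniform on *S*, iterated until
   max|P<sub>t+1</sub> − P<sub>t</sub>| < 1e-10.
3. **Candidate screening.** An altered gene is a candidate driver iff the
   GSEA of its single-seed stationary profile is significant (*p* ≤ 0.05)
   for at least one hallmark.
4. **Subset search.** Fitness of a candidate subset = Pearson correlation
   between its **Dscores** (ssGSEA of the subset's stationary profile over
   the dysfunctional hallmarks) and the individual's **Escores** (ssGSEA
   of the fold changes over the same hallmarks). A genetic algorithm
   (tournament selection of 3, uniform crossover at 0.9, per-bit mutation
   at 0.01, elitism) searches the subsets; the best subset is the
   individual's driver gene set, with a `cor.test` p-value attached.
5. **Reporting.** Driver→hallmark edges (*p* ≤ 0.05 and NES > 0 for the
   single driver's propagation), core enrichment genes, and cumulative
   contribution curves.

A synthetic-cohort generator with planted drivers makes every stage —
and end-to-end recovery — testable without any external data.

## Worked example

```r
library(gadriver)

fix <- generate_fixture(n_individuals = 4, seed = 61)   # planted truth
cohort <- run_pipeline(fix$expr, fix$edges, fix$hallmarks,
                       fix$cna, fix$maf,
                       pipeline_config(seed = 7), outdir = "results")
cohort_summary(cohort)
```

prints (abridged):

```
  individual n_candidates                  driver_genes   pcc  p_value n_dysfunctional
1      ind01            9       g0063,g0124,g0243,g0408 0.834  9.0e-06              19
2      ind02            8       g0054,g0294,g0312,g0376 0.915  1.7e-08              20
3      ind03            9             g0063,g0378,g0493 0.815  2.1e-05              19
4      ind04           11 g0017,g0130,g0262,g0360,g0498 0.922  4.0e-10              23
```

Each row is one individual: of its ~13 altered genes, 8–11 passed the
candidate screen, and the GA selected 3–5 of them whose propagated
influence correlates at 0.81–0.92 with the expression-side hallmark
scores (all significant). Against the planted truth these sets score
Jaccard 0.75, 0.75, 1.0 and 0.6 — e.g. `ind03` is recovered exactly
(`fix$truth$ind03` is `g0063,g0378,g0493`), while `ind01` carries one
extra gene beyond its three true drivers. `results/` contains the cohort
TSV, per-individual JSON (Dscores, Escores, cumulative curve), the
assembled driver-hallmark edge list, and a run manifest.

A command-line front end with `simulate` and `run` subcommands is
installed at `inst/cli/gadriver.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gadriver.R", package="gadriver"))')" \
  simulate --outdir cohort --seed 1
```

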