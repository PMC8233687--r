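---
title: "Methods: per-gene mutation density, rank associations, and the synthetic hypermutator study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-gene mutation density, rank associations, and the synthetic hypermutator study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutdensity)
```

## The statistic and its assumptions

The package's core quantity is the per-gene density of ever-observed
mutations,

$$d_g = \frac{m_g}{L_g},$$

where $m_g$ counts distinct alleles in gene $g$ that were ever detected in
the metagenomic time series of the selected populations — each allele once,
at its first sequenced timepoint — and $L_g$ is the gene's annotated length
in nucleotides. The statistic deliberately ignores allele-frequency dynamics
and phylogenetic structure: whether a hitchhiker later fixed, fluctuated, or
went extinct does not change whether it was *ever observed*, which makes the
count robust to clonal interference and frequency-dependent selection. The
interpretive assumption is that in hypermutator populations the bulk of
observed mutations are nearly neutral hitchhikers, so genes whose mutations
are disproportionately deleterious show *fewer* observed mutations than
their length predicts. Density is compared against gene-level covariates
(mRNA abundance, protein abundance, PPI degree) by rank correlation only; no
dose–response model is fit.

Three conventions matter and are fixed throughout:

* **Coordinates** are stored 0-based half-open, so `length_nt = end - start`
  exactly; GFF3's 1-based inclusive coordinates are converted on read.
* **Generation cutoffs are inclusive** (`generation_observed <= cutoff`):
  "observed by the 10,000-generation mark" includes generation 10,000.
* **The gene universe is the annotation input.** Every annotated gene
  appears in every density table, including genes with $m_g = 0$; intergenic
  records are read and retained but never enter gene-level statistics.

Two readings of "all mutations" exist, since indels and structural variants
within gene boundaries are neither synonymous nor missense. The default
`scheme = "all"` counts every class assigned to a gene; `scheme = "point"`
restricts to point mutations. The normalizer is always the full nucleotide
length, not a per-class target size — synonymous/nonsynonymous site counting
is out of scope, and for rank correlations a class-specific normalizer
proportional to length would change nothing.

## The Spearman test

`spearman_two_sided()` computes Pearson's product-moment correlation on
average ranks (ties share their mean rank). Two-sided p-values use the
t approximation with $n-2$ degrees of freedom — the behaviour of standard
statistical routines, adequate at the thousands of genes this analysis
involves. Below $n = 10$ the approximation degrades, so the p-value is
computed exactly by enumerating all $n!$ permutations of one rank vector;
the two regimes are pinned separately in the tests against independent
oracles (an explicit ranks-then-Pearson implementation, full enumeration,
and `stats::cor.test`). With $|\rho| = 1$ in the t regime the p-value is
clamped to the smallest positive double rather than zero. Constant vectors
and $n < 3$ are errors, not `NA`s: an undefined correlation in this pipeline
always indicates a degenerate subset the caller should know about.

`associate()` defines each test's universe as the *intersection* of the
density table's genes and the covariate's genes. Missing covariate values
are never imputed: "absent from the abundance table" cannot be distinguished
from "not expressed", and imputing zero would manufacture rank signal.
For the same reason genes absent from a PPI edge set are omitted rather than
assigned degree 0 (a caller who prefers the other convention can append
zeros to the degree vector explicitly). The zeros policy
(`zeros = "exclude"`) drops genes with $m_g = 0$ *after* the intersection,
and the reported `n` is the post-filter count. Because Spearman's rho is a
rank statistic, results are invariant under strictly monotone transforms of
either variable (square-root axes in plots are cosmetic); the test suite
asserts this to 1e-12. No multiple-testing correction is applied across
panels — each association is reported with its own per-panel p-value, and a
report-level Benjamini–Hochberg column can be added downstream from the TSV
output with `p.adjust` if desired.

## What the synthetic generator emulates

`sim_config()` + `simulate_ltee()` generate a desk-scale analogue of a
60,000-generation evolution experiment with 6 hypermutator and 6 nonmutator
populations over an *E. coli*-sized genome. The design reduces
observability to a thinning process rather than simulating Wright–Fisher
dynamics: deleterious mutations fail to reach observable frequency, so it is
enough to generate candidate mutations and remove a fraction.

* **Genome.** `n_genes = 4200` genes, lengths log-normal
  (`meanlog = log(800)`, `sdlog = 0.55` nt, rounded to whole codons), laid
  non-overlapping on one circular reference. This gives a median length near
  800 nt and a right tail past 4 kb, the familiar shape of a bacterial
  annotation.
* **Abundance.** A latent standard-normal gene effect $z_g$ drives
  everything: condition $c$ observes
  $\log A_{gc} = \mu + \sigma(\sqrt{r}\, z_g + \sqrt{1-r}\,\epsilon_{gc})$
  with $\sigma = 1.5$ (three decades of spread, typical of proteomes) and
  between-condition coupling $r = 0.8$; $r = 1$ makes condition ranks
  identical. Selection acts on $z_g$ itself — the conditions are noisy
  measurements of the same underlying abundance, mirroring growth-phase
  replicates of one transcriptome/proteome.
* **Mutation arrival.** Candidates arise per population and gene as
  Poisson with mean $\mu L_g$: `mu_h = 1e-3` observable candidates per
  nucleotide per hypermutator population over the horizon (about 4,000 per
  population across a ~3.6 Mb coding genome, the scale seen in hypermutator
  metagenomic time series) and `mu_n = mu_h / 100` for nonmutators. A
  fraction `frac_syn = 0.25` of point mutations is synonymous, roughly the
  coding-sequence share of synonymous sites.
* **Purifying selection.** Each nonsynonymous candidate is removed with
  probability $\pi_g = \mathrm{logistic}(\beta z_g)$. The logistic link is
  the minimal bounded monotone choice for a probability; $\beta = 0$ gives
  the constant $\pi = 0.5$ (density independent of abundance — the
  calibration null), and $\beta = 2$ (the default) a strong, saturating
  coupling. Survivors split missense:nonsense 9:1 — arbitrary but fixed,
  and merged downstream anyway.
* **Synonymous bias.** Synonymous rates get the multiplier
  $1 + \gamma \max(z_g, 0)$, renormalized by the length-weighted mean so the
  genome-wide expected synonymous total is independent of $\gamma$: the
  $\gamma$ effect is purely distributional, isolating the correlation
  mechanism from a rate confound.
* **PPI network.** Target degrees are Poisson with mean
  $\propto e^{\delta z_g}$ (mean degree 8), realized by an erased
  configuration model: stubs are paired uniformly, pairings are re-drawn up
  to five times, and any remaining self-loops or duplicate edges are
  discarded. Realized degrees therefore sit slightly below targets for hubs;
  the handshake identity always holds on the realized network.
* **Observation times** are uniform on (0, horizon]: with no clonal
  dynamics, the rising cumulative-correlation curve emerges purely from
  counts accumulating.
* An optional nonmutator **positive-selection channel**
  (`pos_sel_targets`, `pos_sel_rate`, both 0 by default) concentrates extra
  missense mutations in a small target-gene set shared across nonmutator
  populations, for experiments on parallel adaptive evolution; it is off in
  the default study.

Each generator stage seeds the RNG from the single config seed plus a fixed
stage offset, so stages are individually reproducible and a full run is
byte-deterministic.

**What the generator does not emulate:** fitness trajectories and clonal
interference, mutation-spectrum realism (transition bias, context effects),
epistasis, operon structure, and any direct link between gene length and
abundance. Passing tests therefore show that the pipeline recovers the
directions and calibration of a known generative model — not that the real
data's effect sizes are reproduced. The real analyses' printed correlations
depend on external datasets consumed through the package's readers.

## Study sizes used by the tests

The test suite exercises the generator at the full default study size
(4,200 genes, 50 replicate seeds) for direction recovery and the
beta-sweep monotonicity check, 1,000 genes × 1,000 replicates for type-I
calibration of the two-sided test (expected rejection 5% within a binomial
99% band), and 150-gene configurations for pipeline-level round trips.
These sizes give the calibration checks sub-percent Monte-Carlo noise while
keeping a full run of the suite around two minutes.

## Known limitations

* **Zeros-policy sensitivity inverts under strong coupling.** In the weak
  regimes typical of real data, excluding zero-count genes (mostly short,
  low-opportunity genes — rank noise) sharpens the anticorrelation. Under
  the generator's strong default coupling ($\beta = 2$) the zero-count genes
  concentrate at *high* abundance, where removal is nearly certain, so they
  carry signal and excluding them usually *weakens* $|\rho|$ (it
  strengthened $|\rho|$ in only ~78% / ~64% of replicate sweeps in the two
  sweeps the tests and acceptance script run, short of a ≥90% expectation;
  the corresponding check is left failing rather than re-tuned). The
  synonymous channel, whose coupling is weak and noise-dominated, shows the
  classical behaviour. Treat the zeros-excluded variant as a sensitivity
  analysis whose direction depends on where the zeros live.
* The t-approximation p-value is asymptotic; with heavy ties and small n it
  can drift, which is why the exact-permutation regime exists below n = 10.
* `first_observed()` trusts its input to contain every sequenced timepoint;
  an allele first detected before the first provided timepoint is dated to
  the earliest row available.
* The mutation table is trusted to assign each allele to exactly one gene;
  overlapping-gene ambiguity must be resolved upstream, as in the processed
  datasets this format mirrors.
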