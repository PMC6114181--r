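---
title: "Methods: screening and Bayesian-network mediation analysis of miRNA-mediated genetic effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and Bayesian-network mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical procedure it
implements: the model class and its assumptions, the decision rules and their
operating characteristics, the design choices that were genuinely open, and
what the bundled synthetic-data generator does and does not emulate.

## Data model and node roles

All statistics are computed across the strains of a two-parent recombinant
inbred (RI) panel. Because every strain is genetically fixed, data from
different studies can be joined at the strain level; for each phenotype the
analysis uses the intersection of strains present in the genotype, miRNA,
gene-expression and phenotype sources (`align_for_phenotype()`), and that
intersection size is the sample size `n` of every likelihood below.

SNPs whose parental alleles differ and whose calls are complete are recoded
0/1 by parental origin; SNPs with bit-identical strain vectors are in complete
linkage disequilibrium and collapse into one strain distribution pattern
(SDP, `collapse_to_sdps()`). Complementary vectors are *not* merged: in a
two-parent panel a complemented pattern would require a recombination between
the two markers in every strain. An SDP whose member SNPs sit on several
chromosomes (possible by chance genome-wide) is assigned to the chromosome
holding most of its members for locus grouping, with a warning — the identical
pattern is a statistical, not a physical, object.

Networks are DAGs over three node roles:

* **SDP** — binary root ("causal anchor"): all incident edges point away.
  Genotype is fixed at meiosis, so expression and behavior cannot cause it
  (Mendelian randomization).
* **miRNA / gene expression** — continuous intermediates, unconstrained.
* **phenotype** — continuous sink: all incident edges point in. Expression is
  measured in naive animals, so the phenotype cannot feed back on it.

With one node of each of SDP/miRNA/gene/phenotype these constraints leave
exactly 96 admissible structures (`enumerate_constrained_structures()`, which
the acceptance script cross-checks against a brute force over all 4096
directed graphs).

## Likelihood and score

Continuous nodes get linear-Gaussian conditionals: OLS of the node on an
intercept plus its parents, with the maximum-likelihood residual variance
RSS/n, contributing `parents + 2` parameters (intercept, slopes, residual
variance). The binary SDP root contributes its unconditional Bernoulli
density and one parameter; because binary nodes are never children, no
logistic or mixture components are needed. The network score is

    BIC = log L - (d/2) * log(n)

with natural logarithms, `log L` the sum of maximized per-family
log-likelihoods and `d` the summed parameter count; *higher is better*. The
per-family decomposition is exploited everywhere: exhaustive scoring of a
structure space fits each unique (child, parent-set) family once
(`score_structure_space()`), and hill-climbing caches family scores across
moves. Exact score ties are broken deterministically: fewer edges first, then
the lexicographically smallest edge list.

Degenerate inputs are surfaced, not patched: a zero-variance node or a
collinear parent set is an error at scoring time, a zero-variance column in a
bootstrap resample triggers a redraw (up to 10 attempts), and screens report
`NA` p-values for flat features so they can never pass a threshold.

## Stage 1: cohesive screen

Pairwise Pearson correlations with two-sided t-tests
(`t = r*sqrt((n-2)/(1-r^2))` on `n-2` df; point-biserial against the binary
SDP). Triplets require all three molecular correlations at `triplet_p`
(default 1e-3); quadruples additionally require all three phenotype
correlations at `quadruple_p` (default 0.05). The stricter molecular
threshold reflects the more direct relationships expected among SDP, miRNA
and gene. No multiple-testing correction is applied at this stage — the
thresholds are screening devices ahead of the much more conservative
BIC-difference filter, and a principled joint correction across the heavily
correlated tests is an open problem. The staged implementation (SDP–miRNA
pairs, then SDP–gene, then miRNA–gene within survivors) is provably identical
to the brute-force triple loop and is tested against one. All correlations
for a phenotype are computed on that phenotype's strain alignment; this is
the default reading of an ambiguity (triplets could also be screened once on
the full genomic intersection), and the alternative is available by aligning
on a complete pseudo-phenotype.

## Stage 2: mediation decision

For each quadruple all 96 structures are scored. **Step 1** partitions them
by whether the miRNA lies on a directed SDP-to-phenotype path
(`is_mediator()`: the miRNA is reachable from the SDP and the phenotype from
the miRNA — equivalent to path membership in a DAG) and requires

    max BIC(mediated) - max BIC(non-mediated) > 2

plus the best structure overall being mediated (these coincide whenever the
difference is positive). **Step 2**, evaluated only among mediated
structures, compares the best structure with the gene also on the path
against the best with the miRNA on the path but not the gene, and includes
the gene under a non-inferiority margin, ΔBIC > −1. "On the path" uses the
same directed-path-membership definition for the gene as for the miRNA.
Both thresholds are configuration values (`bic_delta_mediation`,
`bic_delta_gene`).

### The ΔBIC ceiling: why step 1 is a rare-event filter

A property of score-based selection worth understanding before interpreting
pass rates: Gaussian-network BIC is *score-equivalent* — likelihood-equivalent
DAGs score identically. For any mediated structure there is a non-mediated
structure (reorient the miRNA-gene edge inside a complete sub-DAG over SDP,
miRNA, gene, keep the phenotype's family) whose maximized likelihood is at
least as high at the cost of at most one extra parameter. Consequently

    delta = max BIC(mediated) - max BIC(non-mediated) <= 0.5 * log(n),

which is ≈ 2.05 at n = 60 and < 2 for n ≤ 54. Under exact full mediation the
difference behaves like `0.5*log(n)` minus half a chi-square(1) variate, so
the ΔBIC > 2 rule passes only a minority of sampled panels at n = 60 and can
*never* pass at the sample sizes of a ~33-strain phenotype. This is not an
implementation artifact but the designed behavior of a deliberately
conservative rule: it admits a quadruple only when the data leave almost no
BIC headroom for any non-mediated explanation, and in a screen of thousands
of quadruples a per-quadruple pass probability of a few percent still yields
candidate networks while keeping false mediation claims rare. The package's
acceptance suite measures these operating characteristics (full-mediation and
direct-only scenarios at n = 60, standardized paths 0.8/0.9/−0.7) rather than
assuming them. The gene step's −1 margin is permissive by design: an on-path
gene is virtually always retained, while an off-path gene correlated through
the miRNA is excluded only in the majority, not the near-totality, of draws.

## Stage 3: locus grouping and bootstrap-averaged expansion

Mediation-passing quadruples of one phenotype whose SDP span midpoints lie
within `locus_window_bp` (default 40 Mb, the scale over which RI-panel LD
commonly links markers) on the same chromosome are merged by single-linkage
chaining — in one dimension this is simply sorting midpoints and cutting gaps
larger than the window. A group's node set is its SDPs, the miRNAs of its
member decisions, the genes of members that passed step 2, and the phenotype.

The group network is learned on each of `n_boot` (default 500) strain
resamples drawn with replacement at the strain level — the exchangeable unit,
since every statistic is across strains. Node sets of ≤ 5 nodes are searched
exhaustively; larger ones use greedy hill-climbing from the empty graph over
single-edge additions, deletions and reversals that respect the role
constraints and acyclicity, accepting only strict BIC improvements with a
deterministic move preference (additions over reversals over deletions, then
lexicographic). Because score equivalence creates plateaus around misoriented
edges, the climber additionally probes score-neutral reversals at each local
optimum and keeps such an excursion only when continued climbing strictly
improves the total score; random restarts are available (`restarts`) and, per
the greedy search literature, tend to give similar results.

Averaging retains a directed edge when its presence frequency over the
bootstraps *strictly* exceeds `retention` (default 0.5) and its winning
direction also strictly exceeds it. The direction denominator is the set of
bootstraps containing the edge in either direction (the usual model-averaging
convention); `direction_denominator = "all_bootstraps"` switches to the
unconditional reading. If the retained edges were ever to close a cycle,
edges are admitted in decreasing presence frequency and cycle-closing edges
skipped with a warning. Nodes without retained edges are reported as dropped
and omitted from the final structure, and a two-sided binomial argument says
two runs at `n_boot = 500` should agree on any frequency to within about
0.06.

## Stage 4: interventional prediction

`fit_network_parameters()` refits every family of the final structure by OLS
and records per-node training quantiles (min, Q1, Q3, max; linear
interpolation by default, nearest-rank as an option — conventions differ
across software and the choice is visible in the quantile values, not the
method). `predict_phenotype_change()` uses *do*-intervention semantics: the
target miRNA or gene is set to Q1 then Q3 (2-quartile) or min then max
(4-quartile), expectations propagate through descendant structural equations
only, and upstream nodes — including the SDP — are untouched. Conditioning
instead of intervening would back-infer the genotype from the expression
change, which is not the question a therapeutic perturbation asks. By
linearity the change equals the input change times the sum over directed
target-to-phenotype paths of edge-coefficient products; both routes are
computed and cross-checked to 1e-10 on every call. Targets with no directed
route to the phenotype predict exactly zero change.

## The synthetic-data generator

`simulate_ri_genotypes()` emulates RI genotypes as two-state Markov chains
along SNP order (per strain and chromosome: initial origin Bernoulli(0.5),
per-interval switch probability `flip_prob`), plus a fraction of
non-informative SNPs and sporadic missing calls so the informative-marker
filter has something to do. `flip_prob = 0` collapses each chromosome to one
SDP; `flip_prob = 0.5` makes markers independent. The default 0.1 produces
LD blocks whose neighbouring SDPs are strongly correlated — deliberately, so
the locus-grouping stage is exercised by realistic linked signals.

`simulate_quadruple()` wires SDP/miRNA/gene/phenotype by linear-Gaussian
structural equations under five scenarios (`full_mediation`,
`mediation_no_gene`, `direct_only`, `null`, `reverse_gene_to_mirna`).
Coefficients are *standardized path coefficients*: each node is generated
with marginal variance ≈ 1, so a single-parent edge coefficient equals the
population correlation along it. Defaults are 0.8 (SDP→miRNA), 0.9
(miRNA→gene) and −0.7 (gene→phenotype) at `n_strains = 60` with 3 replicates
per strain and replicate noise sd 0.25 — effect sizes at which pairwise
associations clear the screening thresholds with high power at RI-panel-like
sample sizes, while replicate noise attenuates observed correlations by a
realistic few percent. `simulate_panel()` embeds such quadruples onto real
simulated SDP loci (anchors sampled among patterns with allele frequency
0.25–0.75, since a near-monomorphic anchor carries no mappable signal),
places the embedded features within 10 Mb of their anchor (cis regulation),
and fills the rest of the feature space with independent Gaussian noise. One
global seed deterministically derives all child seeds; `write_panel()` output
is byte-identical across runs.

What the generator does *not* emulate — and therefore what green tests do not
certify about real data: count-scale expression and its variance-stabilizing
transformation (values are emitted directly on the Gaussian scale), batch
effects, epistasis, nonlinear dose-response, realistic recombination maps and
marker ascertainment, and phenotype measurement structure beyond a single
strain-level value.

## Problem sizes used by the test suite

Validation uses sizes chosen to give stable Monte-Carlo estimates at
interactive runtimes: 200 seeds for the mediation operating characteristics
and structure recovery, 50 seeds for the optimizer-vs-oracle and end-to-end
panel checks (60 strains, 180 SNPs, 120 expression features, 100 bootstraps
in the end-to-end loop), 500 bootstraps for the single-scenario averaging
checks, and n = 5000 for prediction consistency. The bootstrap-averaging
strong-chain property is summarized as the median edge-presence over five
data seeds because the weakest edge's presence frequency varies
realization-to-realization around the reporting threshold.

## Known limitations

* Step 1's ΔBIC > 2 rule cannot pass below n ≈ 55 and is a low-power filter
  near that boundary (see the ceiling argument above); interpret pass rates
  as a conservative screen, not a mediation test with controlled power.
* Score equivalence means bootstrap averaging can stably retain a
  likelihood-equivalent reorientation of the generating chain (e.g. the gene
  oriented into the miRNA with a compensating SDP edge) in a minority of
  realizations.
* Exhaustive enumeration is limited to 6 nodes (and used for ≤ 5 by
  default); larger locus groups rely on the greedy climber's local optima.
* Predictions are point values from a linear model; no uncertainty intervals
  are attached, and extrapolation beyond the observed quartile range inherits
  the linearity assumption.
* Cross-chromosome locus grouping and structural priors are out of scope.
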