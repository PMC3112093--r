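---
title: "Methods: evolutionary analysis of the GSIS protein network"
author: "gsisEvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary analysis of the GSIS protein network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsisEvol)
```

# The scientific question

Glucose-stimulated insulin secretion (GSIS) in pancreatic β-cells runs on a
core biochemical network — glycolysis, the TCA cycle, the pyruvate cycle and
NADH shuttles, metabolite transport, the respiratory chain, and the
glutathione detoxification pathway. Most of these enzymes are far older than
β-cells themselves. This package asks how the parts of one ancient network
have evolved *relative to each other*: whether sub-pathways form coalitions
that co-evolve in sequence divergence and in gene-duplication history, and
whether individual proteins at sub-pathway interfaces evolve unusually fast
("adapter" proteins).

The working cohort is the packaged `gsis69` fixture: 69 network proteins
with sub-pathway codes, a phylogenetic age class, human–mouse percent
similarity, positive-selection episodes, and OMIM disease associations.

```{r}
fx <- loadFixture("gsis69")
fx
```

# Sequence conservation

Human–mouse divergence is measured on protein sequences: the two genomes are
well assembled and ~90 MY of divergence is short enough to avoid serious
mutational saturation, so percent similarity of orthologue pairs is a usable
proxy for conservation.

`alignGlobal()` computes a true global (Needleman–Wunsch) alignment under
BLOSUM62 with affine gap penalties. Conventions, all configurable:

* a gap of length $L$ costs `gapOpening` $+ L \times$ `gapExtension`;
  defaults are 10 and 0.5, the classical defaults of the EMBOSS-family
  global aligners;
* end gaps are penalized; `endGapsPenalized = FALSE` gives semi-global
  semantics;
* **percent similarity** is the percentage of alignment columns whose
  residue pair has a *positive* substitution score; gap columns count in
  the denominator only. Percent identity is defined analogously with exact
  matches. Since the similarity notion has no universal formula, this
  (the EMBOSS convention) is fixed as the package's definition;
* the optimal *score* is the tested contract (it is tie-break independent);
  the traceback is the aligner's deterministic one, so co-optimal
  alignments are reported reproducibly.

Summaries use the sample ($n-1$) standard deviation. `quintileBins()`
shades the cohort into five equal-rank bins, ties going to the lower bin so
equal values never straddle a boundary. `pathwayOutliers()` flags proteins
beyond Tukey fences (quartiles by linear interpolation, 1.5 IQR) within
their own pathway group; groups of fewer than four members produce no calls
because fences from three points are noise. On the cohort this flags NDK,
PDCc, IDHcp and SOD2e as low outliers — the adapter candidates.

# Phylogenetic age

`classifyProfile()` assigns each protein the taxonomic reach of its
detectable homology, from counts of distinct genomes hit per category, in a
fixed, non-hierarchical order: more than five prokaryote genomes →
Universal; otherwise ≥ 1 non-metazoan eukaryote → Eukaryote-specific;
otherwise ≥ 1 non-mammalian metazoan → Metazoan-specific; otherwise
Vertebrate-specific. Exactly five prokaryote hits do *not* qualify as
Universal; counts are genomes, not HSPs; a separate mammal category in hit
tables is collapsed into vertebrate, since vertebrate-specific is the
terminal class. Hit tables are pre-filtered at E ≤ 10 (configurable) with
the best hit kept per query/genome pair.

`compareComposition()` is a Pearson goodness-of-fit chi-squared of the
cohort's U/E/M/V counts against the genome-wide metabolic reference
proportions (0.56/0.20/0.05/0.19) carried by the fixture.

`sharedHomologClusters()` joins proteins whose homologue-id sets intersect
(single linkage over components). Single linkage is chosen because the
groups it should recover are mutually disjoint families, which connected
components preserve; whether all-hit or best-hit homologue sets enter is a
free choice and the package uses all retained hits after the E-cutoff.

# Duplication histories

Duplication-annotated gene trees are read from NHX (`D=Y` duplication flag,
`T=` taxon, `A=` age in MYA, `F=Y` family founder; unknown tags ignored).
`extractDuplicationVector()` counts duplication nodes on the root-to-leaf
path of the focal gene, binned by the taxon schedule
(`defaultTaxonSchedule()`: Euteleostomi 420 → Catarrhini 31 MYA). Two
truncation rules keep the vector within the focal gene's own vertebrate
family history:

* taxa outside the schedule (pre-vertebrate labels) contribute nothing;
* nodes at or above a family-founding duplication are excluded. The
  founder itself is excluded: it creates the family, so only events *within*
  the family are counted. "Founding" is a curator judgement, hence an
  explicit `F=Y` tag rather than an inferred property.

Histories are compared by Euclidean distance and clustered with `hclust`
(complete linkage by default — the base-R default family — configurable);
the interpretable flat clusters are taken at merge height 0, i.e. groups
with *identical* histories, which equals the exact-equality partition for
any linkage.

## Group (anti)clustering tests and their calibration

`groupClusteringTest()` compares within-group pairwise distances against
all remaining pairs with a two-sided Mann–Whitney test (exact where
`wilcox.test` supports it, normal approximation with tie correction
otherwise); Bonferroni correction multiplies by the number of groups tested
in the same family. A significantly smaller within-group median is
*clustering*, larger is *anticlustering*. Fully tied distances are reported
as p = 1.

A caveat the package measures rather than hides: pairwise distances share
genes, so they are not independent samples, and the plain rank-sum p is
anticonservative under a random-membership null (simulations in the
acceptance suite measure ~10–20% rejection at a nominal 5%, depending on
group size and vector distribution). The package therefore also offers a
label-permutation p (`nPermutations > 0`), which compares the within-group
rank sum against its distribution over random same-size groups and is
calibrated by construction. The rank-sum p is retained as the default
because it is the method the analysis tradition uses; strong claims
(p ≪ 0.001) survive either way, marginal ones should be read against the
permutation p.

# The statistical battery

* **Divergence ANOVA** — one-way fixed effects on percent similarity.
  The default grouping (`six_group`) keeps G, T, M, R, S and merges the
  pyruvate cycle and NADH shuttle into PN: a six-level factor, df = 5.
  Multi-pathway proteins are assigned by their *first-listed* code, the
  only ordering the source tables provide. The five-group variant
  (`five_group_figure3`, TPN merged) is the boxplot/outlier grouping.
  A degenerate design (zero variance everywhere) is an error, not an NaN.
* **Tukey HSD** — all pairwise group contrasts with studentized-range
  adjusted p.
* **Spearman correlation** — midrank ties; exact enumeration for n ≤ 9
  without ties, t approximation otherwise.
* **Disease comparisons** — Welch two-sample t-test of similarity for
  disease vs non-disease proteins (`varEqual = TRUE` gives the pooled
  variant). Welch is the default deliberately: it is the default of the R
  environment this analysis tradition uses, and the pooled variant is
  available by flag. The age-class comparison is a goodness-of-fit of the
  Universal proportion among disease genes against the cohort proportion;
  the selection comparison is a 2×2 chi-squared (1 df, no continuity
  correction by default, Yates by flag) of ≥ 1 recorded
  positive-selection episode against disease membership.

# Synthetic data and what the tests show

Every input the pipeline consumes has a generator that returns its own
ground truth (`synthProteinPair()`, `synthHitProfile()`,
`synthGeneTree()`, `synthCohort()`), and every stage has a recovery test
driven only by these generators. Design choices:

* sequence pairs hit a target similarity by substituting residues with
  non-positive BLOSUM62 scores plus occasional deletions, tuned by a
  bounded rejection loop (50 retries) that adapts the substitution count —
  analytic inversion is awkward because the realized value depends on the
  re-alignment;
* hit profiles are drawn under hard constraints, so the classifier recovers
  the intended class with probability 1 (a diagonal confusion matrix is a
  correctness check, not a statistical one);
* gene trees place Poisson numbers of duplication nodes per schedule bin on
  the focal lineage of a ladder backbone and return the drawn counts;
* cohorts draw per-group Gaussian similarities (truncated to [0, 100]) and
  link duplication counts to similarity through a Gaussian copula; the
  Pearson parameter is $2\sin(\pi\rho_s/6)$, the exact inversion for a
  target Spearman $\rho_s$. Poisson discretization attenuates the realized
  rank correlation slightly (≈ 0.38 realized at a 0.40 target with mean 3
  counts). Cohort defaults reproduce the observed group sizes, means and
  spreads of the study cohort and its reported divergence–duplication
  rank correlation (0.339).

Generators are seeded and byte-reproducible: same seed, same output.

Problem sizes used by the test and acceptance suites — chosen as the sizes
at which the checked quantities stabilize: alignment-oracle equivalence on
~120 random pairs of length ≤ 12; classifier truth table over the full
{0..10}³ count space; 500 simulated trees for vector round-trips; 1000
membership shuffles for test calibration; 1000 replicate cohorts for ANOVA
size/power and 500 for Spearman recovery.

What passing these tests does **not** show: the generators target the
statistical structure the analysis consumes, not realistic protein
evolution (no substitution-rate matrices over trees, no indel length
distributions, no rate heterogeneity), so they validate the machinery, not
biological conclusions about new data.

# Known limitations

* The fixture's similarities are printed to 0.1, so statistics recomputed
  from it differ from values computed on unrounded inputs at the first
  decimal (e.g. cohort mean 93.8 vs an original 93.7).
* The exact assignment of multi-pathway proteins to ANOVA groups admits
  several readings; the first-listed-code convention is one consistent
  choice and moves the F statistic at the few-percent level (the package
  obtains F ≈ 8.4 with df = 5; the significance pattern, including every
  Tukey contrast, is insensitive to this choice).
* The plain Mann–Whitney group test is anticonservative (above); use the
  permutation p for marginal calls.
* Duplication-vector analyses depend entirely on the input trees'
  duplication annotations; the package deliberately performs no
  reconciliation or duplication inference of its own.
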