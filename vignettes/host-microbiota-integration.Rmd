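---
title: "Linking mucosal microbiota to host gene expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking mucosal microbiota to host gene expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mucosa-adherent bacteria and the epithelium they colonize regulate each
other, and studies of that crosstalk routinely produce one 16S OTU count
table and one RNA-seq expression table over the *same* handful of animals —
typically two diet or treatment groups of three. `rumilink` implements the
complete analysis arc for that design: community structure and diversity on
the microbial side, a fold-change screen on the host side, a seed-gene
co-expression network, and a correlation-screened constrained
correspondence analysis (CCA) that places microbial genera and host genes
in one ordination.

The central statistical difficulty is the sample size. With six samples,
asymptotic p-values for rank correlations are meaningless; every inferential
step here is built on exact enumeration instead, and the consequences of
that choice (discrete p-value grids, hard p-value floors) are carried
through the design rather than papered over.

# Pipeline stages and their models

## Community statistics

OTU counts are filtered (`filter_min_count()`: an OTU must *exceed* 3 reads
in at least one sample — a strict reading, so a count of exactly 3
everywhere is dropped), summed hierarchically along the taxonomy
(`aggregate_at_rank()`, with an explicit `unclassified` sentinel bin), and
normalized to per-sample relative abundances. Detectability for clade-level
summaries is *inclusive* at 1% (`detectable_filter()`). Shannon diversity
uses natural logarithms, the convention of the ecology packages this
workflow interoperates with.

Rarefaction is computed analytically: the expected richness in a uniform
subsample of `m` reads is the hypergeometric expectation

$$E[S_m] = \sum_i \left(1 - \binom{N - N_i}{m}\Big/\binom{N}{m}\right),$$

evaluated on the log-choose scale. This is deterministic and exact;
repeated random subsampling appears in the test suite only as an
independent Monte Carlo oracle.

ANOSIM uses midranks of all pairwise Bray–Curtis dissimilarities,
`R = (mean between-group rank − mean within-group rank) / (M/2)`. The
p-value enumerates *all* distinct label assignments whenever there are at
most 10,000 of them (20 at 3+3, 70 at 4+4), falling back to seeded Monte
Carlo above that. The enumerated p lives on a discrete grid; `anosim()`
therefore also returns the strict-tail `p_exclusive`, and the calibration
tests assess uniformity through the randomized probability integral
transform, which is exactly U(0,1) under exchangeability. The raw
inclusive p is sub-uniform (conservative), as a permutation p should be.

Per-taxon group differences are summarized as percent change of group
means; where a significance label is wanted, the package deliberately does
not invent one — the choice of test for 3-vs-3 abundance comparisons is a
user decision, and an exact Wilcoxon rank-sum at these sizes cannot reach
conventional significance levels anyway.

## Expression screen

`compute_rpkm()` is the standard reads-per-kilobase-per-million
normalization. A gene is *expressed* when it strictly exceeds 1 RPKM in at
least one sample. Differential expression is a fold-change rule on group
means: `log2(MC/LC)` with an **inclusive** threshold (`up` iff
`log2FC >= 1`). Inclusivity is deliberate: the bundled reference panel
contains a gene whose group means sit exactly at ratio 2 (printed log2 of
1.00) and that gene belongs to the published up-regulated set; a strict
`>` rule would contradict the published counts. Boundary comparisons carry
a 1e-9 absolute epsilon so decimal inputs that sit exactly on the
threshold classify deterministically under floating-point arithmetic.

The package ships two small group-mean RPKM panels
(`reference_panel("lectin")`, `reference_panel("cytokine")`) from a goat
rumen epithelium diet contrast (35% vs 10% dietary concentrate, three
animals per group). Because the printed group means are rounded to two
decimals, recomputed log2 ratios are compared to the printed ones at one
unit in the last printed digit (±0.01): two chemokine rows differ from
their printed value by ~0.005 purely through that input rounding. A few
rows of the lectin panel have printed log2 values that are arithmetically
inconsistent with their own printed means (e.g. LMAN1, LGALS8, LGALS4);
they are flagged `log2_consistent = FALSE` and excluded from any
quantitative claim rather than silently corrected.

## Co-expression network

All gene pairs among expressed genes are scored with Spearman's rho
(midranks) and a permutation p-value; edges require `|rho| > 0.8` *and*
`p < 0.05`. Three design points matter:

- **Exact p-values.** For `n <= 8` samples the permutation null is
  enumerated completely (`spearman_null()`, cached per `n`). At `n = 6`
  the two-sided p has a hard floor of `2/720 ≈ 0.0028`, and the joint edge
  rule is equivalent to `|rho| >= 0.886` — exactly 24 of the 720
  permutations reach that magnitude, so the per-pair false-edge rate of a
  null panel is 1/30. This arithmetic is frozen into the tests.
- **Ties.** Tie-free pairs use the tabulated null. Tied pairs at
  `n <= 8` are still handled exactly, by enumerating all `n!` relabelings
  of the observed midranks; only `n > 8` with ties falls back to a seeded
  Monte Carlo permutation p. Enumeration is both exact and far cheaper
  than simulation at these sizes.
- **Absolute rho.** Edges are kept by `|rho|`, with the sign carried as an
  edge attribute, because biologically meaningful negative co-expression
  (e.g. a receptor and its repressed target) would otherwise vanish from
  the network. A one-sided option exists (`alternative=`).

Seed genes (typically the differentially expressed lectins) anchor
first-neighbor extraction; neighbors are filtered to differentially
expressed ones and summarized per pathway through a user-supplied two-column
gene-to-pathway map — no database access is performed or assumed.

For `n > 8` tie-free data the t approximation
`t = rho * sqrt((n-2)/(1-rho^2))` replaces enumeration. Its adequacy is
tested against the discrete null under the mid-p convention (half the
probability mass at the observed value); the inclusive decision-grade p is
conservative relative to both.

## Integration: correlation screen and CCA

OTU relative abundances are screened against seed-gene RPKM: an OTU is
retained iff some seed gene shows `|rho| >= 0.6` with `p <= 0.05`
(inclusive boundaries — the removal rule is stated strictly, retention is
its complement). At six samples the exact-p constraint again dominates,
so retention effectively demands near-perfect monotone coupling; with
planted couplings absent, the expected retention rate per OTU-seed pair is
1/30. A `signed_rho` switch restricts retention to positive correlations.

`cca_fit()` implements canonical correspondence analysis from first
principles: chi-square standardization
`Q = (P - r c^T) / sqrt(r c^T)` of the grand-total-normalized community
table, weighted centering of the constraints, weighted least-squares
projection of `Q` onto the constraint space (QR with pivoting; collinear
columns are dropped right-to-left with a warning naming them), and SVD of
the fitted and residual matrices. Constrained plus unconstrained
eigenvalues reproduce the total inertia (the chi-square statistic over the
grand total) to machine precision, and eigenvalues agree with the
ecology-standard implementation to 1e-8 on random problems — that
implementation serves as a cross-check oracle in the tests, never as the
computation.

Scores default to the species-conditional convention ("scaling 2"):
species in principal coordinates, sites as both linear-combination (LC)
and weighted-average (WA) scores. WA scores are *exactly* the
per-site weighted averages of the species scores; they coincide with the
LC axis only in the unconstrained limit, a distinction the tests pin down.
With six samples at most five constrained axes exist; seed panels larger
than the rank are truncated with a warning.

Genus positions are unweighted centroids of their OTUs' species scores
(an abundance-weighted variant sits behind `weighted = TRUE`); "centroid"
is not otherwise canonical, so the convention is recorded in the result.
The community fed to the ordination is the relative abundance of the
retained OTUs; constraints are untransformed seed RPKM by default with a
`log_constraints` option.

# The synthetic-data generator

`synthetic_config()` describes a paired dataset with the structure the
analysis assumes: 3+3 samples, 647 OTUs over 14 phyla and 73 genera, a
100-gene panel of which 35 clear the expression filter, 13 planted
log2 effects (3 up, 10 down), five co-expression blocks around hub genes
(one negative, attached to the strongest down-regulated hub so its
members' opposite-sign response still clears the fold-change threshold),
and 62 OTUs monotonically coupled to seed genes — leaving ~90% of OTUs
uncoupled, the removal regime the integration stage is designed around.

Three design decisions deserve explanation:

- **Deterministic sample ladders.** Each gene's per-sample expected
  expression is its baseline times a permuted geometric ladder
  (step 1.5) renormalized to mean one within each group. Realized group
  means therefore equal the planted effects *exactly* in the noiseless
  limit, while per-sample values stay tie-free — a requirement of the
  exact permutation machinery.
- **Compositional balance.** Relative abundance is a closed composition:
  anything planted into some OTUs leaks into every other OTU through the
  per-sample total. Couplings are therefore planted in compensating
  +/− pairs (same gene, same abundance base; the "−" member is the pair
  total minus the "+" member's ladder, integer-exactly at dispersion 0),
  and group abundance effects default to +1/−1/−1 triplets on a shared
  baseline, which cancel in expectation. Without this balance the
  noiseless screen would spuriously retain *every* OTU.
- **Noise model and its level.** Counts are negative-binomial around the
  expected values with a single shared dispersion; `dispersion = 0`
  switches sampling off entirely (the fully deterministic noiseless
  limit, in which uncoupled effect-free OTUs are constant and the screen's
  retained set equals the planted coupled set by construction). The
  default dispersion of 0.01 (~10% coefficient of variation on
  well-observed features) was fixed from a design-time geometry
  calculation: it keeps planted monotone couplings "near-monotone" at
  n = 6, where one or two adjacent rank flips still pass the exact-p
  edge rule. Real mucosal 16S data are substantially noisier and more
  zero-inflated than this; recovery results on the synthetic preset
  demonstrate the machinery, not field performance.

The generator does **not** simulate reads, chimeras, sequencing error,
phylogenetic correlation among OTUs, or compositional correlation beyond
the planted structure. Ground truth (`SyntheticTruth`) records planted and
realized effects, block membership and coupled pairs, and is serialized as
JSON beside the TSV fixtures.

# Numerical choices

- DE boundary comparisons use a 1e-9 epsilon (see above).
- Eigenvalues below `1e-10 * max(d)` are treated as numerically zero in
  the CCA rank decisions.
- Exact-p tail comparisons use a 1e-9 guard so grid values equal to the
  observed statistic count as "as extreme".
- Comparisons of recomputed log2 ratios against printed two-decimal
  values use ±0.0101 (one unit in the last printed digit), the precision
  the rounded inputs support.
- ANOSIM midranks break dissimilarity ties; permutation p-values are
  inclusive of the observed assignment.

# Problem sizes in tests and the acceptance script

The test suite exercises compact instances (40-OTU/20-gene synthetic
presets, 6–8-sample CCA toys) plus the full default preset; the acceptance
script reruns the default preset end to end, 100 random CCA toys, 20
rarefaction communities against 1e5-draw Monte Carlo, and 500 ANOSIM null
replicates at 4+4. These sizes were chosen so the entire suite runs in
well under a minute of compute per stage while every statistical claim is
still measured, not assumed.

# Known limitations

- All-pairs network construction is O(G²) in the number of genes and is
  computed in one rank-matrix correlation call; panels far beyond ~10⁴
  genes would need blocking that this package does not implement.
- The DE screen is a fold-change rule on group means, as appropriate for
  a two-group RPKM design; it is not a dispersion-aware count model, and
  an external per-gene significance mask can be supplied where one exists.
- With three samples per group the exact Spearman p floor (2/720) means
  the network and screen thresholds act almost deterministically on
  |rho|; users should read edge lists as "near-perfect monotone
  relations", not as FDR-controlled discoveries.
- Genus centroids summarize OTU scores; genera whose OTUs straddle the
  ordination may have centroids near the origin that mean "heterogeneous",
  not "uninvolved".
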