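---
title: "Methods: digital gene expression analysis of SuperSAGE tag libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital gene expression analysis of SuperSAGE tag libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagescape)
```

# Scope

`sagescape` implements the desk side of a SuperSAGE digital gene
expression study comparing the transcriptome-wide immune response of two
diverging populations (the motivating system is lake versus river
stickleback ecotypes exposed experimentally to macroparasites, with
expression profiled in the head–kidney). Everything from raw tag reads to
multivariate statistics, differential expression and GO enrichment is
covered, together with a first-class synthetic-data module so that every
stage is testable without any external download. Wet-lab steps (breeding,
infection, dissection, RNA work, the sequencing chemistry itself) appear
only as parameters of the simulator.

# The experimental design the simulator emulates

`generate_design()` returns the fixed factorial layout: 2 populations × 2
families nested within population × 3 treatments (control, once exposed,
twice exposed) × 2 sexes = 24 libraries, 8 per treatment group, one male
and one female per (population, family, treatment) cell. This layout is a
constant of the analysis, not a knob: the degrees of freedom of the
multivariate tests (2/17, 1/17, 2/17, 1/17 overall; 1/3, 2/3, 1/3 within a
treatment group) follow from it.

Expression is simulated per gene and library as negative binomial with
`Var = mu + phi * mu^2`. Defaults are `baseline_mean = 100` tags per gene
and `phi = 0.2` — a depth at which the exact test is comfortably away from
small-count discreteness and a dispersion typical of biological replicates
of a single tissue in outbred animals. Real tag-count dispersions are not
published for this design, so `phi` is a config-exposed parameter, not a
claim about the study system; it can also be supplied per gene.
Population-specific responses are injected through `effect_spec()`: a
signed log2 fold change applied to a named gene set in one population for
one treatment transition. A `control_to_once` effect persists into the
twice-exposed libraries (the response is triggered, not transient);
`once_to_twice` affects only the twice-exposed group. The default
recovery-harness effect is a 4-fold up-regulation (log2FC = 2) of the
immune-annotated gene set in lake fish upon first exposure, which mirrors
the qualitative pattern the analysis is designed to detect. A sex effect
is available through the same mechanism but is off by default.

The synthetic transcriptome (`generate_transcriptome()`) uses 1 + Poisson(0.31)
transcripts per gene (≈ 1.31 transcripts/gene, the ratio of a
transcriptome of 21 449 transcripts over 16 371 genes), gamma-distributed
lengths with mean 500 bases, and a configurable fraction of *anchor-free*
genes whose transcripts contain no `CATG` anywhere — those genes are
biologically expressed but invisible to the tagging protocol, which is the
structural reason a tag protocol detects only a subset of the genome.
Desk-scale defaults (2 000 genes in the generator, 120–500 in tests and
the demo pipeline) keep simulations fast while leaving every statistical
property intact; the package's own test harness states the sizes it uses
with each check.

## What the simulator does and does not emulate

Reads are `barcode + tag`: a random 8-bp barcode followed by the 26-bp tag
(the `CATG` anchor plus the following 22 bases) taken at the transcript's
3′-most anchor site that still leaves a complete tag window. Copies
falling on transcripts with no usable site are skipped and tallied. PCR
duplication replicates existing (barcode, tag) pairs (each read spawns a
geometric number of copies); substitution errors are applied per base
after duplication. Sanger Q40 qualities are written for every base.

Two deliberate idealizations:

* **Barcode collisions.** Within one library, the original molecules of a
  tag draw *distinct* barcodes (sampled without replacement from the
  4^8-barcode universe). Real barcoding collides at a rate of roughly
  `c^2 / 2·4^8` for `c` molecules and under-counts accordingly — a
  limitation of the protocol itself, which no software step can undo. The
  simulator removes that nuisance so that de-duplication is exactly
  invertible and the round-trip contract (`dedup == ground truth`) is
  testable as an identity.
* **No adapters, no quality model.** Adapter trimming and quality-aware
  cleaning belong to the upstream tag-sorting software of the real
  protocol; the simulator emits pre-clean reads of fixed layout. Passing
  tests therefore certify the counting and statistics machinery, not
  robustness to messy library chemistry.

# Consensus reference

`align_reads_to_backbone()` is a deliberately small seeded ungapped
aligner: reads vote for transcripts by shared k-mers (default `k = 12`),
are placed on the modal diagonal of their best transcript, and must reach
`min_identity = 0.9`; ties across genes are discarded, ties among splice
variants of one gene go to the longest transcript (stable and
documented). Ungapped alignment is sufficient here because the consumer
of the consensus is a 26-bp substitution-tolerant tag match — indel
realignment would add complexity without changing tag assignments at desk
scale. `call_consensus()` recodes a position as the IUPAC code of
backbone ∪ variants when a non-backbone base reaches both
`min_minor_count = 2` reads and `min_minor_frac = 0.2` of local depth.
The thresholds that produced the published consensus are not recorded
anywhere, so ours are parameters with sensible defaults, not claims.
Consensus length always equals backbone length, and an empty read set
returns the backbone byte-for-byte.

# Tag processing rules

* **Extraction**: fixed layout, anchor-checked; short or anchor-violating
  reads are tallied, never silently dropped.
* **De-duplication**: count = distinct barcodes per tag (per library).
* **Artifact reduction**: the cited artifact-reduction method's
  parameters are not published, so the package defines a transparent
  rule: a tag is absorbed into a Hamming-distance-1 neighbour whose
  (pre-absorption) count is ≥ 100× its own; ties go to the highest count,
  then lexicographically; tags are processed in ascending count order
  against frozen decision counts, making the rule order-independent and
  count-conserving.
* **Occurrence filter**: `N`-containing tags are removed, then tags seen
  in fewer than 7 of the libraries. The published order of these steps is
  unstated; this package fixes N-filter → per-library artifact reduction
  → cross-library occurrence filter, and the filter is idempotent.

# Tag-to-gene assignment

A tag scores a transcript at the minimum mismatch count over all forward
offsets; "matched with fewer than two mismatches" is implemented literally
as ≤ 1. A reference IUPAC base *always* costs one mismatch, even for
bases the code covers: this reproduces the neutrality property that
motivated the consensus in the first place — at a recoded SNP both alleles
of a tag carry the same mismatch count, so neither is favoured (the same
behaviour as a BLAST search that treats ambiguity codes as unknown `N`s).
Hits confined to one gene assign the tag (splice variants collapse); hits
spanning several genes are ambiguous and excluded from counting, with
their count share logged. The scan engine is vectorized pattern matching
behind this rule; an exhaustive pure-R offset scan is kept in the package
(`scan_tag_exhaustive()`) and the test suite asserts the two are
identical, so the optimization can never drift from the definition.

Normalization divides by the per-library total of *assigned* tag counts
(×10^6). Whether the published totals were taken before or after
assignment is unstated; assigned totals are the choice here because they
make each column of the analyzed matrix sum to exactly one million.

# Multivariate statistics

`correlation_distance()` uses `d = 1 − r` (range `[0, 2]`), matching the
conventional "correlation" distance for expression profiles; a flag
selects `(1 − r)/2`. The distance is invariant to per-library rescaling,
which makes the interaction with CPM normalization harmless.

`permanova()` computes Gower-centred inner products
`G = −(1/2) C D² C`, sequential (Type I) hat-matrix sums of squares in
the order the terms are given, and pseudo-F statistics tested by free
permutation of library labels, with the standard bias-corrected p-value
`(#{F* ≥ F} + 1)/(n_perm + 1)` (999 permutations by default). Because
family labels are unique within population, listing `family` after
`population` yields the nested coding: four family levels contribute two
additional degrees of freedom, reproducing the 2/17 (overall) and 2/3
(within-treatment) pattern of the design. Restricted/strata permutation
schemes are intentionally out of scope. Confounded terms (no added rank)
raise an error naming the term. The test suite pins the implementation to
two independent oracles: classical one-way ANOVA F in the Euclidean
single-factor case (tolerance 1e-10) and `vegan::adonis2` for the full
sequential multi-term fit.

`nmds()` wraps the global-model monotone-regression engine of `vegan`
(Kruskal stress-1, primary treatment of ties) in a seeded multi-start: one
classical-scaling start plus random starts, keeping the lowest-stress
solution. Determinism is by seed; stress is monotone non-increasing in
the embedding dimension.

# Differential expression

The DE engine is a self-contained conditional-likelihood NB exact-test:

* **Dispersion** (`estimate_dispersion()`): after grouping libraries by
  population × treatment, the per-gene conditional log-likelihood
  `l_g(phi)` (counts conditional on group totals, equal library sizes) is
  maximized — summed over genes for the common value, and per gene plus
  `shrinkage_weight × mean_g l_g(phi)` for tagwise values
  (`shrinkage_weight = 10` by default; tagwise → common as the weight
  grows, by construction). The common part is spline-interpolated on a
  60-point log-phi grid over `[1e-6, 5]` so the per-gene optimizations
  stay O(1) in gene count; a boundary solution at the lower end is
  reported as dispersion 0.
* **Test** (`exact_test()`): conditional on a gene's combined total `t`,
  the group-A total is negative hypergeometric with shapes
  `(n_A/phi, n_B/phi)` — binomial with probability `n_A/(n_A+n_B)` in the
  `phi → 0` limit. The two-sided p-value sums the probabilities of all
  outcomes at most as likely as the observed one (with a 1e-7 relative
  tolerance for floating-point ties; tail doubling is a config
  alternative). Library sizes are treated as exactly equal — the upstream
  normalization fixes every library at one million tags, so the quantile
  pseudo-equalization used by GLM-era DE tools is replaced by this
  documented simplification. Genes with zero total get `p = 1`,
  `log2FC = 0` by definition.
* **Fold change**: normalized group means with a prior count of 0.125 per
  library (conventional; config-exposed). **FDR**: Benjamini–Hochberg
  step-up via the standard library routine behind a validating surface;
  `alpha = 0.05` defines "significant" throughout and is config-exposed.

The contrasts are fixed to the design's transitions — control → once and
once → twice, separately within each population — and
`classify_population_specific()` partitions genes into lake-only,
river-only and shared responder sets per transition, with
`chisq_2x2()` (Pearson, no continuity correction) contrasting the up/down
composition between populations. `mann_whitney()` (midranks; exact by
enumeration for `n ≤ 12` without ties, else normal approximation with tie
correction) serves the parasite-load comparisons that accompany such an
experiment.

The engine is validated against a binomial oracle at `phi = 0`, a
brute-force enumeration of the conditional distribution for small totals,
label-symmetry and null-calibration properties; the GLM/quasi-likelihood
framework, TMM normalization and trended dispersion are non-goals.

# GO enrichment

`load_dag()` reads a minimal OBO subset (`[Term]`, `id:`, `name:`,
`is_a:`) or a two-column parent-child TSV, and validates acyclicity
(Kahn's algorithm, reporting a concrete cycle) and single-rootedness. No
installed R package provides an OBO reader, so this small parser is part
of the package surface. `propagate_annotations()` applies the true-path
rule (a gene annotated to a term is annotated to all its ancestors), which
is what makes parent/child counts nest. `fisher_enrichment()` is the
classic per-term one-sided hypergeometric upper-tail test — the
DAG-decorrelating elim/weight variants are deliberately out of scope — and
omits terms with fewer than 5 annotated universe genes; the minimum-gene
filter is applied to propagated universe counts (the published counting
basis is unstated), and raw p-values are reported with a BH column
alongside. The universe is the set of genes with at least one annotation.
`second_order_profile()` reports, for each direct child of the root, the
proportion of a gene set annotated to that branch via closure; a gene may
hit several branches.

`generate_go()` builds the matching toy ontology: a `biological_process`
root, second-level children including an immune-system term with innate
and adaptive children, and random deeper leaves; a designated immune gene
set is annotated under the immune branch so that recovery of a simulated
immune response is a well-posed test.

# Numerical choices and degenerate inputs

* Permutation p-values always include the observed statistic
  (`+1/+1`), so they can never be 0 and are exact at the resolution
  `1/(n_perm+1)`; permuted F values are compared with a 1e-12 slack to
  keep ties stable across platforms.
* Sums of squares conserve the Gower identity
  `Σ SS_terms + SS_res = (1/n) Σ_{i<j} d²_ij` to 1e-8 relative, which the
  tests assert.
* All generators and resampling stages are pure functions of their
  arguments including `seed` (seeding via scoped RNG state, so user
  sessions are unaffected).
* Zero-variance libraries (correlation undefined), zero-total libraries
  (CPM undefined), empty backbones, confounded model terms, cyclic or
  multi-rooted ontologies, unknown genes in effect specifications and
  out-of-range pileup positions all raise errors naming the offender
  rather than propagating NaNs.
* The demo pipeline and test harness use problem sizes of 40–500 genes,
  chosen so the full suite and the acceptance script each run in about a
  minute on one CPU; all contracts are size-free and hold at any scale.

# Known limitations

* Equal-library-size assumption inside the exact test (see above): counts
  entering `exact_test()` should be of comparable depth, as simulated
  libraries are and as normalized real libraries become by construction.
* The artifact-reduction rule is this package's transparent definition,
  not a reconstruction of the proprietary method used upstream of the
  original data.
* Free permutation only; with two families per population, family and
  population effects are only partially separable — a property of the
  design, visible in the simulator as well.
* The aligner is ungapped and the tag matcher substitution-only; neither
  handles indels, by design.
* Barcode-collision under-counting is simulated away (documented above),
  so round-trip exactness certifies the software, not the chemistry.
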