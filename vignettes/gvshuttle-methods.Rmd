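---
title: "Methods: giant-virus transport and carbon-export analysis in gvshuttle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: giant-virus transport and carbon-export analysis in gvshuttle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvshuttle)
```

## The problem

Giant viruses (*Nucleocytoviricota*, NCLDV) infect eukaryotic plankton
throughout the water column. The "viral shuttle" hypothesis proposes that
viral lysis promotes aggregation of cell debris into sinking particles,
exporting carbon — and virions themselves — from the surface ocean to the
deep sea. Testing this with metagenomes requires three linked analyses:

1. quantify each viral population (assembled contig) across a depth × time
   grid of planktonic samples and in abyssal sediment-trap samples;
2. call *vertical transport*: populations present in the water column that
   are also detected in the 4000 m trap material; and
3. ask whether a population's abundance in the trap co-varies with the
   measured particulate carbon export flux, the signature of
   flux-associated ("shuttled") populations.

gvshuttle implements these stages over plain TSV inputs (per-base depth
tables from read mapping, a contig catalog, marker-gene hits, AMG
annotations, sample metadata, and a trap flux series), plus a synthetic
generator that reproduces the statistical structure of such a dataset so
the whole pipeline can be exercised and validated without any sequencing
data.

## Q2Q3 coverage

Per-contig abundance is the *central two-quartile* (Q2Q3) mean coverage:
sort the L per-base depths, discard the lowest and highest
`k = floor(L/4)` ranks, and average the rest. This trimmed mean ignores
uncovered contig ends and repeat-driven pile-ups. Two consequences matter
downstream:

* **Breadth rule.** If at most `floor(L/4)` positions are covered, every
  kept rank is zero and Q2Q3 is exactly 0. "Detection" (Q2Q3 > 0) therefore
  implicitly requires breadth > ~25% of the contig — a useful guard against
  spurious single-region mappings. The package asserts this arithmetic
  directly (on L = 100, detection flips between 25 and 26 covered
  positions).
* **Scale equivariance.** `q2q3(c·d) = c·q2q3(d)`, so column-wise
  normalizations commute with the statistic.

Trimming is rank-based (order statistics), not value-quantile based: with
`k = floor(L/4)` the kept set is always well defined, no interpolation is
needed, and the result is deterministic for tied depths. Contigs shorter
than 4 bp fall back to the plain mean, where trimming is undefined. Depth
files follow the samtools-depth dialect (contig, 1-based position, depth;
zero-depth rows may be omitted and are zero-filled on read).

Two display normalizations are provided, both column-wise (per sample):
`sum_to_one` (relative abundance; columns sum to 1) and `max_of_sample`
(peak-scaled; column maxima are 1). All-zero columns pass through
unchanged — a sample in which nothing is detected stays a zero column
rather than becoming NaN.

## Contig curation and taxonomy

Catalog membership is defined by NCLDV-specific marker genes: the A32-like
packaging ATPase, family-B DNA polymerase (PolB), late transcription
factor VLTF3, major capsid protein (MCP), and superfamily II helicase
(SFII). `screen_contigs()` keeps contigs with at least `min_markers`
distinct markers (default 1); `gvmag_quality()` applies the stricter
genome-quality bar of at least four of the five markers. Marker names are
matched case-insensitively, since annotation tools disagree on
capitalization; hits outside the five-token vocabulary are an input error
rather than being silently dropped.

Species-level taxonomy from marker hits is genuinely under-determined by
convention — best-hit, last-common-ancestor and voting schemes all appear
in practice. We chose a deterministic, order-independent rule: discard
hits below `min_identity` (default 30% amino-acid identity, a conservative
twilight-zone cut-off), then majority vote across the remaining hits'
reference taxa, breaking ties by higher mean identity (and residual ties
lexicographically). Contigs with no qualifying hit are `NOVEL`. The rule
is monotone in the threshold: raising `min_identity` can only move contigs
toward `NOVEL`, never the reverse.

## Profiles

`depth_time_mean()` averages any per-sample quantity by nominal depth
through time, reporting mean ± SE (sample sd with the n−1 denominator,
divided by √n; `NA` when a depth has a single sample). Taxon profiles sum
member-contig relative abundances; with `identified_only = TRUE` the
`NOVEL` bin is dropped and columns are renormalized among identified
species, the convention used when displaying identifiable-species
composition. AMG profiles report the *abundance-weighted* proportion of
viruses carrying a gene category — the summed relative abundance of
carriers — rather than a carrier count fraction, so depths of unequal
richness are comparable; a count-based variant is available behind a
flag.

## Vertical transport and depth of origin

A contig is *transported* iff it has non-zero Q2Q3 coverage in at least
one sediment-trap sample. "Depth of origin" is not a measured quantity, so
the package operationalizes it and reports both defensible readings: the
planktonic depth at which the contig's time-averaged relative abundance
peaks (ties to the shallower depth), and the shallowest depth of any
planktonic detection. Trap samples never contribute to origin — origin is
a water-column concept — and contigs detected only in the trap get `NA`
origin and a `trap_only` flag, a pattern real trap-dominant taxa show.

Export pulses: a trap sample is a *summer export pulse* iff its
particulate carbon flux is at least 150% of the long-term baseline mean.
The boundary is inclusive and the rule is a ratio, hence invariant to a
common change of units.

## Flux correlation

Per-contig *gene significance* is the Pearson correlation r between a
contig's trap relative-abundance profile and the flux series, with a
two-sided p-value from `t = r√(n−2)/√(1−r²)` on n−2 degrees of freedom.
Constant profiles (typically all-zero: non-transported contigs) carry no
information, are flagged, and are excluded from selection. The correlation
input is per-sample sum-to-one normalized trap coverage — the same
relative-abundance convention used for the trap-block displays.

Selection keeps contigs with r > 0 and p < α (default .05), uncorrected.
This matches the stated per-population criterion (raw P < .05, positive
only); Benjamini–Hochberg adjustment is available behind a flag for users
who prefer a controlled false-discovery rate. An optional *module gate*
reproduces the weighted-correlation-network framing: unsigned adjacency
`|cor|^β` (β = 6), topological-overlap similarity, average-linkage
clustering on 1−TOM with a static cut at height 0.25, modules of ≥ 5
contigs, eigengenes as first principal components of standardized member
profiles (sign-oriented toward the members), and gating on modules whose
eigengene is positively and significantly flux-correlated. These network
parameters are community defaults, all exposed in the configuration;
power auto-selection and dynamic tree cutting are deliberately out of
scope. Module labels are deterministic (numbered by size, ties by smallest
member id), so results do not depend on input row order.

## The synthetic generator

`simulate_dataset()` emulates the study design the analysis assumes, and
its defaults are those conditions: 15 planktonic depths from 5 to 4000 m
sampled monthly over six years, 63 sediment-trap samples at 4000 m over
three years, and a 1496-contig catalog of which 31.3% are planted as
transported and 6.75% additionally as flux-coupled. The generative model:

* each contig gets a **log10-depth Gaussian niche** (mean uniform over the
  log-depth span, width 0.15–0.5 log units) — reproducing surface,
  deep-chlorophyll-maximum and mesopelagic peak structure;
* coverage noise is **multiplicative lognormal** (σ = 0.3 by default):
  coverage is positive and heavy-tailed, and the niche acts on the scale,
  not additively. Planktonic coverage below a detection limit (0.05×) is
  truncated to zero, creating realistic sparsity;
* the **flux series** is a seasonal sinusoid around a baseline of
  1 mg C m⁻² d⁻¹ (the long-term mean at abyssal depth is of order
  1 mg C m⁻² d⁻¹) with designated summer months amplified to ≥ 1.5×
  baseline, guaranteeing both pulse and non-pulse samples exist;
* **flux-coupled contigs'** trap abundance is
  `base × max(1 + coupling_effect · z(flux), 0.05) × noise` with z the
  standardized flux. The floor keeps the linear response positive so
  coupled contigs remain detectable in every trap sample (a contig cannot
  have negative coverage); other transported contigs get flux-independent
  `base × noise`;
* one master seed drives **per-sample derived random streams**, so
  enlarging the sample grid appends columns without perturbing existing
  ones, and identical configurations are byte-identical on disk.

Per-sample sequencing depth variation is not reported for the real survey,
so the generator exposes it only through the read-count metadata (total
reads lognormal around 4×10⁶ with the mapped fraction ~0.5%, peaking near
150–225 m).

Per-base depth files are materialized on demand (`write_depth_files()`) as
Poisson draws around each contig's coverage level; the realized in-memory
Q2Q3 values are returned so tests can verify that parsing the files
reproduces them exactly. Because the per-base representation scales with
contigs × samples × length, statistical experiments (null calibration,
planted-signal recovery) run on the in-memory coverage matrix, and the
file-level round trip is exercised on small bundles (tens of contigs,
hundreds of bp).

**What passing tests do and do not show.** The generator captures
depth-niche structure, compositionality, lognormal noise, planted
transport and linear flux coupling. It does not simulate reads, mapping
ambiguity, strain microdiversity, uneven within-contig coverage beyond
Poisson sampling, or temporal autocorrelation of the planktonic community.
Calibration and recovery results therefore validate the pipeline's
statistics under its stated model, not the ecological conclusions one
would draw from real data. One emergent — and realistic — feature worth
noting: under sum-to-one normalization, flux-coupled contigs inflate trap
column totals during pulses, pushing non-coupled contigs' relative
abundance *negatively* with flux; the positive-only selection rule then
yields conservative false-positive behaviour on compositional data.

## Numerical choices and degenerate inputs

* Q2Q3 of an empty vector is an error; L < 4 uses the plain mean.
* All-zero sample columns survive both normalizations unchanged.
* `|r|` is clamped to 1 before the t transform; exact collinearity gets
  p = 0 rather than NaN.
* Fewer than 4 flux-paired trap samples is an input error (the t-test is
  meaningless below that).
* Ties in depth-of-origin go to the shallower depth; ties in taxonomy
  votes go to higher mean identity, then lexicographic order.
* Problem sizes in the test suite were chosen so the full suite runs in
  well under a minute of compute: 1000-vector oracle sweeps for the
  coverage statistic, 1000-contig × 63-trap simulations for calibration
  and recovery, 10⁴ permutations for the p-value cross-check, and
  ~30–40-contig bundles for file-level end-to-end runs.

## Limitations

* Taxonomy is a voting heuristic over marker hits; it is not a phylogeny,
  and the identity threshold is a tunable convention.
* The module stage implements the standard unsigned TOM workflow but not
  soft-threshold scanning or dynamic tree cutting; with few trap samples,
  module detection is noisy and the default selection path is therefore
  gene-significance only.
* Gene-significance p-values assume independent samples; trap time series
  have temporal structure that the t-test ignores (the permutation
  cross-check in the test suite quantifies the analytic approximation, not
  the autocorrelation question).
* Compositional (sum-to-one) input makes correlations between contigs
  non-independent; the positive-only rule is conservative under this
  coupling, as noted above.
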