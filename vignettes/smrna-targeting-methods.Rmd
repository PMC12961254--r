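---
title: "Methods: annotation-free small-RNA targeting analysis in allopolyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation-free small-RNA targeting analysis in allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrnaploid)
```

## The problem

Allopolyploid plants carry two divergent parental subgenomes in one nucleus.
Small RNAs (smRNAs, here 20-24 nt) mediate much of the regulatory and
epigenetic reconciliation between those subgenomes, in particular the
silencing of transposable elements (TEs) by 24 nt heterochromatic siRNAs.
A recurring question is whether a polyploid's smRNA landscape is *additive*
(intermediate between its diploid parents), *dominant* (matching one parent),
or *transgressive* (outside the parental range) — and whether two sibling
allopolyploids, formed independently from the same parental species pair,
converge on the same answer.

Because smRNA loci are poorly captured by gene annotation, the analysis is
annotation-free: "target regions" are discovered directly from read coverage,
quantified per sample, tested for differential targeting (DT) between
species groups, and only then interpreted against genes, promoters and TEs.

`smrnaploid` implements this entire workflow as composable, pipe-friendly
functions over plain tibbles, together with a seed-deterministic synthetic
data generator so that every stage can be validated against a known ground
truth without any external data.

## The procedure

1. **Region discovery** (`window_read_counts()`, `retain_and_merge()`).
   Each chromosome is tiled with non-overlapping 100 bp windows. A window is
   retained when at least one sample has >= 10 reads overlapping it; a read
   straddling a boundary counts in both windows (coverage semantics).
   Immediately adjacent retained windows are merged into target regions.
   Retention uses raw read counts, never multi-mapper weights, and the
   threshold is applied per window before merging, never re-applied after.

2. **Quantification** (`count_regions()`). Each alignment record of a
   selected read length overlapping a region (>= 1 bp) contributes
   `1/n_hits` to that region's count for its sample, where `n_hits` is the
   read's total number of reported alignments. This fractional assignment
   keeps multi-mapping reads (abundant for TE-derived siRNAs) without double
   counting: the weight of one read always sums to 1 across its records.
   Counts are therefore real-valued.

3. **Filtering and normalization** (`filter_regions()`, `tmm_factors()`).
   Regions are kept when CPM >= 1 in at least
   `max(2, ceiling(0.25 * n_group))` samples of at least one group
   participating in the analysis. Filtering is applied per contrast, so each
   comparison has its own retained-region universe. Library composition is
   normalized with weighted trimmed mean of M-values (TMM): reference sample
   by upper-quartile CPM closest to the mean, 30%/5% two-sided trims on M
   and A, inverse-variance weights, factors rescaled to geometric mean 1.

4. **Differential targeting** (`estimate_dispersion()`, `nb_test()`,
   `bh_adjust()`, `call_dt()`). Counts are modelled as negative binomial
   with effective library sizes (raw size x TMM factor) as offsets. A common
   dispersion `phi` (variance `m + phi m^2`) is estimated by maximizing the
   Cox-Reid adjusted profile likelihood over `[1e-6, 10]`; per-region
   moderated (tagwise) estimates are optional. Each region is then tested by
   a 1-df likelihood-ratio test of separate group means against a pooled
   mean, at fixed dispersion. P-values are Benjamini-Hochberg corrected and
   a region is DT when FDR < 0.05 (strict).

5. **Interaction classification** (`classify_interactions()`). For each
   polyploid, the two tests against its parents are combined: both
   significant with opposite log fold changes -> additive; both significant,
   both positive/negative -> transgressive up/down; exactly one significant
   -> dominance toward the parent the polyploid does *not* differ from;
   neither -> no change. The eight significance/sign combinations cover the
   six categories exactly (a property test enumerates them).

6. **Sharing between sibling polyploids** (`shared_dt_test()`). Whether the
   two polyploids' DT sets overlap more than expected is an exact upper-tail
   hypergeometric test over the universe of regions tested in both analyses.

7. **Summaries** (`per_length_cpm_compare()`, `feature_mapping_proportions()`,
   `mds_coordinates()`, `classify_context()`). Per-length read abundances
   are compared by two-sided Welch t-tests; alignment weight is apportioned
   to exon/TE/other contexts (multi-label reads split their weight equally);
   samples are ordinated by classical MDS on leading-log-fold-change
   distances; regions are labelled promoter/exon/intron/TE/intergenic.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `window_size` | 100 | bp | standard smRNA coverage resolution; regions are unions of windows |
| `min_reads` | 10 | reads | retention floor; guards against singleton noise |
| `promoter_len` | 1000 | bp | operational promoter: window upstream of the gene start |
| `cpm_min`, `group_frac`, `min_samples` | 1, 0.25, 2 | CPM, -, samples | expression filter before testing |
| `alpha` | 0.05 | FDR | strict threshold for DT calls |
| `trim_m`, `trim_a` | 0.30, 0.05 | fraction | classical TMM trim settings |
| `prior_count` | 0.5 | CPM-scale | keeps log fold changes finite |
| length sets | 20-24, 20-23, 24 | nt | genic analysis pools all lengths; TE analyses separate 24 nt het-siRNAs from shorter classes |

## Coordinate and orientation conventions

Internal coordinates are 0-based half-open (BED convention); GFF3 readers and
writers convert at the boundary (1-based closed), so interval arithmetic never
handles off-by-one cases. Overlap means >= 1 shared bp, matching the default
of fractional feature counting. Promoters are strand-aware: for a `-` strand
gene the upstream window lies at higher genomic coordinates; windows are
clipped at chromosome bounds, and features with strand `.` are treated as `+`
with a warning. Log fold changes are oriented `log2(first role / second
role)`; in interaction calls that is always polyploid over diploid.

## The synthetic-data generator

`sim_config()` encodes the study design the package targets:

- four species groups with unequal replicates — 4 maternal diploids, 4
  paternal diploids, 9 and 12 individuals of the two sibling allotetraploids;
- log-normal library-size variation (CV 0.4 by default);
- negative-binomial counts (`phi` = 0.05 by default, Poisson at 0) around
  planted per-class group means with |log2 FC| = 1.5 between differing
  groups: null regions equal everywhere; additive regions separate the
  parents and put both polyploids at the mid-parent arithmetic mean;
  dominance pins both polyploids to one parent; transgressive regions move
  both polyploids above/below equal parents;
- a 20-24 nt read-length mixture with modes at 21-22 nt and 24 nt, and
  preferential placement of 24 nt reads in TE regions (a 24 nt draw landing
  in a non-TE region is resampled to 20-23 nt with probability
  `te_frac_24nt` = 0.7 — a free knob, as no quantitative placement fraction
  is available);
- multi-mapping reads: a 5% fraction of reads is duplicated to
  `k = 2 + Geometric(0.5)` locations (capped at 100 reported hits), with the
  extra hits dropped into random TE intervals; every record of such a read
  carries `n_hits = k`, so its total fractional weight remains 1. Most real
  multi-mappers have few hits, hence the decaying distribution.

The desk-scale genome defaults to 2 chromosomes x 200 kb carrying 60 genes,
80 TEs and 60 intergenic slots — 200 planted target regions with a baseline
expected count of 2^6 per region and ~40,000 reads per library. Class
probabilities default to 40% null and 12% for each of the five non-null
classes.

What the generator does **not** emulate: nucleotide sequences, mismatches and
mapping ambiguity (alignments are abstract intervals with an `n_hits` field),
homeolog-specific mapping bias toward one reference subgenome, miRNA hairpin
structure, spatial autocorrelation of TE silencing, or between-sample batch
effects. Passing tests therefore demonstrate that the statistical machinery
recovers known signals under its own model assumptions — not that those
assumptions hold for any particular real library.

## Numerical choices

- **Dispersion.** The common dispersion maximizes the Cox-Reid *adjusted*
  profile likelihood rather than the raw profile likelihood: profiling out
  two mean parameters per region at 8-25 samples biases raw maximum
  likelihood downward and would make the LRT liberal. The adjustment
  subtracts half the log observed information of each group's log-rate.
  The 1-D search runs on the log scale over `[1e-6, 10]` (tolerance 1e-4);
  a solution at the lower boundary is reported as `phi = 0` (Poisson).
- **Group-mean fits.** Per-region group rates are fitted by a damped Newton
  iteration on the log rate, vectorized across regions (steps capped at 4
  log units, convergence at 1e-10); all-zero groups short-circuit to rate 0.
- **Fractional counts.** The NB likelihood is evaluated on counts rounded to
  the nearest integer at test time; stored counts remain unrounded. This is
  the simplest defensible likelihood treatment of fractional multi-mapper
  counts and is recorded as a deliberate deviation from a weighted
  likelihood.
- **Ties and degenerate inputs.** Region IDs are assigned in (chrom, start)
  order and writing unsorted regions is an error, so IDs are reproducible.
  A record touching two adjacent regions (impossible for merged regions,
  possible for user-supplied ones) is assigned once, to the larger overlap,
  first on ties. Welch comparisons with zero variance in both groups return
  p = 1 for equal means and a flagged p = 0 otherwise. A significant
  contrast with exactly zero log fold change cannot be oriented and yields
  an `ambiguous` interaction call rather than a category. MDS axis signs
  are fixed by making each axis's largest-magnitude coordinate positive.
- **Hypergeometric test.** `P(X >= k)` is computed through the distribution
  function's log-space implementation; `k = 0` returns exactly 1.

## Open design points and how they were resolved

- The filter sentence "25% of samples within a group and a minimum of two
  samples overall" is read as `max(2, ceiling(0.25 n_g))` within at least one
  group participating in the contrast; per-contrast filtering matches the
  observation that different comparisons retain different region totals.
- Whether boundary-straddling reads count in one or both windows is
  tool-dependent; both-windows (coverage semantics) was chosen for
  retention, while quantification assigns each record once — the two stages
  deliberately use different semantics, mirroring the two different tools
  they emulate.
- Dominance is named for the parent the polyploid *matches* (the
  non-significant contrast).
- The overlap-test universe is the set of regions tested in both polyploid
  analyses; per-category tests reuse the same universe rather than
  conditioning on the category.
- The MDS distance uses the top 500 leading log fold changes per sample pair
  (configurable), the common practice for count-based sample ordination; on
  datasets with fewer regions, all are used with a note.
- The quasi-likelihood F-test machinery of the established count-model
  toolchain is intentionally replaced by the NB LRT with Cox-Reid common
  dispersion described above; the contract tested is calibration and
  ranking, not bit-equality with any particular implementation, and the
  classification layer consumes only (logFC, FDR).

## What the test suite established

The suite (see `tests/testthat/`) validates each stage against an independent
oracle: region discovery against a per-base brute-force labeller on 200
random micro-genomes (<= 5 kb); counting against the generator's matrix
(exact integer equality over 20 seeds at `multimap_prob = 0`); BH against a
literal step-up implementation on 1000 random p-vectors; the hypergeometric
test against full enumeration for all N <= 12; TMM against a hand-worked
6-region example and an independent reference implementation; NB type-I
error and dispersion recovery by Monte Carlo (2000 regions; n = 4+4 null
calibration, n = 6+6 recovery at phi in {0.05, 0.1, 0.2}); and the full
pipeline on the packaged design (4/4/9/12 replicates, effect 1.5 log2,
phi = 0.05, seed 1), where planted-category recovery and the empirical FDR
of DT calls are checked and the seed-1 confusion matrix is frozen as a
regression fixture. Problem sizes were chosen so the whole suite runs in a
few minutes on one CPU; they are the package's validation conditions, not
statements about real data.

## Known limitations

- The NB LRT with common dispersion is slightly anti-conservative for very
  small groups if the dispersion is badly misestimated; the packaged design
  estimates it from hundreds of regions, where recovery is within a few
  percent.
- Additive regions are the hardest class: the polyploid-versus-nearer-parent
  effect is only `log2(mid-parent / larger parent)` (about 0.56 at a planted
  1.5), so under-powered additive regions are typically called dominant.
  Misclassification is confined to such adjacent categories.
- Fractional counts are rounded for the likelihood; at very low coverage
  this loses sub-read information.
- The GFF3 reader resolves exon `Parent` attributes through at most one
  intermediate feature (e.g. mRNA) and keeps only ID/Parent/class
  attributes.
- Region discovery assumes alignments fit in memory as a tibble; the
  packaged designs are desk-scale by construction.

## A minimal run

```{r, eval = FALSE}
library(smrnaploid)

cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, "smrnaploid_out")

res$regions                  # discovered target regions
glance(res$tests[["genic.polyA_vs_maternal"]])
res$interactions |> dplyr::count(length_set, polyploid, category)
res$overlaps                 # hypergeometric sharing tests
autoplot(res$tests[["genic.polyA_vs_maternal"]])   # MA plot
autoplot(res$mds, samples = res$samples)           # sample ordination
```
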