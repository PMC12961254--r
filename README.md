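# smrnaploid

Annotation-free small-RNA "targeting" analysis for allopolyploids and their
diploid progenitors.

## The problem

When two diploid plant species hybridize and double their genomes, the
resulting allopolyploid must reconcile two divergent regulatory systems.
Small RNAs (smRNAs, 20–24 nt) are central to that reconciliation — in
particular 24 nt heterochromatic siRNAs that silence transposable elements
(TEs). For each genomic region one asks whether the polyploid's smRNA
abundance is **additive** (mid-parent), **dominant** (matching one parent)
or **transgressive** (outside the parental range), and whether two sibling
allopolyploids formed independently from the same parents converge on the
same pattern.

Because most smRNA loci fall outside gene annotation, the analysis is
annotation-free: target regions are discovered directly from read coverage
and only afterwards interpreted against genes, promoters and TEs.
`smrnaploid` is aimed at analysts of plant smRNA-seq data who want this
workflow as tested, composable R functions — and at methodologists who want
a ground-truth simulator to probe it.

## Method at a glance

- **Discovery**: non-overlapping 100 bp windows; keep windows with ≥ 10
  reads in at least one sample; merge immediately adjacent kept windows into
  *target regions*.
- **Quantification**: each alignment of a read with `n_hits` reported
  locations adds `1/n_hits` to the region it overlaps (fractional
  multi-mapper counting).
- **Differential targeting (DT)**: filter regions at CPM ≥ 1 in
  `max(2, ⌈0.25 n_g⌉)` samples of a group; TMM normalization; per-region
  negative-binomial likelihood-ratio test with a Cox–Reid common dispersion
  φ (variance `m + φm²`), offsets = log effective library sizes;
  Benjamini–Hochberg correction; DT iff FDR < 0.05.
- **Interaction classes**, per polyploid, from its two parent contrasts
  (logFC oriented polyploid/diploid): both significant with opposite signs →
  additive; both significant, same sign → transgressive (up/down); exactly
  one significant → dominant toward the *matching* (non-significant) parent;
  neither → no change.
- **Sharing**: exact upper-tail hypergeometric test,
  `p = P(X ≥ k)`, `X ~ Hypergeom(N, m, n)`, for the DT-set overlap of the
  two polyploids over the jointly tested universe.
- **Summaries**: per-length Welch t-tests of read-class CPM, exon/TE/other
  mapping proportions, classical MDS of samples on leading-logFC distances,
  promoter/exon/intron/TE/intergenic context labels (promoter = 1000 bp
  strand-aware upstream window).

The package also ships a seed-deterministic generator
(`sim_config()`/`simulate_dataset()`) that emulates the target study design:
groups of 4/4/9/12 replicates, log-normal library sizes, NB counts with
planted effect classes at |log2FC| = 1.5, a 21–22/24 nt length mixture, TE
bias of 24 nt reads, and capped multi-mapping.

## Worked example

```r
library(smrnaploid)
library(dplyr)

cfg <- pipeline_config(seed = 1)          # packaged synthetic study design
res <- run_pipeline(cfg, "smrnaploid_out", quiet = TRUE)

res$regions
#> # A tibble: 206 × 4
#>   region_id chrom start   end
#>   <chr>     <chr> <int> <int>
#> 1 reg1      chr1    700   900
#> 2 reg2      chr1   2800  3100
#> 3 reg3      chr1   4400  4800
#> # ℹ 203 more rows

glance(res$tests[["genic.polyA_vs_maternal"]])
#> # A tibble: 1 × 5
#>   contrast       n_regions  n_dt alpha    phi
#>   <chr>              <int> <int> <dbl>  <dbl>
#> 1 polyA:maternal       206    91  0.05 0.0515

res$interactions |> filter(length_set == "genic") |> count(polyploid, category)
#> # A tibble: 12 × 3
#>    polyploid category               n
#>  1 polyA     additive              17
#>  2 polyA     dominant_maternal     29
#>  3 polyA     dominant_paternal     32
#>  4 polyA     no_change             86
#>  5 polyA     transgressive_down    19
#>  6 polyA     transgressive_up      23
#>  ... (polyB rows follow)

res$overlaps |> filter(category == "all_dt")
#> # A tibble: 3 × 8
#>   length_set category     N     m     n     k expected  p_value
#> 1 genic      all_dt     206   120   120   118     69.9 7.56e-53
#> 2 te_short   all_dt     206   121   121   119     71.1 1.06e-52
#> 3 te_24      all_dt     206   116   119   114     67.0 6.16e-49
```

Reading this: 206 target regions were discovered from ~460k simulated
alignment records; 91 of them are DT between polyploid A and its maternal
parent at FDR < 0.05 with an estimated common dispersion of 0.0515 (the
generator planted 0.05); both sibling polyploids share almost all of their
DT regions (k = 118 of m = n = 120 against ~70 expected by chance), exactly
the convergence signal the generator plants by giving both polyploids the
same interaction classes. Against the known truth, 92.7% of DT-called
non-null regions received their planted category
(`res$recovery$accuracy`).

Plots: `autoplot(res$tests[["genic.polyA_vs_maternal"]])` draws the MA plot
with ±1.5 logFC guides; `autoplot(res$mds, samples = res$samples)` the
sample ordination; `plot_interaction_counts(res$interactions)` the category
bars; `plot_length_profile(res$alignments, res$samples)` the bimodal
read-length profile.

A thin CLI over the same functions is installed at
`inst/cli/smrnaploid.R` (`simulate` and `run-all` subcommands).

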