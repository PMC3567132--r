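---
title: "Mapping the genetic architecture of chromatin accessibility in a yeast cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the genetic architecture of chromatin accessibility in a yeast cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

faireqtl treats chromatin accessibility as a quantitative trait. In a cross
between two yeast strains (BY and RM), each haploid segregant inherits a
mosaic of the two parental genomes; FAIRE-seq read density over an open
chromatin region (OCR) then varies across segregants both because the local
DNA sequence differs (cis) and because distant regulators differ (trans).
The package implements the full analysis chain — peak consolidation,
normalization, sequence-based genotyping of each OCR, cis/trans variance
decomposition, permutation-calibrated QTL mapping, hotspot detection and
genomic-context statistics — together with a synthetic cross generator that
makes every stage testable against a known ground truth.

```{r load}
library(faireqtl)
library(dplyr)
```

## The synthetic cross

`simulate_cross()` draws independent haploid recombinants: the first marker
of each chromosome is BY with probability 1/2 and the allele switches
between adjacent markers with the Haldane (no-interference) probability
$r(d) = (1 - e^{-2d})/2$ at genetic distance $d$ Morgans. Haldane is the
simplest standard map function; only the linkage structure matters
downstream, not interference. Genotypes are coded 0 = RM, 1 = BY, with 0.5
reserved for missing calls.

`simulate_dataset()` generates counts from

$$\mathbb{E}[c_{is}] = \frac{L_s}{10^6}\, \mathrm{size}_i(\mathrm{kb})\,
  2^{\,\beta_i + a_i g_{is} + \sum_m b_{m i}\, g_{ms} + \varepsilon_{is}},
  \qquad c_{is} \sim \mathrm{Poisson},$$

where $\beta_i$ is the OCR's baseline log2 density, $a_i$ a cis effect
driven by the genotype at the OCR's own locus, $b_{mi}$ trans effects driven
by the genotype at a source (hotspot) marker, and
$\varepsilon_{is} \sim N(0, \sigma)$ strain-level noise. Poisson counts keep
the null calibration analytic; real FAIRE libraries are likely somewhat
overdispersed, so passing tests demonstrate correctness of the machinery,
not that Poisson is the right noise law for any particular dataset.

Default scale and parameters, chosen once: 16 chromosomes at one tenth of
the yeast genome's physical length, 96 segregants, ~1,500 markers at
0.35 cM/kb, ~2,000 OCRs of 100–500 bp, baseline log2 density 6 (about 64
reads/kb per million, so a 300 bp OCR in a 5 M-read library draws ~100
reads and Poisson noise on the log2 scale is small), baseline SD 0.6 and
noise SD 0.8. The last two are deliberately coupled:
$\sqrt{0.6^2 + 0.8^2} = 1$, so each strain's column of log2 densities has SD
close to 1 and the final per-strain standardization roughly preserves scale
— an injected cis effect of +1 on the log2 scale lands as a BY-vs-RM group
mean difference of about 1 in standardized units. SNP profiles place two
biallelic sites uniformly inside each cis-effect OCR (matching the typical
density seen in real merged peaks) with Poisson read depth and a per-read
error rate that flips alleles.

What the generator does not emulate: read-level sequences, alignment
artifacts, copy-number differences, batch effects, and overdispersion
beyond Poisson. Missing genotypes (0.5) arise downstream from shallow SNP
coverage, not from an injected missingness process.

```{r simulate}
layout <- simulate_genome_layout(n_chrom = 4, seed = 11)
geno   <- simulate_cross(layout, default_marker_positions(layout, 200),
                         n_strains = 96, seed = 12)
ocrs   <- simulate_ocrs(layout, n_ocrs = 400, seed = 13)
truth  <- cross_truth(ocrs, geno, n_cis = 20, cis_effect = 1.2,
                      n_hotspots = 1, targets_per_hotspot = 40, seed = 14)
ds     <- simulate_dataset(layout, geno, ocrs, truth, seed = 15)
```

## Peak consolidation and normalization

Per-strain peak calls are unified by `extend_and_merge_peaks()`: peaks
shorter than 15 bp are extended symmetrically to exactly 15 bp (an odd
deficit puts the extra base rightward, a deterministic tie-break), clipped
at chromosome bounds, and the union is merged. Overlapping *and* bookended
intervals are joined — the semantics of `bedtools merge` at distance 0 and
of a per-base boolean union; two peaks that touch at a boundary describe one
contiguous open region.

`quantify_and_normalize()` assigns each read to the OCR containing its
midpoint (a read is never counted twice), then applies the chain

1. density = count / (OCR size in kb × library size in millions) — reads
   per kb per million, the natural size-and-depth normalization;
2. log2, with zero densities mapped to $-\infty$;
3. ceiling: all negative values set to 0 (densities below 1 read/kb/M are
   treated as background);
4. per-strain standardization to zero mean, unit variance.

Because every strain column is standardized at the end, any positive
rescaling of the density formula gives the same matrix up to the ceiling
step; the reads-per-kb-per-million constant matters only for where the
ceiling bites, and the defaults keep typical densities well above it. No
pseudocount is used: a zero count is ceiled to 0 like any sub-background
density.

```{r normalize}
dens <- normalize_density(ds$counts, ocrs, ds$library_sizes)
round(colMeans(as.matrix(dens[, strain_cols(dens)][1:3])), 12)
```

## Genotyping OCRs from their SNP profiles

SNP calls are filtered (`filter_snp_calls()`): depth < 5 discarded;
heterogeneous calls kept as the major allele only when its frequency
exceeds 80%. `genotype_ocrs()` then compares each strain's surviving
alleles with the two parents at sites where the parents disagree —
sites where they agree carry no information. Strict mode demands that every
compared site match one parent; relaxed mode assigns the parent matched at
more than half of the compared sites. Ties, absent coverage, or fewer than
`min_informative_sites` (default 1) compared sites yield a missing call.
Uncovered sites are ignored rather than counted as mismatches: FAIRE depth
is uneven, and absence of a call is not evidence of mismatch. A consequence
worth noting: with an error-free channel, strict genotyping can abstain
(depth 0 at every informative site) but can never assign the wrong parent,
so accuracy is measured over assigned calls.

## Cis and trans variation

For each OCR with at least 10 strains in each parental group
(`min_per_group`), `estimate_variation()` computes

- **trans-variation**: the within-group standard deviations of standardized
  density, one per parental group — variation among strains that share the
  local sequence, hence attributable to distant factors; and
- **cis significance**: a two-sample t test on the BY-vs-RM group means —
  a shift attributable to the local sequence itself.

Welch's unequal-variance form is the default because group sizes and
variances are rarely balanced; the pooled form is available via
`var_equal = TRUE`. When a single trans-variation number is needed (for
positional profiles and the explained-variation fraction) we use the mean
of the two group SDs. Degenerate inputs are handled explicitly: two
constant groups with equal means give $t = 0$, $p = 1$.

## QTL mapping with a permutation FDR

`map_qtl()` scores every (marker, trait) pair by the Pearson correlation of
the marker's genotype profile (0/0.5/1; missing participates as the numeric
0.5) with the trait vector. The null is built by permuting the strain
labels of the trait matrix as whole sample vectors — columns move together,
so the trait–trait correlation structure is preserved exactly — and the
empirical p uses add-one smoothing,

$$p = \frac{1 + \#\{\text{null } |r| \ge |r_{\mathrm{obs}}|\}}{N_{\mathrm{null}} + 1},$$

so p is never 0. By default the null is pooled across all pairs within each
permutation ($N_{\mathrm{null}} = B \times \#\text{pairs}$), which gives
fine-grained p resolution at $B$ in the hundreds; a pair-specific null
(`null = "pairwise"`, $N_{\mathrm{null}} = B$) and exhaustive enumeration
of all $n!$ orderings (for small $n$) are available, and the exhaustive
pair-specific mode is checked exactly against full enumeration in the test
suite. Benjamini–Hochberg adjustment is applied globally over all pairs,
and associations at $q \le 0.01$ are reported with the sign mapping
$r > 0 \Rightarrow$ BY allele increases the trait.

Markers are first consolidated by `merge_markers()`: scanning left to
right, a raw marker joins the current run while it differs from the run's
*first* member at no more than two strains (0.5 entries excluded from the
comparison); each run contributes its mean profile and covered interval.
Anchoring at the first member keeps the rule deterministic and prevents
run drift.

`classify_associations()` labels a pair cis when marker region and trait
interval are on the same chromosome and at most 100 kb apart (overlap
counts as distance 0), and reports parametric concordance: the fraction of
associations whose single-predictor regression p (an `lm()` fit when the
trait matrix is supplied, else the exact $t = r\sqrt{(n-2)/(1-r^2)}$
identity) falls below given cutoffs. Expression QTL mapping is the same
machinery applied to an expression matrix, and `dual_qtl_overlap()`
compares the two marker sets; "same locus" for dual QTLs defaults to trait
intervals within 100 kb, mirroring the cis-distance convention.

## Regulatory loci and hotspots

`build_regulatory_loci()` combines markers that lie less than 10 kb apart
and share at least one target trait, applied transitively (A–B share one
trait, B–C another: one locus). The transitive reading is a design choice
the merged-locus counts of real data support; the non-transitive
alternative would leave chains fragmented. A locus is a hotspot when its
distinct-target count exceeds 65. `annotate_loci()` attaches every
regulator gene within 10 kb of the locus and then merges adjacent loci
sharing a regulator — a deterministic automation of what is otherwise a
manual curation step. `regulatory_architecture()` reports per-trait locus
counts, per-locus target counts, the explained-trans fraction (the sum of
trans-variation over trans-associated OCRs divided by the sum over all
eligible OCRs), per-trait $R^2$ from regressing the trait on all its
associated locus profiles (skipped when predictors outnumber strains), and
an annotated-vs-unannotated comparison of hotspot target counts.

## Genomic context

`gene_density()` counts genes within 50 kb of the peak boundaries and
divides by peak size (genes/kb), flagging the top 10% and bottom 5%.
`telomere_profile()` measures each OCR's distance to the nearer chromosome
end, averages a statistic in 2 kb windows stepped every 1 kb, and compares
OCRs within 10 kb of an end against the rest. `recombination_hotness()`
averages track scores within 5 kb of the OCR (nearest locus as fallback —
the assignment window is a package choice; the underlying data are sparse
microarray loci) and applies a one-sample t test against zero, two-sided by
default with the alternative configurable. `poly_at_scan()` reports maximal
runs of A/T of length ≥ 5; mixed A/T runs count by default since a
nucleosome-excluding tract need not be a homopolymer, and a strict
homopolymer mode is provided because the defining threshold ("five
consecutive A/Ts") is ambiguous on this point.
`motif_polymorphism_enrichment()` builds the 2×2 table of
motif-polymorphic × cis-associated OCRs (half-open intervals: a SNP at a
motif start is inside, at the end coordinate outside) and returns the
sample odds ratio $ad/bc$ with a two-sided Fisher exact p; a zero margin is
flagged degenerate with $p = 1$.

## Numerical and design notes

- Problem sizes in the test suite are desk-scale by design: 4–16
  chromosomes at 1/10 genome length, 96 strains, hundreds to 2,000 OCRs,
  permutation counts of 100–500. These keep every property check fast while
  preserving the statistical regime (marker linkage, group sizes near
  48/48, genome-wide multiplicity).
- The per-strain standardization couples traits: a trans hotspot that
  shifts a large *fraction* of all OCRs partially absorbs its own effect
  into the strain means. At realistic scale (80 targets among thousands of
  OCRs) the absorption is a few percent; generators for small toy panels
  should keep hotspot targets a small fraction of traits.
- Detection power at the study's own conditions is a hard ceiling, not a
  tuning issue: a trans effect of 1 SD against 1 SD of noise caps the
  point-biserial correlation near 0.45 at $n = 96$, while a genome-wide
  BH threshold at $q \le 0.01$ sits near $|r| \approx 0.43$, so roughly
  half of such targets are recovered in any single dataset. Hotspots of
  that effect size are reliably *flagged* only when their true target
  count is well above the 65-target threshold; the architecture report
  therefore exposes the measured target counts rather than only the flag.
- All randomness flows through explicit integer seeds; generator functions
  save and restore the global RNG state, so calls are reproducible and do
  not perturb the caller's random stream.

## Limitations

The package analyzes haploid two-parent designs only (no heterozygotes, no
interval mapping or hidden-Markov genotype imputation, no epistasis). SNP
calling, peak calling, alignment and motif discovery are upstream inputs.
Statistical results on synthetic data validate the implementation under the
generator's assumptions; applying the pipeline to real FAIRE-seq data
additionally requires the usual scrutiny of library quality, duplicate
handling and batch structure, which are out of scope here.
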