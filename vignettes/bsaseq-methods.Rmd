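---
title: "Mapping a major plant-height QTL from extreme bulks: methods and design"
author: "bsaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a major plant-height QTL from extreme bulks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaseq)
```

## The problem

Bulked segregant analysis by sequencing (BSA-Seq) maps a quantitative trait
locus (QTL) without genotyping every individual of a mapping population.
From an F2 cross between two inbred parents — here modelled on a cross
between a tall and a dwarf foxtail millet line — the individuals with the
most extreme phenotypes are pooled into two bulks (a "high" and a "low"
bulk) and each pool is sequenced as one sample. Away from any
trait-associated locus, both bulks are random draws from the F2 and carry
each parental allele at a frequency near 1/2. Near a QTL, selection on the
phenotype drags the allele frequencies of the two bulks apart, and the
contrast between them localises the locus.

`bsaseq` implements this analysis end to end — marker selection, the
SNP-index and $\Delta$(SNP-index) statistics, sliding-window smoothing,
a simulated null for significance thresholds, candidate-region calling,
codon-level classification of region variants, a compact count-based
differential-expression (DE) test for the accompanying RNA-Seq contrast of
the two parents, and the intersection of the two evidence layers — plus a
seeded simulator that generates every input, so the whole pipeline is
verifiable at desk scale.

## The SNP-index model

At a biallelic marker where the parents are homozygous for different
alleles, the **SNP-index** of a bulk is the fraction of its reads carrying
the dwarf-parent allele:

$$\mathrm{index}_b = \frac{\text{reads carrying the dwarf-parent allele}}{\text{total reads of bulk } b},$$

so a bulk identical to the tall reference parent has index 0 and a bulk
identical to the dwarf parent has index 1. The index is computed from
allele depths (AD), never from called genotypes, and is missing (not zero)
where a bulk has no reads. The mapping statistic is

$$\Delta(\text{SNP-index}) = \mathrm{index}_{\text{high}} - \mathrm{index}_{\text{low}},$$

which has expectation 0 away from trait loci and deviates toward $\pm 1$
near them; the sign depends on which parent carries the trait-increasing
allele, so inference is two-sided.

Markers are screened before mapping:

* only loci where **both parents are homozygous for different alleles**
  are informative (heterozygous or missing parent calls are dropped);
* a locus is removed when its index is **below 0.3 in both bulks**
  (no allele-frequency signal anywhere), when its depth is **below 7** in
  either bulk, or when its index is **missing** in any bulk.

Two boundary conventions are deliberate. "Below" is strict, so a locus at
exactly 0.3 or exactly depth 7 is retained. And the depth clause applies
per bulk ("either"), because a shallow pool makes its own index unreliable
regardless of the other pool's depth; the laxer reading (drop only when
*both* pools are shallow) is available as `depthRule = "both"`.

## Windows, the null distribution, and regions

Per-marker indices are noisy at ~50x depth, so the profile is smoothed
with a sliding window (default 20 kb, step 2 kb). A window's value is the
unweighted mean over its member markers of the per-bulk index and of the
per-marker $\Delta$; windows with fewer than `minMarkers = 3` markers are
masked rather than reported as zero. Depth weighting is available but not
the default: at pooled depths the marker-to-marker depth variation is
modest and unweighted means keep the statistic's null distribution simple.

### Why the null must include bulk composition

The windowed $\Delta$ under no linkage has two variance components:

1. **bulk-composition sampling** — which 30 individuals ended up in each
   bulk. For a bulk of $n$ individuals the allele-frequency standard
   deviation is $\sqrt{p(1-p)/(2n)} \approx 0.065$ at $p = 1/2$, and this
   component is *shared by all markers of a window* (markers 20 kb apart
   in an F2 are essentially completely linked), so window averaging does
   not reduce it;
2. **read sampling** at each marker, which window averaging reduces by
   $\sqrt{m}$ for $m$ member markers.

At the default design (30-plant bulks, ~50x, ~20 markers/window) the
composition component (sd $\approx 0.09$ for the difference of two bulks)
dominates the windowed read noise (sd $\approx 0.02$) by a factor of four.
A null built by only re-splitting reads between the bulks would therefore
be far too narrow and call a third of the genome significant.
`permutationThreshold()` instead replays both stages for each of its
`nPerm = 1000` replicates: per window, each pseudo-bulk's frequency is
drawn as $\mathrm{Binomial}(2n,\ \bar p_w)/2n$ around the window's pooled
read frequency $\bar p_w$, and reads are then drawn at every member
marker's *observed* depths. This is the standard simulated null for
QTL-seq designs; it needs one extra piece of information, the bulk size
`bulkSize`.

Thresholds are the two-sided 2.5th/97.5th percentiles of the null
(`level = 0.95`), pooled within **window marker-count classes**
(3–5, 6–10, 11–20, >20 markers): window precision varies with marker
density, and a single global threshold would be too wide for dense windows
and too narrow for sparse ones. `level = 1` yields infinite thresholds (no
rejections), the natural limit. Because both the direction of the trait
allele and the sign convention of the index are arbitrary, the test is
two-sided; the sidedness and the null scheme are recorded in the profile's
`metadata()`.

A **candidate region** is a maximal run of overlapping or abutting
significant windows (windowed $\Delta$ strictly outside its threshold
band), spanning from the first merged window's start to the last one's end,
clipped to the chromosome. Regions carry their significant-window count,
peak $\Delta$, and member markers.

## Variant effects

Variants inside candidate regions are classified against gene models at
the codon level, replacing an external annotator. For an SNV in a coding
segment the affected codon is substituted (alleles reverse-complemented on
minus-strand genes) and translated with the standard genetic code:
unchanged amino acid = `synonymous`; changed, neither side a stop =
`non-synonymous`; non-stop to stop = `stop-gain`; stop to non-stop =
`stop-loss` (the stop classes are mutually exclusive with the others by
construction). Inside a gene but outside its CDS is `intronic` (one
gene-body class covering introns and UTRs — the analysis only acts on the
three exonic classes), and outside every gene is `intergenic`. A variant
whose stated reference allele disagrees with the genome sequence raises an
error; silent coordinate bugs are the classic failure mode of effect
annotation, and this check catches them at the first variant. When a gene
has several isoforms the longest CDS is used. The test suite holds the
classifier to 100% agreement with an independent oracle that re-translates
the entire mutant CDS.

## Differential expression

The RNA-Seq arm contrasts the two parents (3 biological replicates each).
Counts are normalised with **median-of-ratios** size factors, expression
is flagged at **FPKM > 1** in at least one sample (reported, but not used
to pre-filter tests), and each gene gets a Wald test on the log2 fold
change under the negative-binomial variance $\mathrm{var} = \mu + \alpha\mu^2$:

* per-gene $\alpha$ by method of moments, pooled across the two groups;
* the per-gene estimate is **moderated toward the across-gene median**
  with `priorDf = 10` pseudo-degrees of freedom, and the statistic is
  referred to a $t$ distribution with $n_1 + n_2 - 2 + \texttt{priorDf}$
  df. With 3 replicates per group a raw moment estimate is so noisy that
  one must either accept an inflated type-I error (normal reference,
  measured ~0.12 at nominal 0.05) or lose essentially all power after FDR
  correction (an honest $t_4$ reference cannot produce small p-values:
  measured power ~8% on 4-fold changes). Moderation resolves the dilemma
  — measured type-I 0.050 and power 0.93 under the calibration settings
  below — and is the same idea DESeq/edgeR/limma rely on, in its simplest
  form. This is the one deliberate extension of an otherwise minimal test;
  there is no outlier handling, no independent filtering, no fold-change
  shrinkage;
* a 0.5 pseudo-count stabilises fold changes of low-count genes, and the
  dispersion is floored at $10^{-8}$;
* BH adjustment across genes; a **DEG** requires $|\log_2 FC| > 1$ and
  $q < 0.05$, both strict, with the tall parent as the control
  (denominator), so "down" means lower expression in the dwarf.

Enrichment of DEG sets against user-supplied term-to-gene maps uses the
upper-tail hypergeometric probability with BH correction (significant at
FDR $\le$ 0.05); replicate quality uses Pearson correlation of
$\log_2(\text{normalised count} + 1)$; and qPCR validation is summarised
by $2^{-\Delta\Delta C_t}$, the control condition being 1 by construction.

## Integration

The BSA gene set (genes with $\ge 1$ protein-altering site inside a
candidate region) is intersected exactly with the DEG set, keyed by gene
id; an empty intersection whose ids would match after case-folding is
treated as an annotation-release mismatch and raised as an error. A region
is **excluded** when every one of its mutated genes is unexpressed
(FPKM $\le 1$ everywhere) or non-differential — the transcription layer
must corroborate the mapping layer — and region membership of a gene is
any overlap between gene span and region span. Refinement only ever drops
regions. The final report (JSON plus TSV/BED companions) carries the
phenotype summary, region table, per-gene evidence, the full
configuration, its hash, and the seed; on simulated data it also states
whether the planted QTL lies in a retained region.

## What the simulator emulates — and what it does not

`runSimulation()` generates the complete experiment under the design of
the study the package models: an F2 of **200 plants**, bulks of
**30 + 30** phenotype extremes, parents at **~10x** and bulks at **~50x**
Poisson depth, fully homozygous and fully polymorphic parents, and a
normally distributed height controlled by one major additive locus.

Choices the underlying study leaves open are fixed once:

* **Genome scale.** Two 2-Mb chromosomes with 2,000 markers each — a
  desk-scale genome. The recombination rate default of 50 cM/Mb makes
  each 2-Mb chromosome carry ~100 cM, the genetic length of a real crop
  chromosome: physical size is compressed, genetic length is not. This
  preserves what matters statistically — linkage decay along the
  chromosome, within-window marker correlation, the number of effectively
  independent windows per genome — where a literal small genome (a few cM
  per chromosome) would be one giant linkage block and make region
  calling degenerate.
* **Genetics of the trait.** Baseline 130 cm, effect −15 cm per
  dwarf-allele copy, residual sd 8 cm: a single-locus $h^2 \approx 0.64$,
  i.e. "a quantitative trait controlled by a major gene" with visible but
  not overwhelming environmental noise. Dominance defaults to 0 and is a
  parameter. Recombination uses Haldane's map function (no interference),
  the simplest standard model.
* **Sequencing error** is a symmetric allele flip at rate 0.01.
* **Gene models**: non-overlapping single-CDS genes of 600–1500 bp
  (realistic plant CDS lengths), ATG-initiated, on both strands, with
  200-bp gene-body flanks; the chromosome sequence is generated alongside
  so CDS extraction and effect classification are exact.
* **RNA-Seq counts** are negative-binomial with dispersion 0.05 and a
  planted DE structure: genes within 300 kb of the QTL are down-regulated
  4-fold in the dwarf (mirroring a causal locus embedded among correlated
  expression changes), plus a few background DEGs of either sign.

Features of real data the simulator deliberately does **not** model:
mapping bias and alignment artefacts, indels and multi-allelic sites,
segregation distortion, polygenic background variation, batch effects in
the RNA-Seq arm, and GC- or length-dependent coverage. Passing tests
therefore demonstrate that the statistics do what they claim under their
own assumptions — not that those assumptions absorb every pathology of
real sequencing data.

## Numerical and testing choices

Coordinates are 1-based inclusive externally (VCF/GFF convention); BED
output is 0-based half-open with tested converters. Bulk selection breaks
height ties by ascending id (deterministic, and exactly antisymmetric
under negating all heights); if one tie group would have to span both
bulks the selection errors rather than silently overlapping them. The
phenotype summary uses the adjusted Fisher–Pearson skewness and the
small-sample-corrected *excess* kurtosis — the conventions of mainstream
statistics packages, which is how the "|skewness| < 1 and |kurtosis| < 1"
normality screen is interpreted here. All simulations are seeded and
bit-reproducible; identical seeds give byte-identical reports.

The test suite checks every set-level operation (marker filtering, window
averaging, interval merging, BH, intersection) against brute-force
oracles on random fixtures of 500–10,000 elements, the effect classifier
against full-CDS re-translation on 1,000 random SNVs on both strands, and
the statistical contracts by simulation at the default study conditions:
QTL recovery over 20 seeded replicates, null exceedance of the
permutation thresholds over 8 replicates (compared with 5% within 3
Monte-Carlo standard errors of the replicate mean — windows are strongly
correlated, so a binomial-over-windows standard error would be wrong),
and DE type-I/power at 5,000 genes, 3 vs 3, $\mu = 100$, $\alpha = 0.1$.
These problem sizes keep a full run of the suite in the ten-minute range
on a single core while leaving the Monte-Carlo bands meaningful.

## Known limitations

* The NB test is two-group only, with no covariates or batch terms.
* The null for thresholds treats windows independently when pooling by
  marker class; quantiles are exact marginally, but no attempt is made to
  control family-wise error across correlated windows.
* The two-stage null is marginally conservative because it ignores the
  small attenuation of $\Delta$ caused by symmetric sequencing error
  (a factor $1-2e$), which is unknown in real data.
* One isoform per gene is classified (the longest CDS); splice-site
  classes are folded into the gene-body class.
* Enrichment treats terms independently — no ontology-graph propagation
  or pathway topology.

## A minimal run

```{r, eval = FALSE}
cfg <- pipelineConfig(seed = 1L, sim = SimConfig(seed = 1L))
report <- runPipeline(cfg, outdir = "bsaseq-out")
report
```
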