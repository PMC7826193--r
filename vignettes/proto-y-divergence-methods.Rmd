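---
title: "Methods: measuring proto-Y / proto-X divergence from RNA-seq variants and allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring proto-Y / proto-X divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protoY)
```

This vignette documents the statistical model, the tunable parameters, the
synthetic-data generator and the numerical choices behind `protoY`. The
package analyses a two-genotype design for very young sex chromosomes:
*genotypic males* carry one proto-Y and one proto-X copy of the focal
chromosome (here called III^M and III), *sex-reversed males* carry two
proto-X copies and no proto-Y. Both are phenotypic males of the same
genetic background, so any third-chromosome signal specific to genotypic
males is attributable to the proto-Y.

## Relative heterozygosity

For each gene, let $h_G$ and $h_{SR}$ be the numbers of variant sites
(SNPs and small indels) called heterozygous in the genotypic and
sex-reversed group respectively; a site heterozygous in both groups counts
toward both. The per-gene statistic is

$$100 \cdot \frac{h_G}{h_G + h_{SR}},$$

which is 0 when only sex-reversed males are heterozygous, 100 when only
genotypic males are, and 50 under equality. Genes with $h_G + h_{SR} = 0$
carry no information and are excluded (with a message); how such genes were
handled in comparable published analyses is not documented, so exclusion is
this package's choice. Chromosome-level contrasts use the two-sided
Wilcoxon rank-sum test (`stats::wilcox.test`, normal approximation with
continuity correction at these sample sizes): the focal chromosome against
all others, and X against autosomes I, II, IV, V. Because per-gene values
are ratios of small counts they are heavily tied; the tie-corrected normal
approximation is then mildly conservative, which the type-I-error tests
account for by testing the attained size against a band rather than the
nominal level.

Both group genotypes are joint calls across the group's three replicates;
per-replicate genotype disagreement is outside the model. Multi-allelic
sites reduce to the two alleles observed per group; a genotypic-male
heterozygote that shares no allele with the sex-reversed homozygote
(a triallelic conflict) cannot be oriented and is excluded.

## Variant filters

`hard_filter_variants()` removes sites with Fisher-strand score
$FS > 20$ or quality-by-depth $QD < 2$ — both strict inequalities — and
then every SNP belonging to a set of three or more SNPs spanning at most
35 bp. *Window semantics*: positions are 1-based and the 35-bp window is
inclusive of both endpoints, so three SNPs are a cluster iff
$\max(p) - \min(p) \le 34$. Upstream tools do not document their exact
convention, so this one is fixed here and verified against a brute-force
all-windows oracle in the tests. Indels are never cluster-filtered (the
cluster filter targets SNP-dense mapping artifacts) but do count toward
$h_G$/$h_{SR}$. `cluster_bias_filter()` exposes the cluster stage alone —
it is also applied, idempotently, before ASE estimation to reduce
reference-mapping bias. Sites with missing FS or QD pass those filters
with a warning rather than being dropped.

## Diagnostic sites and phasing

A *diagnostic site* is heterozygous in genotypic males and homozygous in
sex-reversed males. The allele shared with the sex-reversed homozygote is
assigned to the proto-X (III); the allele unique to genotypic males to the
proto-Y (III^M). Sites heterozygous in both groups have the same genotype
in both and carry no discriminating information; they are removed.

`phase_haplotypes()` reconstructs each gene's two haplotypes over its
diagnostic sites from long-read allele observations by greedy chaining:
sites are processed outward from the first covered site, each read is
oriented against the already-phased sites by majority agreement, and
oriented reads vote on the next site's phase (ties break deterministically
toward the lexicographically smaller allele). Haplotype 1 is canonically
the one carrying the smaller allele at the gene's first diagnostic site, so
the labeling is reproducible; which haplotype is proto-Y is decided later,
per gene, by `assign_allele_direction()` via majority vote over the
diagnostic-site assignments (a tied vote yields `"undetermined"`).

## The ASE model

For a gene and genotype, let $f_i \le t_i$ be the focal-haplotype and total
read counts in replicate $i$. The model is a shared binomial:

$$f_i \sim \mathrm{Binomial}(t_i, \rho), \qquad \rho \sim \mathrm{U}(0,1),$$

so the pooled counts $(f, t)$ are sufficient. `sample_rho()` runs
random-walk Metropolis on $\mathrm{logit}(\rho)$ (proposal SD 0.5, uniform
prior via the logit Jacobian), discards a 1,000-iteration burn-in and keeps
at least 500 draws. The per-gene statistic is the proportion of kept
iterations with $\rho > 0.5$.

**Orientation invariance.** Which haplotype is called "focal" is an
arbitrary label: chromosome-wide there is no way to know whether it is the
proto-Y or proto-X copy, and relabeling maps $\rho \mapsto 1-\rho$. The
default likelihood is therefore symmetrized over the labeling,
$L(\rho) + L(1-\rho)$, implemented with a latent orientation variable
updated by its own Metropolis flip each iteration (acceptance
$\min\{1, L(1-\rho)/L(\rho)\}$). The behaviour of the resulting statistic
is exactly what the classification assumes:

* for a balanced gene the flip is almost always accepted, the chain mixes
  freely across 0.5, and the statistic concentrates near 0.5;
* for a clearly skewed gene the flip acceptance is astronomically small,
  the chain stays in the data-supported mode, and the statistic goes to 0
  or 1.

This matters because under the plain *identified* binomial posterior the
exceedance probability $\Pr(\rho > 0.5 \mid f, t)$ is, across balanced-gene
datasets, close to uniformly distributed (a probability integral
transform), so a quarter of truly balanced genes would land in the extreme
bins at any depth — no classification threshold can fix that. The
symmetrized statistic instead measures whether the data *identify* an
orientation, which is the quantity the downstream screens need. The
identified likelihood remains available (`likelihood = "identified"`) and
is the right choice when the focal haplotype is externally fixed; its
posterior is the closed-form $\mathrm{Beta}(f+1,\,t-f+1)$, which the test
suite uses as an exact oracle for the sampler.

**Iterations.** `sample_rho()` defaults to 500 kept draws (the documented
minimum); `ase_fit()` and `run_pipeline()` keep 2,000. The source protocol
adjusted its iteration count upward automatically; a fixed larger count
plays that role here and bounds the Monte-Carlo error of the proportion
statistic (effective sample size roughly 250 at the default proposal,
Monte-Carlo SD of the statistic about 0.03). A convergence flag is raised
when the first-quarter and last-quarter means of the kept draws differ by
more than 0.1.

**Bins.** The statistic is binned as extreme-low $[0, 0.125)$,
moderate-low $[0.125, 0.375)$, non-ASE $[0.375, 0.625]$, moderate-high
$(0.625, 0.875]$, extreme-high $(0.875, 1]$. "ASE" means either extreme
bin; "non-ASE" means the middle bin only; moderate genes are excluded from
the contingency analysis to be conservative. The published bin definitions
say "between" without specifying closed or open ends; the assignment above
is this package's documented convention and the tests avoid asserting at
the boundaries. Genes enter only with $\ge 10$ reads pooled across the
genotype's three libraries.

## Chromosome-level ASE contrasts

`build_ase_contingency()` counts, among genes classified in *both*
genotypes, the focal-chromosome genes with ASE in genotypic males that are
non-ASE in sex-reversed males ($a$), the reverse pattern ($b$), and the
same two counts on all other chromosomes ($c$, $d$). Moderate-bin genes
fall in neither cell; whether they should also leave the denominator is
ambiguous in the source analyses — here they simply occupy no cell.
`fisher_exact_2x2()` applies the standard two-sided Fisher's exact test
(sum of hypergeometric probabilities no larger than the observed table's),
which reproduces the published p-value on the published counts to its
printed precision; sidedness was not stated in the source and was
validated against that value. The reported statistic is the sample odds
ratio $ad/bc$. A per-chromosome genotypic-vs-sex-reversed comparison of
(ASE, non-ASE) counts is also run; it has no published counts to compare
against.

The final screen intersects cell $a$ with genes showing *discordant
sex-biased expression* — male-biased relative to phenotypic females in one
male genotype and female-biased in the other. Bias labels are consumed as
input from an upstream differential-expression analysis;
`sex_bias_labels()` offers a convenience derivation from log2 fold changes
at threshold $|\log_2 FC| \ge 1$, which is not the upstream method, only a
stand-in for data lacking labels.

## The k-mer contig screen

`build_kmer_set()` collects the distinct canonical k-mers (lexicographic
minimum of each window and its reverse complement; windows containing N
yield nothing) of the female read set, by default at $k = 15$.
`percent_ufr()` scores each contig by
$100 \cdot n_{\text{unmatched}} / n_{\text{distinct}}$ over its distinct
canonical k-mers — distinct, not occurrences, so repeats do not inflate the
denominator. Canonicalization makes the score strand-invariant, which the
tests assert directly. The membership structure is an exact in-memory set;
bit-array compression used by large-scale tools is an optimization, not
part of the contract. The classification threshold (default 50%) is
configurable because no universal cutoff is published; 50 separates
predominantly shared from predominantly male-specific sequence and
recovers planted truth exactly in the generator's error-free regime.

## The synthetic-data generator

`simulate_study()` emulates the study design: two genotype groups × 3
replicates; chromosomes I–V and X; per-gene heterozygous sites at rate
`het_site_rate` (default 4 per gene per group) split between group-specific,
shared and fixed sites symmetrically, so the null heterozygosity statistic
centres at 50; a fraction `frac_div_genes_III` (default 0.1) of
third-chromosome genes receives planted diagnostic sites and a proto-Y
allele fraction `planted_rho` (default 0.8) in genotypic males only.
Defaults are desk-scale — 200 genes per autosome, 100 on the gene-poor X —
and scale up toward the real chromosome sizes (the real third chromosome
carries ~2,500 genes) via `genes_per_chromosome`.

Design choices worth knowing:

* **Variant placement.** Sites occupy a 72-bp-spaced slot grid with ≤11 bp
  jitter, so no background sites ever form a 3-in-35-bp cluster by chance;
  the only clusters are the planted artifacts (3 SNPs at +0/+12/+24 bp in
  one slot, rate `cluster_artifact_rate` per gene). Truth labels for the
  cluster filter are therefore exact.
* **Counts.** Per-replicate totals are Poisson(`depth_mean`, default 50);
  focal counts are binomial, or beta-binomial with overdispersion
  `dispersion` when positive. The default 0.02 is the point where
  replicate-level variance equals the binomial counting variance at the
  default pooled depth of 150 ($3/150$); below it counting noise dominates,
  above it biological replicate scatter does. The published analyses do not
  model counts at all, so the beta-binomial is purely a stress test for the
  sampler.
* **Long reads.** Half of reads span all diagnostic sites, half a random
  contiguous sub-window; each carried allele flips independently with
  probability `long_read_error` (default 0.05 at depth 20).
* **Contigs.** Female reads tile a simulated female genome with $k-1$
  overlap, so shared contigs (substrings of that genome) have %UFR exactly
  0; male-specific contigs are resampled until they share no canonical
  k-mer with the female set (%UFR exactly 100); mixed contigs put the
  junction so that unmatched k-mers are exactly half the distinct total.
* **Orientation bookkeeping.** The generator anchors the "focal" haplotype
  of the count tables to the same canonical rule the phaser uses (smaller
  allele at the first diagnostic site), so direction assignment is testable
  against truth.
* **Reproducibility.** One top-level seed; each stage draws from a derived
  substream, so stages regenerate independently, and the RNG state of the
  calling session is restored afterwards.

What the generator does *not* emulate: real linkage structure along
chromosomes, mapping and alignment artifacts beyond the planted SNP
clusters, isoform structure, expression-level variation between genes,
library-size differences, or real genome sequence content. Passing
parameter-recovery tests therefore demonstrates correctness of the
statistical machinery under the stated model, not performance on real
libraries.

## Degenerate inputs and tie-breaks

Zero-depth genes are dropped by the read filter; genes whose every
diagnostic site fails the quality filters simply leave the phasing and
direction stages (direction `"undetermined"`), while remaining classifiable
for ASE; empty read sets give an empty k-mer set with a warning; contigs
shorter than $k$ are excluded with a warning; unsorted variant input is an
error instructing the caller to sort (silent reordering could mask joint
mis-specification of chromosome blocks).

## Problem sizes used by the test suite

The suite exercises desk-scale versions of each analysis: 250 genes for
parameter recovery (pooled depth ~150), 500 null replicates for the
Wilcoxon size check and 200 for the Fisher contrast (the full
classification pipeline per replicate), 1,000 random site configurations
against the cluster-filter oracle, and every 2×2 table with $N \le 30$
against hypergeometric enumeration. These sizes were chosen so the entire
suite completes in minutes while keeping Monte-Carlo error well inside the
asserted tolerances.

## Known limitations

* The ASE model is a single shared-ρ binomial per gene and genotype; it
  does not model isoforms, per-read alignment uncertainty, or the hybrid
  short/long-read error structure of the original estimation software. The
  statistic is re-implemented, not the software.
* The discreteness of published statistic distributions (mass at 0, 0.25,
  0.5, 0.75, 1) arising from sampling only two genotypes is not
  reproduced.
* Dataset-dependent published numbers (gene counts per cell, chromosome-
  wide p-values, the 21.3% SNP retention of the real data, assembly sizes)
  depend on the real libraries and are out of reach of a desk-scale
  simulation; only the published contingency test is reproduced exactly,
  from its printed counts.
* With heavy ties the Wilcoxon contrast is conservative; at very small
  gene counts per chromosome its attained size falls below nominal.
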