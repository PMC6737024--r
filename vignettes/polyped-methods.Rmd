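---
title: "Methods: pedigree tracing, selection scans, local ancestry and genetic load"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree tracing, selection scans, local ancestry and genetic load}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polyped` dissects the genome of a young allotetraploid crop cultivar (two
subgenomes, A and C) against its breeding pedigree and its population
context. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## Identity-by-descent tracing

The derived cultivar's assembly is cut into consecutive 50 kb blocks
(`segment_blocks()`; the trailing block of each chromosome keeps its true,
shorter span so that coverage is conserved). Each block is scored against
every candidate parent assembly and assigned to the parent with the
**longest accumulated match length** (`assign_blocks()`).

The matcher (`match_lengths()`) is a k-mer-anchored maximal-exact-match
engine: every parental k-mer (default `anchor_k = 21`, near-unique in a
gigabase-scale plant genome) is indexed; maximal exact matches of length at
least `k` between block and parent are located from these anchors; the
score is the number of block positions covered by at least one such match.
Counting covered positions — rather than summing match lengths — means
repeated hits can never double-count a block position, which is the purpose
served by colinear chaining in alignment-based pipelines. The implementation
is verified in the test suite against an independent per-diagonal
run-enumeration oracle on small blocks, where the two formulations are
provably identical.

Two policies are deliberate package decisions because the block-assignment
rule alone does not determine them:

* **ties**: blocks whose top two parents match exactly equally are
  `unassigned` rather than arbitrarily attributed;
* **floor**: a best match below 10% of the block length
  (`min_match_fraction = 0.1`) is also `unassigned`, so unalignable
  sequence is never credited to a parent.

`decompose_parent()` re-scores one parent's blocks against that parent's
own parents (the grandparent generation), which separates, for example, the
landrace-derived from the donor-derived portions of an F1 parent.

`summarize_contributions()` reports per-line percentages of the genome.
With `drop_unassigned = TRUE` percentages are renormalized over assigned
blocks — the convention of pedigree pie charts, in which every slice is a
parental line. Block-level accuracy statements in the package's validation
are made over blocks with a single true origin: a block that straddles a
crossover is a genuine mixture at 50 kb resolution and has no single
correct label.

## Windowed selection scans

Windows of 100 kb advancing in 10 kb steps are anchored at position 0 of
each chromosome; trailing partial windows keep their true span as the
denominator.

**Nucleotide diversity.** Per site, with `n` called alleles and alternate
frequency `p`, the unbiased per-site heterozygosity is
`2 p (1 - p) n / (n - 1)`; the window value is the sum over sites divided
by the window span in bp, which equals the mean pairwise difference per bp
among haplotypes (checked against an all-pairs oracle to 1e-12).

**FST.** The Weir & Cockerham (1984) two-population estimator is computed
per site from called sample sizes, allele frequencies and observed
heterozygosity; window values sum the per-site numerator and denominator
components separately ("ratio of averages"), the convention of the standard
VCF toolchains. Raw window values are kept, including negative ones:
clamping at zero would distort the null distribution that the
Z-transformation below relies on.

**Z-transformation and region calling.** Window values are centred and
scaled by the genome-wide sample standard deviation (`z_transform()`), and
windows with Z above 3 are merged into maximal regions wherever they
overlap or abut on the grid (`call_divergent_regions()`). Z is computed
over both subgenomes jointly by default; a `z_scope = "subgenome"` switch
normalizes each subgenome separately, since either convention is
defensible for an allopolyploid. Zero variance raises an error rather than
propagating NaN.

Because windows overlap, a called region necessarily extends up to one
window length (90 kb at the defaults) past the true edge of a selected
tract; this spill is grid geometry, not a calling error, and it bounds how
small a genome can be before boundary spill dominates false-positive
accounting. The package's scan-recovery check therefore runs on a
10 x 2 Mb genome with a 300 kb locally fixed tract.

**Site filter.** Scans run after the standard `maf >= 0.01` and
call-rate `>= 0.9` filter (`filter_sites()`), the VCFtools
`-maf 0.01 -max-missing 0.9` convention.

**LD decay** (`ld_decay()`) averages genotype-correlation r² per distance
bin over all intra-chromosome pairs within `max_dist`.

## Local ancestry and fixed introgressions

The ancestry painter is a transparent stand-in for haplotype-copying
optimizers: in windows of 50 consecutive SNPs, each phased query haplotype
is labelled with the source panel whose closest member has the smaller
Hamming distance; exact ties are `unresolved`. Windows are defined in SNP
counts, not bp, so the painter is robust to variable SNP density; bp spans
for reporting are delimited at midpoints between flanking sites. The
painter exceeds 99% window accuracy when the panels differ at 10% of sites
(verified in tests) and degrades as divergence approaches the noise rate —
it is not a substitute for model-based local-ancestry inference at low
divergence, and the package's contribution is the downstream fixation
summary, not the painter itself.

A diploid *carries* donor ancestry in a window if at least one of its two
haplotypes is donor-labelled (`population_ancestry_frequency()`); counting
can be switched to haplotype level, since published ">90% of samples"
statements rarely say which was meant. `call_fixed_introgressions()` flags
windows whose carrier fraction **strictly exceeds** 0.9 — a fraction of
exactly 0.9 is not "more than 90%" — and merges consecutive flagged
windows.

The package's recovery check runs the fixation rule at 200 samples: with a
carrier fraction of 0.95, the binomial realization of the carrier count
then clears the strict 0.9 rule with failure probability below 1e-3, so the
check measures the method rather than binomial luck. At a carrier fraction
of 0.80 the same rule must stay silent.

## Genetic load

Sites are classified from annotations (`classify_sites()`): a score
strictly below 0.05 is **deleterious**; otherwise intergenic context makes
a site **neutral-intergenic** (the reference class); everything else is
`other` and excluded. Allele counting follows the twice-homozygous-plus-
heterozygous rule over called genotypes, with twice the called samples as
denominator.

`frequency_spectrum()` histograms the alternate-allele frequency per class
in bins of 0.05 on (0, 1]; the top bin, frequency in (0.95, 1], is the
explicit "fixed" bin (the left boundary is open: a frequency of exactly
0.95 is not fixed — the printed range "0.95-1" does not state a boundary
convention, so the package declares one). Monomorphic-reference sites are
excluded. `relative_load()` divides the normalized deleterious spectrum by
the neutral one per bin, flagging bins with no neutral mass as undefined.

`individual_load()` counts, per sample, deleterious and neutral-intergenic
sites carrying at least one alternate allele and reports their ratio per
subgenome and genome-wide (the A- and C-subgenome counts add exactly to the
genome-wide count). Site presence is the default because published
per-individual "numbers of dSNPs" are site counts; an allele-dosage mode is
available. The alternate allele is treated as the derived/deleterious
allele throughout — the reference is a progenitor-like combined genome, so
no outgroup re-polarization is attempted; a folded-spectrum option is out
of scope.

## The synthetic-data generator

The generator is coalescent-free by design: ground truth must be exact, and
the procedures above need realistic *structure* (pedigree mosaics, drifted
groups, introgression tracts, selection-skewed frequencies), not a specific
demography.

* **Founders** (`simulate_founders()`): one random ancestral genome; the
  founder landrace mutates at the polymorphism density (1e-3/bp), the
  interspecific donor at its divergence rate (5e-3/bp, a between-species
  scale for the A subgenome's diploid relative).
* **Crosses** (`simulate_cross()`): Poisson(2) crossovers per chromosome
  per meiosis at uniform positions, no interference — the simplest model
  that produces realistic block structure; each generation adds 1e-4/bp
  mutations. Truth tracts tile every chromosome exactly.
* **Groups**: three panels sized like a typical resequencing study
  (EU = 59, AS_DH = 38, AS_DL = 30 diploids). Per-site group frequencies
  drift around a shared base frequency under a Balding-Nichols model
  (F = 0.1 between groups, 0.5 for the donor panel); haplotypes are drawn
  independently per site and paired at random into diploids. Selected
  regions force a local fixed difference between the first two groups.
* **Site classes** (`assign_site_classes()`): genes cover 35% of each
  chromosome; 20% of genic sites are deleterious with synthetic scores
  below 0.05; deleterious frequencies are the base frequencies multiplied
  by the selection skew (0.5), so the realized deleterious:neutral mean
  frequency ratio converges to the skew by construction.
* **Introgression** (`simulate_admixed_population()`): recipient haplotypes
  copy random background-panel haplotypes; carriers (a binomial draw at the
  carrier fraction, default 0.95) have one haplotype's alleles replaced by
  a donor-panel haplotype inside the event tract (default: the middle 60%
  of the first A chromosome); 1% allele noise emulates post-admixture
  mutation and genotyping error.

What the generator does **not** emulate: linkage disequilibrium within
groups away from introgression tracts (sites are drawn independently), a
calibrated mutation rate or demography, structural variation,
homoeologous exchange between subgenomes, and sequencing-level error
models. Passing tests therefore demonstrate that the *procedures* recover
known structure under controlled conditions; they do not calibrate
real-data expectations such as absolute diversity levels.

Default problem sizes are the package's validation conditions: 10
chromosomes of 1 Mb (five per subgenome) for the pedigree stages; the scan
recovery check uses 2 Mb chromosomes (see above); the load checks use two
3 Mb chromosomes so each class holds thousands of sites. Everything is
seeded: identical configuration (including the seed) gives byte-identical
simulated files and pipeline reports.

## Degenerate inputs and numerical edges

* Blocks consisting entirely of ambiguous bases score zero against every
  parent and are flagged, never silently assigned.
* Z-transformation refuses constant input and fewer than two values.
* Windows with no usable site are reported missing, and stay missing
  through Z-transformation.
* An empty genotype matrix still writes a valid VCF header with zero
  records; reading it back returns an empty matrix.
* Undefined ratios (zero neutral mass in a bin, zero iSNP count for a
  sample) are flagged `undefined`, never silently dropped or zeroed.
* All internal coordinates are 0-based half-open; conversion to 1-based
  happens only at the VCF boundary (BED is natively 0-based).

## Known limitations

* The painter assumes phased haplotypes and panels that contain close
  relatives of the true sources; it reports `unresolved` on exact ties but
  has no explicit uncertainty model.
* IBD assignment at 50 kb resolution cannot split a block that straddles a
  crossover; breakpoint blocks are attributed to whichever line happens to
  match best, which is why a small fraction of blocks drains to
  grandparent labels even on perfect data — mirroring the real
  phenomenon that makes grandparent slices appear in published pedigree
  pies.
* The Weir-Cockerham implementation covers two populations (the pairwise
  scans used here), not the general r-population form.
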