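---
title: "Localizing a nematode-tolerance locus by pooled allele-frequency mapping"
author: "beetMBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing a nematode-tolerance locus by pooled allele-frequency mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tolerance of sugar beet (*Beta vulgaris*) to the beet cyst nematode
(*Heterodera schachtii*) is a quantitative trait: tolerant plants limit
nematode development and yield loss rather than blocking reproduction
outright. The phenotype is laborious — cysts on washed roots are counted
plant by plant — so genotyping every individual of a large mapping
population is replaced by *bulked-segregant mapping-by-sequencing*: only
the phenotypic extremes of an F2 population are sequenced, as two pools,
and the trait locus reveals itself as a region where the two pools'
allele frequencies diverge.

beetMBS implements that analysis end to end at desk scale:

1. **Phenotyping** — cyst counts are variance-stabilized, adjusted for
   incomplete-block (box) effects, and summarized per F2:3 line; a
   within-line coefficient of variation screens out segregating
   families; the extreme lines form a tolerant pool (20 lines) and a
   susceptible pool (16 lines).
2. **Variant filtering** — a multi-sample VCF (two parents, F1, two
   pools) is reduced to high-confidence, population-informative SNVs.
3. **dAF genome scan** — per-variant delta allele frequencies are
   averaged in tumbling 10-SNP windows; runs of at least five windows
   above 0.5 delimit candidate intervals.
4. **Marker design** — KASP-style assay candidates are screened by flank
   cleanliness, GC content and per-contig quotas, and a well-spread panel
   is chosen.
5. **Simulation** — a seeded generator produces F2 genotypes, cyst-count
   phenotypes and pooled allele depths with the statistical structure the
   analysis assumes, so every stage can be exercised and validated
   without the original sequencing data.

## The statistic

Each biallelic SNV is oriented by the parents: the *tolerant allele* is
the allele the tolerant parent is homozygous for. For a pool with
reference/alternate allele depths $(d_r, d_a)$ the tolerant-allele
frequency is $\hat p = d_T / (d_r + d_a)$ (masked below a minimum depth,
default 10), and the per-variant statistic is the signed difference

$$\mathrm{dAF} = \hat p_{\mathrm{tol}} - \hat p_{\mathrm{sus}} \in [-1, 1].$$

At a fully penetrant monogenic locus with pools fixed for opposite
alleles the dAF is exactly 1; elsewhere it fluctuates around 0 with
binomial sampling noise of order $\sqrt{p(1-p)/\mathrm{depth}}$ per pool.
Averaging ten consecutive unmasked variants suppresses that noise by
roughly a factor of three, and demanding five *consecutive* windows
above 0.5 suppresses isolated noise peaks: a qualifying run is a 50-SNP
delimitation of the candidate region.

Windows are *tumbling* (non-overlapping): five consecutive 10-SNP
windows can only equal a 50-SNP span if windows do not overlap, which is
why the package fixes this mode as the default and offers no silent
smoothing. The signed statistic is thresholded (strictly greater than
0.5); an absolute-value mode would be needed only for data without
parental orientation, which the high-confidence filter guarantees here.

## The phenotype model

Counted cysts $n$ are transformed as $SN = \sqrt{n + 3/8}$
(Anscombe-style variance stabilization) before any modeling. Boxes of up
to 120 plants are incomplete blocks; the package fits the additive
two-way model

$$SN_{ij} = \ell_i + b_j + \varepsilon_{ij}$$

by alternating least squares (lines and blocks updated in turn,
block effects centered, convergence when no effect moves by more than
1e-10, cap 200 iterations). The *adjusted* plant value is
$SN - \hat b_j$; a line's adjusted mean averages its plants. On balanced
designs this coincides with the closed-form least-squares solution; on
connected unbalanced designs it converges to the fixed-effects solution
without shrinkage. A mixed model with random blocks would shrink block
effects slightly; the fixed-effects choice is deterministic,
dependency-free and coincides with it in the balanced limit, which the
test suite exploits. A disconnected line/block design has no unique
solution and is rejected with the disconnected block groups named.

The CV screen (sd/mean of a line's adjusted plant values, default
ceiling 0.3) flags families that still segregate. Lines whose CV is
undefined because the adjusted mean is non-positive are *kept* eligible:
a near-zero mean cyst count is itself the strongest tolerance signal,
and discarding such lines would bias the tolerant pool. Ties at either
selection cutoff go to the lexicographically smaller line id, so pool
membership is reproducible.

## The synthetic study

The generator's defaults are the emulated study's design: 406 F2 lines
from one F1, 10 phenotyped F3 plants per line, pools of 20 tolerant and
16 susceptible lines, ~20x pooled coverage, nine chromosomes carrying
2,007 parent-contrasting SNVs. Meiosis uses the Haldane map function (no
interference) between adjacent variants; each F2 is the fusion of two
independent F1 gametes. Genetic length defaults to 65 cM per chromosome,
the scale implied by a beet linkage map of ~190 markers at ~3 cM average
spacing over nine groups; physical length defaults to 54 Mb, the
pseudochromosome scale of recent assemblies.

Phenotypes are negative-binomial counts with line mean
$\max(0,\ \mu_0 - a \cdot \mathrm{dosage})$: baseline $\mu_0 = 90$
cysts for the susceptible homozygote, additive effect $a = 11$ cysts per
tolerant-allele dose (heterozygotes exactly intermediate — no
dominance), so single-plant counts span roughly 0–280 as in the emulated
study. Values the study does not report are package choices, fixed once:
dispersion (NB size) 5, giving a per-plant CV near 45% as typical for
greenhouse cyst counts, with `Inf` selecting the Poisson limit; block
effects Normal(0, 0.5) on the SN scale, applied additively on that scale
and back-transformed (means pushed below zero are clamped to zero and
reported); per-read miscall rate 0.005. Sequencing is simulated at the
allele-depth level only: per sample and variant, depth ~
Poisson(coverage) and alternate reads ~ Binomial(depth, q') with
$q' = q(1-e) + (1-q)e$ — the analysis consumes AD fields, so read-level
simulation would add cost without adding validity. A configurable
fraction (default 0.1) of population-monomorphic decoy sites is
interleaved so filter specificity can be measured against the emitted
truth table.

One root seed drives everything; each stage (map, meiosis, phenotypes,
pool reads, reference) derives its own stream, so outputs are
byte-identical under a repeated seed and stages can be re-run
independently.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: polygenic background variance (the locus
here is the only genetic signal, whereas the real trait has substantial
residual genetic variance), within-family F3 segregation (a plant
inherits its line's dosage, so the CV screen is exercised structurally
but cannot detect heterozygous families the way real F2:3 data allow),
read-level artifacts (mapping bias, duplicates, indel misalignment), and
real marker density — ~2,000 desk-scale variants make a 50-SNP run span
several cM, a far harsher linkage-attenuation regime than the millions
of variants of a real pool-seq experiment. Detection power measured here
is conservative in that one respect and optimistic in the first.

## Numerical and boundary choices

* Filter criteria are evaluated in a fixed order — missing genotype,
  parents homozygous, parents contrasting, F1 heterozygous, parent
  depth, site QUAL — and each rejected record is counted once under its
  first failing criterion, so reports reconcile exactly
  (`in = out + sum(rejections)`). Missing genotypes are ordered first
  because a missing call cannot be classified homozygous or
  heterozygous. Depth and QUAL defaults (5 reads per parent, QUAL 30)
  are declared package substitutes for caller-specific hard filters,
  both configurable.
* Window means use only unmasked variants; masked records do not occupy
  window slots or shift boundaries. A trailing window short of 10
  variants is reported with its true count but flagged incomplete and
  never contributes to an interval.
* All interval coordinates are 1-based inclusive internally; BED export
  converts to 0-based half-open.
* Thresholds are strict where the rules are printed strictly: window
  mean dAF must exceed 0.5, flank GC must be below 65%, and a lenient
  variant within 50 bp inclusive disqualifies a marker candidate. "100 bp
  of flanking sequence" is read as 50 bp per side, consistent with the
  50 bp flank-variant window.
* The distributed marker panel solves the 1-D max-min dispersion problem
  exactly (binary search on the minimum gap with a greedy feasibility
  sweep; the two outermost candidates are always retained, which an
  exchange argument shows is optimal). A sequential farthest-point
  greedy was considered and rejected: for four or more markers it can
  return a panel with half the optimal minimum spacing (positions
  0/30/50/70/100, k = 4), violating the guarantee that no random subset
  spaces better. For k = 1 the candidate nearest the chromosome midpoint
  is taken; quality ties in per-contig quotas go to the lower position.
* Interval detection is monotone in the expected directions: raising the
  run minimum can only drop intervals, and raising the threshold can
  only shrink total coverage, with every surviving interval nested in a
  looser-threshold interval. The interval *count* is deliberately not
  claimed monotone under the threshold — a long run can split into two
  qualifying fragments.

## Validation sizes

The test suite validates Mendelian segregation and Haldane recombination
on populations of 10,000–20,000 lines at one or two variants; the
phenotype model in the Poisson limit on 10,000 plants per genotype
class; window, run, flank and GC logic against independent brute-force
recomputations on 220 randomized instances; filter sensitivity and
specificity against simulator truth at zero error; and locus recovery on
50 seeded replicates of the full study shape (406 lines, 2,007 variants,
pools 20/16, 20x) plus 50 no-locus null replicates, requiring the causal
variant inside a detected interval in at least 90% of signal replicates
and zero intervals in at least 95% of null replicates. These sizes keep
the whole suite under a few minutes on a laptop core while leaving the
binomial uncertainty of each rate well below the margin being asserted.

## Known limitations

* The fixed-effects adjustment differs from REML under severe imbalance;
  differences are small by construction (no shrinkage) but not zero.
* The scan offers no analytic confidence interval for the locus
  position (no G' statistic or simulation-based CI); the interval is a
  rule-based delimitation, as in the emulated workflow.
* Marker design stops at sequence-level screening; primer
  thermodynamics and assay chemistry are out of scope.
* The generator draws variant positions uniformly; real SNV density is
  locally clumped, which mostly affects the bp (not SNP) width of
  windows.
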