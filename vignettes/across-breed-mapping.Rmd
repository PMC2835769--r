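---
title: "Across-breed mapping of breed-fixed traits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-breed mapping of breed-fixed traits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmap)
```

## The mapping problem

Many of the most striking dog phenotypes — head shape, leg length, coat
pattern — are *fixed* within breeds: every individual of an affected breed
carries the trait, so classical within-breed segregation mapping has
nothing to segregate. Across-breed mapping sidesteps this by treating
whole breeds as the sampling unit: breeds fixed for the trait are "cases",
phenotypically unlike breeds are "controls". Because such traits usually
predate modern breed formation, affected breeds share the causal
haplotype identical by descent (IBD), while the strong artificial
selection that fixed the trait dragged a long flanking haplotype to
fixation with it — a selective sweep. Three signals follow, and the
package implements one analysis stage for each:

1. **Association**: the causal allele is at high frequency in case breeds
   and lower frequency in control breeds, detectable by a single-marker
   allelic test on a moderately dense SNP array.
2. **Reduced case heterozygosity**: around the causal locus, case breeds
   are unusually homozygous relative to controls.
3. **Shared homozygous haplotype**: within the swept region, all affected
   breeds carry the *same* homozygous haplotype; its across-breed
   intersection is the minimal critical interval.

## Association with genome-wide permutation

Each SNP is tested with the 1-df Pearson chi-square on the 2×2
case/control × minor/major allele-count table,

$$\chi^2 = \frac{N (ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)},$$

with missing calls dropped per SNP and pooled-monomorphic SNPs assigned
$\chi^2 = 0$. Breed structure makes the nominal p-value badly
anticonservative — cases and controls are clusters of relatives, so allele
frequencies differ genome-wide. The package therefore reports a
genome-wide corrected p-value by max-T permutation: case/control labels
are reassigned at random (group sizes preserved), all statistics
recomputed, and the genome-wide maximum recorded; a SNP's corrected
p-value is the probability that the null maximum reaches its observed
statistic. In Monte-Carlo mode the estimator is $(1 + k)/(1 + B)$ so that
no p-value is ever exactly zero; when the number of distinct label
assignments is small (at most $10^6$ by default) the package enumerates
them all and reports the exact permutation p-value instead.

Permutation correction absorbs the genome-wide multiplicity but *not* the
breed clustering itself: permuting individual labels treats dogs as
exchangeable, which they are not when status is constant within breeds.
The same limitation applies to any individual-label permutation on
breed-clustered data; it is the reason the design relies on many breeds
per group and on the *support ratio* heuristic rather than on the nominal
0.05 threshold alone. The support ratio divides the best corrected
p-value on any competing chromosome by the top locus's corrected p-value;
the locus is "accepted" only when the ratio exceeds 100. Ties for the
best SNP are broken deterministically: smaller corrected p, then larger
chi-square, then chromosome and position order.

Default permutation counts are 100,000 genome-wide and 50,000
chromosome-wide. (Both figures circulate for this kind of analysis;
where a source states both 50,000 and 100,000 for the genome-wide scan we
default to the larger and expose the count as configuration.)

## Haplotype blocks and haplotype association

Chromosome-wide follow-up works on haplotype blocks delimited by the
**four-gamete rule**: observing all four two-locus gametes between
adjacent SNPs is evidence of historical recombination, so a block
boundary is placed there. Gamete frequencies come from a two-locus EM
(below); a gamete counts as "observed" at frequency ≥ 0.01 by default —
the conventional small cutoff that keeps a single genotyping error from
shattering a block. Maximal runs of compatible adjacent pairs form
blocks; the partition covers every SNP on the chromosome.

Haplotype frequencies within a block are estimated by EM over all
haplotypes consistent with each individual's unphased multilocus
genotype: double heterozygotes contribute a mixture of their phase
resolutions weighted by current frequency estimates. The EM starts from
linkage equilibrium (the product of allele frequencies, restricted to the
compatible haplotype set), and stops when the largest frequency change
falls below $10^{-8}$ or after 1,000 iterations. Its log-likelihood is
non-decreasing by construction, which the test suite asserts at every
iteration. Two numerical caveats are deliberate choices. First, a
symmetric tie (e.g. a lone double heterozygote, whose two resolutions are
equally likely) leaves the EM at the symmetric mixture reached from the
linkage-equilibrium start: that point is a saddle, not a maximum, but it
is deterministic and fabricates no phase. Second, individuals missing any
SNP in a block are excluded from that block's EM rather than imputed.
Blocks are capped at 12 SNPs for the exact EM (the haplotype space grows
as $2^k$); wider four-gamete blocks are analysed in consecutive chunks of
at most 12.

Each haplotype at frequency ≥ 0.01 is tested haplotype-vs-all-others with
the same chi-square, on *fractional* expected haplotype counts in cases
and controls derived from the EM posterior phase probabilities (whether
historical haplotype tests used fractional or best-guess counts is not
documentable; fractional counts are the statistically cleaner reading and
are flagged as an interpretation). Correction is chromosome-wide: the
permutation null maximum is taken over all SNP *and* haplotype statistics
on the chromosome.

## The sweep scan

Heterozygosity rates (fraction of non-missing calls equal to dosage 1)
are computed per SNP separately in cases and controls, after the scan's
own filters: samples with a call rate above 75% are used and SNPs with a
call rate below 95% removed. Rates are averaged over sliding windows of 5
SNPs (10 for a denser panel), the window ratio cases/controls is formed,
and the ratio is normalized:

$$f(r) = \begin{cases} 1 - 1/r & 0 < r < 1 \\ r - 1 & \text{otherwise}. \end{cases}$$

The normalized value is 0 when the groups are equally heterozygous,
negative exactly when cases are less heterozygous than controls, and
antisymmetric under $r \mapsto 1/r$. Three boundary decisions are
documented rather than hidden:

* *Averaging before the ratio.* Windows average per-SNP rates first and
  then form one ratio, not the mean of per-SNP ratios — per-SNP ratios
  are undefined whenever a single control SNP is monomorphic.
* *Zero control heterozygosity.* A window with control heterozygosity 0
  leaves the ratio undefined and is emitted as missing.
* *Complete case fixation.* Ratio 0 maps to −1 by the literal formula.
  This is anomalous — a window with *nearly* fixed cases can map far below
  −1 because $1 - 1/r$ diverges as $r \to 0$ — so an optional floor mode
  maps ratio-0 windows to the minimum of the remaining profile; it is off
  by default for fidelity to the plain formula. The divergence also means
  an occasional noisy off-sweep window can undercut the sweep's own −1
  plateau; the sweep scan is descriptive, and the profile minimum should
  be read together with the association peak.

## Homozygosity fine mapping

Around an anchor SNP (by default the top association), each case breed's
homozygous run extends in both directions while, SNP by SNP, the fraction
of that breed's individuals that are heterozygous or homozygous for a
discordant allele stays within a tolerance (0 by default: all called
individuals identical homozygotes). Missing calls neither break nor
extend a run, and a SNP with no calls in the breed ends the extension.
The critical interval is the maximal contiguous stretch, containing the
anchor, of SNPs present in every run with all runs carrying the same
allele. Intersection is order-invariant, and adding a breed can only
narrow it.

Affected dogs are grouped by the haplotype they carry rather than forced
into a single per-breed consensus: a breed that is homozygous for the
*other* allele at the anchor (or uncalled there) forms its own haplotype
group and is excluded from the shared-haplotype intersection, with the
exclusion reported. At least two concordant breeds are required.

## The simulator

Validation needs data with known truth, so the package ships a generative
multi-breed simulator rather than relying on any particular array
dataset. It emulates exactly the three structural features the analysis
exploits, and no more:

* **Ancestral pool.** Per-SNP allele frequencies are drawn from a
  U-shaped Beta(0.5, 0.5) rescaled to (0.05, 0.95); haplotypes come from
  a latent Gaussian first-order process whose correlation decays as
  $\exp(-d/L)$ with distance $d$ and scale $L$ = 500 kb by default,
  thresholded at each SNP's frequency quantile. Marker positions follow
  a Poisson process with 50 kb mean spacing.
* **Breeds.** Each breed draws 10 founder haplotypes from the pool
  (the bottleneck that creates long within-breed LD and across-breed
  heterogeneity) and then drifts for 20 generations of random union with
  recombination (1 cM/Mb) at a census of 50 haplotypes. The census keeps
  residual within-breed heterozygosity near 0.15–0.2 — roughly what array
  data from real breeds shows — while the founding bottleneck preserves
  the IBD sharing structure. Genotypes are two haplotypes drawn from the
  final pool; 2% of calls are masked missing.
* **The sweep.** One pool haplotype is chosen as the trait haplotype; at
  the causal SNP its allele is made the pool-*minor* allele (a trait
  variant that arose once should be the rarer allele ancestrally).
  In every affected breed, both haplotypes of every dog are overwritten
  with this haplotype across a 1 Mb core around the causal SNP — IBD
  fixation shared across all affected breeds — with each breed eroding
  the core's flanks by a geometric number of SNPs (mean 2 per side),
  which creates the staggered run endpoints the fine-mapping intersection
  needs. Phenotype is deterministic given breed: the trait is fixed
  within breeds, so there is no penetrance model.

The default scenario mirrors the motivating study design: 9 affected
breeds carrying 20 case dogs and 13 control breeds carrying 31 control
dogs, on a reduced genome of 5 chromosomes × 400 SNPs (a desk-scale
stand-in for a 38-autosome, ~50,000-SNP array at the same marker
density). A Wright-Fisher-style pool-plus-drift model was chosen over a
coalescent simulator deliberately: it is small, dependency-free, exactly
reproducible from one seed, and sufficient for the three properties
above. What it does **not** emulate: mutation, gene conversion,
population growth, variable recombination maps, array ascertainment
beyond the frequency floor, genotyping error (only missingness), or
realistic inter-breed phylogeny (breeds are exchangeable draws from one
pool). Passing the simulation-based checks therefore demonstrates that
the pipeline recovers the signal its assumptions describe — not that
those assumptions hold for any particular real dataset.

### The null scenario and calibration

The calibration check asks that, with no planted sweep, the genome-wide
minimum corrected p-value falls below 0.05 in about 5% of replicates. An
individual-label permutation test is exact only when status is randomized
at the permuted unit, so the null scenario uses 24 single-dog breeds with
a random 12/12 case/control split: breed-level and individual-level
randomization then coincide and the check isolates the permutation
machinery itself. With multi-dog breeds the same check would fail for a
real statistical reason — permuting individuals under breed-level
assignment understates the null variance — which is a property of the
method (and of the standard tooling it mirrors), not of this
implementation; the association section above documents it as the reason
for the many-breeds design and the support-ratio rule.

## Validation scales

The test suite and the acceptance script run entirely on simulated or
constructed data, at sizes chosen to give each check statistical teeth
while keeping the whole suite at desk scale: exhaustive-vs-Monte-Carlo
permutation agreement on samples small enough to enumerate (50,000
Monte-Carlo permutations, 3-standard-error band); 1,000 random 2×2 tables
against the closed-form statistic at $10^{-10}$; 100 random two-SNP
datasets against a grid-plus-simplex maximizer of the explicit likelihood
at $10^{-4}$; 500 random 10-SNP datasets against an independent
re-implementation of the four-gamete partition; 50 replicates of the
default scenario for locus, sweep and interval recovery (500 permutations
per replicate — the max-T ranking that determines the top SNP is
insensitive to the permutation count); and 200 null replicates at 399
permutations for calibration.

## Known limitations

* Permutation p-values treat dogs as exchangeable; with breed-fixed
  status they are anticonservative, which is why acceptance of a locus
  additionally requires a 100-fold support ratio.
* The EM reports one mode; for symmetric ties it sits at a saddle by
  design. Block width is capped at 12 SNPs.
* The sweep normalization diverges for nearly-fixed case windows; the
  profile is descriptive, not a test.
* PED/MAP input assumes biallelic autosomal SNPs sorted by position;
  binary PLINK files, VCF, multiallelic sites and sex chromosomes are out
  of scope.
* The simulator's breeds are exchangeable and neutral apart from the one
  planted sweep; no claim is made about demographic realism.
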