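---
title: "Methods: bin maps, ridge QTL scans and candidate screening in backcross RILs"
author: "brilqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin maps, ridge QTL scans and candidate screening in backcross RILs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brilqtl)
```

## Scope and model of the data

`brilqtl` implements the inference chain that leads from low-coverage
genotyping-by-sequencing (GBS) calls in a biparental backcross recombinant
inbred line (BRIL) population to candidate genes under seedling
cold-tolerance QTLs. The population emulated throughout is a BC1F9: an F1
between a cold-tolerant donor (a wild rice accession) and a recurrent
*indica* parent, backcrossed once to the recurrent parent and advanced by
eight generations of single-seed descent. Under this design the expected
donor genome share is 25% and residual heterozygosity is
0.5 x (1/2)^8 ~ 0.2% of the genome. Genotype calls are coded A
(recurrent-parent homozygote), H (heterozygote) and B (donor homozygote).

Because the original genotype matrix is not publicly distributable, the
package carries a first-class simulator that generates every input with
known ground truth; all statistical machinery is tested against that truth.

## The simulator

**Meiosis.** Gametes are formed without crossover interference: the number
of crossovers per chromosome is Poisson with mean equal to the chromosome's
genetic length in Morgans, and crossover positions are uniform on the
genetic scale. Each simulated chromosome has a uniform cM/bp rate, so
positions are also uniform in bp. This is deliberately the same
no-interference model that underlies the Haldane mapping function used in
map construction, making the simulator and the estimator a matched pair.

**Genome.** The default `rice_genome()` has 12 chromosomes with physical
sizes scaled to rice (23-45 Mb, ~373 Mb total) and 2341.9 cM of genetic
length apportioned by physical size. The default marker grid is 150 evenly
spaced markers per chromosome (1800 genome-wide) — a desk-scale stand-in
for a ~55k GBS SNP set that keeps simulation studies fast; marker density
is a single argument when higher resolution is wanted.

**Observation noise.** `observe_gbs()` models ~2x effective coverage: each
call is missing with probability 0.15; surviving heterozygotes are called
as a random homozygote with probability 0.4 (at ~2 reads, sampling only one
allele is the dominant error mode); homozygotes flip with probability 0.01.
These three rates are the package's choice of realistic defaults for
low-coverage GBS and are plain arguments.

**Phenotype.** Survival after cold treatment is a bounded proportion, so
the generative model is liability-logistic-binomial: per line, liability =
sum(effect x donor dosage) + intercept + N(0, residual SD); survival
probability is the inverse logit; the observed rate is Binomial(30, p)/30,
matching a 30-seedling assay. `plant_qtls()` converts target liability-scale
variance shares (default ten QTLs at 2-7%, nine donor-increasing) into
additive effects assuming dosage variance 4p(1-p) at donor frequency
p = 0.25, and sets the residual SD so the liability variance is 1. Note two
dilutions between the planted shares and the observed phenotype: the
logistic squashing, and the binomial sampling noise of ~p(1-p)/30. The
realized phenotype-scale PVE per QTL is therefore somewhat below the
planted liability share; this matters for power (below).

**Counts.** The cold time course (0 h, 4 h, 12 h in duplicate) is
negative-binomial: counts ~ NB(mean = baseline x 2^lfc x size factor,
dispersion), with planted log2 fold-changes per gene and timepoint and a
truth table per contrast. Default DE-gene counts scale the proportions seen
in rice cold time courses (about 0.7%/1.5% of genes up/down at 4 h,
3.2%/5.3% at 12 h, with ~94%/87% of the 4-h responses sustained at 12 h).
The simulator does not emulate read-level artifacts, mapping bias, or
outlier dispersion genes, so passing tests demonstrate correctness of the
set algebra and normalization, not robustness to those real-data features.

## SNP filtering

`filter_snps()` retains markers with missing fraction <= 0.5 and minor
allele frequency >= 0.05, the conventional thresholds for such populations.
Boundary semantics are strict on the removal side (removed when strictly
above 50% missing or strictly below 5% MAF); MAF is computed on allele
counts over non-missing calls with H contributing one allele of each kind.
Heterozygote handling before binning is configurable (`het_policy` in
`build_bin_map()`): the default keeps H as a genuine third state because a
BC1F9 still segregates residual heterozygosity.

## Bin-map construction

Per line and chromosome the call vector is smoothed with a centered
sliding window (default 15 markers) requiring a 70% majority among
non-missing calls, then weakly supported blocks — physical span < 250 kb
AND fewer than 5 sequenced SNPs — are masked to avoid false double
recombination. Breakpoints are placed at the midpoint between the flanking
informative markers of each A/H/B transition (the unbiased choice given no
read-level information). Population-wide bin boundaries are the union of
all lines' breakpoints plus chromosome ends; bins are half-open
[start, end) intervals that tile each chromosome exactly. Bin genotypes are
the constant track call per bin; cells under masked regions are missing and
are filled by nearest-flank imputation (physical midpoint distance, ties to
the left flank) — a deliberately transparent replacement for HMM-style
imputation that is easy to validate by mask-and-recover experiments
(>= 95% restoration at 10% masking in the test suite).

Two numerical caveats are documented rather than hidden. First, the
original study never states its window length; 15 markers is this package's
default for ~2x-coverage noise. Its physical span scales inversely with
marker density: at the desk-scale grid (one marker per ~210 kb) a 15-marker
window spans ~3 Mb and absorbs genuine short segments, which shortens the
estimated genetic map in full-noise desk-scale runs; at a realistic 55k-SNP
density the same window spans ~100 kb. Second, breakpoint midpoints from
different lines may almost coincide, producing occasional very narrow bins;
they are harmless to the scan (near-duplicate columns) and are kept.

## Genetic map

Adjacent-bin recombination fractions use only homozygous call pairs
(heterozygotes carry ambiguous phase at fixation) and at least 10
informative lines. The observed mismatch frequency R is corrected for the
pedigree before applying the Haldane function d = -50 ln(1 - 2r):

- `BC`: r = R;
- `RIL_self` (F1-derived selfed RILs): R = 2r/(1+2r), r = R/(2-2R);
- `BC1_RIL` (this design): R = 3r/(2+4r), r = 2R/(3-4R).

The BC1-RIL transition is derived by conditioning on the F1 gamete that
made the BC1 plant: with probability (1-r)/2 it is a double heterozygote
whose selfed descent follows the classic 2r/(1+2r); with probability r it
is a single heterozygote that fixes a recombinant genotype with probability
1/2; homozygous configurations contribute no mismatch. Simulation recovery
(planted 500 cM genome, 500 lines, clean calls) reproduces the total within
a few percent, while the uncorrected selfed-RIL formula shrinks it by
~25% — which is why the package implements the exact form. Pairs whose r is
not estimable are interpolated from physical distance times the
chromosome-average cM/bp.

## Ridge-regression scan and QTL calling

All bins are fit jointly: y (mean survival proportion, centered, used
untransformed by default with an arcsine option) on column-standardized
donor dosage (A/H/B = 0/1/2; additive coding, dominance out of scope).
Coefficients are (X'X + lambda I)^-1 X'y via the SVD. The penalty is chosen
by generalized cross-validation with one guard: when bins outnumber lines
the unconstrained GCV criterion is minimized by the interpolating fit
(tr(H) -> n, RSS -> 0), which destroys inference; the search is therefore
restricted to penalties keeping tr(H) <= n/2, where the criterion has a
well-behaved interior minimum (effective model df ~ 15-20 for 1700 bins x
132 lines). Standard errors come from the ridge sandwich covariance with
sigma^2 estimated on n - tr(H) residual df, and two-sided p-values from the
t distribution on those df. This is a concrete, type-I-calibrated stand-in
for the unreported inference rule of the original ridge analysis: under
null simulations the bin-wise false-positive fraction at the 0.005
threshold stays below 1% in the test suite.

QTLs are declared by the peak-bin rule: each maximal run of contiguous bins
with p < 0.005 yields one QTL located at its lowest-p bin, named
qSCT<chromosome> (with .1/.2 suffixes), signed by the peak coefficient
(positive = donor increases survival). No multiplicity correction beyond
the fixed genome-wide bin threshold is applied, matching standard practice
for this design.

**Variance decomposition.** The phenotypic variance explained is
apportioned among the peak bins by the LMG statistic: the average over all
orderings of the sequential R^2 increment when each predictor enters,
computed by exact enumeration over all 2^k subsets with factorial weights
(identical to averaging over k! orderings, verified to 1e-10 against a
brute-force oracle). Shares sum exactly to the full OLS R^2 on the peak
bins; both the per-QTL shares and the full-model R^2 are reported, since
the two totals answer different questions. Enumeration is limited to 15
QTLs; an ordering-sampling mode is intentionally not provided.

**Power under the emulated conditions.** With 132 lines, a QTL explaining
5% of the phenotypic variance has a marginal t of ~2.6 (p ~ 0.01), so at
the 0.005 threshold per-QTL detection power ranges from ~0.1 (2% PVE) to
~0.5-0.7 (7% PVE, before the liability-to-rate dilution). Summed over ten
planted QTLs, the expected number detected is 3-4, and that is what
simulation studies with this package show (median 3/10 recovered within
+-2 bins across seeds). Any scan calibrated to the null cannot do much
better at this sample size; detecting ten 2-7% QTLs at p < 0.005 from 132
lines requires anti-conservative inference. Users should read small-effect
QTL lists from populations of this size accordingly.

## Transcript utilities

TPM corrects counts for gene length, then depth:
TPM = 1e6 (count/length) / sum(count/length); every sample column sums to
one million by construction and the suite asserts conservation to 1e-6
relative. DEG set overlap reports exact cardinalities with percentages
rounded half-up to one decimal (the reporting convention of the field).
Time-course classes partition the DE genes into early-only, sustained,
late-only and reversed from the 0-4 h and 0-12 h contrasts. Relative qPCR
quantification uses 2^-ddCt with replicate Ct values averaged per gene and
condition. Enrichment is the upper-tail hypergeometric test against a
user-supplied term-to-gene map with Benjamini-Hochberg correction; term
databases themselves are out of scope.

## Candidate screening

Genes overlapping a QTL interval by >= 1 bp (1-based inclusive coordinates,
GFF3 convention; BED converted on read) are tiered: (1) expressed
(max TPM >= 1 in any sample) and cold-responsive (present in the DEG
table), (2) expressed only, (3) not detectably expressed; within tiers,
best FDR then largest |log2FC|. Promoter allele pairs are compared by
global alignment (match +1, mismatch -1, gap open -5, gap extend -1;
alignment identity < 50% is rejected as non-homologous), with variants
reported on allele-A coordinates relative to the predicted start codon
(position -1 is the base immediately 5' of the ATG). Motif disruption is a
literal-string screen — the biological question concerns a specific
element, e.g. a MADS-box-associated A-rich element, not a PWM family — on
both strands of both alleles; a hit is "lost" when the homologous span in
the other allele (mapped through the alignment) carries no hit, and the
variants inside the lost span are reported as the candidate cause.

## Reproducibility and problem sizes

All randomness flows through R's global RNG; `simulate_study(seed = )`
makes an entire study reproducible byte-for-byte. The test suite and the
acceptance script run desk-scale problems chosen as the package's own
defaults: 1800 markers and 132 lines for pipeline runs, ~200-locus genomes
for repeated power/calibration studies (tens of replicates), and counts
matrices of a few thousand genes. Scaling any of these up is a matter of
arguments, not code.

## Known limitations

- No hidden-Markov genotype calling from read depths; the smoothing window
  is a pragmatic substitute whose fidelity to the original study's
  unpublished parameters is unknown.
- Breakpoint placement at inter-marker midpoints cannot resolve double
  crossovers within a marker interval; genetic maps shrink accordingly at
  low marker density.
- Adjacent-pair map estimation, not multipoint EM; with dense bins and
  hundreds of lines the difference is small but not zero.
- The ridge p-value rule is a calibrated reconstruction, not the original
  (unpublished) one; absolute QTL counts from real data will differ.
- DE calling itself (negative-binomial Wald tests) is consumed, not
  implemented.
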