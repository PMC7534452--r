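---
title: "Methods: simulating and analysing a recurrent-parent NAM panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a recurrent-parent NAM panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(namqtl)
set.seed(1)
```

`namqtl` simulates and analyses nested association mapping (NAM) panels of
the kind built in *Arabidopsis thaliana*: a set of F8 recombinant inbred
line (RIL) populations that all share one recurrent parent (coded REF
everywhere) crossed to a different alternate founder each. This vignette
records the statistical model behind each module, the numerical choices,
and the resolutions of the design questions that come up when the pieces
are wired together. Function-level detail lives in the help pages; the
worked example lives in the README; the `analysis/` scripts run the whole
workflow at study scale.

## Genetic model and generator

**Genome and founders.** A chromosome specification gives each chromosome a
physical length (bp) and a genetic length (cM); the default
`default_chrom_spec()` is a five-chromosome genome of Arabidopsis-like
proportions (~480 cM). Dense biallelic SNPs are placed uniformly at a
chosen density (SNPs/Mb) and each alternate founder carries the
non-reference allele at an independent random subset of them, so crosses
differ in which SNPs segregate. cM positions interpolate linearly in bp
within a chromosome.

**Meiosis and inbreeding.** Gametes are generated by an interference-free
(Poisson) crossover process on the cM map: crossover count ~
Poisson(length/100), positions uniform in cM. RILs are bred by single-seed
descent to F8, giving expected residual heterozygosity
$(1/2)^{7} \approx 0.8\%$. Genotypes are stored as integer codes
(`GENO_REF = 0`, `GENO_ALT = 1`, `GENO_HET = 2`, `NA` missing), letters
`A/B/H/-` on disk.

**GBS observation model.** Each population observes its own marker set:
markers are drawn uniformly from the SNPs polymorphic in that cross, so
marker sets rarely overlap across populations — the property that makes a
joint NAM analysis non-trivial. Observed calls are thinned to a
per-population missing rate and corrupted at a per-call error rate
(default 0.2%).

*Realism and limits.* The generator reproduces the study conditions the
panel design targets (14 populations, ~137–150 lines each, 563–1525
markers with 16–27% missing), but it is deliberately idealised: no
crossover interference, no segregation distortion (except where planted by
`simulate_incompatibility()`), error and missingness independent of
genotype, and founders drawn independently rather than from a real
population's LD structure. Consequences are noted where they bite below.

## Map functions and map estimation

Kosambi is the working map function
($d = 25\,\ln\frac{1+2r}{1-2r}$, $r = \tfrac12\tanh(d/50)$), with Haldane
available. Observed RIL recombinant fractions are corrected for the map
expansion accumulated over selfing generations with the
Haldane–Waddington relation $R = 2r/(1+2r)$, inverted as
$r = R/(2(1-R))$.

`estimate_map()` chains adjacent-interval estimates: lines homozygous and
non-missing at both markers are informative, the recombinant share among
them is the $\hat R$, and cM positions are cumulative sums. Two
data-hygiene rules matter more than the formulas:

- **Estimate from observed calls, never from fill-in imputed ones.**
  Filled cells copy their flanks, so they add concordant pairs while
  breakpoint-spanning runs stay missing and are excluded — recombinants
  are selectively discarded and the map deflates (by ~25% at study-scale
  missingness). `simulate_nam_panel()` keeps `geno_observed` for exactly
  this use.
- **Screen genotyping errors first.** Every erroneous call adds a
  spurious recombinant pair to two intervals; at a 0.2% error rate on
  sub-cM intervals this inflates the map by ~20%.
  `correct_genotype_errors()` reverts observed calls whose own-state
  multipoint posterior falls below 0.5: a singleton error is outvoted by
  its neighbours (posterior ≪ 0.5) while a call adjacent to a true
  breakpoint keeps posterior ≈ 1 − ε, so breakpoints survive.

After both corrections the estimated length sits a little below the
generating length: Kosambi assumes interference the Poisson generator
lacks (a ~2% shortfall, since the estimator converges to
`kosambi_d(haldane_r(d))`), and the error screen sacrifices genuine
single-marker haplotype blocks.

## Imputation: fill-in, posterior filter, dense projection

`fill_in_missing()` is deliberately conservative: a maximal missing run is
filled only when both nearest flanking calls are the same homozygous
state; runs at chromosome ends, at breakpoints (differing flanks) or with
a heterozygous flank stay missing, and observed calls are never altered.

`genotype_probabilities()` is a three-state hidden Markov model per
chromosome: stationary distribution $((1-h)/2, (1-h)/2, h)$ with
$h = (1/2)^{t-1}$, transitions from interval cM through the map function
and the RIL correction, emissions $1-\varepsilon$ on the observed call and
$\varepsilon/2$ elsewhere, missing calls uninformative. The
forward–backward pass is vectorised over lines and validated against an
exhaustive path-enumeration oracle in the tests.

`filter_low_confidence()` reverts filled cells whose posterior for the
filled state is below 0.99. **The posteriors must be computed on the
observed (pre-fill) matrix**: computed on the filled matrix, every filled
call would certify itself through its own emission and the filter becomes
inert. Computed on the observed matrix, a filled cell's confidence comes
only from its flanking evidence, which is what the filter is supposed to
interrogate. At study-scale parameters this pipeline takes ~22% missing
GBS calls to a few percent with fill accuracy above 99.5%.

`impute_parental_snps()` projects the dense founder SNPs into each line:
an interval between consecutive homozygous GBS anchors of the same state
assigns the interior dense SNPs that parent's allele. Heterozygous calls
are **ignored, not treated as interval breakers**: a selfed RIL's HET call
is as likely residual heterozygosity or error as a real short segment, and
treating it as an anchor would propagate it into many dense calls.
Conditional on homozygous truth, the projected-call error in a like-
anchored interval of length $d$ cM is bounded by the double-crossover
probability $(d/100)^2$ (`double_crossover_error_rate()`); the bound holds
for unequal sub-intervals because $4 d_1 d_2 \le (d_1 + d_2)^2$. Raw
mismatch against truth is instead dominated by residual F8 heterozygosity
(~0.5%), which no homozygous projection can represent — the tests and the
acceptance script separate the two effects.

## QTL scans

`scan_qtl()` is a single-QTL maximum-likelihood interval scan on one
population. At a fully observed marker the normal-mixture likelihood
degenerates to ordinary regression and the LOD equals the regression LOD
exactly (tested to 1e-6); with missing or heterozygous calls an EM step
weights lines by their multipoint genotype probabilities. Genome-wide
significance uses permutation of the phenotype (default 1000 permutations,
95th percentile of the genome-wide maximum), and localisation uses
1.5-LOD support intervals, extended outward to the last marker within
1.5 LOD of the (leftmost, in ties) peak. With a single complete marker the
permutation threshold converges on
$\chi^2_{1,0.95} / (2\ln 10) \approx 0.834$ LOD, a closed form the tests
check.

## Joint NAM association

Populations are merged on the union of dense SNPs (population-prefixed
line names). `collapse_perfect_ld()` removes dense SNPs whose genotype
*and missingness* pattern duplicates an earlier SNP on the same
chromosome, keeping a representative map for reconstruction.
`build_joint_map()` keeps SNPs carried (polymorphic) by at least a minimum
number of alternate founders, blanking populations where a SNP is
monomorphic.

Association uses a single-random-effect linear mixed model
$y = \mu + x\beta + u + e$, $u \sim N(0, \sigma^2_g K)$, with the
realised-relationship kinship $K = Z Z^\top / p$ on centred, mean-imputed
genotypes. The eigendecomposition of $K$ is computed once and reused
across SNPs; for each SNP the rotated profile likelihood is optimised over
$\log \lambda \in [-5, 5] \cdot \log 10$ and significance comes from a
likelihood-ratio test against $\chi^2_1$. **K-only, no fixed population
effects:** in a recurrent-parent NAM the population structure is exactly
what the kinship blocks encode, and the tests confirm the model holds the
type-I error at nominal level under block structure while plain OLS is
anticonflated by orders of magnitude. With $K = I$ the LMM collapses to
OLS ($\mathrm{LRT} = n \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$), a further
exact identity in the tests.

## LD decay and the incompatibility screen

`pairwise_r2()` is the squared Pearson correlation of allele dosages over
pairwise-complete homozygous calls (≥3 pairs). Under independence its
expectation is $1/(n-1)$, which sets a noise floor: a single population of
a few dozen lines never decays below $r^2 = 0.1$ within 10 Mb, and the
decay distance is reported `NA` in that case rather than extrapolated.
Pooling populations shortens the decay distance monotonically — the
panel's argument for joint mapping resolution.

`interchromosomal_screen()` tests thinned between-chromosome SNP pairs for
association ($r^2$ against a permutation-free $\chi^2$ reference with
Bonferroni control) and reports the two-locus homozygote frequency table
of each hit; a planted lethal homozygote combination (epistatic
incompatibility purged during inbreeding) shows up as the near-empty cell.

## Power pipelines

`nam_power_engine()` simulates phenotypes on the real panel genotypes and
asks, for subsets of 1..14 populations and a grid of QTL effect sizes
(PVE), how often the mixed-model scan detects the QTL. Subsets drop whole
populations from the end of a fixed random order so the series is nested;
for a QTL private to one founder that population is placed first so every
subset contains it. `density_comparison()` contrasts support-interval
width and detection at sparse versus dense marker spacing on identical
phenotypes, so a density effect is isolated from sampling noise.
`summarize_power()` reports the knee of the power curve (the smallest
subset within ε of the plateau).

## Problem sizes and budgets

Defaults reproduce the study scale (14 populations, ~140–150 lines,
hundreds of markers). The tests and the acceptance script run on
desk-scale versions of the same design — two chromosomes, 50 lines per
population, reduced marker density — chosen so the full suite runs in a
few minutes on one CPU while keeping every qualitative property being
asserted (LD nesting needs ≥50 lines per population to clear the
$1/(n-1)$ noise floor; power curves need ≥100 replicates for stable
rates). Every stochastic assertion is seeded and tolerances are stated in
standard-error units where the quantity is a Monte-Carlo estimate.
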