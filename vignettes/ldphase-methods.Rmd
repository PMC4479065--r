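---
title: "Models and methods behind ldphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ldphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ldphase` estimates linkage disequilibrium (LD), cross-population
consistency of gametic phase, ancestral effective population size and
genomic relationships from unphased SNP-array genotypes, and ships a
forward simulator that provides phased ground truth for validating every
estimator. This vignette explains the models, the parameters that matter,
the numerical conventions, and what the validation experiments do and do
not establish.

## The composite LD estimator

For two biallelic loci, the natural LD measure is the squared correlation
of allelic state, `r² = D² / (f(A) f(a) f(B) f(b))` with
`D = f(AB) − f(A) f(B)`. Computing `f(AB)` requires phased haplotypes,
which samples of typical chip studies (tens to a few hundred animals) do
not support reliably. `ldphase` therefore uses the Burrows-type composite
disequilibrium, computable from the two-locus genotype counts of `N`
individuals:

    D = N/(N−1) · [ (4·N_AABB + 2·(N_AABb + N_AaBB) + N_AaBb)/(2N) − 2·f(A)·f(B) ]

The bracketed count is algebraically the per-individual mean of the
product of the two dose columns divided by two, which is how the
vectorized engine evaluates it (`pair_stats`). The composite D absorbs
both gametic and non-gametic (within-individual, between-gamete)
disequilibrium; under random mating the non-gametic part is zero in
expectation, and the package's oracle test shows correlation above 0.95
between composite r² and the true haplotype-frequency r² on simulated
random-mating samples of 100 diploids.

Numerical conventions:

* **Capping.** The `N/(N−1)` factor and non-HWE genotype configurations
  can push `D²/(f(A)f(a)f(B)f(b))` slightly above 1 (an `N = 4`
  perfect-coupling table yields 16/9). Since r² is a squared correlation
  with range [0, 1], values are capped at 1; the cap events are flagged
  per pair (`capped`) so the rate is auditable.
* **Signed r** is `sign(D)·√r²`. Capped pairs contribute ±1.
* **Missing genotypes** are handled pairwise-complete: `N` and both
  allele frequencies are computed on the individuals called at *both*
  markers of the pair. Pairs with fewer than two complete observations,
  or with a locus monomorphic among them, are skipped and counted.
* **Small-sample correction.** `(r² − 1/N)/(1 − 1/N)` with `N` the number
  of haplotypes (twice the individuals), floored at 0, is available
  everywhere as an option; raw r² is the primary scale, because the shift
  is small (≈0.008 at 48 individuals and r² = 0.25) and keeping the raw
  scale makes bins comparable with the bulk of the chip literature.

Pairs are computed within chromosome only, by default up to 15 Mb — far
beyond the last decay bin, because the ancestral-Ne analysis needs pairs
out to `c = 0.1` Morgan (10 Mb at 1 cM/Mb).

## Distance bins

The decay summary uses 20 bins: below 0.02 Mb, 0.02–0.1 Mb in 0.01 steps,
0.1–1 Mb in 0.1 steps, 1–1.2 Mb, and beyond 1.2 Mb. Binning is half-open
`[lo, hi)` with ties going to the upper bin; the first bin is effectively
`(0, 0.02)` since pair distances are positive. Empty bins are reported
with a count of zero rather than dropped, so tables from different
populations align row by row.

## Consistency of gametic phase

For two populations, phase consistency is the Pearson correlation of
signed r over marker pairs that pass QC in both, per distance bin (at
least 3 shared pairs and non-zero variance on both sides, otherwise the
bin is flagged). It measures whether the sign and strength of marker–marker
association transfers between populations — the prerequisite for pooling
them into one genomic-selection training set.

The single most dangerous failure mode of this statistic is silent
orientation drift: if one population counts the other allele at some
marker, every signed r involving that marker flips sign. `ldphase`
therefore records the reference allele per marker inside every genotype
container and LD table, and `shared_pairs()` refuses to align tables whose
orientation registries disagree (and also verifies that shared pairs agree
on physical distance, which catches tables built from different maps). The
sign-flip construction — recoding every odd-indexed marker in a copy of a
population — is part of the test suite and yields exactly −1 for
mixed-parity pairs.

Alongside the per-bin table, a compact matrix layout reports one pooled
window above the diagonal (default: all pairs below 0.2 Mb) and one below
(default: 0.02–0.03 Mb). Pooling pairs, rather than averaging per-bin
correlations, is the chosen aggregation; the alternative gives similar
values but weights thin bins equally with rich ones.

## Ancestral effective population size

Under drift–recombination equilibrium without mutation, Sved's expectation
links LD to effective size: `E(r²) = 1/(1 + 4·Ne·c)` with `c` the genetic
distance in Morgans. LD at distance `c` reflects the effective size
roughly `t = 1/(2c)` generations ago, so sweeping a grid of times maps the
demographic trajectory. The default grid is 21 log-spaced points from 5 to
1500 generations; for each `t` the pairs whose genetic distance falls
within ±10% of `c = 1/(2t)` are averaged and the expectation inverted
(`Ne = (1/r̄² − 1)/(4c)`).

Parameters that matter:

* **`cm_per_mb`** (default 1 cM/Mb). The physical-to-genetic conversion
  scales every `c`, and hence every Ne, linearly. It is the largest single
  assumption in the analysis; it is an explicit argument and is recorded
  in the run manifest.
* **`window_frac`** (default 0.10). Wider windows smooth the trajectory at
  the cost of mixing time depths; the pair count per point is reported so
  thin windows are visible.
* **Raw vs corrected r²** (default raw). The correction lowers r̄²,
  raising Ne estimates by roughly `2n/(4c)`-scaled amounts; at the sample
  sizes the package targets the difference is within the sampling noise.

Interpretation caveats: the Sved formula is an approximation whose quality
varies with `4·Ne·c` and with the allele-frequency spectrum that survives
QC (MAF filtering removes the low-frequency pairs that drag r̄² down).
Validation on the package's own simulator recovers a constant Ne = 100
within ±30% at `t` ∈ {10, 20, 50}, and a 500→50 bottleneck 50 generations
ago is reproduced qualitatively (recent Ne well below ancient Ne, with the
ancient level attenuated toward the present — LD windows mix adjacent time
depths, so step changes appear smoothed). Absolute values at any single
time point should be read with those calibration widths in mind.

## Quality control

QC is per population (allele-frequency-based filters are only meaningful
within a random-mating group) and applies, in order: (1) individuals with
call rate below 0.90; (2) removal of non-autosomal/unmapped markers
(chromosome codes outside 1–29 by default, the goat karyotype); (3)
per-SNP filters on the remaining individuals — MAF (0.05 for large
samples, 0.15 for small ones, per configuration), SNP call rate 0.90,
Hardy–Weinberg χ² with 1 df and no continuity correction at p < 10⁻⁶, and
heterozygosity excess `Ho − He > 0.15`. Individual-level QC runs first so
that bad samples cannot distort the SNP statistics; the order is a design
choice (the alternative order changes counts only marginally on clean
data) and is fixed and documented rather than configurable.

The report counts failures per criterion on the post-autosome marker set;
a SNP can fail several criteria, so per-criterion counts can exceed the
unique total but never the reverse, and
`remaining + unique-failing + non-autosomal = input` is a tested
invariant. "Heterozygosity excess" is defined as observed minus expected
heterozygosity (a proportion), the most common reading; the threshold and
definition live in one function (`het_excess`) should a different
convention be needed. Missing genotypes are never imputed, except inside
the G-matrix construction, which specifies its own imputation.

## Genomic relationships and PCA

The relationship matrix is VanRaden's
`G = (M − 2P)(M − 2P)′ / (2·Σ pᵢ(1−pᵢ))`, with `pᵢ` the pooled frequency
over all populations in the analysis. Missing doses are imputed with twice
the *within-population* allele frequency before centering. This asymmetry
— pooled frequencies for centering and scaling, within-population
frequencies for imputation — is deliberate: the imputed value is the
individual's best within-group expectation, while the relationship scale
is defined on the pooled sample being compared. Markers monomorphic in the
pooled sample contribute nothing to the denominator and are dropped with a
warning.

For a joint PCA across populations that were QC'd separately, the marker
set is the intersection of the per-population survivor sets — the
conservative choice, since every retained marker then satisfies every
population's filters. Principal components come from the symmetric
eigendecomposition of G; scores are eigenvectors scaled by the square root
of (the non-negative part of) their eigenvalues, and each component's sign
is fixed so its largest-magnitude loading is positive, making output
reproducible bit for bit.

## The simulator: what it emulates, and what it does not

`wf_simulate()` is a discrete-generation Wright–Fisher diploid simulator:
random mating with replacement (selfing allowed), recombination as Poisson
crossovers on a uniform genetic map (`cm_per_mb`, no interference,
chromosomes assorting independently), population splits that copy the
parent's haplotypes at the stated generation, and admixture as a
single-generation replacement of a fraction of one population's parents by
individuals from another. Founder haplotypes are drawn site-wise
independently with frequencies uniform on (0.1, 0.9); a burn-in (default
`4·Ne` generations) then builds the equilibrium LD that a finite
random-mating population carries. There is no mutation after
initialization, matching the model without mutation that underlies the
Sved expectation. The final sample of each population is drawn as one
extra offspring generation of the requested size, so samples larger than
Ne are possible (they then contain sibs, as a real herd sample would). The
per-generation gamete kernel is implemented in C++ but draws from R's RNG,
so a seed fixes the entire simulation bit for bit.

The simulator emulates: drift at configurable Ne with known trajectories,
equilibrium LD decay, divergence and admixture between populations, a
SNP-chip-like marker panel (configurable density and missing-call rate)
and the ascertainment-like conditioning that QC imposes afterwards. It
does **not** emulate: mutation, selection, non-uniform recombination maps,
genotyping error beyond missingness, pedigree structure beyond what random
mating produces, or the SNP-discovery ascertainment of a real chip (real
50k panels are enriched for intermediate frequencies in the discovery
breeds). Consequently, passing validation here shows the estimators are
correct under their stated model; it does not certify accuracy under
selection, map heterogeneity or chip ascertainment.

## Validation experiment sizes

The test-suite and acceptance-script experiments are sized to finish in a
few minutes on one CPU while keeping the statistical checks sharp; the
sizes are the package's own choices:

* **Drift calibration**: 500 unlinked-ish loci, Ne = 100, 200 generations;
  the variance of the standardized per-generation frequency change matches
  `1/(2Ne)` within three standard errors.
* **Oracle agreement**: 100 diploids, 500 pairs; composite vs haplotype
  r² correlation > 0.95.
* **Constant-Ne recovery**: 29 chromosomes × 15 Mb × 700 markers
  (mirroring the 29-autosome genome the panel targets), Ne = 100, burn-in
  400, 200 diploids sampled; ±30% at `t` ∈ {10, 20, 50}. Twenty-nine
  moderate chromosomes beat fewer long ones here because long-range LD is
  correlated within a chromosome: independent chromosomes, not extra
  markers, shrink the between-seed spread.
* **Bottleneck**: 8 × 12 Mb × 700 markers, Ne 500 → 50 at 50 generations
  ago, with a 1000-generation ancestral epoch: equilibration is only
  needed at the probed time depths (`t ≤ 200`), and a full `4·Ne` burn-in
  would drift most of the panel out through the MAF filter, starving the
  short-distance windows.
* **Phase vs divergence**: splits at 0/20/100 generations, Ne = 100,
  compared in the 0.5–1.0 Mb window. At very short range ancestral LD
  persists almost unchanged and consistency stays near 1 for every
  divergence level (conditioning on joint polymorphism after deep drift
  even nudges it up); at 0.5–1 Mb recombination turnover during the
  divergence period dominates and the decrease is clean and monotone —
  the same pattern as the fastest decay at long distances seen on real
  breed pairs.
* **PCA separation**: 50 + 50 diploids from populations of Ne = 500 split
  200 generations ago, short (100-generation) burn-in. Sampling half of a
  small population creates sib clusters that can hijack the leading
  principal component — a real phenomenon, but not the setting emulated
  here, where chip studies genotype a few dozen animals from breeds of
  thousands. PCA depends on allele-frequency divergence, not LD
  equilibrium, so the short burn-in is appropriate.

## Known limitations

* The composite estimator is validated under random mating; under strong
  inbreeding or family structure the non-gametic component biases r²
  upward, and Ne estimates inherit that bias.
* The Mb→Morgan conversion is a global constant; organisms with strong
  recombination heterogeneity need a per-interval map, which the data
  model does not currently carry.
* Ne inversion assumes equilibrium at each probed depth; trajectories with
  very recent sharp changes appear smoothed across neighbouring time
  points.
* PLINK text files declare no allele order, so the reader pins the
  reference allele as the first allele of the first heterozygote (first
  allele seen, if none); a marker with no heterozygous call and only
  hom-alt genotypes is monomorphic in-file and its orientation cannot be
  recovered from a `.ped` alone. The binary dialect carries A1/A2
  explicitly and round-trips exactly.
* D′ and haplotype-based persistence measures are out of scope by design;
  r² is less sensitive to allele frequency and sample size.
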