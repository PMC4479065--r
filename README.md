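# ldphase

Linkage disequilibrium, consistency of gametic phase, and ancestral
effective population size from medium-density SNP-array genotypes.

`ldphase` is aimed at population and livestock geneticists who want to
judge, from a 50k-class SNP chip, whether a panel is dense enough for
within-breed genomic selection (is r² between adjacent markers above the
≈0.2 rule of thumb?), whether two populations can share a genomic-selection
training set (does marker–marker phase transfer between them?), and what
the demographic history of each population looks like (how has Ne changed
over the last ~1500 generations?).

## What it computes

Samples of typical chip studies are too small to phase reliably, so gametic
D is replaced by the Burrows-type composite estimator computed from the
two-locus genotype counts of `N` individuals:

    D = N/(N−1) · [ (4·N_AABB + 2·(N_AABb + N_AaBB) + N_AaBb)/(2N) − 2·f(A)·f(B) ]

    r² = D² / ( f(A) f(a) f(B) f(b) ),   capped at 1
    signed r = sign(D) · √r²

From these, per population:

* **QC** (`apply_qc`) — within-population filters with per-criterion
  accounting: MAF, SNP call rate, Hardy–Weinberg χ² (1 df), heterozygosity
  excess (Ho − He), individual call rate, autosomes only.
* **LD decay** (`ld_pairs`, `adjacent_ld`, `ld_decay`) — all
  within-chromosome pairs up to a maximum distance, adjacent-marker
  summaries, and means over a 20-bin distance scheme (<0.02 Mb; 0.02–0.1
  by 0.01; 0.1–1 by 0.1; 1–1.2; >1.2). An optional small-sample correction
  `(r² − 1/N)/(1 − 1/N)` (N = haplotypes) is available.
* **Phase consistency** (`shared_pairs`, `phase_consistency`) — Pearson
  correlation of signed r between two populations over marker pairs
  passing QC in both, per distance bin; a registry of per-marker dose
  orientation makes silent sign corruption impossible.
* **Ancestral Ne** (`ne_trajectory`) — inverts Sved's drift–recombination
  expectation `E(r²) = 1/(1 + 4·Ne·c)` at genetic distances `c = 1/(2t)`
  Morgans to estimate Ne roughly `t` generations ago, on a log-spaced grid
  of 21 time points from 5 to 1500 generations.
* **Structure** (`build_G`, `pca_g`) — VanRaden genomic relationship
  matrix `G = (M−2P)(M−2P)′ / 2Σpᵢ(1−pᵢ)` (missing doses imputed with
  twice the within-population allele frequency) and its principal
  components.

A forward Wright–Fisher diploid simulator (`sim_config`, `wf_simulate`)
with recombination, population splits and admixture pulses generates
phased ground truth against which every estimator is validated. PLINK
text (`.ped/.map`) and binary (`.bed/.bim/.fam`) files are read and
written natively (`read_plink`, `write_plink`).

## Worked example

Two populations that split 30 generations ago, analysed end to end
(about half a minute on one CPU):

```r
library(ldphase)

cfg <- sim_config(n_chromosomes = 10, chrom_length_mb = 10,
                  n_markers_per_chrom = 800, ne = 100,
                  split_events = data.frame(gen_ago = 30,
                                            parent = "A", child = "B"),
                  sample_sizes = c(A = 60, B = 60),
                  burn_in = 400, seed = 61)
pops <- lapply(wf_simulate(cfg), to_genotypes, missing_rate = 0.02, seed = 62)

res <- run_all(pops, run_config(qc = qc_config(maf_min = 0.05),
                                max_dist_mb = 6,
                                ne_time_points = c(10, 20, 50),
                                out_dir = "reports", seed = 61))
res$qc_table[, c("pop", "fail_maf", "fail_any", "n_remaining")]
#>   pop fail_maf fail_any n_remaining
#> A   A     7030     7048         952
#> B   B     7084     7088         912
res$adjacent[res$adjacent$chrom == "Overall", c("pop", "mean_r2", "mean_dist_mb")]
#>  pop   mean_r2 mean_dist_mb
#>    A 0.7801379   0.08463132
#>    B 0.8232045   0.08643851
round(res$phase_matrix, 2)
#>      A    B
#> A   NA 0.95
#> B 0.99   NA
subset(res$ne, pop == "A", c(t, n_pairs, mean_r2, ne))
#>   t n_pairs    mean_r2       ne
#>  10    5674 0.03903057 123.1047
#>  20    4776 0.07141353 130.0295
#>  50    2422 0.13808679 156.0456
```

Reading the output: 400 generations of drift at Ne = 100 push most
founder variants below the 0.05 MAF bar, leaving a chip-like panel of
roughly 950 markers per population at ≈0.085 Mb spacing; between adjacent
markers mean r² ≈ 0.8, far above the 0.2 level useful for genomic
prediction (tight linkage at Ne = 100 is strong); the populations split
only 30 generations ago, so their gametic phase is still nearly
interchangeable — 0.95 below 0.2 Mb (above diagonal), 0.99 in the
0.02–0.03 Mb bin (below diagonal) — and they could share a training set;
and the Ne trajectory places the effective size at 123–156 across the
probed depths, the right magnitude for the simulated Ne = 100 given this
deliberately small 100 Mb genome (the calibrated recovery experiment in
`scripts/acceptance.R` uses a 29-chromosome genome and lands within a few
percent). `reports/` contains the same tables as CSV plus a manifest of
every threshold and seed.

A command-line wrapper with `simulate` and `run` subcommands is installed
under `exec/ldphase` (YAML configs; see `inst/exec/ldphase`).

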