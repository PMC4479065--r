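# Per-population genotype quality control with per-criterion accounting.
# QC is meant to be run within population: allele-frequency-based filters
# (MAF, HWE, heterozygosity excess) are only meaningful inside a
# random-mating group.

#' QC configuration
#'
#' Thresholds for SNP- and individual-level quality control.  A SNP is
#' removed when its minor allele frequency is below `maf_min`, its call
#' rate is below `snp_call_rate_min`, its Hardy-Weinberg chi-squared
#' p-value is below `hwe_p_min`, or its heterozygosity excess (observed
#' minus expected heterozygosity) exceeds `het_excess_max`.  Individuals
#' with call rate below `ind_call_rate_min` are removed first, and
#' non-autosomal or unmapped markers (chromosome code outside `autosomes`)
#' are set aside before the SNP statistics are computed.
#'
#' @param maf_min Minimum minor allele frequency (typically 0.05 for large
#'   samples, 0.15 for small ones).
#' @param snp_call_rate_min Minimum per-SNP call rate.
#' @param hwe_p_min Hardy-Weinberg equilibrium p-value threshold.
#' @param het_excess_max Maximum tolerated heterozygosity excess Ho - He.
#' @param ind_call_rate_min Minimum per-individual call rate.
#' @param autosomes_only Drop markers whose chromosome code is not in
#'   `autosomes`?
#' @param autosomes Vector of autosome codes (default 1-29, the goat
#'   karyotype).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.05,
                      snp_call_rate_min = 0.90,
                      hwe_p_min = 1e-6,
                      het_excess_max = 0.15,
                      ind_call_rate_min = 0.90,
                      autosomes_only = TRUE,
                      autosomes = 1:29) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1,
            ind_call_rate_min >= 0, ind_call_rate_min <= 1)
  structure(list(maf_min = maf_min,
                 snp_call_rate_min = snp_call_rate_min,
                 hwe_p_min = hwe_p_min,
                 het_excess_max = het_excess_max,
                 ind_call_rate_min = ind_call_rate_min,
                 autosomes_only = autosomes_only,
                 autosomes = autosomes),
            class = "qc_config")
}

#' Per-marker allele and genotype statistics
#'
#' Frequencies are computed over non-missing calls only.
#'
#' @param doses Dose vector or individuals x markers matrix (0/1/2/NA).
#' @return Data frame, one row per marker: `n_called`, `call_rate`,
#'   `n_AA`, `n_Aa`, `n_aa` (genotype counts by reference-allele dose
#'   2/1/0), `f_A` (reference allele frequency), `maf`, `het_obs`.
#'   All-missing markers get `call_rate` 0 and `NA` frequencies.
#' @export
allele_stats <- function(doses) {
  if (!is.matrix(doses)) doses <- matrix(doses, ncol = 1L)
  n <- nrow(doses)
  called <- !is.na(doses)
  n_called <- as.integer(colSums(called))
  n_AA <- as.integer(colSums(doses == 2L, na.rm = TRUE))
  n_Aa <- as.integer(colSums(doses == 1L, na.rm = TRUE))
  n_aa <- as.integer(colSums(doses == 0L, na.rm = TRUE))
  f_A <- ifelse(n_called > 0, (2 * n_AA + n_Aa) / (2 * n_called), NA_real_)
  data.frame(n_called = n_called,
             call_rate = n_called / n,
             n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
             f_A = f_A,
             maf = pmin(f_A, 1 - f_A),
             het_obs = ifelse(n_called > 0, n_Aa / n_called, NA_real_),
             row.names = colnames(doses))
}

#' Hardy-Weinberg equilibrium chi-squared test
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype
#' counts against the expected `n p^2`, `2 n p q`, `n q^2` computed from
#' the observed allele frequency; no continuity correction.  Monomorphic
#' loci return statistic 0 and p-value 1 (they can never fail the HWE
#' filter).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorized).
#' @return Data frame with columns `chi2` and `p`.
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(all(n >= 1))
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  eAA <- n * p^2; eAa <- 2 * n * p * q; eaa <- n * q^2
  chi2 <- ifelse(p == 0 | q == 0, 0,
                 (n_AA - eAA)^2 / eAA + (n_Aa - eAa)^2 / eAa +
                   (n_aa - eaa)^2 / eaa)
  data.frame(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Heterozygosity excess
#'
#' Observed minus expected heterozygosity, `Ho - He`, with `Ho` the
#' observed heterozygote fraction and `He = 2pq` from the observed allele
#' frequency.  Monomorphic loci return 0.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (vectorized).
#' @return Numeric vector.
#' @export
het_excess <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  stopifnot(all(n >= 1))
  p <- (2 * n_AA + n_Aa) / (2 * n)
  n_Aa / n - 2 * p * (1 - p)
}

#' Apply quality control to one population
#'
#' Order of application: (1) individuals with call rate below
#' `ind_call_rate_min` are removed; (2) non-autosomal/unmapped markers are
#' set aside; (3) per-SNP statistics are computed on the remaining
#' individuals and SNPs failing the MAF, call-rate, HWE or
#' heterozygosity-excess criteria are removed.  Per-criterion counts are
#' reported on the post-step-2 marker set; a SNP can fail several criteria
#' at once, so their sum can exceed the unique total.
#'
#' @param g A [genotypes] object holding a single population.
#' @param config A [qc_config()] object.
#' @return List with elements `genotypes` (filtered; may have zero
#'   markers), `report` (a `qc_report`), `removed_markers` and
#'   `removed_individuals` (identifiers with failure reasons).
#' @export
apply_qc <- function(g, config = qc_config()) {
  stopifnot(inherits(g, "genotypes"), inherits(config, "qc_config"))
  if (length(unique(g$samples$pop)) > 1L)
    warning("apply_qc expects a single population; received ",
            length(unique(g$samples$pop)))
  n_input <- ncol(g$doses)

  # (1) individual call rate
  ind_cr <- rowMeans(!is.na(g$doses))
  ind_keep <- ind_cr >= config$ind_call_rate_min
  removed_individuals <- data.frame(
    id = g$samples$id[!ind_keep],
    call_rate = ind_cr[!ind_keep], stringsAsFactors = FALSE)
  g1 <- subset_genotypes(g, individuals = which(ind_keep))

  # (2) non-autosomal / unmapped markers
  if (config$autosomes_only) {
    autosomal <- g1$map$chrom %in% config$autosomes & !is.na(g1$map$pos)
  } else {
    autosomal <- rep(TRUE, ncol(g1$doses))
  }
  n_non_autosomal <- sum(!autosomal)
  g2 <- subset_genotypes(g1, markers = which(autosomal))

  # (3) per-SNP statistics on the remaining individuals
  st <- allele_stats(g2$doses)
  poly <- !is.na(st$maf) & st$maf > 0 & st$n_called > 0
  hwe_p <- rep(1, nrow(st))
  hexc <- rep(0, nrow(st))
  if (any(poly)) {
    hwe_p[poly] <- hwe_chi2(st$n_AA[poly], st$n_Aa[poly], st$n_aa[poly])$p
    hexc[poly] <- het_excess(st$n_AA[poly], st$n_Aa[poly], st$n_aa[poly])
  }
  fail_maf <- is.na(st$maf) | st$maf < config$maf_min
  fail_cr <- st$call_rate < config$snp_call_rate_min
  fail_hwe <- hwe_p < config$hwe_p_min
  fail_het <- hexc > config$het_excess_max
  fail_any <- fail_maf | fail_cr | fail_hwe | fail_het

  removed_markers <- data.frame(
    name = g2$map$name[fail_any],
    maf = fail_maf[fail_any], call_rate = fail_cr[fail_any],
    hwe = fail_hwe[fail_any], het_excess = fail_het[fail_any],
    stringsAsFactors = FALSE)

  g3 <- subset_genotypes(g2, markers = which(!fail_any))

  report <- structure(list(
    pop = unique(g$samples$pop)[1],
    n_input_snps = n_input,
    n_individuals = nrow(g$doses),
    n_individuals_removed = sum(!ind_keep),
    n_non_autosomal = n_non_autosomal,
    n_fail_maf = sum(fail_maf),
    n_fail_call_rate = sum(fail_cr),
    n_fail_hwe = sum(fail_hwe),
    n_fail_het_excess = sum(fail_het),
    n_fail_any = sum(fail_any),
    n_remaining = ncol(g3$doses)
  ), class = "qc_report")

  list(genotypes = g3, report = report,
       removed_markers = removed_markers,
       removed_individuals = removed_individuals)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report, population '", x$pop, "' (", x$n_individuals,
      " individuals, ", x$n_input_snps, " SNPs)\n", sep = "")
  cat("  individuals removed (call rate): ", x$n_individuals_removed, "\n",
      "  non-autosomal/unmapped SNPs:     ", x$n_non_autosomal, "\n",
      "  failing MAF: ", x$n_fail_maf,
      "  call rate: ", x$n_fail_call_rate,
      "  HWE: ", x$n_fail_hwe,
      "  het excess: ", x$n_fail_het_excess, "\n",
      "  failing >=1 criterion: ", x$n_fail_any,
      "  remaining: ", x$n_remaining, "\n", sep = "")
  invisible(x)
}

#' Collect QC reports into one table
#'
#' @param reports List of `qc_report` objects.
#' @return Data frame, one row per population, mirroring the usual
#'   per-criterion accounting layout.
#' @export
qc_report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r)
    data.frame(pop = r$pop, n_individuals = r$n_individuals,
               n_individuals_removed = r$n_individuals_removed,
               n_input_snps = r$n_input_snps,
               n_non_autosomal = r$n_non_autosomal,
               fail_maf = r$n_fail_maf, fail_call_rate = r$n_fail_call_rate,
               fail_hwe = r$n_fail_hwe, fail_het_excess = r$n_fail_het_excess,
               fail_any = r$n_fail_any, n_remaining = r$n_remaining,
               stringsAsFactors = FALSE)))
}
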