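test_that("allele_stats counts frequencies over non-missing calls", {
  st <- allele_stats(c(2L, 2L, 1L, 0L))
  expect_equal(st$f_A, 5 / 8)
  expect_equal(st$maf, 0.375)
  expect_equal(st$call_rate, 1)
  expect_identical(c(st$n_AA, st$n_Aa, st$n_aa), c(2L, 1L, 1L))

  mono <- allele_stats(c(2L, 2L, 2L, 2L))
  expect_equal(mono$maf, 0)

  set.seed(6)
  col <- rbinom(50, 2, 0.3)
  col[sample(50, 5)] <- NA
  st2 <- allele_stats(col)
  ok <- !is.na(col)
  expect_equal(st2$n_called, sum(ok))
  expect_equal(st2$f_A, sum(col[ok]) / (2 * sum(ok)))
  expect_equal(st2$het_obs, mean(col[ok] == 1))

  allmiss <- allele_stats(rep(NA_integer_, 4))
  expect_equal(allmiss$call_rate, 0)
  expect_true(is.na(allmiss$f_A))
})

test_that("HWE chi-squared matches the direct goodness-of-fit formula", {
  expect_equal(hwe_chi2(25, 50, 25), data.frame(chi2 = 0, p = 1))

  h <- hwe_chi2(0, 30, 0)
  expect_equal(h$chi2, 30)
  expect_equal(h$p, pchisq(30, 1, lower.tail = FALSE))
  expect_lt(h$p, 1e-6)
  expect_equal(h$p, 4.3e-8, tolerance = 0.01)

  set.seed(8)
  for (k in 1:10) {
    cnt <- rmultinom(1, 40, c(0.3, 0.45, 0.25))
    n <- sum(cnt); p <- (2 * cnt[1] + cnt[2]) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    expect_equal(hwe_chi2(cnt[1], cnt[2], cnt[3])$chi2,
                 sum((cnt - e)^2 / e))
  }
  # monomorphic: never a reason for exclusion
  expect_equal(hwe_chi2(10, 0, 0), data.frame(chi2 = 0, p = 1))
})

test_that("het_excess is Ho minus 2pq", {
  expect_equal(het_excess(0, 30, 0), 1 - 0.5)
  expect_equal(het_excess(25, 50, 25), 0)
  expect_equal(het_excess(10, 0, 0), 0)
  set.seed(9)
  for (k in 1:10) {
    cnt <- rmultinom(1, 60, c(0.2, 0.5, 0.3))
    n <- sum(cnt); p <- (2 * cnt[1] + cnt[2]) / (2 * n)
    expect_equal(het_excess(cnt[1], cnt[2], cnt[3]),
                 cnt[2] / n - 2 * p * (1 - p))
  }
})

test_that("apply_qc reproduces hand-verified per-criterion accounting", {
  g <- qc_fixture()
  res <- apply_qc(g, qc_config(maf_min = 0.15, ind_call_rate_min = 0))
  r <- res$report
  expect_equal(r$n_input_snps, 8L)
  expect_equal(r$n_non_autosomal, 1L)
  expect_equal(r$n_fail_maf, 2L)
  expect_equal(r$n_fail_call_rate, 1L)
  expect_equal(r$n_fail_hwe, 1L)
  expect_equal(r$n_fail_het_excess, 1L)
  expect_equal(r$n_fail_any, 3L)      # s2 fails two criteria, s3 fails two
  expect_equal(r$n_remaining, 4L)
  expect_equal(r$n_individuals_removed, 0L)
  expect_setequal(res$genotypes$map$name, paste0("s", 5:8))

  # idempotent: re-filtering the survivors removes nothing
  res2 <- apply_qc(res$genotypes, qc_config(maf_min = 0.15,
                                            ind_call_rate_min = 0))
  expect_equal(res2$report$n_fail_any, 0L)
  expect_identical(res2$genotypes$map$name, res$genotypes$map$name)
})

test_that("vacuous thresholds remove nothing", {
  g <- qc_fixture()
  cfg <- qc_config(maf_min = 0, snp_call_rate_min = 0, hwe_p_min = 0,
                   het_excess_max = 1, ind_call_rate_min = 0,
                   autosomes_only = FALSE)
  res <- apply_qc(g, cfg)
  expect_equal(res$report$n_remaining, 8L)
  expect_equal(res$report$n_fail_any, 0L)
})

test_that("low-call-rate individuals are removed before SNP statistics", {
  g <- random_genotypes(n = 10, m = 8, missing_rate = 0, seed = 71)
  # one individual loses half its calls
  g$doses[1, c(1, 3, 5, 7)] <- NA_integer_
  res <- apply_qc(g, qc_config(maf_min = 0, snp_call_rate_min = 0.9,
                               ind_call_rate_min = 0.9))
  expect_equal(res$report$n_individuals_removed, 1L)
  expect_equal(res$removed_individuals$id, g$samples$id[1])
  # SNP stats computed on the 9 remaining, fully called individuals:
  # no SNP can then fail the call-rate criterion
  expect_equal(nrow(res$genotypes$doses), 9L)
  expect_equal(res$report$n_fail_call_rate, 0L)
})

test_that("QC bookkeeping identity holds on random inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40L; m <- 30L
    doses <- sapply(runif(m, 0.02, 0.6), function(p) rbinom(n, 2, p))
    doses[matrix(runif(n * m) < 0.08, n, m)] <- NA_integer_
    g <- genotypes(doses,
                   map = data.frame(chrom = sample(c(1:5, 30), m, TRUE),
                                    pos = as.integer(seq(1e5, by = 5e4,
                                                         length.out = m)),
                                    name = sprintf("x%02d", 1:m)),
                   samples = data.frame(id = sprintf("n%02d", 1:n),
                                        pop = "rp"))
    r <- apply_qc(g, qc_config(maf_min = 0.1))$report
    expect_equal(r$n_remaining + r$n_fail_any + r$n_non_autosomal,
                 r$n_input_snps)
    per_criterion <- r$n_fail_maf + r$n_fail_call_rate + r$n_fail_hwe +
      r$n_fail_het_excess
    expect_gte(per_criterion, r$n_fail_any)
  }
})
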