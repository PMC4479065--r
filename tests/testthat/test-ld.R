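test_that("composite_D reproduces hand-evaluated fixtures", {
  # independence at f(A) = f(B) = 0.5, N = 16: D = 0
  indep <- matrix(c(1, 2, 1,
                    2, 4, 2,
                    1, 2, 1), 3, 3, byrow = TRUE)
  expect_equal(composite_D(indep), 0)

  # N = 4 perfect coupling: D = (4/3) * (0.75 - 0.5) = 1/3
  coup <- matrix(c(1, 0, 0,
                   0, 2, 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(composite_D(coup), 1 / 3)

  # swapping allele labels at one locus negates D
  expect_equal(composite_D(coup[3:1, ]), -1 / 3)
  expect_equal(composite_D(indep[, 3:1]), 0)

  expect_error(composite_D(matrix(c(2, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "monomorphic")
  expect_error(composite_D(diag(c(1, 0, 0))), "N < 2")
})

test_that("pair_r2 evaluates, caps and signs the composite estimator", {
  # independence fixture as dose vectors (the 9-class table with N = 16)
  ind_x <- rep(c(2, 1, 0), c(4, 8, 4))
  ind_y <- c(2, 1, 1, 0, 2, 2, 1, 1, 1, 1, 0, 0, 2, 1, 1, 0)
  res <- pair_r2(ind_x, ind_y)
  expect_equal(res$D, 0)
  expect_equal(res$r2, 0)
  expect_equal(res$r, 0)

  # N = 4 coupling fixture: raw ratio (1/3)^2 / 0.0625 = 16/9 -> capped
  cp <- pair_r2(c(2, 1, 1, 0), c(2, 1, 1, 0))
  expect_equal(cp$D, 1 / 3)
  expect_equal(cp$r2, 1)
  expect_equal(cp$r, 1)
  expect_true(cp$capped)

  expect_error(pair_r2(c(2, NA, NA, 0), c(NA, 1, 1, NA)), "complete")
  expect_error(pair_r2(c(2, 2, 2), c(1, 0, 1)), "monomorphic|complete")
})

test_that("pair statistics match brute-force formula evaluation", {
  set.seed(10)
  for (k in 1:20) {
    n <- sample(10:60, 1)
    x <- rbinom(n, 2, runif(1, 0.2, 0.8))
    y <- rbinom(n, 2, runif(1, 0.2, 0.8))
    x[runif(n) < 0.1] <- NA; y[runif(n) < 0.1] <- NA
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || length(unique(x[ok])) == 1 ||
        length(unique(y[ok])) == 1) next
    bf <- brute_force_D(x, y)
    res <- pair_r2(x, y)
    expect_equal(res$D, bf$D)
    expect_equal(res$r2, bf$r2)
    expect_equal(res$r, bf$r)
    expect_equal(res$n, bf$n)
  }
})

test_that("recoding alleles flips D and r but never r2", {
  set.seed(11)
  x <- rbinom(40, 2, 0.4); y <- rbinom(40, 2, 0.6)
  a <- pair_r2(x, y)
  b <- pair_r2(2 - x, y)      # one locus recoded
  cc <- pair_r2(2 - x, 2 - y) # both recoded
  expect_equal(b$D, -a$D)
  expect_equal(b$r, -a$r)
  expect_equal(b$r2, a$r2)
  expect_equal(cc$D, a$D)
  expect_equal(cc$r2, a$r2)
})

test_that("correct_r2 follows the haplotype-count correction", {
  expect_equal(correct_r2(1 / 96, 48), 0)
  expect_equal(correct_r2(1, 48), 1)
  corr <- correct_r2(0.25, 48)
  expect_equal(corr, (0.25 - 1 / 96) / (1 - 1 / 96))
  expect_equal(corr, 0.2421, tolerance = 1e-3)
  expect_lt(0.25 - corr, 0.01)  # small-sample shift below 0.01 units
  # corrected never exceeds raw for r2 <= 1, floored at 0
  set.seed(12)
  r2 <- runif(50)
  expect_true(all(correct_r2(r2, 100) <= r2))
  expect_true(all(correct_r2(r2, 100) >= 0))
})

test_that("the default decay scheme has exactly 20 contiguous bins", {
  b <- default_bins()
  expect_equal(b$n_bins, 20L)
  expect_equal(b$edges, c(0, 2:10 / 100, 2:10 / 10, 1.2, Inf))
  expect_true(all(diff(b$edges) > 0))
  # 0.025 Mb falls in [0.02, 0.03); edge value 0.02 goes to the upper bin
  expect_equal(assign_bins(0.025, b), 2L)
  expect_equal(assign_bins(0.02, b), 2L)
  expect_equal(assign_bins(0.0199, b), 1L)
  expect_equal(assign_bins(5, b), 20L)
})

test_that("adjacent_ld averages consecutive pairs only", {
  doses <- cbind(c(2L, 1L, 0L, 2L, 1L, 0L),
                 c(1L, 2L, 0L, 1L, 0L, 2L),
                 c(0L, 1L, 2L, 1L, 2L, 0L))
  g <- genotypes(doses,
                 map = data.frame(chrom = 1,
                                  pos = c(1000001L, 1060001L, 1090001L),
                                  name = c("a", "b", "c")),
                 samples = data.frame(id = paste0("i", 1:6), pop = "t"))
  adj <- adjacent_ld(g)
  expect_equal(adj$mean_dist_mb[adj$chrom == "1"], 0.045)
  expect_equal(adj$n_pairs[adj$chrom == "1"], 2L)
  bf <- mean(c(pair_r2(doses[, 1], doses[, 2])$r2,
               pair_r2(doses[, 2], doses[, 3])$r2))
  expect_equal(adj$mean_r2[adj$chrom == "1"], bf)
  expect_equal(adj$mean_r2[adj$chrom == "Overall"], bf)
})

test_that("ld_pairs agrees with per-pair brute force on simulated data", {
  sim <- sim_pop_with_truth(seed = 31, n = 40)
  g <- sim$genotypes
  pr <- ld_pairs(g, max_dist_mb = 1)
  expect_true(all(pr$r2 >= 0 & pr$r2 <= 1))
  expect_true(all(pr$dist_mb > 0 & pr$dist_mb <= 1))
  set.seed(13)
  for (k in sample(nrow(pr), 25)) {
    i <- match(pr$marker_i[k], g$map$name)
    j <- match(pr$marker_j[k], g$map$name)
    bf <- brute_force_D(g$doses[, i], g$doses[, j])
    expect_equal(pr$D[k], bf$D)
    expect_equal(pr$r2[k], bf$r2)
    expect_equal(pr$r[k], bf$r)
    expect_equal((g$map$pos[j] - g$map$pos[i]) / 1e6, pr$dist_mb[k])
  }
})

test_that("ld_decay bins match a brute-force binning of the pair table", {
  sim <- sim_pop_with_truth(seed = 32, n = 60)
  pr <- ld_pairs(sim$genotypes, max_dist_mb = 5)
  dec <- ld_decay(pr, max_dist_mb = 5)
  expect_equal(nrow(dec), 20L)
  expect_equal(sum(dec$n_pairs), nrow(pr))
  b <- default_bins()
  for (k in c(1, 3, 10, 20)) {
    lo <- b$lo[k]; hi <- min(b$hi[k], 5 + 1e-12)
    sel <- pr$dist_mb >= lo & pr$dist_mb < hi
    if (k == 20) sel <- pr$dist_mb >= lo & pr$dist_mb <= 5
    expect_equal(dec$n_pairs[k], sum(sel))
    if (any(sel)) expect_equal(dec$mean_r2[k], mean(pr$r2[sel]))
  }
  # empty bins flagged, not dropped
  tiny <- ld_decay(fake_ld_pairs(c(0.05, 0.06), c(0.2, 0.3)), max_dist_mb = 5)
  expect_equal(sum(tiny$n_pairs), 2L)
  expect_true(is.na(tiny$mean_r2[1]))
})

test_that("mean r2 decays with distance on an equilibrium population", {
  # denser panel so each fine bin collects enough pairs
  cfg <- sim_config(n_chromosomes = 3, chrom_length_mb = 8,
                    n_markers_per_chrom = 1500, ne = 100,
                    sample_sizes = c(p = 100), burn_in = 400, seed = 33)
  pp <- wf_simulate(cfg)$p
  g <- apply_qc(to_genotypes(pp), qc_config(maf_min = 0.05))$genotypes
  dec <- ld_decay(ld_pairs(g, max_dist_mb = 5), max_dist_mb = 5)
  use <- dec$n_pairs >= 200
  mid <- ifelse(is.finite(dec$hi), (dec$lo + dec$hi) / 2, dec$lo)
  expect_gte(sum(use), 8)
  expect_lt(cor(mid[use], dec$mean_r2[use], method = "spearman"), -0.9)
})

test_that("composite r2 tracks the haplotype-truth r2", {
  sim <- sim_pop_with_truth(seed = 34, n = 100)
  pr <- ld_pairs(sim$genotypes, max_dist_mb = 2)
  set.seed(14)
  sel <- sample(nrow(pr), 200)
  i <- match(pr$marker_i[sel], sim$truth$map$name)
  j <- match(pr$marker_j[sel], sim$truth$map$name)
  hr2 <- true_haplotype_r2(sim$truth, i, j)
  expect_gt(cor(pr$r2[sel], hr2), 0.9)
})
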