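test_that("identical seed and config give bit-identical haplotypes", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_mb = 5,
                    n_markers_per_chrom = 60, ne = 30,
                    sample_sizes = c(a = 20), burn_in = 40, seed = 11)
  p1 <- wf_simulate(cfg)
  p2 <- wf_simulate(cfg)
  expect_identical(p1$a$haplotypes, p2$a$haplotypes)
  expect_identical(p1$a$map, p2$a$map)
})

test_that("per-generation drift variance matches p(1-p)/(2Ne)", {
  cfg <- sim_config(n_chromosomes = 10, chrom_length_mb = 5,
                    n_markers_per_chrom = 50,
                    ne = data.frame(span = 200, ne = 100),
                    sample_sizes = c(p = 100), burn_in = 0, seed = 99)
  pp <- wf_simulate(cfg, record_freqs = TRUE)$p
  fh <- pp$freq_history
  expect_equal(nrow(fh), 201L)  # founders + 200 generations
  # standardized squared change per transition; expectation 1/(2Ne)
  zvar <- sapply(seq_len(nrow(fh) - 1), function(g) {
    p <- fh[g, ]; ok <- p > 0 & p < 1
    mean((fh[g + 1, ok] - p[ok])^2 / (p[ok] * (1 - p[ok])))
  })
  ratio <- mean(zvar) * 2 * 100
  se <- sd(zvar) * 2 * 100 / sqrt(length(zvar))
  expect_lt(abs(ratio - 1), 3 * se)
})

test_that("zero recombination copies founder haplotypes unchanged", {
  base <- list(n_chromosomes = 1, chrom_length_mb = 5,
               n_markers_per_chrom = 80, ne = 30,
               sample_sizes = c(a = 30), cm_per_mb = 0, seed = 5)
  founders <- wf_simulate(do.call(sim_config, c(base, burn_in = 0)))$a
  evolved <- wf_simulate(do.call(sim_config, c(base, burn_in = 40)))$a
  # same seed, same map draw, so the founder pool is shared
  founder_rows <- unique(apply(founders$haplotypes, 1, paste, collapse = ""))
  evolved_rows <- apply(evolved$haplotypes, 1, paste, collapse = "")
  expect_true(all(evolved_rows %in% founder_rows))
})

test_that("to_genotypes sums haplotype pairs and masks at missing_rate", {
  haps <- rbind(c(1L, 1L, 0L), c(1L, 0L, 0L),
                c(0L, 1L, 1L), c(0L, 0L, 1L))
  pp <- phased_pop(haps, data.frame(chrom = 1, pos = c(1e5, 2e5, 3e5),
                                    name = c("a", "b", "c")), "t")
  g <- to_genotypes(pp, missing_rate = 0)
  expect_identical(unname(g$doses),
                   rbind(c(2L, 1L, 0L), c(0L, 1L, 2L)))
  expect_false(anyNA(g$doses))

  cfg <- sim_config(n_chromosomes = 1, chrom_length_mb = 10,
                    n_markers_per_chrom = 500, ne = 100,
                    sample_sizes = c(p = 100), burn_in = 0, seed = 3)
  big <- to_genotypes(wf_simulate(cfg)$p, missing_rate = 0.05, seed = 4)
  n_entries <- length(big$doses)  # 100 x 500 = 5e4
  miss <- sum(is.na(big$doses))
  ci <- qbinom(c(0.005, 0.995), n_entries, 0.05)
  expect_gte(miss, ci[1])
  expect_lte(miss, ci[2])
})

test_that("true_haplotype_r2 matches direct haplotype counting", {
  mk <- function(tab) {
    # tab: counts of haplotypes (AB, Ab, aB, ab)
    h <- rbind(matrix(1L, tab[1], 2),
               cbind(rep(1L, tab[2]), rep(0L, tab[2])),
               cbind(rep(0L, tab[3]), rep(1L, tab[3])),
               matrix(0L, tab[4], 2))
    if (nrow(h) %% 2L == 1L) h <- rbind(h, h[1, ])  # even rows for container
    phased_pop(h, data.frame(chrom = 1, pos = c(1e5, 2e5),
                             name = c("x", "y")), "t")
  }
  expect_equal(true_haplotype_r2(mk(c(10, 0, 0, 10)), 1, 2), 1)
  expect_equal(true_haplotype_r2(mk(c(25, 25, 25, 25)), 1, 2), 0)

  set.seed(7)
  h <- matrix(rbinom(40, 1, 0.5), 20, 2)
  while (length(unique(h[, 1])) == 1 || length(unique(h[, 2])) == 1)
    h <- matrix(rbinom(40, 1, 0.5), 20, 2)
  pp <- phased_pop(h, data.frame(chrom = 1, pos = c(1e5, 2e5),
                                 name = c("x", "y")), "t")
  fA <- mean(h[, 1]); fB <- mean(h[, 2]); fAB <- mean(h[, 1] * h[, 2])
  expected <- (fAB - fA * fB)^2 / (fA * (1 - fA) * fB * (1 - fB))
  expect_equal(true_haplotype_r2(pp, 1, 2), expected)
  expect_error(true_haplotype_r2(mk(c(20, 0, 0, 0)), 1, 2), "monomorphic")
})

test_that("inconsistent split ordering is a configuration error", {
  expect_error(
    sim_config(sample_sizes = c(a = 10, b = 10, c = 10),
               split_events = data.frame(gen_ago = c(50, 100),
                                         parent = c("a", "b"),
                                         child = c("b", "c"))),
    "before it exists")
})

test_that("admixture pulse moves haplotypes from source into target", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_mb = 5,
                    n_markers_per_chrom = 100, ne = 40,
                    split_events = data.frame(gen_ago = 200, parent = "a",
                                              child = "b"),
                    admixture_events = data.frame(gen_ago = 2, target = "b",
                                                  source = "a",
                                                  proportion = 0.5),
                    sample_sizes = c(a = 40, b = 40),
                    burn_in = 100, seed = 21)
  mixed <- wf_simulate(cfg)
  cfg$admixture_events <- NULL
  pure <- wf_simulate(cfg)
  # allele-frequency distance between a and b shrinks under admixture
  fd <- function(ps) mean((colMeans(ps$a$haplotypes) -
                             colMeans(ps$b$haplotypes))^2)
  expect_lt(fd(mixed), fd(pure))
})
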