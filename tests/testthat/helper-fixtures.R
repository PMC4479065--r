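# Fixtures built in code; nothing is read from disk.

# Small genotypes object with known content.
toy_genotypes <- function() {
  doses <- rbind(c(2L, 1L, 0L, 2L),
                 c(1L, 1L, 1L, NA),
                 c(0L, 2L, 2L, 1L))
  genotypes(doses,
            map = data.frame(chrom = c(1, 1, 2, 2),
                             pos = c(100000L, 160000L, 50000L, 75000L),
                             name = paste0("m", 1:4)),
            samples = data.frame(id = paste0("i", 1:3), pop = "toy"),
            ref_allele = c("A", "C", "G", "T"),
            alt_allele = c("G", "T", "A", "C"))
}

# Random genotypes with missing calls, for round-trip and property tests.
random_genotypes <- function(n = 12, m = 8, missing_rate = 0.1,
                             pop = "rnd", seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  doses <- sapply(p, function(pi) rbinom(n, 2L, pi))
  doses[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
  letters_pairs <- c("A", "C", "G", "T")
  ref <- sample(letters_pairs, m, replace = TRUE)
  alt <- sapply(ref, function(r) sample(setdiff(letters_pairs, r), 1))
  genotypes(doses,
            map = data.frame(chrom = rep(1:2, each = ceiling(m / 2))[seq_len(m)],
                             pos = as.integer(50000 * seq_len(m)),
                             name = sprintf("r%02d", seq_len(m))),
            samples = data.frame(id = sprintf("%s_%02d", pop, seq_len(n)),
                                 pop = pop),
            ref_allele = ref, alt_allele = unname(alt))
}

# One split pair sharing a single marker map, for cross-population tests.
sim_split_pair <- function(seed = 45, gen_ago = 30, n = 50L) {
  cfg <- sim_config(n_chromosomes = 3, chrom_length_mb = 8,
                    n_markers_per_chrom = 400, ne = 100,
                    split_events = data.frame(gen_ago = gen_ago,
                                              parent = "A", child = "B"),
                    sample_sizes = c(A = n, B = n),
                    burn_in = 400, seed = seed)
  pops <- wf_simulate(cfg)
  lapply(pops, function(p)
    apply_qc(to_genotypes(p), qc_config(maf_min = 0.05))$genotypes)
}

# 8-SNP QC fixture (30 individuals, maf_min = 0.15), with hand-verifiable
# accounting.  Meant to exercise the SNP-level criteria: with only 8
# markers a single missing call already drops an individual below the
# usual 0.90 call-rate bar, so pair it with ind_call_rate_min = 0.
#   s1: MAF 0.05            -> fails MAF only
#   s2: call rate 0.8 and MAF ~0.04 among called -> fails MAF and call rate
#   s3: all heterozygote    -> fails HWE (chi2 = 30) and het excess (0.5)
#   s4: on chromosome 30 (sex/unmapped) -> removed as non-autosomal
#   s5-s8: well behaved, kept
# Unique SNPs failing >=1 criterion: 3 (s1, s2, s3); remaining: 4.
qc_fixture <- function() {
  n <- 30L
  s1 <- c(rep(1L, 3), rep(0L, 27))                    # f = 0.05
  s2 <- c(rep(NA_integer_, 6), rep(1L, 2), rep(0L, 22))  # CR 0.8, f = 2/48
  s3 <- rep(1L, n)                                    # all het
  s4 <- rep(c(0L, 1L, 2L), 10)                        # non-autosomal
  good <- function(k) c(rep(2L, k), rep(1L, 15L), rep(0L, 15L - k))
  doses <- cbind(s1, s2, s3, s4, good(8), good(7), good(6), good(9))
  genotypes(doses,
            map = data.frame(chrom = c(1, 1, 1, 30, 2, 2, 3, 3),
                             pos = c(1e5, 2e5, 3e5, 1e5, 1e5, 2e5, 1e5, 2e5),
                             name = paste0("s", 1:8)),
            samples = data.frame(id = sprintf("q%02d", 1:n), pop = "qcpop"))
}

# Dose-class counts for a two-locus pair, rows/cols in dose order 2/1/0.
dose_class_counts <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  table(factor(2L - x[ok], levels = 0:2),
        factor(2L - y[ok], levels = 0:2))
}

# Literal evaluation of the composite-D formula from dose vectors,
# independent of the package's vectorized engine.
brute_force_D <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  N <- length(x)
  n_AABB <- sum(x == 2 & y == 2)
  n_AABb <- sum(x == 2 & y == 1)
  n_AaBB <- sum(x == 1 & y == 2)
  n_AaBb <- sum(x == 1 & y == 1)
  fA <- mean(x) / 2; fB <- mean(y) / 2
  D <- N / (N - 1) *
    ((4 * n_AABB + 2 * (n_AABb + n_AaBB) + n_AaBb) / (2 * N) - 2 * fA * fB)
  r2 <- D^2 / (fA * (1 - fA) * fB * (1 - fB))
  list(D = D, r2 = min(r2, 1), r = sign(D) * sqrt(min(r2, 1)), n = N)
}

# Hand-rolled ld_pairs table for interface-level tests of downstream
# consumers (ne_trajectory operates on this documented contract).
fake_ld_pairs <- function(dist_mb, r2, n = 100L, pop = "fake") {
  m <- length(dist_mb)
  out <- data.frame(marker_i = sprintf("a%03d", seq_len(m)),
                    marker_j = sprintf("b%03d", seq_len(m)),
                    chrom = 1L, dist_mb = dist_mb, n = n,
                    D = r2 / 4, r = sqrt(r2), r2 = r2, capped = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "orientation") <- setNames(rep("A", 2 * m),
                                       c(out$marker_i, out$marker_j))
  attr(out, "pop") <- pop
  attr(out, "n_individuals") <- n
  attr(out, "n_skipped") <- 0L
  class(out) <- c("ld_pairs", "data.frame")
  out
}

# One QC'd simulated population plus its phased truth, shared by LD tests.
sim_pop_with_truth <- function(seed = 101, n = 100L) {
  cfg <- sim_config(n_chromosomes = 4, chrom_length_mb = 10,
                    n_markers_per_chrom = 300, ne = 100,
                    sample_sizes = setNames(n, "p"),
                    burn_in = 400, seed = seed)
  truth <- wf_simulate(cfg)$p
  qc <- apply_qc(to_genotypes(truth), qc_config(maf_min = 0.05))
  list(truth = truth, genotypes = qc$genotypes)
}
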