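# Forward Wright-Fisher diploid simulator: discrete generations, random
# mating (selfing allowed), Poisson recombination on a uniform genetic map,
# population splits and single-generation admixture pulses.  No mutation
# after founder initialization, matching the drift-recombination model that
# underlies the Sved E(r2) = 1/(1 + 4*Ne*c) expectation used downstream.

#' Simulation configuration
#'
#' Describes a multi-population Wright-Fisher simulation: the marker panel,
#' the demography (effective-size trajectories, splits, admixture pulses)
#' and the final diploid samples to draw.
#'
#' Founder haplotypes are drawn site-wise independently with allele
#' frequencies uniform on (0.1, 0.9); the burn-in then builds up the
#' equilibrium linkage disequilibrium expected of a finite random-mating
#' population.  A burn-in of at least `4 * Ne` generations is recommended
#' and is the default.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_mb Physical length of each chromosome in Mb.
#' @param n_markers_per_chrom Markers per chromosome, placed uniformly at
#'   random (positions are strictly increasing within a chromosome).
#' @param ne Effective population size: a single number (constant), a
#'   two-column data frame with columns `span` (generations) and `ne`
#'   ordered most ancient first, or a named list of either keyed by
#'   population label (unlisted populations inherit the root trajectory).
#' @param split_events `NULL` or a data frame with columns `gen_ago`,
#'   `parent`, `child`: at `gen_ago` generations before present the child
#'   population is founded as a copy of the parent and evolves
#'   independently afterwards.
#' @param admixture_events `NULL` or a data frame with columns `gen_ago`,
#'   `target`, `source`, `proportion`: in that single generation the stated
#'   fraction of the target's parents is replaced by individuals drawn from
#'   the source population.
#' @param sample_sizes Named integer vector of diploid sample sizes; names
#'   are the populations returned by [wf_simulate()].
#' @param missing_rate Default missing-genotype rate used by
#'   [to_genotypes()] when none is given there.
#' @param cm_per_mb Genetic-to-physical scale (cM per Mb); the genetic map
#'   is uniform.
#' @param burn_in Generations of burn-in before the most ancient event;
#'   default `4 *` the most ancient root Ne.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical output.
#'
#' @return An object of class `sim_config`.
#' @seealso [wf_simulate()]
#' @export
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, chrom_length_mb = 5,
#'                   n_markers_per_chrom = 50, ne = 50,
#'                   sample_sizes = c(popA = 20), burn_in = 20, seed = 1)
sim_config <- function(n_chromosomes = 3,
                       chrom_length_mb = 25,
                       n_markers_per_chrom = 500,
                       ne = 100,
                       split_events = NULL,
                       admixture_events = NULL,
                       sample_sizes = c(pop1 = 50),
                       missing_rate = 0,
                       cm_per_mb = 1,
                       burn_in = NULL,
                       seed = 1L) {
  cfg <- structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_mb = as.numeric(chrom_length_mb),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    ne = ne,
    split_events = split_events,
    admixture_events = admixture_events,
    sample_sizes = sample_sizes,
    missing_rate = as.numeric(missing_rate),
    cm_per_mb = as.numeric(cm_per_mb),
    burn_in = burn_in,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1, cfg$chrom_length_mb > 0,
            cfg$n_markers_per_chrom >= 1, cfg$cm_per_mb >= 0,
            cfg$missing_rate >= 0, cfg$missing_rate < 1,
            length(cfg$sample_sizes) >= 1,
            !is.null(names(cfg$sample_sizes)))

  sp <- cfg$split_events
  if (!is.null(sp)) {
    stopifnot(all(c("gen_ago", "parent", "child") %in% names(sp)))
    sp <- sp[order(-sp$gen_ago), , drop = FALSE]
    root <- setdiff(sp$parent, sp$child)
    if (length(root) != 1L)
      stop("split events must define a single root population")
    existing <- root
    for (k in seq_len(nrow(sp))) {
      if (!(sp$parent[k] %in% existing))
        stop("configuration error: population '", sp$parent[k],
             "' is used as a split parent before it exists")
      existing <- c(existing, sp$child[k])
    }
    cfg$root <- root
    cfg$split_events <- sp
  } else {
    cfg$root <- names(cfg$sample_sizes)[1]
  }

  ad <- cfg$admixture_events
  if (!is.null(ad)) {
    stopifnot(all(c("gen_ago", "target", "source", "proportion") %in% names(ad)),
              all(ad$proportion >= 0), all(ad$proportion <= 1))
  }

  # every epoch Ne >= 2
  trajs <- if (is.list(cfg$ne) && !is.data.frame(cfg$ne)) cfg$ne else list(cfg$ne)
  for (tr in trajs) {
    nes <- if (is.data.frame(tr)) tr$ne else tr
    if (any(nes < 2)) stop("Ne must be >= 2 in every epoch")
  }
  if (is.null(cfg$burn_in))
    cfg$burn_in <- 4L * ancient_ne(resolve_traj(cfg$ne, cfg$root))
  stopifnot(cfg$burn_in >= 0)
  cfg
}

# trajectory for one population: list(spans, nes) most ancient first,
# or a constant
resolve_traj <- function(ne, pop) {
  x <- ne
  if (is.list(x) && !is.data.frame(x)) {
    x <- if (pop %in% names(x)) x[[pop]] else x[[1L]]
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("span", "ne") %in% names(x)))
    list(spans = as.numeric(x$span), nes = as.numeric(x$ne))
  } else {
    list(spans = numeric(0), nes = as.numeric(x))
  }
}

ancient_ne <- function(traj) traj$nes[1L]

# Ne in force for the generation living t generations before present
ne_at <- function(traj, t) {
  if (length(traj$spans) == 0L) return(traj$nes)
  rs <- rev(traj$spans); rn <- rev(traj$nes)
  b <- cumsum(rs)
  i <- which(t < b)
  if (length(i) == 0L) rn[length(rn)] else rn[i[1L]]
}

sim_marker_map <- function(cfg) {
  len_bp <- round(cfg$chrom_length_mb * 1e6)
  maps <- lapply(seq_len(cfg$n_chromosomes), function(ch) {
    pos <- sort(sample.int(len_bp, cfg$n_markers_per_chrom))
    data.frame(chrom = ch, pos = pos,
               name = sprintf("snp_c%02d_%05d", ch,
                              seq_len(cfg$n_markers_per_chrom)))
  })
  do.call(rbind, maps)
}

#' Run a Wright-Fisher forward simulation
#'
#' Evolves one or more diploid populations under the configured demography
#' and returns phased samples.  Each generation is produced by random
#' mating: every offspring haplotype is a recombinant gamete of one parent
#' drawn uniformly (with replacement) from the previous generation.
#' Recombination is Poisson on the genetic map (`cm_per_mb` cM/Mb, no
#' interference); there is no mutation after founder initialization.
#' Splits copy the parent population's haplotypes at the stated
#' generation; admixture replaces a fraction of one generation's parents
#' with individuals from the source population.  The final sample of each
#' population is drawn as one more offspring generation of the requested
#' size, so samples larger than Ne are allowed.
#'
#' @param config A [sim_config()] object.
#' @param record_freqs If `TRUE`, attach to each population a
#'   `freq_history` matrix (generations x markers) of per-generation allele
#'   frequencies; useful for drift diagnostics, memory-hungry otherwise.
#' @return Named list of [phased_pop] objects, one per entry of
#'   `config$sample_sizes`.
#' @export
wf_simulate <- function(config, record_freqs = FALSE) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  map <- sim_marker_map(cfg)
  m <- nrow(map)
  gpos <- (map$pos / 1e6) * cfg$cm_per_mb / 100  # Morgans within chromosome
  chrom_rle <- rle(map$chrom)
  chrom_len <- chrom_rle$lengths
  chrom_start <- cumsum(c(0L, chrom_len[-length(chrom_len)]))

  sp <- cfg$split_events
  ad <- cfg$admixture_events
  event_gens <- c(0, if (!is.null(sp)) sp$gen_ago, if (!is.null(ad)) ad$gen_ago)
  traj_root <- resolve_traj(cfg$ne, cfg$root)
  t_hist <- max(c(event_gens, sum(traj_root$spans)))
  t_start <- t_hist + cfg$burn_in

  # founders for the root population
  n0 <- ne_at(traj_root, t_start)
  freq0 <- runif(m, 0.1, 0.9)
  pops <- list()
  pops[[cfg$root]] <- matrix(rbinom(2L * n0 * m, 1L, rep(freq0, each = 2L * n0)),
                             nrow = 2L * n0, ncol = m)
  hist_list <- if (record_freqs) setNames(list(colMeans(pops[[cfg$root]])),
                                          cfg$root) else NULL

  reproduce <- function(haps, n_next) {
    n_cur <- nrow(haps) %/% 2L
    parents <- sample.int(n_cur, 2L * n_next, replace = TRUE)
    wf_gametes_cpp(haps, parents, gpos, chrom_start, chrom_len)
  }

  for (tau in (if (t_start >= 1) seq(t_start, 1) else integer(0))) {
    # events scheduled tau generations ago act on the generation alive then
    if (!is.null(sp)) {
      for (k in which(sp$gen_ago == tau)) {
        pops[[sp$child[k]]] <- pops[[sp$parent[k]]]
      }
    }
    if (!is.null(ad)) {
      for (k in which(ad$gen_ago == tau)) {
        tgt <- ad$target[k]; src <- ad$source[k]
        if (is.null(pops[[tgt]]) || is.null(pops[[src]]))
          stop("configuration error: admixture at generation ", tau,
               " references a population that does not exist yet")
        n_tgt <- nrow(pops[[tgt]]) %/% 2L
        n_src <- nrow(pops[[src]]) %/% 2L
        n_rep <- round(ad$proportion[k] * n_tgt)
        if (n_rep > 0) {
          into <- sample.int(n_tgt, n_rep)
          from <- sample.int(n_src, n_rep, replace = TRUE)
          rows_into <- as.vector(rbind(2L * into - 1L, 2L * into))
          rows_from <- as.vector(rbind(2L * from - 1L, 2L * from))
          pops[[tgt]][rows_into, ] <- pops[[src]][rows_from, ]
        }
      }
    }
    for (pn in names(pops)) {
      t_next <- tau - 1L
      n_next <- if (t_next == 0L && pn %in% names(cfg$sample_sizes)) {
        as.integer(cfg$sample_sizes[[pn]])
      } else {
        ne_at(resolve_traj(cfg$ne, pn), t_next)
      }
      pops[[pn]] <- reproduce(pops[[pn]], n_next)
      if (record_freqs) {
        hist_list[[pn]] <- rbind(hist_list[[pn]], colMeans(pops[[pn]]))
      }
    }
  }
  # splits at generation 0: child is an identical copy of the parent sample
  if (!is.null(sp)) {
    for (k in which(sp$gen_ago == 0)) {
      pops[[sp$child[k]]] <- pops[[sp$parent[k]]]
    }
  }

  out <- lapply(names(cfg$sample_sizes), function(pn) {
    haps <- pops[[pn]]
    if (is.null(haps)) stop("population '", pn, "' was never created")
    n_want <- as.integer(cfg$sample_sizes[[pn]])
    n_have <- nrow(haps) %/% 2L
    if (n_have != n_want) {
      if (n_have < n_want)
        stop("sample size for '", pn, "' exceeds its final population size")
      keep <- sort(sample.int(n_have, n_want))
      haps <- haps[as.vector(rbind(2L * keep - 1L, 2L * keep)), , drop = FALSE]
    }
    pp <- phased_pop(haps, map, pn)
    if (record_freqs) pp$freq_history <- hist_list[[pn]]
    pp
  })
  names(out) <- names(cfg$sample_sizes)
  out
}

#' Phased population sample
#'
#' A container for phased haplotypes: a `2n x m` binary matrix (rows
#' `2k-1`, `2k` are the two haplotypes of individual `k`), the marker map,
#' and the population label.  Serves as the ground truth against which
#' genotype-based LD estimators are validated.
#'
#' @param haplotypes Binary matrix with an even number of rows.
#' @param map Marker map data frame (`chrom`, `pos`, `name`).
#' @param pop Population label.
#' @return An object of class `phased_pop`.
#' @export
phased_pop <- function(haplotypes, map, pop) {
  stopifnot(is.matrix(haplotypes), nrow(haplotypes) %% 2L == 0L,
            all(haplotypes %in% c(0L, 1L)),
            nrow(map) == ncol(haplotypes))
  structure(list(haplotypes = haplotypes, map = map, pop = pop,
                 n = nrow(haplotypes) %/% 2L),
            class = "phased_pop")
}

#' @export
print.phased_pop <- function(x, ...) {
  cat("phased_pop '", x$pop, "': ", x$n, " diploids, ",
      ncol(x$haplotypes), " markers on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Collapse phased haplotypes to unphased genotype doses
#'
#' Sums the two haplotype alleles of each individual into an allele dose
#' (0/1/2 copies of allele 1) and optionally masks entries as missing,
#' independently at `missing_rate`, emulating SNP-chip no-calls.  Phase is
#' discarded.
#'
#' @param pop A [phased_pop] object.
#' @param missing_rate Probability in \[0, 1) that an entry is set missing.
#' @param seed Optional seed for the missingness mask.
#' @return A [genotypes] object (alleles coded "A" = allele 1, "B").
#' @export
to_genotypes <- function(pop, missing_rate = 0, seed = NULL) {
  stopifnot(inherits(pop, "phased_pop"),
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  h <- pop$haplotypes
  odd <- seq(1L, nrow(h), by = 2L)
  doses <- h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  if (missing_rate > 0) {
    doses[runif(length(doses)) < missing_rate] <- NA_integer_
  }
  ids <- sprintf("%s_%03d", pop$pop, seq_len(pop$n))
  genotypes(doses,
            map = pop$map,
            samples = data.frame(id = ids, pop = pop$pop),
            ref_allele = rep("A", ncol(doses)),
            alt_allele = rep("B", ncol(doses)))
}

#' Exact haplotype-frequency r-squared
#'
#' Computes LD directly from known haplotypes: `D = f(AB) - f(A) f(B)` and
#' `r2 = D^2 / (f(A) f(a) f(B) f(b))`, where f(AB) is the observed
#' frequency of the two-locus haplotype carrying allele 1 at both markers.
#' This is the oracle against which the composite (genotype-based)
#' estimator is checked.
#'
#' @param pop A [phased_pop] object.
#' @param marker_i,marker_j Marker indices (vectors of equal length are
#'   evaluated pairwise).
#' @return Numeric vector of r-squared values in \[0, 1\].
#' @export
true_haplotype_r2 <- function(pop, marker_i, marker_j) {
  stopifnot(inherits(pop, "phased_pop"), length(marker_i) == length(marker_j))
  h <- pop$haplotypes
  fA <- colMeans(h[, marker_i, drop = FALSE])
  fB <- colMeans(h[, marker_j, drop = FALSE])
  if (any(fA %in% c(0, 1)) || any(fB %in% c(0, 1)))
    stop("undefined LD: monomorphic marker")
  fAB <- colMeans(h[, marker_i, drop = FALSE] * h[, marker_j, drop = FALSE])
  D <- fAB - fA * fB
  unname(D^2 / (fA * (1 - fA) * fB * (1 - fB)))
}
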