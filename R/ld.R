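# Pairwise linkage disequilibrium from unphased genotypes.
#
# Because samples of this size cannot be phased reliably, gametic D is
# replaced by the Burrows-type composite estimator computable from
# two-locus genotype counts:
#
#   D = N/(N-1) * [ (4 N_AABB + 2 (N_AABb + N_AaBB) + N_AaBb) / (2N)
#                   - 2 f(A) f(B) ]
#
# and r2 = D^2 / (f(A) f(a) f(B) f(b)), capped at 1.  The signed r is
# sign(D) * sqrt(r2) and carries the gametic-phase orientation compared
# across populations by the phase module.  The numerator count is
# algebraically the sum over individuals of the product of the two dose
# columns, which is how the vectorized engine computes it.

#' Distance bin scheme
#'
#' Contiguous, non-overlapping distance bins in Mb.  Assignment is to
#' half-open intervals `[lo, hi)` (ties at an edge go to the upper bin);
#' the first bin is `(0, edge_2)` since pair distances are strictly
#' positive, and the last extends to the maximum analysed distance.
#'
#' @param edges Strictly increasing numeric vector of bin edges; bin `k`
#'   is `[edges[k], edges[k+1])`.
#' @return An object of class `bin_scheme` with `edges`, `lo`, `hi`,
#'   `labels` and `n_bins`.
#' @export
bin_scheme <- function(edges) {
  stopifnot(is.numeric(edges), length(edges) >= 2, all(diff(edges) > 0))
  n <- length(edges) - 1L
  lo <- edges[-length(edges)]; hi <- edges[-1]
  structure(list(edges = edges, lo = lo, hi = hi,
                 labels = sprintf("[%g,%g)", lo, hi), n_bins = n),
            class = "bin_scheme")
}

#' Default 20-bin LD decay scheme
#'
#' The standard scheme for 50k-array LD decay: one bin below 0.02 Mb,
#' 0.02 to 0.1 Mb every 0.01 Mb, 0.1 to 1 Mb every 0.1 Mb, one bin from
#' 1 to 1.2 Mb, and one above 1.2 Mb - 20 bins in all.
#'
#' @return A [bin_scheme()] with 20 bins.
#' @export
default_bins <- function() {
  bin_scheme(c(0, 2:10 / 100, 2:10 / 10, 1.2, Inf))
}

#' Assign distances to bins
#' @param d Numeric vector of distances (Mb), strictly positive.
#' @param bins A [bin_scheme()].
#' @return Integer bin index (NA outside the scheme).
#' @export
assign_bins <- function(d, bins = default_bins()) {
  stopifnot(all(d > 0, na.rm = TRUE))
  k <- findInterval(d, bins$edges)
  k[k < 1L | k > bins$n_bins] <- NA_integer_
  k
}

#' Composite (Burrows-type) disequilibrium from genotype counts
#'
#' Evaluates the composite D estimator from the 3 x 3 table of two-locus
#' genotype counts.  `counts` rows are doses 2/1/0 at the first locus and
#' columns doses 2/1/0 at the second (so `counts[1, 1]` is N_AABB,
#' `counts[1, 2]` is N_AABb, and so on); `f(A)` and `f(B)` are computed
#' from the same table.
#'
#' @param counts 3 x 3 numeric matrix of genotype-class counts in dose
#'   order 2, 1, 0.
#' @return Composite D (a single number).
#' @export
composite_D <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3L, 3L)), all(counts >= 0))
  N <- sum(counts)
  if (N < 2) stop("composite D undefined for N < 2")
  fA <- sum(counts * c(2, 1, 0)) / (2 * N)        # row doses recycle by column
  fB <- sum(t(counts) * c(2, 1, 0)) / (2 * N)
  if (fA %in% c(0, 1) || fB %in% c(0, 1))
    stop("undefined LD: monomorphic locus")
  num <- 4 * counts[1, 1] + 2 * (counts[1, 2] + counts[2, 1]) + counts[2, 2]
  N / (N - 1) * (num / (2 * N) - 2 * fA * fB)
}

# Vectorized pair engine: composite D, signed r and r2 for arbitrary
# column-index pairs, on pairwise-complete individuals.  Chunked so the
# temporaries stay modest for large pair lists.
pair_stats <- function(doses, i, j, chunk = 50000L) {
  stopifnot(length(i) == length(j))
  X <- doses; X[is.na(X)] <- 0L
  storage.mode(X) <- "double"
  M <- (!is.na(doses)) * 1
  P <- length(i)
  out <- vector("list", ceiling(P / chunk))
  for (b in seq_along(out)) {
    sel <- ((b - 1L) * chunk + 1L):min(b * chunk, P)
    ii <- i[sel]; jj <- j[sel]
    Xi <- X[, ii, drop = FALSE]; Xj <- X[, jj, drop = FALSE]
    Mi <- M[, ii, drop = FALSE]; Mj <- M[, jj, drop = FALSE]
    n <- colSums(Mi * Mj)
    sxy <- colSums(Xi * Xj)
    sa <- colSums(Xi * Mj)
    sb <- colSums(Mi * Xj)
    fA <- ifelse(n > 0, sa / (2 * n), NA_real_)
    fB <- ifelse(n > 0, sb / (2 * n), NA_real_)
    valid <- n >= 2 & !is.na(fA) & fA > 0 & fA < 1 & fB > 0 & fB < 1
    D <- r <- r2 <- rep(NA_real_, length(sel))
    capped <- rep(NA, length(sel))
    if (any(valid)) {
      nv <- n[valid]
      Dv <- nv / (nv - 1) * (sxy[valid] / (2 * nv) -
                               2 * fA[valid] * fB[valid])
      den <- fA[valid] * (1 - fA[valid]) * fB[valid] * (1 - fB[valid])
      r2raw <- Dv^2 / den
      cp <- r2raw > 1
      r2v <- pmin(r2raw, 1)
      D[valid] <- Dv
      r2[valid] <- r2v
      r[valid] <- sign(Dv) * sqrt(r2v)
      capped[valid] <- cp
    }
    out[[b]] <- data.frame(n = n, f_A = fA, f_B = fB, D = D, r = r,
                           r2 = r2, capped = capped, valid = valid)
  }
  do.call(rbind, out)
}

#' Composite D, signed r and r-squared for one marker pair
#'
#' Computed on pairwise-complete individuals (both calls non-missing).
#' `r2` is capped at 1 - the finite-sample factor N/(N-1) and non-HWE
#' genotype configurations can push the composite ratio above 1 - and
#' the signed r is `sign(D) * sqrt(r2)`.
#'
#' @param x,y Dose vectors (0/1/2/NA) of equal length.
#' @return List with `n`, `D`, `r`, `r2` and `capped`.
#' @export
pair_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  st <- pair_stats(cbind(x, y), 1L, 2L)
  if (!st$valid[1])
    stop("LD undefined: fewer than 2 complete observations or a locus ",
         "monomorphic among them")
  list(n = st$n[1], D = st$D[1], r = st$r[1], r2 = st$r2[1],
       capped = st$capped[1])
}

#' All within-chromosome LD pairs up to a maximum distance
#'
#' Computes the composite D, signed r and r-squared for every
#' same-chromosome marker pair whose distance does not exceed
#' `max_dist_mb`.  Pairs with fewer than two complete observations, or
#' with a locus monomorphic among the complete observations, are skipped;
#' their count is recorded in the `n_skipped` attribute.  The per-marker
#' reference alleles are attached as the `orientation` attribute, which
#' the phase module uses to refuse cross-population comparisons with
#' mismatched dose orientation.
#'
#' @param g A [genotypes] object (QC-filtered input expected).
#' @param max_dist_mb Maximum pair distance in Mb. The default, 15 Mb, is
#'   wide enough for ancestral-Ne estimation at 5 generations (c = 0.1
#'   Morgan, i.e. 10 Mb at 1 cM/Mb).
#' @return Data frame of class `ld_pairs`: `marker_i`, `marker_j`,
#'   `chrom`, `dist_mb`, `n`, `D`, `r`, `r2`, `capped`.
#' @export
ld_pairs <- function(g, max_dist_mb = 15) {
  stopifnot(inherits(g, "genotypes"), max_dist_mb > 0)
  res <- list()
  n_skipped <- 0L
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2L) next
    pos <- g$map$pos[idx] / 1e6
    dm <- outer(pos, pos, function(a, b) b - a)  # dm[i,j] = pos_j - pos_i
    sel <- which(upper.tri(dm) & dm <= max_dist_mb, arr.ind = TRUE)
    if (nrow(sel) == 0L) next
    i <- idx[sel[, 1]]; j <- idx[sel[, 2]]
    st <- pair_stats(g$doses, i, j)
    keep <- st$valid
    n_skipped <- n_skipped + sum(!keep)
    res[[length(res) + 1L]] <- data.frame(
      marker_i = g$map$name[i[keep]],
      marker_j = g$map$name[j[keep]],
      chrom = ch,
      dist_mb = dm[sel][keep],
      n = st$n[keep], D = st$D[keep], r = st$r[keep], r2 = st$r2[keep],
      capped = st$capped[keep], stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(marker_i = character(0), marker_j = character(0),
               chrom = integer(0), dist_mb = numeric(0), n = integer(0),
               D = numeric(0), r = numeric(0), r2 = numeric(0),
               capped = logical(0))
  rownames(out) <- NULL
  attr(out, "orientation") <- setNames(g$ref_allele, g$map$name)
  attr(out, "pop") <- unique(g$samples$pop)[1]
  attr(out, "n_individuals") <- nrow(g$doses)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("ld_pairs", "data.frame")
  out
}

#' Mean LD between adjacent markers
#'
#' Mean r-squared and mean distance over consecutive-in-map marker pairs,
#' per chromosome and overall.  Pairs skipped by the estimator
#' (insufficient complete observations, monomorphic in the complete
#' subset) are excluded from both the r-squared mean and the distance
#' mean.  Chromosomes with fewer than two markers are omitted with a
#' warning.
#'
#' @param g A [genotypes] object (QC-filtered input expected).
#' @return Data frame: `chrom`, `n_pairs` (adjacent pairs), `n_used`,
#'   `mean_r2`, `mean_dist_mb`, plus an `Overall` row.
#' @export
adjacent_ld <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  rows <- list(); all_r2 <- numeric(0); all_d <- numeric(0)
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2L) {
      warning("chromosome ", ch, " has fewer than 2 markers; omitted")
      next
    }
    i <- idx[-length(idx)]; j <- idx[-1]
    d <- (g$map$pos[j] - g$map$pos[i]) / 1e6
    st <- pair_stats(g$doses, i, j)
    use <- st$valid
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(ch), n_pairs = length(i), n_used = sum(use),
      mean_r2 = if (any(use)) mean(st$r2[use]) else NA_real_,
      mean_dist_mb = if (any(use)) mean(d[use]) else NA_real_,
      stringsAsFactors = FALSE)
    all_r2 <- c(all_r2, st$r2[use]); all_d <- c(all_d, d[use])
  }
  out <- do.call(rbind, rows)
  rbind(out, data.frame(chrom = "Overall", n_pairs = sum(out$n_pairs),
                        n_used = sum(out$n_used),
                        mean_r2 = if (length(all_r2)) mean(all_r2) else NA_real_,
                        mean_dist_mb = if (length(all_d)) mean(all_d) else NA_real_,
                        stringsAsFactors = FALSE))
}

#' LD decay by distance bin
#'
#' Sorts same-chromosome marker pairs into distance bins and averages
#' r-squared per bin.  Empty bins are reported with a count of 0 and `NA`
#' mean.
#'
#' @param x A [genotypes] object or a precomputed [ld_pairs()] table.
#' @param bins A [bin_scheme()]; default the 20-bin scheme of
#'   [default_bins()].
#' @param max_dist_mb Maximum pair distance considered; must reach at
#'   least the largest finite bin edge.  Pairs beyond the last bin edge
#'   but within `max_dist_mb` fall in the final open-ended bin.
#' @param corrected If `TRUE`, apply the small-sample correction
#'   [correct_r2()] per pair before averaging.
#' @return Data frame of class `ld_decay`: `bin`, `lo`, `hi`, `n_pairs`,
#'   `mean_r2`, `sd_r2`.
#' @export
ld_decay <- function(x, bins = default_bins(), max_dist_mb = 15,
                     corrected = FALSE) {
  stopifnot(inherits(bins, "bin_scheme"))
  finite_edges <- bins$edges[is.finite(bins$edges)]
  if (max_dist_mb < max(finite_edges))
    stop("max_dist_mb must reach the largest finite bin edge (",
         max(finite_edges), " Mb)")
  pairs <- if (inherits(x, "ld_pairs")) x else ld_pairs(x, max_dist_mb)
  pairs <- pairs[pairs$dist_mb <= max_dist_mb, , drop = FALSE]
  r2 <- pairs$r2
  if (corrected) r2 <- correct_r2(r2, pairs$n / 2)
  k <- assign_bins(pairs$dist_mb, bins)
  out <- data.frame(bin = bins$labels, lo = bins$lo, hi = bins$hi,
                    n_pairs = 0L, mean_r2 = NA_real_, sd_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  tab <- tapply(r2, factor(k, levels = seq_len(bins$n_bins)),
                function(v) c(length(v), mean(v), sd(v)))
  for (b in seq_len(bins$n_bins)) {
    v <- tab[[b]]
    if (!is.null(v)) {
      out$n_pairs[b] <- as.integer(v[1])
      out$mean_r2[b] <- v[2]
      out$sd_r2[b] <- v[3]
    }
  }
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' Small-sample correction of r-squared
#'
#' `(r2 - 1/N) / (1 - 1/N)` with `N` the number of haplotypes, i.e. twice
#' the number of individuals; removes the inflation of r-squared expected
#' from sampling a finite number of gametes.  Floored at 0.
#'
#' @param r2 Raw r-squared value(s).
#' @param n_individuals Number of individuals (vectorized).
#' @return Corrected r-squared.
#' @export
correct_r2 <- function(r2, n_individuals) {
  N <- 2 * n_individuals
  stopifnot(all(N >= 2))
  pmax((r2 - 1 / N) / (1 - 1 / N), 0)
}

#' Plot an LD decay curve
#'
#' @param x An `ld_decay` table (or a list of them, named by population).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_ld_decay <- function(x, ...) {
  tabs <- if (inherits(x, "ld_decay")) list(x) else x
  mid <- function(tb) ifelse(is.finite(tb$hi), (tb$lo + tb$hi) / 2, tb$lo)
  ylim <- c(0, max(unlist(lapply(tabs, function(tb) tb$mean_r2)), na.rm = TRUE))
  plot(NA, xlim = range(unlist(lapply(tabs, mid))), ylim = ylim,
       xlab = "Distance (Mb)", ylab = expression(mean ~ r^2), log = "x", ...)
  for (s in seq_along(tabs))
    lines(mid(tabs[[s]]), tabs[[s]]$mean_r2, type = "b", pch = 16, col = s)
  if (!is.null(names(tabs)))
    legend("topright", legend = names(tabs), col = seq_along(tabs),
           lty = 1, pch = 16, bty = "n")
  invisible(x)
}
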