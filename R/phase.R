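# Consistency of gametic phase between populations: the Pearson
# correlation of signed r over marker pairs shared by two populations,
# per distance bin.  This is the quantity that decides whether marker-QTL
# phase learned in one population transfers to another, i.e. whether
# populations can be pooled into one genomic-selection training set.
#
# Signed r is only comparable across populations when the allele-dose
# orientation of every marker is identical in both; a mismatched
# orientation silently negates signs, so it is checked and is a hard
# error.

#' Align LD pairs shared by two populations
#'
#' Intersects two [ld_pairs()] tables by `(marker_i, marker_j)` identity
#' and returns the signed r of each population side by side.  The two
#' tables must carry the same recorded dose orientation for every shared
#' marker; a mismatch is an error, never silently reconciled.
#'
#' @param lt_a,lt_b [ld_pairs()] tables for the two populations.
#' @return Data frame of class `shared_pairs`: `marker_i`, `marker_j`,
#'   `dist_mb`, `r_a`, `r_b`.  Attributes `pop_a`/`pop_b` carry the
#'   population labels.  An empty intersection yields a zero-row table.
#' @export
shared_pairs <- function(lt_a, lt_b) {
  stopifnot(inherits(lt_a, "ld_pairs"), inherits(lt_b, "ld_pairs"))
  ori_a <- attr(lt_a, "orientation"); ori_b <- attr(lt_b, "orientation")
  shared_markers <- intersect(names(ori_a), names(ori_b))
  bad <- shared_markers[ori_a[shared_markers] != ori_b[shared_markers]]
  if (length(bad))
    stop("dose orientation mismatch for ", length(bad), " marker(s) (e.g. '",
         bad[1], "'); signed r is not comparable across these tables")
  key_a <- paste(lt_a$marker_i, lt_a$marker_j, sep = "\r")
  key_b <- paste(lt_b$marker_i, lt_b$marker_j, sep = "\r")
  ix <- match(key_a, key_b)
  keep <- !is.na(ix)
  if (any(abs(lt_a$dist_mb[keep] - lt_b$dist_mb[ix[keep]]) > 1e-9))
    stop("shared marker pairs disagree on distance; the two tables do not ",
         "derive from the same marker map")
  out <- data.frame(marker_i = lt_a$marker_i[keep],
                    marker_j = lt_a$marker_j[keep],
                    dist_mb = lt_a$dist_mb[keep],
                    r_a = lt_a$r[keep],
                    r_b = lt_b$r[ix[keep]],
                    stringsAsFactors = FALSE)
  attr(out, "pop_a") <- attr(lt_a, "pop")
  attr(out, "pop_b") <- attr(lt_b, "pop")
  class(out) <- c("shared_pairs", "data.frame")
  out
}

#' Phase consistency per distance bin
#'
#' Pearson correlation of signed r between two populations within each
#' distance bin.  Bins with fewer than `min_pairs` shared pairs, or with
#' zero variance of signed r in either population, are reported with `NA`
#' correlation and a reason.
#'
#' @param shared A [shared_pairs()] table.
#' @param bins A [bin_scheme()].
#' @param min_pairs Minimum shared pairs for a correlation (default 3).
#' @return Data frame of class `phase_consistency`: `bin`, `lo`, `hi`,
#'   `n_pairs`, `correlation`, `note`.
#' @export
phase_consistency <- function(shared, bins = default_bins(), min_pairs = 3L) {
  stopifnot(inherits(shared, "shared_pairs"), inherits(bins, "bin_scheme"))
  k <- if (nrow(shared)) assign_bins(shared$dist_mb, bins) else integer(0)
  out <- data.frame(bin = bins$labels, lo = bins$lo, hi = bins$hi,
                    n_pairs = 0L, correlation = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (b in seq_len(bins$n_bins)) {
    sel <- which(k == b)
    out$n_pairs[b] <- length(sel)
    if (length(sel) < min_pairs) {
      out$note[b] <- "too few pairs"
    } else if (var(shared$r_a[sel]) == 0 || var(shared$r_b[sel]) == 0) {
      out$note[b] <- "zero variance"
    } else {
      out$correlation[b] <- cor(shared$r_a[sel], shared$r_b[sel])
    }
  }
  attr(out, "pop_a") <- attr(shared, "pop_a")
  attr(out, "pop_b") <- attr(shared, "pop_b")
  class(out) <- c("phase_consistency", "data.frame")
  out
}

#' Phase consistency pooled over a distance window
#'
#' Pools all shared pairs with `lo <= dist < hi` into a single Pearson
#' correlation - the coarse aggregate usually reported alongside the
#' per-bin breakdown (e.g. "all pairs below 0.2 Mb").
#'
#' @param shared A [shared_pairs()] table.
#' @param lo,hi Window bounds in Mb (half-open, `[lo, hi)`).
#' @param min_pairs Minimum pairs for a correlation.
#' @return Single correlation (NA when undefined).
#' @export
phase_consistency_window <- function(shared, lo = 0, hi = 0.2,
                                     min_pairs = 3L) {
  stopifnot(inherits(shared, "shared_pairs"))
  sel <- which(shared$dist_mb >= lo & shared$dist_mb < hi)
  if (length(sel) < min_pairs) return(NA_real_)
  if (var(shared$r_a[sel]) == 0 || var(shared$r_b[sel]) == 0) return(NA_real_)
  cor(shared$r_a[sel], shared$r_b[sel])
}

#' Pairwise phase-consistency matrix for several populations
#'
#' For every pair of populations, computes the pooled phase consistency
#' in two distance windows and lays them out as a square matrix: window 1
#' above the diagonal, window 2 below (the customary compact layout).
#'
#' @param ld_tables Named list of [ld_pairs()] tables, one per population.
#' @param window_upper,window_lower Length-2 numeric windows in Mb for
#'   the above- and below-diagonal aggregates (defaults `c(0, 0.2)` and
#'   `c(0.02, 0.03)`).
#' @return Numeric matrix with population names as dimnames and `NA` on
#'   the diagonal.
#' @export
phase_matrix <- function(ld_tables, window_upper = c(0, 0.2),
                         window_lower = c(0.02, 0.03)) {
  pops <- names(ld_tables)
  stopifnot(length(pops) >= 2)
  M <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (a in seq_along(pops)) {
    for (b in seq_along(pops)) {
      if (a >= b) next
      sh <- shared_pairs(ld_tables[[a]], ld_tables[[b]])
      M[a, b] <- phase_consistency_window(sh, window_upper[1], window_upper[2])
      M[b, a] <- phase_consistency_window(sh, window_lower[1], window_lower[2])
    }
  }
  M
}
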