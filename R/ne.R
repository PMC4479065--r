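# Ancestral effective population size from binned r2.
#
# Under drift-recombination equilibrium without mutation (Sved 1971),
# E(r2) = 1 / (1 + 4 Ne c) with c the genetic distance in Morgans.
# LD at genetic distance c reflects the effective size roughly
# t = 1/(2c) generations ago (Hayes et al. 2003), so sweeping c from
# large to small traces Ne back in time.  The Mb -> Morgan conversion is
# the single largest constant in this analysis and is an explicit,
# logged parameter (default 1 cM/Mb).

#' Genetic distance probed for a given generation in the past
#'
#' Inverts `t = 1/(2c)`: the LD between markers `c` Morgans apart
#' reflects the effective size about `t` generations ago.
#'
#' @param t Generations in the past (> 0, vectorized).
#' @return Genetic distance in Morgans, `c = 1/(2t)`.
#' @export
c_for_generation <- function(t) {
  if (any(t <= 0)) stop("t must be positive")
  1 / (2 * t)
}

#' Effective population size from mean r-squared
#'
#' Exact inversion of the Sved expectation:
#' `Ne = (1/r2 - 1) / (4c)`.  `r2 >= 1` gives Ne = 0; non-positive r2 is
#' undefined and returns `NA` with a warning.
#'
#' @param r2 Mean r-squared at genetic distance `c` (vectorized).
#' @param c Genetic distance in Morgans (> 0).
#' @return Ne estimate(s).
#' @export
ne_from_r2 <- function(r2, c) {
  if (any(c <= 0)) stop("c must be positive")
  out <- (1 / r2 - 1) / (4 * c)
  out[r2 >= 1] <- 0
  if (any(r2 <= 0, na.rm = TRUE)) {
    warning("non-positive mean r2: Ne undefined, returning NA")
    out[r2 <= 0] <- NA_real_
  }
  out
}

#' Default time grid for the Ne trajectory
#'
#' `n` log-spaced time points spanning `t_min` to `t_max` generations in
#' the past (default 21 points from 5 to 1500), rounded to whole
#' generations with duplicates removed.
#'
#' @param n Number of points.
#' @param t_min,t_max Grid endpoints in generations.
#' @return Numeric vector of generations, increasing.
#' @export
ne_time_grid <- function(n = 21L, t_min = 5, t_max = 1500) {
  unique(round(exp(seq(log(t_min), log(t_max), length.out = n))))
}

#' Ancestral Ne trajectory from an LD pair table
#'
#' For each time point `t`: the target genetic distance is
#' `c = 1/(2t)`; all pairs whose genetic distance (from physical distance
#' via `cm_per_mb`) falls within `window_frac` of the target are
#' collected; their mean r-squared is inverted through the Sved
#' expectation.  Time points with no pairs in the window are omitted with
#' a warning.
#'
#' @param pairs An [ld_pairs()] table.
#' @param time_points Generations in the past (default [ne_time_grid()]).
#' @param cm_per_mb Genetic-to-physical scale (cM per Mb); must match the
#'   organism's map or the simulation that produced the data.
#' @param window_frac Half-width of the distance window as a fraction of
#'   the target `c` (default 0.10, i.e. pairs within +/-10%).
#' @param corrected If `TRUE`, apply [correct_r2()] per pair before
#'   averaging (the raw r-squared is the default, primary scale).
#' @return Data frame of class `ne_trajectory`, ordered by `t`:
#'   `t`, `c_morgan`, `window_mb_lo`, `window_mb_hi`, `n_pairs`,
#'   `mean_r2`, `ne`.
#' @export
ne_trajectory <- function(pairs, time_points = ne_time_grid(),
                          cm_per_mb = 1, window_frac = 0.10,
                          corrected = FALSE) {
  stopifnot(inherits(pairs, "ld_pairs"), cm_per_mb > 0, window_frac > 0)
  c_pair <- pairs$dist_mb * cm_per_mb / 100  # Morgans
  r2 <- pairs$r2
  if (corrected) r2 <- correct_r2(r2, pairs$n / 2)
  rows <- lapply(sort(time_points), function(t) {
    ct <- c_for_generation(t)
    lo <- ct * (1 - window_frac); hi <- ct * (1 + window_frac)
    sel <- which(c_pair >= lo & c_pair <= hi)
    if (length(sel) == 0L) {
      warning("no pairs in the distance window for t = ", t,
              " generations; point omitted")
      return(NULL)
    }
    mr2 <- mean(r2[sel])
    data.frame(t = t, c_morgan = ct,
               window_mb_lo = lo * 100 / cm_per_mb,
               window_mb_hi = hi * 100 / cm_per_mb,
               n_pairs = length(sel), mean_r2 = mr2,
               ne = suppressWarnings(ne_from_r2(mr2, ct)))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(t = numeric(0), c_morgan = numeric(0),
                      window_mb_lo = numeric(0), window_mb_hi = numeric(0),
                      n_pairs = integer(0), mean_r2 = numeric(0),
                      ne = numeric(0))
  attr(out, "cm_per_mb") <- cm_per_mb
  attr(out, "window_frac") <- window_frac
  attr(out, "corrected") <- corrected
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Plot Ne trajectories
#'
#' @param x An `ne_trajectory` table or a named list of them.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_ne_trajectory <- function(x, ...) {
  tabs <- if (inherits(x, "ne_trajectory")) list(x) else x
  plot(NA, xlim = range(unlist(lapply(tabs, `[[`, "t"))),
       ylim = c(0, max(unlist(lapply(tabs, `[[`, "ne")), na.rm = TRUE)),
       log = "x", xlab = "Generations ago", ylab = expression(N[e]), ...)
  for (s in seq_along(tabs))
    lines(tabs[[s]]$t, tabs[[s]]$ne, type = "b", pch = 16, col = s)
  if (!is.null(names(tabs)))
    legend("topleft", legend = names(tabs), col = seq_along(tabs),
           lty = 1, pch = 16, bty = "n")
  invisible(x)
}
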