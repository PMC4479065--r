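# Population structure through the VanRaden genomic relationship matrix
# G = (M - 2P)(M - 2P)' / (2 * sum_i p_i (1 - p_i)) and its principal
# components.  Centering and scaling use pooled (all-populations) allele
# frequencies, while missing genotypes are imputed with twice the
# *within-population* allele frequency - deliberately asymmetric: the
# imputed value is the within-group expectation, whereas the relationship
# scale is defined on the pooled sample being compared.

#' VanRaden genomic relationship matrix
#'
#' Builds `G = (M - 2P)(M - 2P)' / (2 sum p_i (1 - p_i))` from allele
#' doses.  `p_i` is the pooled frequency of the reference allele over all
#' non-missing calls; missing entries of `M` are first replaced by twice
#' the within-population frequency of the individual's population (falling
#' back to the pooled frequency, with a warning, if a population has no
#' call at a marker).  Markers monomorphic in the pooled sample contribute
#' nothing to the denominator and are dropped with a warning.
#'
#' @param g A [genotypes] object, usually several populations on a shared
#'   QC-passing marker set.
#' @return An object of class `g_matrix`: `G` (n x n), `p` (pooled
#'   frequencies used), `ids`, `pop`, `denominator` and `n_imputed`.
#' @export
build_G <- function(g) {
  stopifnot(inherits(g, "genotypes"))
  M <- g$doses
  storage.mode(M) <- "double"
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " marker(s) monomorphic in the pooled sample; dropped")
    M <- M[, poly, drop = FALSE]
    p <- p[poly]
  }
  n_imputed <- 0L
  if (anyNA(M)) {
    for (pp in unique(g$samples$pop)) {
      rows <- which(g$samples$pop == pp)
      sub <- M[rows, , drop = FALSE]
      miss <- is.na(sub)
      if (!any(miss)) next
      p_pop <- colMeans(sub, na.rm = TRUE) / 2
      nocall <- is.nan(p_pop)
      if (any(nocall & colSums(miss) > 0)) {
        warning("population '", pp, "' has no calls at ",
                sum(nocall), " marker(s); pooled frequency used for imputation")
        p_pop[nocall] <- p[nocall]
      }
      fill <- matrix(2 * p_pop, nrow = length(rows), ncol = ncol(M),
                     byrow = TRUE)
      sub[miss] <- fill[miss]
      M[rows, ] <- sub
      n_imputed <- n_imputed + sum(miss)
    }
  }
  W <- sweep(M, 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  structure(list(G = G, p = p, ids = g$samples$id, pop = g$samples$pop,
                 denominator = denom, n_imputed = n_imputed),
            class = "g_matrix")
}

#' @export
print.g_matrix <- function(x, ...) {
  cat("VanRaden G: ", nrow(x$G), " individuals, ", length(x$p),
      " markers, denominator ", format(x$denominator), ", ",
      x$n_imputed, " imputed calls\n", sep = "")
  invisible(x)
}

#' Principal components of a genomic relationship matrix
#'
#' Eigendecomposition of G.  Component scores are the eigenvectors scaled
#' by the square root of their (non-negative part of the) eigenvalues.
#' The sign of each component is fixed so that its largest-magnitude
#' loading is positive, making the output reproducible bit-for-bit.
#'
#' @param gm A [build_G()] result.
#' @param k Number of components to return (default 10, capped at n).
#' @return An object of class `g_pca`: `scores` (n x k), `eigenvalues`
#'   (all n), `var_prop` (proportion of variance per returned component),
#'   `ids`, `pop`.
#' @export
pca_g <- function(gm, k = 10L) {
  stopifnot(inherits(gm, "g_matrix"))
  if (any(!is.finite(gm$G))) stop("G contains non-finite entries")
  n <- nrow(gm$G)
  k <- min(as.integer(k), n)
  eig <- eigen(gm$G, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    if (vecs[which.max(abs(vecs[, c])), c] < 0) vecs[, c] <- -vecs[, c]
  }
  scores <- vecs %*% diag(sqrt(pmax(vals[seq_len(k)], 0)), k, k)
  dimnames(scores) <- list(gm$ids, paste0("PC", seq_len(k)))
  total <- sum(pmax(vals, 0))
  structure(list(scores = scores, eigenvalues = vals,
                 var_prop = pmax(vals[seq_len(k)], 0) / total,
                 ids = gm$ids, pop = gm$pop),
            class = "g_pca")
}

#' Scatter plot of two principal components, colored by population
#'
#' @param p A [pca_g()] result.
#' @param comps Length-2 vector of component indices (default 1:2).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `p`.
#' @export
plot_pca <- function(p, comps = c(1L, 2L), ...) {
  stopifnot(inherits(p, "g_pca"))
  pops <- factor(p$pop)
  lab <- function(i) sprintf("PC%d (%.1f%%)", comps[i],
                             100 * p$var_prop[comps[i]])
  plot(p$scores[, comps[1]], p$scores[, comps[2]], col = as.integer(pops),
       pch = 16, xlab = lab(1), ylab = lab(2), ...)
  legend("topright", legend = levels(pops), col = seq_along(levels(pops)),
         pch = 16, bty = "n")
  invisible(p)
}
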