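# Per-transect taxonomic metrics, rank-based univariate tests, and
# permutational multivariate statistics on Bray-Curtis distances.

#' Per-transect taxonomic metrics
#'
#' Richness counts species-level columns with positive density; density
#' totals sum all columns including unresolved taxa.
#'
#' @param abundance A `community_matrix` of kind `"abundance"`.
#' @param biomass Optional `community_matrix` of kind `"biomass"`.
#' @return Data frame: `transect_id`, `richness`, `abundance_density`, and
#'   `biomass_density` if `biomass` is supplied (all per 100 m^2).
#' @export
transect_metrics <- function(abundance, biomass = NULL) {
  sp <- species_columns(abundance)
  out <- data.frame(transect_id = rownames(abundance),
                    richness = rowSums(sp > 0),
                    abundance_density = rowSums(abundance),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(biomass))
    out$biomass_density <- rowSums(biomass)[out$transect_id]
  out
}

#' Kruskal-Wallis test across groups
#'
#' Midrank-based H with tie correction (via [stats::kruskal.test()]),
#' chi-square p with g - 1 degrees of freedom. The degenerate all-equal case
#' returns H = 0, p = 1.
#'
#' @param values Numeric metric values.
#' @param groups Grouping factor (>= 2 levels present).
#' @return List (class `depthfd_test`): `statistic`, `df`, `p_value`.
#' @export
kruskal_depth <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need >= 2 groups for a Kruskal-Wallis test", call. = FALSE)
  if (length(unique(values)) == 1L) {
    return(structure(list(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, method = "Kruskal-Wallis"),
                     class = "depthfd_test"))
  }
  kt <- stats::kruskal.test(values, groups)
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 method = "Kruskal-Wallis"), class = "depthfd_test")
}

#' Pairwise Mann-Whitney tests with FDR correction
#'
#' Two-sided U test for every group pair: exact enumeration when both group
#' sizes are <= 8 and there are no ties, otherwise the normal approximation
#' with tie and continuity corrections. P values are Benjamini-Hochberg
#' adjusted across all pairs.
#'
#' @param values Numeric metric values.
#' @param groups Grouping factor.
#' @return Data frame: `group1`, `group2`, `U`, `p_value`, `p_adjusted`.
#' @export
pairwise_mann_whitney <- function(values, groups) {
  groups <- droplevels(factor(groups))
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need >= 2 groups", call. = FALSE)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    exact <- length(x) <= 8 && length(y) <= 8 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    c(U = unname(wt$statistic), p = wt$p.value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             U = res["U", ], p_value = res["p", ],
             p_adjusted = stats::p.adjust(res["p", ], "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d_ij = sum |x_i - x_j| / sum (x_i + x_j)` on (optionally square-root
#' transformed) species-level densities. Two all-zero rows get d = 0 by
#' convention, with a warning.
#'
#' @param mat Community matrix (non-negative); only species-level columns are
#'   used when `mat` is a `community_matrix`.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return Symmetric dissimilarity matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(mat, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- species_columns(mat)
  if (any(x < 0)) stop("community matrix must be non-negative", call. = FALSE)
  if (transform == "sqrt") x <- sqrt(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  zero_rows <- rowSums(x) == 0
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in (i + 1):n) {
      denom <- sum(xi + x[j, ])
      d[i, j] <- d[j, i] <- if (denom == 0) 0 else
        sum(abs(xi - x[j, ])) / denom
    }
  }
  if (sum(zero_rows) >= 2)
    warning("two or more all-zero communities: their mutual Bray-Curtis ",
            "distance is 0 by convention", call. = FALSE)
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition. Axes
#' are ordered by descending eigenvalue; coordinates are returned for
#' positive-eigenvalue axes only, and the magnitude of any negative part is
#' reported. For a Euclidean-embeddable input the pairwise distances in the
#' full coordinate space reproduce the input to numerical tolerance.
#'
#' @param d Symmetric distance matrix (n >= 2).
#' @param eps Eigenvalues within `eps * max(|eigenvalue|)` of zero are
#'   treated as null.
#' @return List of class `depthfd_pcoa`: `points` (n x k), `eig` (all
#'   eigenvalues, descending), `negative_magnitude` (sum of |negative
#'   eigenvalues|), and `neg_points` (coordinates on negative axes, scaled by
#'   `sqrt(|eigenvalue|)`, used for dispersion corrections).
#' @export
pcoa_dist <- function(d, eps = 1e-10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 objects for a PCoA", call. = FALSE)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- eps * max(abs(e$values), 1e-300)
  pos <- e$values > tol
  neg <- e$values < -tol
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  npts <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  rownames(pts) <- rownames(npts) <- rownames(d)
  colnames(pts) <- if (ncol(pts)) paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts, eig = e$values,
                 negative_magnitude = sum(-e$values[neg]),
                 neg_points = npts),
            class = "depthfd_pcoa")
}

## internal: sums of squares for the one-way PERMANOVA decomposition
permanova_F <- function(D2, groups) {
  N <- nrow(D2)
  g <- droplevels(factor(groups))
  k <- nlevels(g)
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (lv in levels(g)) {
    idx <- which(g == lv)
    ng <- length(idx)
    if (ng > 1)
      ss_within <- ss_within +
        sum(D2[idx, idx][upper.tri(diag(ng))]) / ng
  }
  Fstat <- ((ss_total - ss_within) / (k - 1)) / (ss_within / (N - k))
  list(F = Fstat, ss_total = ss_total, ss_within = ss_within, k = k, N = N)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from the distance decomposition
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, tested by permuting
#' group labels. With a single factor, type III partial sums of squares
#' reduce to this one-way form. The permutation p value is the
#' `(b + 1) / (m + 1)` estimator and never exactly zero; with
#' `exact = TRUE` (two groups only) all distinct label splits are enumerated
#' and `p = (#F_perm >= F_obs) / #splits`, the observed split included.
#'
#' @param d Distance matrix.
#' @param groups Grouping factor; every group needs n >= 2.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional seed for the permutation stream.
#' @param exact Enumerate all label splits instead of sampling (2 groups).
#' @return `depthfd_test` list: `statistic` (pseudo-F), `p_value`, `df`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = NULL, exact = FALSE) {
  d <- as.matrix(d)
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("every group needs n >= 2 for PERMANOVA", call. = FALSE)
  D2 <- d^2
  obs <- permanova_F(D2, g)
  if (obs$ss_total <= .Machine$double.eps * nrow(d)^2) {
    return(structure(list(statistic = 0, p_value = 1,
                          df = c(obs$k - 1, obs$N - obs$k),
                          n_permutations = 0L, seed = seed,
                          method = "PERMANOVA"), class = "depthfd_test"))
  }
  tol <- 1e-12 * max(1, abs(obs$F))
  if (exact) {
    if (nlevels(g) != 2L)
      stop("exact enumeration is implemented for two groups only",
           call. = FALSE)
    n1 <- sum(g == levels(g)[1])
    splits <- utils::combn(obs$N, n1)
    Fs <- apply(splits, 2, function(ix) {
      gg <- rep(levels(g)[2], obs$N)
      gg[ix] <- levels(g)[1]
      permanova_F(D2, gg)$F
    })
    p <- mean(Fs >= obs$F - tol)
    n_used <- ncol(splits)
  } else {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (i in seq_len(n_perm)) {
      Fp <- permanova_F(D2, sample(g))$F
      if (Fp >= obs$F - tol) b <- b + 1L
    }
    p <- (b + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = obs$F, p_value = p,
                 df = c(obs$k - 1, obs$N - obs$k),
                 n_permutations = n_used, seed = seed,
                 method = "PERMANOVA"), class = "depthfd_test")
}

#' Pairwise PERMANOVA with FDR correction
#'
#' Runs [permanova()] on every two-group submatrix and Benjamini-Hochberg
#' adjusts the p values across pairs. Pairs involving a group of size < 2
#' raise an error.
#'
#' @inheritParams permanova
#' @return Data frame: `group1`, `group2`, `F`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 9999, seed = NULL) {
  d <- as.matrix(d)
  g <- droplevels(factor(groups))
  lv <- levels(g)
  small <- names(which(table(g) < 2L))
  if (length(small))
    stop("group(s) with n < 2 cannot enter pairwise PERMANOVA: ",
         paste(small, collapse = ", "), call. = FALSE)
  pairs <- utils::combn(lv, 2)
  res <- apply(pairs, 2, function(pr) {
    idx <- g %in% pr
    r <- permanova(d[idx, idx, drop = FALSE], g[idx], n_perm = n_perm,
                   seed = seed)
    c(F = r$statistic, p = r$p_value)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], F = res["F", ],
             p_value = res["p", ],
             p_adjusted = stats::p.adjust(res["p", ], "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

## internal: distances to own-group centroid in the corrected PCoA embedding
permdisp_z <- function(d, groups) {
  pc <- pcoa_dist(d)
  g <- droplevels(factor(groups))
  P <- pc$points; Np <- pc$neg_points
  z <- numeric(length(g))
  for (lv in levels(g)) {
    idx <- which(g == lv)
    cp <- colMeans(P[idx, , drop = FALSE])
    cn <- if (ncol(Np)) colMeans(Np[idx, , drop = FALSE]) else numeric(0)
    for (i in idx) {
      d2 <- sum((P[i, ] - cp)^2)
      if (ncol(Np)) d2 <- d2 - sum((Np[i, ] - cn)^2)
      z[i] <- sqrt(max(0, d2))
    }
  }
  z
}

anova_F <- function(z, g) {
  N <- length(z); k <- nlevels(g)
  gm <- tapply(z, g, mean); ng <- tabulate(g)
  ssb <- sum(ng * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.integer(g)])^2)
  if (ssw <= .Machine$double.eps * N) return(if (ssb <= .Machine$double.eps * N) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (N - k))
}

#' PERMDISP: permutational test of multivariate dispersion homogeneity
#'
#' Embeds the distance matrix by PCoA keeping real and imaginary parts
#' (squared distance to centroid = real-part distance^2 - imaginary-part
#' distance^2, floored at zero), computes each sample's distance to its own
#' group centroid, and tests the one-way ANOVA F on those distances by
#' permuting group labels across the distance-to-centroid values.
#'
#' @inheritParams permanova
#' @param pairwise If `TRUE`, also return BH-adjusted pairwise comparisons;
#'   groups of one sample are excluded from pairwise tests with a warning.
#' @return `depthfd_test` list with `statistic` (F), `p_value`,
#'   `distances` (per-sample distance to own centroid), `group_means`, and
#'   optionally `pairwise`.
#' @export
permdisp <- function(d, groups, n_perm = 9999, seed = NULL,
                     pairwise = FALSE) {
  d <- as.matrix(d)
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  z <- permdisp_z(d, g)
  Fobs <- anova_F(z, g)
  if (!is.null(seed)) set.seed(seed)
  tol <- 1e-12 * max(1, abs(Fobs))
  b <- 0L
  for (i in seq_len(n_perm)) {
    if (anova_F(z, g[sample.int(length(g))]) >= Fobs - tol) b <- b + 1L
  }
  out <- structure(list(statistic = Fobs, p_value = (b + 1) / (n_perm + 1),
                        distances = stats::setNames(z, rownames(d)),
                        group_means = tapply(z, g, mean),
                        n_permutations = n_perm, seed = seed,
                        method = "PERMDISP"), class = "depthfd_test")
  if (pairwise) {
    lv <- levels(g)
    singles <- names(which(table(g) < 2L))
    if (length(singles))
      warning("group(s) of one sample excluded from pairwise PERMDISP: ",
              paste(singles, collapse = ", "), call. = FALSE)
    keep <- setdiff(lv, singles)
    prs <- utils::combn(keep, 2)
    res <- apply(prs, 2, function(pr) {
      idx <- g %in% pr
      r <- permdisp(d[idx, idx, drop = FALSE], g[idx], n_perm = n_perm,
                    seed = seed)
      c(F = r$statistic, p = r$p_value)
    })
    out$pairwise <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                               F = res["F", ], p_value = res["p", ],
                               p_adjusted = stats::p.adjust(res["p", ], "BH"),
                               stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie correction via [stats::cor()]; the p value comes from
#' [stats::cor.test()]. A constant input vector makes tau undefined: the
#' result carries `tau = NA` and a note.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return `depthfd_test` list: `statistic` (tau), `p_value`, `note`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(structure(list(statistic = NA_real_, p_value = NA_real_,
                          note = "tau undefined for a constant vector",
                          method = "Kendall tau-b"), class = "depthfd_test"))
  tau <- stats::cor(x, y, method = "kendall")
  p <- suppressWarnings(stats::cor.test(x, y, method = "kendall")$p.value)
  structure(list(statistic = tau, p_value = p, note = NULL,
                 method = "Kendall tau-b"), class = "depthfd_test")
}

#' @export
print.depthfd_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4), "\n")
  if (!is.null(x$n_permutations) && x$n_permutations > 0)
    cat("  permutations =", x$n_permutations, "\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}
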