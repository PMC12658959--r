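# General-dimension convex hull volume by the incremental (beneath-beyond)
# algorithm. Needed for functional richness in the m-dimensional PCoA trait
# space; communities are small (tens to a few hundred points), so a plain R
# implementation is adequate.

## hyperplane through the d facet vertices V (d x d matrix, rows = points):
## returns list(normal, offset) with normal %*% x = offset on the plane
facet_plane <- function(V) {
  d <- ncol(V)
  E <- V[-1, , drop = FALSE] - matrix(V[1, ], d - 1, d, byrow = TRUE)
  ## normal spans the null space of E
  sv <- svd(E, nu = 0, nv = d)
  normal <- sv$v[, d]
  list(normal = normal, offset = sum(normal * V[1, ]))
}

ridge_key <- function(v) paste(sort(v), collapse = ",")

#' Convex hull volume in arbitrary dimension
#'
#' Incremental construction: an initial simplex of affinely independent
#' points is grown by inserting each remaining point, replacing the facets it
#' can see with new facets through its horizon ridges. The volume is the sum
#' of the simplices formed by each facet with an interior point. Point sets
#' that are affinely dependent (fewer than d + 1 independent points) have no
#' d-volume and return `NA` with a message attribute.
#'
#' @param X Numeric matrix, n points x d coordinates (n >= d + 1 for a
#'   nondegenerate hull).
#' @param tol Relative tolerance for visibility/degeneracy tests.
#' @return Hull volume (scalar), or `NA_real_` for degenerate input.
#' @export
convhull_volume <- function(X, tol = 1e-9) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  if (d < 1L) stop("need at least 1 coordinate dimension", call. = FALSE)
  if (n < d + 1L) return(structure(NA_real_, reason = "too few points"))
  if (d == 1L) return(max(X) - min(X))

  scale <- max(abs(sweep(X, 2, colMeans(X))), 1e-12)
  eps <- tol * scale

  ## initial simplex: greedily extend an affinely independent set
  init <- 1L
  for (i in 2:n) {
    E <- X[c(init, i), , drop = FALSE]
    E <- E[-1, , drop = FALSE] - matrix(E[1, ], nrow(E) - 1, d, byrow = TRUE)
    if (sqrt(sum(E^2)) > eps) { init <- c(init, i); break }
  }
  if (length(init) < 2L) return(structure(NA_real_, reason = "degenerate"))
  while (length(init) < d + 1L) {
    base <- X[init, , drop = FALSE]
    added <- FALSE
    for (i in setdiff(seq_len(n), init)) {
      M <- rbind(base, X[i, ]) -
        matrix(base[1, ], length(init) + 1L, d, byrow = TRUE)
      if (qr(M, tol = eps / scale)$rank == length(init)) {
        init <- c(init, i); added <- TRUE; break
      }
    }
    if (!added) return(structure(NA_real_, reason = "degenerate"))
  }

  interior <- colMeans(X[init, , drop = FALSE])

  ## facets of the initial simplex
  facets <- vector("list", d + 1L)
  for (k in seq_len(d + 1L)) {
    vids <- init[-k]
    pl <- facet_plane(X[vids, , drop = FALSE])
    if (sum(pl$normal * interior) > pl$offset) {
      pl$normal <- -pl$normal; pl$offset <- -pl$offset
    }
    facets[[k]] <- list(v = vids, normal = pl$normal, offset = pl$offset)
  }

  for (p in setdiff(seq_len(n), init)) {
    x <- X[p, ]
    dists <- vapply(facets, function(f) sum(f$normal * x) - f$offset,
                    numeric(1))
    vis <- which(dists > eps)
    if (length(vis) == 0L) next  # inside (or on) the current hull

    ## horizon ridges: ridges of visible facets seen exactly once among them
    ridges <- list(); counts <- integer(); keys <- character()
    for (fi in vis) {
      v <- facets[[fi]]$v
      for (k in seq_along(v)) {
        r <- v[-k]
        key <- ridge_key(r)
        j <- match(key, keys)
        if (is.na(j)) {
          keys <- c(keys, key); ridges <- c(ridges, list(r))
          counts <- c(counts, 1L)
        } else counts[j] <- counts[j] + 1L
      }
    }
    horizon <- ridges[counts == 1L]
    new_facets <- vector("list", length(horizon))
    ok <- TRUE
    for (k in seq_along(horizon)) {
      vids <- c(horizon[[k]], p)
      pl <- facet_plane(X[vids, , drop = FALSE])
      if (sqrt(sum(pl$normal^2)) < 0.5) { ok <- FALSE; break }
      if (sum(pl$normal * interior) > pl$offset) {
        pl$normal <- -pl$normal; pl$offset <- -pl$offset
      }
      new_facets[[k]] <- list(v = vids, normal = pl$normal,
                              offset = pl$offset)
    }
    if (!ok) next  # numerically degenerate insertion; point is ~on the hull
    facets <- c(facets[-vis], new_facets)
  }

  vol <- 0
  for (f in facets) {
    M <- X[f$v, , drop = FALSE] -
      matrix(interior, d, d, byrow = TRUE)
    vol <- vol + abs(det(M))
  }
  vol / factorial(d)
}
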