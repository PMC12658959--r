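# Functional entities and redundancy metrics; convex-hull, dispersion,
# evenness, specialization and uniqueness indices in the PCoA trait space;
# the FUSE conservation-priority index.

#' Assign species to functional entities
#'
#' Species with identical (post-pruning, imputed) trait vectors share a
#' functional entity. FE identifiers are deterministic: entities are sorted
#' by their trait combination string.
#'
#' @param traits Imputed trait table.
#' @param scheme Trait scheme (only its columns present in `traits` are
#'   used).
#' @return List: `assignment` (data frame `species_id`, `fe_id`) and
#'   `entities` (data frame `fe_id`, `combination`, `n_species`).
#' @export
assign_functional_entities <- function(traits, scheme) {
  cols <- intersect(names(scheme), names(traits))
  if (length(cols) == 0L) stop("no trait columns found", call. = FALSE)
  combo <- do.call(paste, c(lapply(traits[cols], as.character), sep = "|"))
  if (anyNA(traits[cols]))
    stop("trait table has missing cells; impute first", call. = FALSE)
  u <- sort(unique(combo))
  fe_id <- sprintf("FE%03d", match(combo, u))
  entities <- data.frame(fe_id = sprintf("FE%03d", seq_along(u)),
                         combination = u,
                         n_species = as.integer(table(match(combo, u))),
                         stringsAsFactors = FALSE)
  list(assignment = data.frame(species_id = traits$species_id, fe_id = fe_id,
                               stringsAsFactors = FALSE),
       entities = entities)
}

#' Functional-entity redundancy metrics
#'
#' For S species spread over K functional entities of sizes `n_k`:
#' functional redundancy `FRed = S / K` (mean species per FE), functional
#' vulnerability `FVul = 100 * #\{k : n_k = 1\} / K` (percent of FEs with a
#' single species), and functional over-redundancy
#' `FOR = 100 * sum_k max(0, n_k - FRed) / S` (percent of species in excess
#' in FEs more speciose than the mean; the species-in-excess convention).
#' `variant = "total"` instead counts all members of above-mean FEs.
#'
#' @param fes Output of [assign_functional_entities()].
#' @param community Character vector of member species; defaults to the
#'   whole pool.
#' @param variant `"excess"` (default) or `"total"` convention for FOR.
#' @return List: `S`, `K`, `FRed`, `FOR`, `FVul` (percent scales for
#'   FOR/FVul).
#' @export
fe_metrics <- function(fes, community = NULL, variant = c("excess", "total")) {
  variant <- match.arg(variant)
  asg <- fes$assignment
  if (!is.null(community)) asg <- asg[asg$species_id %in% community, ]
  if (nrow(asg) == 0L) stop("community is empty", call. = FALSE)
  sizes <- as.integer(table(asg$fe_id))
  S <- sum(sizes); K <- length(sizes)
  fred <- S / K
  fvul <- 100 * sum(sizes == 1L) / K
  for_ <- if (variant == "excess") 100 * sum(pmax(0, sizes - fred)) / S
          else 100 * sum(sizes[sizes > fred]) / S
  list(S = S, K = K, FRed = fred, FOR = for_, FVul = fvul)
}

#' Functional richness (convex-hull volume fraction)
#'
#' Volume of the convex hull of the community's coordinates in the
#' `m`-dimensional trait space, divided by the pool hull volume. Undefined
#' (NA) when the community has no more species than axes or its points are
#' affinely dependent.
#'
#' @param space A `trait_space`.
#' @param community Character vector of member species.
#' @param pool_volume Optional precomputed pool hull volume (computed from
#'   `space` if omitted).
#' @return Fraction in `[0, 1]`, or `NA` for degenerate communities.
#' @export
fric <- function(space, community, pool_volume = NULL) {
  P <- space$coords
  if (is.null(pool_volume)) pool_volume <- convhull_volume(P)
  idx <- intersect(community, rownames(P))
  if (length(idx) <= space$m) return(NA_real_)
  v <- convhull_volume(P[idx, , drop = FALSE])
  as.numeric(v) / as.numeric(pool_volume)
}

#' Functional dispersion
#'
#' Abundance-weighted mean distance to the abundance-weighted centroid of
#' the community in trait space.
#'
#' @param space A `trait_space`.
#' @param weights Named non-negative abundances (names = species).
#' @return FDis in trait-space distance units.
#' @export
fdis <- function(space, weights) {
  P <- space$coords
  w <- weights[names(weights) %in% rownames(P)]
  w <- w[w > 0]
  if (length(w) == 0L) stop("no positive weights", call. = FALSE)
  Pm <- P[names(w), , drop = FALSE]
  cen <- colSums(Pm * w) / sum(w)
  dists <- sqrt(rowSums((Pm - matrix(cen, nrow(Pm), ncol(Pm),
                                     byrow = TRUE))^2))
  sum(w * dists) / sum(w)
}

## deterministic Prim MST with lexicographic tie-breaks; returns edge list
mst_edges <- function(P) {
  n <- nrow(P)
  D <- as.matrix(stats::dist(P))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        dij <- D[i, j]
        if (dij < best_d - 1e-15 ||
            (abs(dij - best_d) <= 1e-15 && !is.null(best) &&
             (i < best[1] || (i == best[1] && j < best[2])))) {
          best_d <- dij; best <- c(i, j)
        }
      }
    }
    edges[k, ] <- best
    in_tree[best[2]] <- TRUE
  }
  edges
}

#' Functional evenness
#'
#' Regularity of abundance distribution along the minimum spanning tree of
#' the community in trait space. Each branch `l = (i, j)` gets weight
#' `EW_l = length(l) / (w_i + w_j)`; with `PEW_l = EW_l / sum EW`,
#' `FEve = (sum min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1))`. The MST is
#' built by a deterministic Prim algorithm with lexicographic tie-breaks.
#' Undefined (NA) for communities of fewer than 3 species.
#'
#' @param space A `trait_space`.
#' @param weights Named non-negative abundances (relative abundances are
#'   used, so global rescaling does not change the result).
#' @return FEve in `[0, 1]`, or `NA` when S < 3.
#' @export
feve <- function(space, weights) {
  P <- space$coords
  w <- weights[names(weights) %in% rownames(P)]
  w <- w[w > 0]
  S <- length(w)
  if (S < 3L) return(NA_real_)
  w <- w / sum(w)
  Pm <- P[names(w), , drop = FALSE]
  ed <- mst_edges(Pm)
  len <- sqrt(rowSums((Pm[ed[, 1], , drop = FALSE] -
                         Pm[ed[, 2], , drop = FALSE])^2))
  ew <- len / (w[ed[, 1]] + w[ed[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional specialization
#'
#' Species-level FSpe is the Euclidean distance to the unweighted centroid
#' of the global species pool, scaled by the pool maximum (the most
#' peripheral species scores 1). The community-level value is the
#' abundance-weighted mean of member FSpe.
#'
#' @param space A `trait_space` (the pool is all its species).
#' @return Named numeric vector of species FSpe in `[0, 1]`.
#' @export
fspe <- function(space) {
  P <- space$coords
  if (nrow(P) < 2L) stop("pool needs >= 2 species", call. = FALSE)
  cen <- colMeans(P)
  d <- sqrt(rowSums((P - matrix(cen, nrow(P), ncol(P), byrow = TRUE))^2))
  mx <- max(d)
  if (mx == 0) return(stats::setNames(rep(0, nrow(P)), rownames(P)))
  stats::setNames(d / mx, rownames(P))
}

#' Community-level functional specialization
#'
#' @param fspe_values Species FSpe from [fspe()].
#' @param weights Named abundances of community members.
#' @return Abundance-weighted mean FSpe of the community.
#' @export
fspe_community <- function(fspe_values, weights) {
  w <- weights[names(weights) %in% names(fspe_values)]
  w <- w[w > 0]
  if (length(w) == 0L) stop("no positive weights", call. = FALSE)
  sum(w * fspe_values[names(w)]) / sum(w)
}

#' Functional uniqueness
#'
#' Species-level FUn is the mean Euclidean distance to the `k` nearest pool
#' neighbours, scaled by the pool maximum of that quantity (the most
#' isolated species scores 1). If the pool has no more than `k` species, `k`
#' is reduced to pool size minus one, with a warning.
#'
#' @param space A `trait_space`.
#' @param k Number of neighbours (default 5).
#' @return Named numeric vector of species FUn in `[0, 1]`.
#' @export
fun_uniqueness <- function(space, k = 5) {
  P <- space$coords
  n <- nrow(P)
  if (n <= k) {
    warning("pool size ", n, " <= k = ", k, "; using k = ", n - 1,
            call. = FALSE)
    k <- n - 1L
  }
  D <- as.matrix(stats::dist(P))
  mnd <- vapply(seq_len(n), function(i)
    mean(sort(D[i, -i], partial = k)[seq_len(k)]), numeric(1))
  mx <- max(mnd)
  stats::setNames(if (mx > 0) mnd / mx else rep(0, n), rownames(P))
}

#' IUCN category to GE rank
#'
#' Maps IUCN Red List categories to the 0-4 threat rank used by FUSE:
#' LC = 0, NT = 1, VU = 2, EN = 3, CR = 4. DD/NE must have been imputed
#' beforehand and raise an error.
#'
#' @param iucn Character vector of categories.
#' @return Integer vector of GE ranks.
#' @export
ge_rank <- function(iucn) {
  map <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L)
  bad <- setdiff(unique(iucn), names(map))
  if (length(bad))
    stop("IUCN categories without a GE rank (impute DD/NE first): ",
         paste(bad, collapse = ", "), call. = FALSE)
  unname(map[iucn])
}

#' FUSE index
#'
#' Functionally Unique, Specialized and Endangered score:
#' `FUSE = ln(1 + FUn * GE) + ln(1 + FSpe * GE)`. A least-concern species
#' (GE = 0) scores 0 regardless of its uniqueness or specialization, and the
#' score is nondecreasing in each input.
#'
#' @param fun_s Functional uniqueness in `[0, 1]`.
#' @param fspe_s Functional specialization in `[0, 1]`.
#' @param ge Threat rank 0-4 (see [ge_rank()]).
#' @return FUSE score(s) >= 0.
#' @export
fuse <- function(fun_s, fspe_s, ge) {
  if (any(fun_s < 0 | fun_s > 1) || any(fspe_s < 0 | fspe_s > 1))
    stop("FUn and FSpe must lie in [0, 1]", call. = FALSE)
  if (any(!ge %in% 0:4))
    stop("GE must be an integer in 0..4", call. = FALSE)
  log(1 + fun_s * ge) + log(1 + fspe_s * ge)
}

#' Habitat class from the shallowest depth band of occurrence
#'
#' `shallow` up to 30 m, `MCE` above 30 m and up to 150 m, `deep` below
#' 150 m.
#'
#' @param depth_m Numeric depth(s) in metres.
#' @return Character vector of habitat classes.
#' @export
habitat_class <- function(depth_m) {
  ifelse(depth_m <= 30, "shallow", ifelse(depth_m <= 150, "MCE", "deep"))
}

#' Ranked FUSE table
#'
#' Species sorted by descending FUSE (ties by descending FUn, then label),
#' annotated with commercial value, IUCN category, habitat class (from the
#' shallowest band of occurrence), number of atolls of occurrence, and mean
#' individuals per standard 1250 m^2 transect over the transects where the
#' species occurs. An all-LC pool (every FUSE zero) is flagged via attribute
#' `degenerate`.
#'
#' @param fun_s,fspe_s Named species FUn and FSpe vectors.
#' @param iucn Named character vector of (imputed) IUCN categories.
#' @param traits Trait table carrying `commercial_value` (optional).
#' @param abundance Optional abundance `community_matrix` for occurrence and
#'   density annotations.
#' @param meta Optional transect metadata (needed with `abundance`).
#' @return Data frame, one row per species, highest FUSE first.
#' @export
fuse_ranking <- function(fun_s, fspe_s, iucn, traits = NULL,
                         abundance = NULL, meta = NULL) {
  sp <- names(fun_s)
  ge <- ge_rank(unname(iucn[sp]))
  score <- fuse(unname(fun_s[sp]), unname(fspe_s[sp]), ge)
  out <- data.frame(species_id = sp, FUSE = score,
                    FUn = unname(fun_s[sp]), FSpe = unname(fspe_s[sp]),
                    GE = ge, iucn = unname(iucn[sp]),
                    stringsAsFactors = FALSE)
  if (!is.null(traits) && "commercial_value" %in% names(traits))
    out$commercial_value <- traits$commercial_value[
      match(sp, traits$species_id)]
  if (!is.null(abundance) && !is.null(meta)) {
    A <- species_columns(abundance)
    band <- stats::setNames(meta$depth_band_m, meta$transect_id)
    atoll <- stats::setNames(meta$atoll, meta$transect_id)
    area <- stats::setNames(meta$length_m * meta$width_m, meta$transect_id)
    hab <- occ <- dens <- rep(NA, length(sp))
    for (i in seq_along(sp)) {
      if (!sp[i] %in% colnames(A)) next
      pres <- rownames(A)[A[, sp[i]] > 0]
      if (length(pres) == 0L) next
      hab[i] <- habitat_class(min(band[pres]))
      occ[i] <- length(unique(atoll[pres]))
      counts <- A[pres, sp[i]] * area[pres] / 100  # back to individuals
      dens[i] <- mean(counts * 1250 / area[pres])
    }
    out$habitat <- hab
    out$occurrence_atolls <- as.integer(occ)
    out$density_1250m2 <- as.numeric(dens)
  }
  ord <- order(-out$FUSE, -out$FUn, out$species_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- all(out$FUSE == 0)
  if (attr(out, "degenerate"))
    warning("all FUSE scores are zero (no threatened species in the pool); ",
            "ranking is degenerate", call. = FALSE)
  out
}

#' Filter species-poor transects before alpha functional diversity
#'
#' Transects with species richness below `min_species` are excluded from the
#' convex-hull, dispersion and evenness indices only (they stay in every
#' other analysis). The report counts removals per depth band.
#'
#' @param abundance Abundance `community_matrix`.
#' @param meta Transect metadata.
#' @param min_species Minimum richness (default 5).
#' @return List: `matrix` (filtered), `removed` (transect ids),
#'   `report` (per-band removal counts).
#' @export
alpha_fd_filter <- function(abundance, meta, min_species = 5) {
  rich <- rowSums(species_columns(abundance) > 0)
  drop <- names(rich)[rich < min_species]
  band <- stats::setNames(meta$depth_band_m, meta$transect_id)
  report <- if (length(drop)) table(band[drop]) else table(integer(0))
  keep <- setdiff(rownames(abundance), drop)
  m <- abundance[keep, , drop = FALSE]
  attr(m, "kind") <- attr(abundance, "kind")
  attr(m, "species") <- attr(abundance, "species")
  class(m) <- class(abundance)
  list(matrix = m, removed = drop, report = report)
}

#' Kendall correlation matrix of per-transect metrics
#'
#' Pairwise tau-b between the columns of a per-transect metric table
#' (delegating to [kendall_tau()]). Constant columns yield NA entries.
#'
#' @param metrics Data frame of numeric per-transect metrics (>= 3 rows).
#' @return Symmetric matrix of tau values with unit diagonal.
#' @export
metric_correlation_summary <- function(metrics) {
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  if (nrow(num) < 3L) stop("need >= 3 transects", call. = FALSE)
  p <- ncol(num)
  out <- matrix(NA_real_, p, p, dimnames = list(names(num), names(num)))
  diag(out) <- 1
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ok <- stats::complete.cases(num[[i]], num[[j]])
      out[i, j] <- out[j, i] <-
        kendall_tau(num[[i]][ok], num[[j]][ok])$statistic
    }
  }
  out
}
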