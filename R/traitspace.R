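# Categorical trait table -> pruned, imputed, Gower-distance PCoA trait
# space with mean-absolute-deviation dimensionality selection.

ordered_traits <- function(scheme) {
  names(scheme)[vapply(scheme, function(s) isTRUE(s$ordered), logical(1))]
}

trait_ranks <- function(col, levels) {
  match(as.character(col), levels)
}

#' Prune highly correlated ordered traits
#'
#' Computes Kendall's tau-b between every pair of ordered traits (on their
#' modality ranks, pairwise-complete) and iteratively drops one trait of the
#' worst offending pair until no pair exceeds `threshold` in absolute value.
#' The trait with more missing cells is dropped; on a tie, the one declared
#' later in the trait order. Unordered traits are never screened (tau is
#' undefined for them) and are always kept.
#'
#' @param traits Trait table.
#' @param scheme Trait scheme.
#' @param threshold Absolute tau above which a pair is "highly correlated"
#'   (default 0.8).
#' @return The pruned trait table; attribute `pruning` reports each dropped
#'   trait, its partner and the tau value.
#' @export
prune_correlated <- function(traits, scheme, threshold = 0.8) {
  ord <- intersect(ordered_traits(scheme), names(traits))
  keep <- names(scheme)[names(scheme) %in% names(traits)]
  report <- data.frame(dropped = character(), against = character(),
                       tau = numeric(), stringsAsFactors = FALSE)
  repeat {
    ord_now <- intersect(ord, keep)
    if (length(ord_now) < 2L) break
    worst <- NULL; worst_tau <- threshold
    for (i in seq_len(length(ord_now) - 1L)) {
      for (j in (i + 1L):length(ord_now)) {
        a <- trait_ranks(traits[[ord_now[i]]], scheme[[ord_now[i]]]$levels)
        b <- trait_ranks(traits[[ord_now[j]]], scheme[[ord_now[j]]]$levels)
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) < 2L) next
        tau <- suppressWarnings(stats::cor(a[ok], b[ok], method = "kendall"))
        if (!is.na(tau) && abs(tau) > worst_tau) {
          worst_tau <- abs(tau)
          worst <- c(ord_now[i], ord_now[j], tau)
        }
      }
    }
    if (is.null(worst)) break
    na1 <- sum(is.na(traits[[worst[1]]]))
    na2 <- sum(is.na(traits[[worst[2]]]))
    drop <- if (na1 > na2) worst[1]
            else if (na2 > na1) worst[2]
            else worst[which.max(match(worst[1:2], names(scheme)))]
    other <- setdiff(worst[1:2], drop)
    keep <- setdiff(keep, drop)
    report <- rbind(report, data.frame(dropped = drop, against = other,
                                       tau = as.numeric(worst[3]),
                                       stringsAsFactors = FALSE))
  }
  out <- traits[, c(setdiff(names(traits), names(scheme)), keep),
                drop = FALSE]
  ## restore original column order where possible
  ord_cols <- c(intersect(names(traits), setdiff(names(traits),
                                                 names(scheme))), keep)
  out <- out[, unique(ord_cols), drop = FALSE]
  attr(out, "pruning") <- report
  attr(out, "kept_traits") <- keep
  out
}

col_mode <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  names(tb)[1L]
}

#' Iterative random-forest imputation of categorical traits
#'
#' Missing cells are initialised with column modes, then columns are visited
#' in order of increasing missingness: a 100-tree classification forest of
#' each column on all others is fitted on the observed rows and its
#' predictions replace the column's missing cells. Iteration stops when the
#' proportion of changed categorical imputations increases relative to the
#' previous iteration, and the previous iterate is returned. IUCN categories
#' `DD` and `NE` are treated as missing and imputed from the traits when
#' `impute_iucn = TRUE`.
#'
#' The out-of-bag Proportion of Falsely Classified (PFC) is reported for the
#' imputed categorical columns; with all-categorical data the NRMSE (reserved
#' for continuous columns) is reported as 0.
#'
#' @param traits Trait table (data frame; trait columns + optionally `iucn`).
#' @param scheme Trait scheme.
#' @param n_trees Trees per forest (default 100).
#' @param seed Optional seed.
#' @param impute_iucn Impute DD/NE IUCN categories alongside the traits.
#' @param max_iter Safety cap on iterations.
#' @return The imputed table; attributes `oob_error` (list `PFC`, `NRMSE`)
#'   and `n_iterations`.
#' @export
impute_missforest <- function(traits, scheme, n_trees = 100, seed = NULL,
                              impute_iucn = TRUE, max_iter = 10) {
  if (!is.null(seed)) set.seed(seed)
  cols <- intersect(names(scheme), names(traits))
  work <- data.frame(row.names = seq_len(nrow(traits)))
  for (cl in cols) {
    work[[cl]] <- factor(as.character(traits[[cl]]),
                         levels = scheme[[cl]]$levels)
  }
  if (impute_iucn && "iucn" %in% names(traits)) {
    iu <- as.character(traits$iucn)
    iu[iu %in% c("DD", "NE")] <- NA
    work$iucn <- factor(iu, levels = c("LC", "NT", "VU", "EN", "CR"))
  }
  all_missing <- names(which(vapply(work, function(x) all(is.na(x)),
                                    logical(1))))
  if (length(all_missing))
    stop("column(s) entirely missing, cannot impute: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  na_idx <- lapply(work, function(x) which(is.na(x)))
  n_missing <- vapply(na_idx, length, integer(1))
  imp_cols <- names(work)[n_missing > 0]
  if (length(imp_cols) == 0L) {
    out <- finish_imputation(traits, work, cols, impute_iucn, scheme)
    attr(out, "oob_error") <- list(PFC = 0, NRMSE = 0)
    attr(out, "n_iterations") <- 0L
    return(out)
  }
  imp_cols <- imp_cols[order(n_missing[imp_cols])]

  filled <- work
  for (cl in imp_cols)
    filled[[cl]][na_idx[[cl]]] <- col_mode(work[[cl]])

  prev <- filled
  prev_diff <- Inf
  prev_oob <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    oob_wrong <- 0; oob_n <- 0
    for (cl in imp_cols) {
      obs_rows <- setdiff(seq_len(nrow(filled)), na_idx[[cl]])
      y <- droplevels(filled[[cl]][obs_rows])
      X <- filled[obs_rows, setdiff(names(filled), cl), drop = FALSE]
      if (nlevels(y) < 2L) next  # constant column: mode fill stands
      rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees)
      oob_pred <- rf$predicted
      oob_wrong <- oob_wrong + sum(oob_pred != y)
      oob_n <- oob_n + length(y)
      newdata <- filled[na_idx[[cl]], setdiff(names(filled), cl),
                        drop = FALSE]
      pred <- stats::predict(rf, newdata = newdata)
      filled[[cl]][na_idx[[cl]]] <-
        factor(as.character(pred), levels = levels(filled[[cl]]))
    }
    oob <- list(PFC = if (oob_n > 0) oob_wrong / oob_n else 0, NRMSE = 0)
    n_imp <- sum(vapply(imp_cols, function(cl) length(na_idx[[cl]]),
                        integer(1)))
    changed <- sum(vapply(imp_cols, function(cl)
      sum(filled[[cl]][na_idx[[cl]]] != prev[[cl]][na_idx[[cl]]]),
      integer(1)))
    diff <- if (n_imp > 0) changed / n_imp else 0
    if (diff > prev_diff || iter >= max_iter) {
      use <- if (diff > prev_diff) prev else filled
      use_oob <- if (diff > prev_diff && !is.null(prev_oob)) prev_oob else oob
      out <- finish_imputation(traits, use, cols, impute_iucn, scheme)
      attr(out, "oob_error") <- use_oob
      attr(out, "n_iterations") <- iter
      return(out)
    }
    if (diff == 0) {
      out <- finish_imputation(traits, filled, cols, impute_iucn, scheme)
      attr(out, "oob_error") <- oob
      attr(out, "n_iterations") <- iter
      return(out)
    }
    prev <- filled
    prev_diff <- diff
    prev_oob <- oob
  }
}

finish_imputation <- function(traits, filled, cols, impute_iucn, scheme) {
  out <- traits
  for (cl in cols)
    out[[cl]] <- factor(as.character(filled[[cl]]),
                        levels = scheme[[cl]]$levels,
                        ordered = isTRUE(scheme[[cl]]$ordered))
  if (impute_iucn && "iucn" %in% names(filled))
    out$iucn <- as.character(filled$iucn)
  out
}

#' Gower distance between species on categorical traits
#'
#' Per-trait contribution: 0/1 mismatch for unordered traits;
#' `|rank_i - rank_j| / (n_modalities - 1)` with evenly spaced ranks for
#' ordered traits. The distance is the unweighted mean of the per-trait
#' contributions, so it lies in `[0, 1]` with zero diagonal. Missing cells
#' are an error: impute first.
#'
#' @param traits Trait table (imputed, pruned).
#' @param scheme Trait scheme.
#' @return Species x species symmetric distance matrix.
#' @export
gower_distance <- function(traits, scheme) {
  cols <- intersect(names(scheme), names(traits))
  if (length(cols) == 0L) stop("no trait columns found", call. = FALSE)
  n <- nrow(traits)
  labs <- if (!is.null(traits$species_id)) traits$species_id
          else rownames(traits)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (cl in cols) {
    lv <- scheme[[cl]]$levels
    x <- as.character(traits[[cl]])
    if (anyNA(x))
      stop("trait '", cl, "' has missing cells; run impute_missforest() ",
           "before computing Gower distances", call. = FALSE)
    bad <- setdiff(unique(x), lv)
    if (length(bad))
      stop("trait '", cl, "' has undeclared modalities: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (isTRUE(scheme[[cl]]$ordered)) {
      r <- match(x, lv)
      contrib <- abs(outer(r, r, "-")) / (length(lv) - 1)
    } else {
      contrib <- 1 - outer(x, x, "==")
    }
    d <- d + contrib
  }
  d / length(cols)
}

#' Build the PCoA trait space
#'
#' Runs [pcoa_dist()] on the Gower distance matrix and keeps the first `m`
#' positive-eigenvalue axes; Euclidean distances on these axes define the
#' working trait space.
#'
#' @param d Species x species Gower distance matrix.
#' @param m Number of axes (default 4).
#' @return Object of class `trait_space`: `coords` (species x m), `eig`,
#'   `m`, `negative_magnitude`.
#' @export
build_trait_space <- function(d, m = 4) {
  pc <- pcoa_dist(d)
  avail <- ncol(pc$points)
  if (m > avail)
    stop("m = ", m, " exceeds the ", avail,
         " positive-eigenvalue axes available", call. = FALSE)
  structure(list(coords = pc$points[, seq_len(m), drop = FALSE],
                 eig = pc$eig, m = m,
                 full_coords = pc$points,
                 negative_magnitude = pc$negative_magnitude),
            class = "trait_space")
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait space:", nrow(x$coords), "species on", x$m, "PCoA axes\n")
  pos <- sum(x$eig > 0)
  cat("  positive eigenvalues:", pos,
      "| negative magnitude:", format(x$negative_magnitude, digits = 3),
      "\n")
  invisible(x)
}

#' Trait-space quality by mean absolute deviation (mAD)
#'
#' For each candidate dimensionality m, the embedded Euclidean distances on
#' the first m axes are rescaled so their maximum equals the maximum Gower
#' distance, and mAD is the mean over species pairs of the absolute deviation
#' between rescaled embedded and Gower distances. The best m is the argmin;
#' ties go to the smaller m.
#'
#' @param d Gower distance matrix.
#' @param space A `trait_space` (its `full_coords` are used).
#' @param dims Candidate dimensionalities (defaults to 1..available axes,
#'   capped at 10).
#' @return List: `mad` (named numeric per m), `best` (chosen m).
#' @export
quality_mad <- function(d, space, dims = NULL) {
  d <- as.matrix(d)
  P <- space$full_coords
  if (is.null(dims)) dims <- seq_len(min(ncol(P), 10L))
  if (max(dims) > ncol(P))
    stop("candidate dimensionality exceeds available axes", call. = FALSE)
  ut <- upper.tri(d)
  gmax <- max(d[ut])
  mads <- vapply(dims, function(m) {
    e <- as.matrix(stats::dist(P[, seq_len(m), drop = FALSE]))
    emax <- max(e[ut])
    if (emax > 0) e <- e * (gmax / emax)
    mean(abs(e[ut] - d[ut]))
  }, numeric(1))
  names(mads) <- dims
  list(mad = mads, best = dims[which.min(mads)])
}
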