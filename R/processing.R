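# Raw per-individual observations -> corrected lengths, biomass, and
# transect x species density matrices (individuals or grams per 100 m^2).

#' Stereo-video length correction factor
#'
#' A calibration fault that underestimates lengths by a fraction `u` is
#' corrected by multiplying stored lengths by `1 / (1 - u)`; e.g. a 46%
#' underestimation gives a multiplier of 1.85 (2 d.p.).
#'
#' @param underestimation Fraction in `[0, 1)`.
#' @return The multiplier (full precision; round to 2 d.p. for reporting).
#' @export
correction_factor <- function(underestimation) {
  if (!is.numeric(underestimation) || underestimation < 0 ||
      underestimation >= 1)
    stop("underestimation must be a fraction in [0, 1)", call. = FALSE)
  1 / (1 - underestimation)
}

#' Apply the length correction to flagged transects
#'
#' Multiplies lengths on calibration-flagged transects by `factor`; all other
#' lengths are untouched. A `length_corrected` provenance column records which
#' rows were corrected.
#'
#' @param obs Observation table.
#' @param meta Transect metadata with `calibration_flag`.
#' @param factor Multiplier >= 1, typically from [correction_factor()].
#' @return The observation table with corrected `length_cm`.
#' @export
apply_length_correction <- function(obs, meta, factor) {
  stopifnot(factor >= 1)
  flagged <- meta$transect_id[meta$calibration_flag]
  hit <- obs$transect_id %in% flagged & !is.na(obs$length_cm)
  obs$length_cm[hit] <- obs$length_cm[hit] * factor
  obs$length_corrected <- hit
  obs
}

#' Fill missing fish lengths
#'
#' Missing lengths are replaced by the mean measured length of conspecifics
#' on the same transect; failing that, by the species mean within the same
#' atoll (logged as a fallback); failing that, the individual is excluded
#' from biomass (its `length_cm` stays `NA`, `biomass_excluded` is set) but
#' retained for abundance.
#'
#' @param obs Observation table.
#' @param meta Transect metadata (for the atoll fallback).
#' @return Observation table with `length_filled` and `biomass_excluded`
#'   columns; fallback/exclusion counts attached as attribute `fill_log`.
#' @export
fill_missing_lengths <- function(obs, meta) {
  obs$length_filled <- FALSE
  obs$biomass_excluded <- FALSE
  miss <- which(is.na(obs$length_cm))
  if (length(miss) == 0L) {
    attr(obs, "fill_log") <- c(transect = 0L, atoll = 0L, excluded = 0L)
    return(obs)
  }
  atoll_of <- stats::setNames(meta$atoll, meta$transect_id)
  obs_atoll <- atoll_of[obs$transect_id]
  key_tr <- paste(obs$transect_id, obs$taxon)
  key_at <- paste(obs_atoll, obs$taxon)
  measured <- !is.na(obs$length_cm)
  mean_by <- function(key) {
    tapply(obs$length_cm[measured], key[measured], mean)
  }
  m_tr <- mean_by(key_tr)
  m_at <- mean_by(key_at)
  n_tr_fill <- 0L; n_at_fill <- 0L; n_excl <- 0L
  for (i in miss) {
    v <- unname(m_tr[key_tr[i]])
    if (length(v) == 1L && !is.na(v)) {
      obs$length_cm[i] <- v; obs$length_filled[i] <- TRUE
      n_tr_fill <- n_tr_fill + 1L
    } else {
      v <- unname(m_at[key_at[i]])
      if (length(v) == 1L && !is.na(v)) {
        obs$length_cm[i] <- v; obs$length_filled[i] <- TRUE
        n_at_fill <- n_at_fill + 1L
      } else {
        obs$biomass_excluded[i] <- TRUE
        n_excl <- n_excl + 1L
      }
    }
  }
  if (n_excl > 0)
    warning(n_excl, " individual(s) have no conspecific length anywhere; ",
            "excluded from biomass, retained in abundance", call. = FALSE)
  attr(obs, "fill_log") <- c(transect = n_tr_fill, atoll = n_at_fill,
                             excluded = n_excl)
  obs
}

#' Length-weight conversion
#'
#' Converts fish total length (cm) to wet weight (g) with the allometric
#' relation `W = a * L^b`.
#'
#' @param length_cm Length(s) in cm, >= 0.
#' @param a,b Species-specific conversion constants (`a > 0`, `b > 0`).
#' @return Weight(s) in grams.
#' @export
biomass_g <- function(length_cm, a, b) {
  stopifnot(all(a > 0), all(b > 0), all(length_cm >= 0, na.rm = TRUE))
  a * length_cm^b
}

#' Assign length-weight constants, with surrogates for unresolved taxa
#'
#' Species-level rows take their own constants (an error names any species
#' without constants). Rows identified only to genus/order inherit the
#' constants of the most abundant species of the same `taxon_group` on the
#' same transect; failing that, in the same location (atoll x depth band);
#' ties broken by greater study-wide abundance, then lexicographic taxon
#' label. Unresolved taxa with no resolved group member anywhere raise an
#' error listing the orphans.
#'
#' @param obs Observation table with `taxon_group` and `id_level`.
#' @param constants Data frame `taxon`, `a`, `b`.
#' @param meta Transect metadata (for the location fallback).
#' @return Observation table with `lw_a`, `lw_b` and `surrogate_taxon`
#'   columns.
#' @export
assign_surrogate_constants <- function(obs, constants, meta) {
  ab <- stats::setNames(seq_len(nrow(constants)), constants$taxon)
  obs$lw_a <- NA_real_; obs$lw_b <- NA_real_
  obs$surrogate_taxon <- NA_character_
  is_sp <- obs$id_level == "species"
  idx <- ab[obs$taxon[is_sp]]
  if (anyNA(idx)) {
    bad <- sort(unique(obs$taxon[is_sp][is.na(idx)]))
    stop("no length-weight constants for species: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  obs$lw_a[is_sp] <- constants$a[idx]
  obs$lw_b[is_sp] <- constants$b[idx]
  un <- which(!is_sp)
  if (length(un) == 0L) return(obs)

  loc_of <- stats::setNames(paste(meta$atoll, meta$depth_band_m),
                            meta$transect_id)
  res <- obs[is_sp, , drop = FALSE]
  study_tot <- table(res$taxon)
  pick_donor <- function(cands) {
    ## cands: resolved rows (data frame) of the right group & scope
    if (nrow(cands) == 0L) return(NA_character_)
    tab <- sort(table(cands$taxon), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      tot <- study_tot[top]
      top <- top[tot == max(tot)]
    }
    sort(top)[1L]
  }
  for (i in un) {
    grp <- obs$taxon_group[i]
    same_tr <- res[res$taxon_group == grp &
                     res$transect_id == obs$transect_id[i], , drop = FALSE]
    donor <- pick_donor(same_tr)
    if (is.na(donor)) {
      same_loc <- res[res$taxon_group == grp &
                        loc_of[res$transect_id] ==
                          loc_of[[obs$transect_id[i]]], , drop = FALSE]
      donor <- pick_donor(same_loc)
    }
    if (is.na(donor)) {
      study <- res[res$taxon_group == grp, , drop = FALSE]
      donor <- pick_donor(study)
    }
    if (is.na(donor)) next  # collected below as orphan
    j <- ab[[donor]]
    obs$lw_a[i] <- constants$a[j]
    obs$lw_b[i] <- constants$b[j]
    obs$surrogate_taxon[i] <- donor
  }
  orphan <- !is_sp & is.na(obs$lw_a)
  if (any(orphan))
    stop("no resolved group member anywhere for unresolved taxa: ",
         paste(sort(unique(obs$taxon[orphan])), collapse = ", "),
         call. = FALSE)
  obs
}

#' Group species complexes under a single label
#'
#' Relabels the member taxa of visually inseparable species complexes to
#' their group label (counts and lengths are simply concatenated). Applying
#' the same mapping twice is a no-op.
#'
#' @param obs Observation table.
#' @param synonymy Named character vector or list: member label -> group
#'   label. A member mapped to two different groups is a configuration error.
#' @return Relabelled observation table.
#' @export
group_species <- function(obs, synonymy) {
  if (length(synonymy) == 0L) return(obs)
  syn <- unlist(synonymy)
  if (anyDuplicated(names(syn))) {
    dup <- names(syn)[duplicated(names(syn))]
    conflicting <- unique(dup[vapply(dup, function(d)
      length(unique(syn[names(syn) == d])) > 1L, logical(1))])
    if (length(conflicting))
      stop("taxa mapped to more than one group: ",
           paste(conflicting, collapse = ", "), call. = FALSE)
    syn <- syn[!duplicated(names(syn))]
  }
  hit <- obs$taxon %in% names(syn)
  obs$taxon[hit] <- unname(syn[obs$taxon[hit]])
  obs
}

#' Aggregate observations into a transect x taxon density matrix
#'
#' Cell (t, s) is the count (kind = "abundance") or the summed weight in
#' grams (kind = "biomass") of taxon s on transect t, standardised per
#' 100 m^2 of transect area. Taxa not resolved to species level are kept in
#' reserved columns (prefix `"unid."`): they contribute to density totals but
#' are excluded from species-level analyses via the `species` column
#' attribute.
#'
#' @param obs Observation table (lengths corrected/filled, and constants
#'   assigned via [assign_surrogate_constants()] if `kind = "biomass"`).
#' @param meta Transect metadata.
#' @param kind `"abundance"` or `"biomass"`.
#' @return A `community_matrix`: numeric matrix (transects x taxa) with
#'   attributes `kind` and `species` (logical per column).
#' @export
aggregate_matrix <- function(obs, meta, kind = c("abundance", "biomass")) {
  kind <- match.arg(kind)
  unknown <- setdiff(unique(obs$transect_id), meta$transect_id)
  if (length(unknown))
    stop("observations reference unknown transect(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  col_lab <- ifelse(obs$id_level == "species", obs$taxon,
                    paste0("unid.", obs$taxon))
  if (kind == "abundance") {
    val <- rep(1, nrow(obs))
  } else {
    if (is.null(obs$lw_a))
      stop("biomass requires length-weight constants; ",
           "run assign_surrogate_constants() first", call. = FALSE)
    excl <- if (is.null(obs$biomass_excluded)) is.na(obs$length_cm)
            else obs$biomass_excluded | is.na(obs$length_cm)
    val <- ifelse(excl, 0, biomass_g(ifelse(excl, 0, obs$length_cm),
                                     obs$lw_a, obs$lw_b))
  }
  taxa <- sort(unique(col_lab))
  mat <- matrix(0, nrow(meta), length(taxa),
                dimnames = list(meta$transect_id, taxa))
  if (nrow(obs)) {
    agg <- tapply(val, list(obs$transect_id, col_lab), sum)
    agg[is.na(agg)] <- 0
    mat[rownames(agg), colnames(agg)] <- agg
  }
  area <- meta$length_m * meta$width_m
  mat <- mat * (100 / area)
  structure(mat, kind = kind,
            species = !startsWith(taxa, "unid."),
            class = c("community_matrix", "matrix", "array"))
}

#' Species-level columns of a community matrix
#'
#' @param mat A `community_matrix` from [aggregate_matrix()].
#' @return The matrix restricted to species-level columns.
#' @export
species_columns <- function(mat) {
  sp <- attr(mat, "species")
  if (is.null(sp)) return(mat)
  mat[, sp, drop = FALSE]
}
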