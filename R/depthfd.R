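# End-to-end analysis: observations -> corrected lengths and biomass ->
# community matrices -> taxonomic and permutational statistics -> trait
# space -> functional-entity and distance-based FD metrics -> FUSE ranking.

#' Fit the full depth-gradient diversity analysis
#'
#' Runs the whole pipeline on an observation table, transect metadata, a
#' species trait table and length-weight constants: species-complex
#' grouping, stereo-video length correction, missing-length filling,
#' surrogate length-weight constants, per-100-m^2 abundance and biomass
#' matrices, per-transect taxonomic metrics with Kruskal-Wallis and
#' FDR-corrected pairwise Mann-Whitney tests across depth bands,
#' square-root Bray-Curtis PCoA with PERMANOVA and PERMDISP, trait pruning,
#' iterative random-forest imputation, the Gower/PCoA trait space with mAD
#' quality, functional-entity redundancy metrics, convex-hull/dispersion/
#' evenness alpha diversity (on transects with at least `min_species`
#' species), species functional specialization and uniqueness, and the FUSE
#' ranking.
#'
#' @param observations Per-individual observation table (`transect_id`,
#'   `taxon`, `taxon_group`, `id_level`, `length_cm`).
#' @param transects Transect metadata (`transect_id`, `atoll`,
#'   `depth_band_m`, `length_m`, `width_m`, `calibration_flag`).
#' @param traits Species trait table (`species_id`, trait columns, `iucn`,
#'   `commercial_value`), possibly with missing cells.
#' @param lw_constants Data frame `taxon`, `a`, `b`.
#' @param scheme Trait scheme (see [default_trait_scheme()]).
#' @param synonymy Optional named vector mapping member taxa to species
#'   complexes, applied before everything else.
#' @param underestimation Length underestimation fraction on
#'   calibration-flagged transects (default 0.46).
#' @param min_species Richness threshold for alpha FD (default 5).
#' @param axes Trait-space dimensionality (default 4).
#' @param k_neighbors Neighbours for functional uniqueness (default 5).
#' @param n_perm Permutations for PERMANOVA/PERMDISP (default 9999).
#' @param prune_threshold Kendall threshold for trait pruning (default 0.8).
#' @param seed Seed for imputation and permutation streams.
#' @param run_permutation_tests Set `FALSE` to skip the (slow) PERMANOVA /
#'   PERMDISP stage.
#' @return An object of class `depthfd`; see [print.depthfd()],
#'   [summary.depthfd()], [plot.depthfd()]. Components include
#'   `abundance`, `biomass` (community matrices), `transect_table`
#'   (per-transect taxonomic + functional metrics), `tests`, `trait_space`,
#'   `fe`, `species_table` (FUSE ranking), `correlations`.
#' @export
depthfd <- function(observations, transects, traits, lw_constants,
                    scheme = default_trait_scheme(), synonymy = NULL,
                    underestimation = 0.46, min_species = 5, axes = 4,
                    k_neighbors = 5, n_perm = 9999, prune_threshold = 0.8,
                    seed = 1L, run_permutation_tests = TRUE) {
  obs <- observations
  if (!is.null(synonymy)) obs <- group_species(obs, synonymy)
  fac <- correction_factor(underestimation)
  obs <- apply_length_correction(obs, transects, fac)
  obs <- fill_missing_lengths(obs, transects)
  obs <- assign_surrogate_constants(obs, lw_constants, transects)

  abundance <- aggregate_matrix(obs, transects, "abundance")
  biomass <- aggregate_matrix(obs, transects, "biomass")
  tm <- transect_metrics(abundance, biomass)
  band <- factor(transects$depth_band_m[
    match(tm$transect_id, transects$transect_id)])
  tm$depth_band_m <- as.numeric(as.character(band))

  tests <- list(
    kruskal = lapply(
      c(richness = "richness", abundance = "abundance_density",
        biomass = "biomass_density"),
      function(v) kruskal_depth(tm[[v]], band)),
    mann_whitney = lapply(
      c(richness = "richness", abundance = "abundance_density",
        biomass = "biomass_density"),
      function(v) pairwise_mann_whitney(tm[[v]], band)))

  bc <- bray_curtis(abundance, "sqrt")
  ord <- pcoa_dist(bc)
  if (run_permutation_tests) {
    tests$permanova <- permanova(bc, band, n_perm = n_perm, seed = seed)
    tests$permanova_pairwise <- pairwise_permanova(bc, band, n_perm = n_perm,
                                                   seed = seed)
    tests$permdisp <- permdisp(bc, band, n_perm = n_perm, seed = seed,
                               pairwise = TRUE)
  }

  ## the pool is every species observed (at species level) across the study
  observed <- colnames(species_columns(abundance))
  no_traits <- setdiff(observed, traits$species_id)
  if (length(no_traits))
    stop("observed species missing from the trait table: ",
         paste(utils::head(no_traits, 5), collapse = ", "),
         if (length(no_traits) > 5) ", ...", call. = FALSE)
  traits <- traits[traits$species_id %in% observed, , drop = FALSE]

  pruned <- prune_correlated(traits, scheme, prune_threshold)
  kept <- attr(pruned, "kept_traits")
  sub_scheme <- scheme[kept]
  imputed <- impute_missforest(pruned, sub_scheme, seed = seed)
  gd <- gower_distance(imputed, sub_scheme)
  space <- build_trait_space(gd, m = axes)
  mad <- quality_mad(gd, space,
                     dims = seq_len(min(10L, ncol(space$full_coords))))

  fes <- assign_functional_entities(imputed, sub_scheme)
  pool_fe <- fe_metrics(fes)

  A <- species_columns(abundance)
  pool_volume <- convhull_volume(space$coords)
  filt <- alpha_fd_filter(abundance, transects, min_species)
  fspe_s <- fspe(space)
  fun_s <- fun_uniqueness(space, k = k_neighbors)

  tm$n_fe <- tm$FRed <- tm$FOR <- tm$FVul <- NA_real_
  tm$FRic <- tm$FDis <- tm$FEve <- tm$FSpe <- NA_real_
  for (r in seq_len(nrow(tm))) {
    t_id <- tm$transect_id[r]
    w <- A[t_id, ]
    members <- names(w)[w > 0]
    if (length(members) == 0L) next
    fm <- fe_metrics(fes, members)
    tm$n_fe[r] <- fm$K; tm$FRed[r] <- fm$FRed
    tm$FOR[r] <- fm$FOR; tm$FVul[r] <- fm$FVul
    wpos <- w[members]
    tm$FSpe[r] <- fspe_community(fspe_s, wpos)
    if (t_id %in% rownames(filt$matrix)) {
      tm$FRic[r] <- fric(space, members, pool_volume)
      tm$FDis[r] <- fdis(space, wpos)
      tm$FEve[r] <- feve(space, wpos)
    }
  }

  iucn <- stats::setNames(imputed$iucn, imputed$species_id)
  sp_table <- fuse_ranking(fun_s, fspe_s, iucn, traits = imputed,
                           abundance = abundance, meta = transects)

  corr_cols <- c("richness", "n_fe", "FRed", "FOR", "FVul", "FRic",
                 "FDis", "FEve", "FSpe")
  correlations <- metric_correlation_summary(tm[corr_cols])

  structure(list(
    observations = obs, transects = transects,
    abundance = abundance, biomass = biomass,
    transect_table = tm, tests = tests,
    ordination = ord, bray_curtis = bc,
    traits_imputed = imputed, pruning = attr(pruned, "pruning"),
    imputation_error = attr(imputed, "oob_error"),
    gower = gd, trait_space = space, mad = mad,
    fe = fes, pool_fe = pool_fe, pool_volume = pool_volume,
    alpha_filter = filt, fspe = fspe_s, fun = fun_s,
    species_table = sp_table, correlations = correlations,
    config = list(underestimation = underestimation,
                  min_species = min_species, axes = axes,
                  k_neighbors = k_neighbors, n_perm = n_perm,
                  prune_threshold = prune_threshold, seed = seed)),
    class = "depthfd")
}

#' @describeIn depthfd Compact overview of the fitted analysis.
#' @param x,object A `depthfd` object.
#' @param ... Unused.
#' @export
print.depthfd <- function(x, ...) {
  tm <- x$transect_table
  cat("Depth-gradient diversity analysis\n")
  cat("  ", nrow(tm), "transects,",
      sum(attr(x$abundance, "species")), "species,",
      nrow(x$fe$entities), "functional entities\n")
  cat("  trait space:", x$trait_space$m, "PCoA axes (mAD-best m =",
      x$mad$best, ")\n")
  if (!is.null(x$tests$permanova))
    cat("  PERMANOVA depth effect: pseudo-F =",
        format(x$tests$permanova$statistic, digits = 4), ", p =",
        format(x$tests$permanova$p_value, digits = 3), "\n")
  cat("  top FUSE species:",
      paste(utils::head(x$species_table$species_id, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn depthfd Per-depth-band medians of the main metrics and the
#'   head of the FUSE ranking.
#' @export
summary.depthfd <- function(object, ...) {
  tm <- object$transect_table
  bands <- sort(unique(tm$depth_band_m))
  med <- function(v) vapply(bands, function(b)
    stats::median(tm[[v]][tm$depth_band_m == b], na.rm = TRUE), numeric(1))
  band_table <- data.frame(
    depth_band_m = bands,
    richness = med("richness"),
    abundance = med("abundance_density"),
    FRic = med("FRic"), FRed = med("FRed"), FVul = med("FVul"),
    row.names = NULL)
  out <- list(band_table = band_table,
              fuse_head = utils::head(object$species_table, 10),
              imputation_error = object$imputation_error,
              pruning = object$pruning)
  class(out) <- "summary.depthfd"
  out
}

#' @export
print.summary.depthfd <- function(x, ...) {
  cat("Per-depth-band medians:\n")
  print(format(x$band_table, digits = 3), row.names = FALSE)
  cat("\nTop FUSE species:\n")
  print(format(x$fuse_head[c("species_id", "FUSE", "FUn", "FSpe", "iucn")],
               digits = 3), row.names = FALSE)
  if (!is.null(x$imputation_error))
    cat("\nImputation OOB error: PFC =",
        format(x$imputation_error$PFC, digits = 3),
        ", NRMSE =", x$imputation_error$NRMSE, "\n")
  if (!is.null(x$pruning) && nrow(x$pruning))
    cat("Pruned traits:", paste(x$pruning$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn depthfd Boxplots of richness and the main functional metrics
#'   by depth band.
#' @export
plot.depthfd <- function(x, ...) {
  tm <- x$transect_table
  band <- factor(tm$depth_band_m, levels = sort(unique(tm$depth_band_m)))
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (v in c("richness", "FRic", "FDis", "FRed", "FOR", "FVul")) {
    graphics::boxplot(tm[[v]] ~ band, xlab = "depth band (m)", ylab = v,
                      main = v, col = "grey85", ...)
  }
  invisible(x)
}

#' Write the main result tables of a fitted analysis to CSV
#'
#' Writes the per-transect metric table, the species FUSE table, the
#' functional-entity table, the metric correlation matrix and the
#' per-100-m^2 community matrices into `dir`.
#'
#' @param fit A `depthfd` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_depthfd <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(transect_metrics = file.path(dir, "transect_metrics.csv"),
             species_fuse = file.path(dir, "species_fuse.csv"),
             functional_entities = file.path(dir, "functional_entities.csv"),
             correlations = file.path(dir, "metric_correlations.csv"),
             abundance = file.path(dir, "abundance_matrix.csv"),
             biomass = file.path(dir, "biomass_matrix.csv"))
  utils::write.csv(fit$transect_table, paths[["transect_metrics"]],
                   row.names = FALSE)
  utils::write.csv(fit$species_table, paths[["species_fuse"]],
                   row.names = FALSE)
  utils::write.csv(fit$fe$entities, paths[["functional_entities"]],
                   row.names = FALSE)
  utils::write.csv(fit$correlations, paths[["correlations"]])
  utils::write.csv(as.data.frame(unclass(fit$abundance)),
                   paths[["abundance"]])
  utils::write.csv(as.data.frame(unclass(fit$biomass)), paths[["biomass"]])
  invisible(paths)
}
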