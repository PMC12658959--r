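# Synthetic survey generator: species pools with depth-band affinities and
# habitat-filtered categorical traits, transect observation tables, and trait
# masking -- so the whole downstream pipeline is testable without field data.

#' Default depth bands (m) of the survey design
#'
#' Seven target depth bands spanning shallow reef (2-5 m, labelled 2),
#' scuba/ROV depths (10, 30 m), mesophotic (60, 120 m), rariphotic (250 m)
#' and upper bathyal (500 m).
#' @return Integer vector of band labels in metres, shallowest first.
#' @export
default_depth_bands <- function() c(2L, 10L, 30L, 60L, 120L, 250L, 500L)

#' Default atoll labels
#' @return Character vector of five atoll labels.
#' @export
default_atolls <- function() c("Vaavu", "Laamu", "Huvadhu", "Addu", "NorthMale")

#' Default categorical trait scheme
#'
#' Eight life-history traits, each with a declared modality set and an
#' ordered/unordered flag. Ordered traits carry their modalities in rank
#' order. Bin boundaries (e.g. maximum length at 15/30/50/80/150 cm) are
#' configuration: any scheme with >= 2 modalities per trait is accepted by
#' the generator and the trait-space code is bin-agnostic.
#'
#' @return Named list; each element has `levels` (character) and `ordered`
#'   (logical).
#' @export
default_trait_scheme <- function() {
  list(
    age_maturity = list(
      levels = c("<1y", "1-2y", "2-5y", "5-10y", ">10y"), ordered = TRUE),
    generation_time = list(
      levels = c("<2y", "2-4y", "4-8y", "8-15y", ">15y"), ordered = TRUE),
    max_length = list(
      levels = c("<15cm", "15-30cm", "30-50cm", "50-80cm", "80-150cm",
                 ">150cm"), ordered = TRUE),
    pop_doubling = list(  # minimum population doubling time (resilience proxy)
      levels = c("<15mo", "1.4-4.4y", "4.5-14y", ">14y"), ordered = TRUE),
    fishing_vulnerability = list(
      levels = c("low", "moderate", "high", "very_high"), ordered = TRUE),
    water_column = list(
      levels = c("benthic", "demersal", "benthopelagic", "pelagic"),
      ordered = FALSE),
    temp_range = list(
      levels = c("narrow", "moderate", "wide"), ordered = TRUE),
    vertical_range = list(
      levels = c("<50m", "50-200m", "200-500m", ">500m"), ordered = TRUE)
  )
}

#' IUCN Red List categories recognised by the package
#' @return Character vector.
#' @export
iucn_categories <- function() c("LC", "NT", "VU", "EN", "CR", "DD", "NE")

trait_columns <- function(scheme) names(scheme)

check_trait_scheme <- function(scheme) {
  if (is.null(scheme) || length(scheme) == 0L)
    stop("trait scheme is empty: declare at least one trait", call. = FALSE)
  for (tr in names(scheme)) {
    lv <- scheme[[tr]]$levels
    if (length(lv) < 2L)
      stop("trait '", tr, "' must declare >= 2 modalities", call. = FALSE)
    if (anyDuplicated(lv))
      stop("trait '", tr, "' has duplicated modalities", call. = FALSE)
  }
  invisible(scheme)
}

## cut a latent value in [0,1] into one of L ordered modalities
discretize01 <- function(x, L) {
  pmin(L, pmax(1L, as.integer(floor(pmin(pmax(x, 0), 0.999999) * L)) + 1L))
}

#' Generate a synthetic species pool
#'
#' Builds a pool of demersal fish species with depth-band affinities,
#' length-weight constants, categorical trait vectors, IUCN categories and
#' commercial-value scores. Depth structures the pool in two ways: a latent
#' "pace of life" drifts slower with depth (so the correlated life-history
#' trio of age at maturity, generation time and population doubling time
#' shifts together), and habitat filtering restricts the modality subsets
#' available to deeper-band specialists (water-column position and
#' temperature range), so the count of distinct trait combinations per
#' species declines with depth. Threat status (VU/EN/CR) is drawn with
#' elevated probability for large-bodied modalities; a fraction of species
#' are Data Deficient or Not Evaluated.
#'
#' @param n_species Number of species (>= 0).
#' @param scheme Trait scheme, see [default_trait_scheme()].
#' @param depth_bands Ordered depth band labels (m).
#' @param filter_strength In `[0, 1]`; 0 disables trait-depth filtering, 1
#'   restricts the deepest band to the minimal modality subsets.
#' @param seed Optional integer seed; fixed seed gives identical pools.
#' @return A data frame with one row per species: `species_id`, `genus`,
#'   `depth_affinity` (semicolon-separated band labels), `typical_length_cm`,
#'   `length_sdlog`, `lw_a`, `lw_b`, one factor column per trait, `iucn`,
#'   `commercial_value`.
#' @export
generate_species_pool <- function(n_species = 300,
                                  scheme = default_trait_scheme(),
                                  depth_bands = default_depth_bands(),
                                  filter_strength = 0.5,
                                  seed = NULL) {
  check_trait_scheme(scheme)
  stopifnot(n_species >= 0, length(depth_bands) >= 1)
  if (!is.null(seed)) set.seed(seed)
  nb <- length(depth_bands)
  empty <- function() {
    out <- data.frame(species_id = character(), genus = character(),
                      depth_affinity = character(),
                      typical_length_cm = numeric(), length_sdlog = numeric(),
                      lw_a = numeric(), lw_b = numeric(),
                      stringsAsFactors = FALSE)
    for (tr in names(scheme)) out[[tr]] <- character()
    out$iucn <- character(); out$commercial_value <- integer()
    out
  }
  if (n_species == 0L) return(empty())

  ## shallow-weighted primary band (richness peaks near the second band)
  w <- c(0.16, 0.22, 0.18, 0.14, 0.11, 0.08, 0.11)
  w <- if (nb <= 7) w[seq_len(nb)] else c(w, rep(0.05, nb - 7))
  primary <- sample.int(nb, n_species, replace = TRUE, prob = w / sum(w))
  half_w <- sample(0:2, n_species, replace = TRUE, prob = c(0.35, 0.45, 0.20))
  lo <- pmax(1L, primary - half_w)
  hi <- pmin(nb, primary + half_w)
  affinity <- mapply(function(a, b) paste(depth_bands[a:b], collapse = ";"),
                     lo, hi)
  depth_frac <- if (nb > 1) (primary - 1) / (nb - 1) else rep(0, n_species)

  ## latent pace of life: slower (higher) at depth
  pace <- pmin(1, pmax(0, 0.55 * stats::runif(n_species) +
                            0.25 * depth_frac + 0.20 * stats::runif(n_species)))
  ## body size: lognormal, drifting larger with depth
  typical_length <- stats::rlnorm(n_species,
                                  meanlog = log(14) + 0.9 * depth_frac,
                                  sdlog = 0.65)
  max_length_cm <- typical_length / 0.6

  pick_ordered <- function(latent, trait, noise = 0.06) {
    lv <- scheme[[trait]]$levels
    discretize01(latent + stats::rnorm(n_species, 0, noise), length(lv))
  }

  traits <- list()
  size01 <- pmin(1, pmax(0, (log(max_length_cm) - log(8)) / (log(300) - log(8))))
  for (tr in names(scheme)) {
    lv <- scheme[[tr]]$levels
    L <- length(lv)
    idx <- switch(tr,
      age_maturity    = pick_ordered(pace, tr, 0.05),
      generation_time = pick_ordered(pace, tr, 0.05),
      pop_doubling    = pick_ordered(pace, tr, 0.06),
      max_length      = {
        br <- c(0, 15, 30, 50, 80, 150, Inf)
        if (L == 6L) as.integer(cut(max_length_cm, br))
        else discretize01(size01, L)
      },
      fishing_vulnerability = discretize01(
        0.9 * size01 + 0.1 * stats::runif(n_species), L),
      temp_range = discretize01(
        0.85 * (1 - depth_frac) + 0.15 * stats::runif(n_species), L),
      vertical_range = {
        ## tied to the depth extent of the affinity window
        maxd <- depth_bands[hi]
        pmin(L, findInterval(maxd, c(0, 50, 200, 500)) )
      },
      ## depth-filtered traits: deeper specialists draw from a restricted
      ## leading subset of the modality list
      {
        k <- pmax(1L, ceiling(L * (1 - filter_strength * depth_frac)))
        vapply(k, function(kk) sample.int(kk, 1L), integer(1))
      })
    traits[[tr]] <- factor(lv[idx], levels = lv, ordered = scheme[[tr]]$ordered)
  }

  ## IUCN: threat probability rises with body size
  p_threat <- pmin(0.6, 0.03 + 0.45 * size01^2)
  u <- stats::runif(n_species)
  iucn <- rep("LC", n_species)
  threatened <- u < p_threat
  iucn[threatened] <- sample(c("NT", "VU", "EN", "CR"), sum(threatened),
                             replace = TRUE, prob = c(0.40, 0.35, 0.15, 0.10))
  dd <- !threatened & stats::runif(n_species) < 0.17
  iucn[dd] <- sample(c("DD", "NE"), sum(dd), replace = TRUE,
                     prob = c(0.6, 0.4))

  commercial <- pmin(5L, pmax(0L, as.integer(round(
    4.5 * size01 * (1 - 0.6 * depth_frac) + stats::rnorm(n_species, 0, 0.6)))))

  ## genera: clustered within primary bands so surrogate donors exist
  gen_idx <- vapply(primary, function(b) {
    sample.int(max(1L, round(n_species * w[b] / sum(w) / 3)), 1L)
  }, integer(1))
  genus <- sprintf("gen%02d_%02d", primary, gen_idx)

  out <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n_species)),
    genus = genus,
    depth_affinity = affinity,
    typical_length_cm = typical_length,
    length_sdlog = 0.20,
    lw_a = stats::rlnorm(n_species, log(0.013), 0.35),
    lw_b = pmin(3.6, pmax(2.5, stats::rnorm(n_species, 3.03, 0.12))),
    stringsAsFactors = FALSE
  )
  for (tr in names(scheme)) out[[tr]] <- traits[[tr]]
  out$iucn <- iucn
  out$commercial_value <- commercial
  attr(out, "trait_scheme") <- scheme
  attr(out, "depth_bands") <- depth_bands
  out
}

#' Survey design parameters
#'
#' The default emulates the study design: 7 depth bands x 5 atolls x 3
#' replicate 250 x 5 m transects (105 cells), per-band expected richness
#' peaking at 10 m and lowest at 250 m, negative-binomial per-species counts,
#' lognormal individual lengths, a fraction of unmeasured lengths and of
#' genus-level identifications, and a fraction of deep (>= 60 m) transects
#' flagged with a stereo-camera calibration bias that shrinks stored lengths
#' by `underestimation`.
#'
#' @param depth_bands,atolls,replicates_per_cell Survey grid.
#' @param transect_length,transect_width Metres.
#' @param richness_decay Named numeric: expected species per transect per band.
#' @param abundance_mu Named numeric: negative-binomial mean count per present
#'   species per band.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param length_missing_rate Fraction of individuals with no length.
#' @param unresolved_rate Fraction of individuals identified to genus only.
#' @param underestimation Length underestimation fraction on flagged transects.
#' @param miscalibration_rate Fraction of >= 60 m transects flagged.
#' @param trait_missing_rate Fraction of trait cells masked as missing.
#' @param short_vaavu_30 If `TRUE`, 30-m transects on the first atoll are
#'   140 m long (emulating a camera failure).
#' @param seed Integer seed for the whole simulation.
#' @return An object of class `survey_design` (a list).
#' @export
survey_design <- function(depth_bands = default_depth_bands(),
                          atolls = default_atolls(),
                          replicates_per_cell = 3,
                          transect_length = 250,
                          transect_width = 5,
                          richness_decay = NULL,
                          abundance_mu = NULL,
                          dispersion = 1.2,
                          length_missing_rate = 0.05,
                          unresolved_rate = 0.02,
                          underestimation = 0.46,
                          miscalibration_rate = 0.3,
                          trait_missing_rate = 0.07,
                          short_vaavu_30 = TRUE,
                          seed = 1L) {
  nb <- length(depth_bands)
  if (is.null(richness_decay)) {
    rd <- c(30, 45, 38, 24, 12, 6, 9)
    richness_decay <- stats::setNames(rd[seq_len(nb)], depth_bands)
  }
  if (is.null(abundance_mu)) {
    am <- c(9, 11, 9, 6, 4, 3, 3)
    abundance_mu <- stats::setNames(am[seq_len(nb)], depth_bands)
  }
  stopifnot(transect_length > 0, transect_width > 0,
            replicates_per_cell >= 0,
            length_missing_rate >= 0, length_missing_rate < 1,
            underestimation >= 0, underestimation < 1)
  structure(list(
    depth_bands = depth_bands, atolls = atolls,
    replicates_per_cell = replicates_per_cell,
    transect_length = transect_length, transect_width = transect_width,
    richness_decay = richness_decay, abundance_mu = abundance_mu,
    dispersion = dispersion,
    length_missing_rate = length_missing_rate,
    unresolved_rate = unresolved_rate,
    underestimation = underestimation,
    miscalibration_rate = miscalibration_rate,
    trait_missing_rate = trait_missing_rate,
    short_vaavu_30 = short_vaavu_30,
    seed = as.integer(seed)), class = "survey_design")
}

## deterministic per-transect sub-seed so adding transects never perturbs
## earlier draws; kept below 2^31
transect_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) * 7919 + i * 104729) %% 2147483629)
}

#' Simulate transect observations from a species pool
#'
#' Per transect, species whose depth affinity includes the band are present
#' independently with probability set so expected richness follows
#' `design$richness_decay`; per-species counts are zero-truncated negative
#' binomial; individual lengths are lognormal around the species' typical
#' length. A fraction of individuals carry no length; a fraction are recorded
#' at genus level only. On calibration-flagged transects the stored length is
#' `(1 - underestimation)` times the latent true length (the true lengths are
#' attached as attribute `latent_length_cm`).
#'
#' @param pool Species pool from [generate_species_pool()].
#' @param design A [survey_design()].
#' @return List with `observations` (one row per individual: `transect_id`,
#'   `taxon`, `taxon_group`, `id_level`, `length_cm`, `measured`) and
#'   `transects` (metadata: `transect_id`, `atoll`, `depth_band_m`,
#'   `length_m`, `width_m`, `calibration_flag`).
#' @export
simulate_transects <- function(pool, design = survey_design()) {
  if (nrow(pool) == 0L) stop("species pool is empty", call. = FALSE)
  bands <- design$depth_bands
  aff <- strsplit(pool$depth_affinity, ";", fixed = TRUE)
  aff_num <- lapply(aff, as.numeric)
  covered <- vapply(bands, function(b)
    any(vapply(aff_num, function(a) b %in% a, logical(1))), logical(1))
  if (any(!covered))
    stop("no species has affinity for depth band(s): ",
         paste(bands[!covered], collapse = ", "), call. = FALSE)

  grid <- expand.grid(rep = seq_len(design$replicates_per_cell),
                      depth_band_m = bands, atoll = design$atolls,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_tr <- nrow(grid)
  meta <- data.frame(
    transect_id = sprintf("T%03d", seq_len(n_tr)),
    atoll = as.character(grid$atoll),
    depth_band_m = grid$depth_band_m,
    length_m = rep_len(design$transect_length, n_tr),
    width_m = rep_len(design$transect_width, n_tr),
    stringsAsFactors = FALSE)
  if (isTRUE(design$short_vaavu_30) && 30 %in% bands)
    meta$length_m[meta$depth_band_m == 30 &
                    meta$atoll == design$atolls[1]] <- 140

  set.seed(design$seed)
  meta$calibration_flag <- meta$depth_band_m >= 60 &
    stats::runif(n_tr) < design$miscalibration_rate

  obs_list <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    set.seed(transect_seed(design$seed, i))
    b <- meta$depth_band_m[i]
    cand <- which(vapply(aff_num, function(a) b %in% a, logical(1)))
    if (length(cand) == 0L) next
    p <- min(1, design$richness_decay[[as.character(b)]] / length(cand))
    pres <- cand[stats::runif(length(cand)) < p]
    if (length(pres) == 0L) next
    counts <- stats::rnbinom(length(pres),
                             mu = design$abundance_mu[[as.character(b)]],
                             size = design$dispersion)
    counts[counts == 0L] <- 1L
    sp <- rep(pres, counts)
    n_ind <- length(sp)
    true_len <- stats::rlnorm(n_ind, log(pool$typical_length_cm[sp]),
                              pool$length_sdlog[sp])
    stored <- if (meta$calibration_flag[i])
      true_len * (1 - design$underestimation) else true_len
    missing <- stats::runif(n_ind) < design$length_missing_rate
    stored[missing] <- NA_real_
    genus_only <- stats::runif(n_ind) < design$unresolved_rate
    obs_list[[i]] <- data.frame(
      transect_id = meta$transect_id[i],
      taxon = ifelse(genus_only, pool$genus[sp], pool$species_id[sp]),
      taxon_group = pool$genus[sp],
      id_level = ifelse(genus_only, "genus", "species"),
      length_cm = stored,
      measured = !missing,
      latent = true_len,
      stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs_list)
  if (is.null(obs))
    obs <- data.frame(transect_id = character(), taxon = character(),
                      taxon_group = character(), id_level = character(),
                      length_cm = numeric(), measured = logical(),
                      latent = numeric(), stringsAsFactors = FALSE)
  latent <- obs$latent
  obs$latent <- NULL
  rownames(obs) <- NULL
  attr(obs, "latent_length_cm") <- latent
  list(observations = obs, transects = meta)
}

#' Mask trait cells at random
#'
#' Sets exactly `round(rate * n_cells)` non-missing entries of the trait
#' columns to `NA`, uniformly at random, and returns the mask so imputation
#' error can be scored against known truths. Cells already missing are never
#' selected.
#'
#' @param traits Trait table (data frame with `species_id`).
#' @param rate Fraction in `[0, 1)`.
#' @param seed Optional seed.
#' @param cols Columns eligible for masking; defaults to the trait-scheme
#'   columns present in `traits`.
#' @return The masked table, with attribute `mask` (data frame of `row`,
#'   `col`, `truth`).
#' @export
mask_traits <- function(traits, rate, seed = NULL,
                        cols = intersect(names(default_trait_scheme()),
                                         names(traits))) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_cells <- nrow(traits) * length(cols)
  n_mask <- round(rate * n_cells)
  avail <- which(!is.na(as.matrix(
    as.data.frame(lapply(traits[cols], as.character),
                  stringsAsFactors = FALSE))))
  if (n_mask > length(avail))
    stop("not enough observed cells to mask", call. = FALSE)
  pick <- if (n_mask > 0) sample(avail, n_mask) else integer()
  rows <- ((pick - 1L) %% nrow(traits)) + 1L
  colj <- ((pick - 1L) %/% nrow(traits)) + 1L
  mask <- data.frame(row = rows, col = cols[colj],
                     truth = vapply(seq_along(pick), function(k)
                       as.character(traits[[cols[colj[k]]]][rows[k]]),
                       character(1)),
                     stringsAsFactors = FALSE)
  for (k in seq_along(pick)) traits[rows[k], cols[colj[k]]] <- NA
  attr(traits, "mask") <- mask
  traits
}

#' Simulate a complete survey bundle
#'
#' Convenience wrapper: generates a species pool, transect observations and
#' metadata, a trait table with missingness, and a length-weight constants
#' table, all from one seed.
#'
#' @param n_species Pool size.
#' @param design A [survey_design()]; its `seed` drives everything.
#' @param scheme Trait scheme.
#' @param filter_strength Trait-depth filtering strength, see
#'   [generate_species_pool()].
#' @return List with `pool`, `observations`, `transects`, `traits`,
#'   `lw_constants`, `scheme`, `design`.
#' @export
simulate_survey <- function(n_species = 300, design = survey_design(),
                            scheme = default_trait_scheme(),
                            filter_strength = 0.5) {
  pool <- generate_species_pool(n_species, scheme, design$depth_bands,
                                filter_strength, seed = design$seed)
  sim <- simulate_transects(pool, design)
  traits <- pool[c("species_id", names(scheme), "iucn", "commercial_value")]
  if (design$trait_missing_rate > 0)
    traits <- mask_traits(traits, design$trait_missing_rate,
                          seed = design$seed + 1L,
                          cols = intersect(names(scheme), names(traits)))
  lw <- data.frame(taxon = pool$species_id, a = pool$lw_a, b = pool$lw_b,
                   stringsAsFactors = FALSE)
  list(pool = pool, observations = sim$observations,
       transects = sim$transects, traits = traits, lw_constants = lw,
       scheme = scheme, design = design)
}

#' Write a survey bundle to CSV files
#'
#' Writes `observations.csv`, `transects.csv`, `traits.csv` and
#' `lw_constants.csv` into `dir`.
#'
#' @param survey A bundle from [simulate_survey()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_survey <- function(survey, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(observations = file.path(dir, "observations.csv"),
             transects = file.path(dir, "transects.csv"),
             traits = file.path(dir, "traits.csv"),
             lw_constants = file.path(dir, "lw_constants.csv"))
  utils::write.csv(survey$observations, paths[["observations"]],
                   row.names = FALSE)
  utils::write.csv(survey$transects, paths[["transects"]], row.names = FALSE)
  tr <- survey$traits
  tr[] <- lapply(tr, as.character)
  utils::write.csv(tr, paths[["traits"]], row.names = FALSE, na = "")
  utils::write.csv(survey$lw_constants, paths[["lw_constants"]],
                   row.names = FALSE)
  invisible(paths)
}
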