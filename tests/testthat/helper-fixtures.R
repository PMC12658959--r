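# Shared fixtures and independent oracles used across test files.

## minimal transect metadata
toy_meta <- function(ids = c("A", "B"), atoll = "At1", band = 10,
                     len = 250, width = 5, flag = FALSE) {
  data.frame(transect_id = ids,
             atoll = rep_len(atoll, length(ids)),
             depth_band_m = rep_len(band, length(ids)),
             length_m = rep_len(len, length(ids)),
             width_m = rep_len(width, length(ids)),
             calibration_flag = rep_len(flag, length(ids)),
             stringsAsFactors = FALSE)
}

toy_obs <- function(transect, taxon, length_cm = NA_real_,
                    id_level = "species", group = substr(taxon, 1, 3)) {
  n <- max(length(transect), length(taxon), length(length_cm))
  data.frame(transect_id = rep_len(transect, n),
             taxon = rep_len(taxon, n),
             taxon_group = rep_len(group, n),
             id_level = rep_len(id_level, n),
             length_cm = rep_len(length_cm, n),
             stringsAsFactors = FALSE)
}

## Cayley-Menger determinant volume of a simplex (n = d + 1 points)
cayley_menger_volume <- function(P) {
  n <- nrow(P); d <- n - 1L
  D <- as.matrix(stats::dist(P))^2
  B <- rbind(c(0, rep(1, n)), cbind(1, D))
  sqrt((-1)^(d + 1) * det(B) / (2^d * factorial(d)^2))
}

## shoelace area of the 2-D convex hull of a point set
shoelace_hull_area <- function(P) {
  h <- grDevices::chull(P)
  Ph <- P[h, , drop = FALSE]
  n <- nrow(Ph)
  abs(sum(Ph[, 1] * Ph[c(2:n, 1), 2] - Ph[c(2:n, 1), 1] * Ph[, 2])) / 2
}

## mode-imputation baseline: fills NA cells with the column mode
mode_impute <- function(traits, cols) {
  for (cl in cols) {
    x <- as.character(traits[[cl]])
    if (anyNA(x)) {
      tb <- sort(table(x), decreasing = TRUE)
      x[is.na(x)] <- names(tb)[1]
      traits[[cl]] <- factor(x, levels = levels(traits[[cl]]),
                             ordered = is.ordered(traits[[cl]]))
    }
  }
  traits
}

## proportion of masked cells imputed wrongly, scored against the mask truth
masked_pfc <- function(imputed, mask) {
  wrong <- vapply(seq_len(nrow(mask)), function(k)
    as.character(imputed[[mask$col[k]]][mask$row[k]]) != mask$truth[k],
    logical(1))
  mean(wrong)
}

## a small trait scheme used by several toy tests
toy_scheme <- function() {
  list(size = list(levels = c("s", "m", "l"), ordered = TRUE),
       diet = list(levels = c("herb", "carn"), ordered = FALSE),
       depth = list(levels = c("sh", "mid", "dp"), ordered = TRUE))
}
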