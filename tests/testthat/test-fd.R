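make_space <- function(P) {
  ## wrap a raw coordinate matrix as a trait space for metric tests
  structure(list(coords = P, eig = rep(1, ncol(P)), m = ncol(P),
                 full_coords = P, negative_magnitude = 0),
            class = "trait_space")
}

test_that("functional entities group identical trait combinations", {
  sch <- toy_scheme()
  mk <- function(size, diet, depth) {
    data.frame(species_id = sprintf("s%02d", seq_along(size)),
               size = factor(size, levels = sch$size$levels, ordered = TRUE),
               diet = factor(diet, levels = sch$diet$levels),
               depth = factor(depth, levels = sch$depth$levels,
                              ordered = TRUE),
               stringsAsFactors = FALSE)
  }
  all_same <- mk(rep("s", 4), rep("herb", 4), rep("sh", 4))
  fe1 <- assign_functional_entities(all_same, sch)
  expect_equal(nrow(fe1$entities), 1L)
  all_diff <- mk(c("s", "m", "l"), c("herb", "carn", "herb"),
                 c("sh", "mid", "dp"))
  expect_equal(nrow(assign_functional_entities(all_diff, sch)$entities), 3L)
  mixed <- mk(c(rep("s", 4), "m", "l"), c(rep("herb", 4), "carn", "carn"),
              c(rep("sh", 4), "mid", "dp"))
  fe <- assign_functional_entities(mixed, sch)
  expect_equal(sort(fe$entities$n_species, decreasing = TRUE), c(4, 1, 1))
  ## every species in exactly one FE; sum of sizes = S
  expect_equal(sum(fe$entities$n_species), 6L)
  expect_equal(anyDuplicated(fe$assignment$species_id), 0L)
  ## deterministic ids under row shuffling
  fe_shuf <- assign_functional_entities(mixed[c(5, 3, 1, 6, 2, 4), ], sch)
  expect_identical(fe$entities, fe_shuf$entities)
})

test_that("FE metrics follow the S/K, excess and singleton formulas", {
  sch <- toy_scheme()
  sizes411 <- data.frame(
    species_id = sprintf("s%02d", 1:6),
    size = factor(c(rep("s", 4), "m", "l"), levels = sch$size$levels,
                  ordered = TRUE),
    diet = factor(rep("herb", 6), levels = sch$diet$levels),
    depth = factor(c(rep("sh", 4), "mid", "dp"), levels = sch$depth$levels,
                   ordered = TRUE),
    stringsAsFactors = FALSE)
  fes <- assign_functional_entities(sizes411, sch)
  m <- fe_metrics(fes)
  expect_equal(m$FRed, 2)
  expect_equal(m$FVul, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(m$FOR, 100 * (4 - 2) / 6, tolerance = 1e-12)
  expect_equal(m$FRed * m$K, m$S)
  ## all singletons
  single <- fe_metrics(assign_functional_entities(
    data.frame(species_id = c("a", "b"),
               size = factor(c("s", "l"), levels = sch$size$levels,
                             ordered = TRUE),
               diet = factor(c("herb", "carn"), levels = sch$diet$levels),
               depth = factor(c("sh", "dp"), levels = sch$depth$levels,
                              ordered = TRUE)), sch))
  expect_equal(single$FRed, 1)
  expect_equal(single$FVul, 100)
  expect_equal(single$FOR, 0)
  ## one FE holding everything
  allone <- fe_metrics(assign_functional_entities(
    data.frame(species_id = letters[1:5],
               size = factor(rep("s", 5), levels = sch$size$levels,
                             ordered = TRUE),
               diet = factor(rep("herb", 5), levels = sch$diet$levels),
               depth = factor(rep("sh", 5), levels = sch$depth$levels,
                              ordered = TRUE)), sch))
  expect_equal(allone$FVul, 0)
  expect_equal(allone$FRed, 5)
  ## community scoping
  comm <- fe_metrics(fes, community = c("s01", "s05"))
  expect_equal(comm$S, 2L); expect_equal(comm$K, 2L)
})

test_that("convex hull volume matches independent geometric oracles", {
  ## 5-point simplex in 4-D vs the Cayley-Menger determinant
  set.seed(21)
  for (r in 1:5) {
    S <- matrix(rnorm(20), 5, 4)
    expect_equal(convhull_volume(S), cayley_menger_volume(S),
                 tolerance = 1e-9)
  }
  ## 2-D random clouds vs the shoelace formula on chull()
  for (r in 1:5) {
    P <- matrix(runif(40 + 2 * r), ncol = 2)
    expect_equal(convhull_volume(P), shoelace_hull_area(P),
                 tolerance = 1e-9)
  }
  ## unit cube with interior points
  cube <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)),
                matrix(runif(30, 0.2, 0.8), ncol = 3))
  expect_equal(convhull_volume(cube), 1, tolerance = 1e-9)
  ## degenerate (affinely dependent) input
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_true(is.na(convhull_volume(flat)))
})

test_that("FRic is a pool fraction, monotone under species addition", {
  set.seed(22)
  P <- matrix(rnorm(60), 30, 2)
  rownames(P) <- sprintf("s%02d", 1:30)
  sp <- make_space(P)
  expect_equal(fric(sp, rownames(P)), 1, tolerance = 1e-9)
  sub <- rownames(P)[1:10]
  v_sub <- fric(sp, sub)
  expect_lte(v_sub, 1)
  ## adding a species never decreases the hull
  for (r in 1:5) {
    extra <- sample(setdiff(rownames(P), sub), 1)
    v_more <- fric(sp, c(sub, extra))
    expect_gte(v_more, v_sub - 1e-12)
  }
  ## undefined below m + 1 members
  expect_true(is.na(fric(sp, rownames(P)[1:2])))
})

test_that("FDis is the weighted mean distance to the weighted centroid", {
  P1 <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), NULL))
  sp <- make_space(P1)
  expect_equal(fdis(sp, c(a = 1, b = 1)), 0.5)          # d/2 at midpoint
  expect_equal(fdis(sp, c(a = 3, b = 1)), 0.375)        # centroid at 0.25
  expect_equal(fdis(sp, c(a = 2)), 0)                   # single species
  ## translation and rotation invariance
  set.seed(23)
  P <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  w <- setNames(runif(10, 0.5, 2), letters[1:10])
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  P2 <- P %*% R + 3
  rownames(P2) <- rownames(P)
  expect_equal(fdis(make_space(P), w), fdis(make_space(P2), w),
               tolerance = 1e-12)
})

test_that("FEve is 1 for perfectly regular configurations and matches hand math", {
  ## equally spaced collinear points, equal abundances
  P <- matrix(seq(0, 1, length.out = 5), 5, 1,
              dimnames = list(letters[1:5], NULL))
  sp <- make_space(P)
  w <- setNames(rep(1, 5), letters[1:5])
  expect_equal(feve(sp, w), 1, tolerance = 1e-12)
  ## 3 collinear points with branch lengths 9 and 1, equal abundances:
  ## EW ratio 9:1, PEW = (0.9, 0.1), threshold 1/2
  P3 <- matrix(c(0, 9, 10), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  w3 <- setNames(rep(1, 3), c("a", "b", "c"))
  expect_equal(feve(make_space(P3), w3),
               (min(0.9, 0.5) + min(0.1, 0.5) - 0.5) / (1 - 0.5),
               tolerance = 1e-12)
  ## abundance rescaling leaves FEve unchanged
  set.seed(24)
  P <- matrix(rnorm(16), 8, 2, dimnames = list(letters[1:8], NULL))
  w <- setNames(runif(8, 0.2, 3), letters[1:8])
  expect_equal(feve(make_space(P), w), feve(make_space(P), 10 * w),
               tolerance = 1e-12)
  ## undefined for S < 3
  expect_true(is.na(feve(make_space(P), w[1:2])))
  ## MST total length agrees with the vegan spantree oracle
  ed <- depthfd:::mst_edges(P)
  len <- sum(sqrt(rowSums((P[ed[, 1], ] - P[ed[, 2], ])^2)))
  expect_equal(len, sum(vegan::spantree(dist(P))$dist), tolerance = 1e-9)
})

test_that("FSpe scales distances to the pool centroid to a max of 1", {
  P <- matrix(c(0, 0, 1, 0, 0, 2, -3, 0), 4, 2, byrow = TRUE,
              dimnames = list(c("centr", "near", "mid", "far"), NULL))
  P <- rbind(P, colMeans(P))  # a species exactly at the pool centroid
  rownames(P)[5] <- "atcen"
  sp <- make_space(P)
  fs <- fspe(sp)
  expect_equal(unname(fs["atcen"]), 0, tolerance = 1e-12)
  expect_equal(max(fs), 1)
  expect_equal(names(which.max(fs)), "far")
  ## community of one species equals that species' value
  expect_equal(fspe_community(fs, c(mid = 4)), unname(fs["mid"]))
})

test_that("FUn ranks isolated species highest and handles small pools", {
  x <- matrix(c(0, 0.1, 0.2, 5), 4, 1,
              dimnames = list(c("a", "b", "c", "far"), NULL))
  fu <- fun_uniqueness(make_space(x), k = 2)
  expect_equal(unname(fu["far"]), 1)
  expect_true(all(fu[c("a", "b", "c")] < fu["far"]))
  ## exact duplicate with k = 1 -> 0
  dup <- matrix(c(0, 0, 3, 7), 4, 1,
                dimnames = list(c("a", "a2", "b", "c"), NULL))
  fu1 <- fun_uniqueness(make_space(dup), k = 1)
  expect_equal(unname(fu1["a"]), 0)
  ## pool <= k: k reduced with a warning
  expect_warning(fun_uniqueness(make_space(dup), k = 4), "k = 3")
})

test_that("FUSE follows ln(1 + FUn GE) + ln(1 + FSpe GE) and its bounds", {
  expect_equal(fuse(0.7, 0.9, 0), 0)
  expect_equal(fuse(0.5, 0.5, 2), log(2) + log(2), tolerance = 1e-12)
  expect_error(fuse(1.2, 0.5, 2), "\\[0, 1\\]")
  expect_error(fuse(0.5, 0.5, 5), "0..4")
  ## nondecreasing in every argument
  set.seed(25)
  for (r in 1:20) {
    u <- runif(1); s <- runif(1); g <- sample(0:4, 1)
    du <- runif(1, 0, 1 - u); ds <- runif(1, 0, 1 - s)
    expect_gte(fuse(u + du, s, g), fuse(u, s, g))
    expect_gte(fuse(u, s + ds, g), fuse(u, s, g))
    if (g < 4) expect_gte(fuse(u, s, g + 1), fuse(u, s, g))
  }
  expect_equal(ge_rank(c("LC", "NT", "VU", "EN", "CR")), 0:4)
  expect_error(ge_rank("DD"), "impute")
})

test_that("the FUSE ranking sorts, annotates and flags degenerate pools", {
  set.seed(26)
  n <- 30
  fun_s <- setNames(runif(n), sprintf("s%02d", 1:n))
  fspe_s <- setNames(runif(n), names(fun_s))
  iucn <- setNames(sample(c("LC", "NT", "VU", "EN"), n, TRUE), names(fun_s))
  ## make one CR species maximal in both -> must rank first
  fun_s["s01"] <- 1; fspe_s["s01"] <- 1; iucn["s01"] <- "CR"
  rk <- fuse_ranking(fun_s, fspe_s, iucn)
  expect_equal(rk$species_id[1], "s01")
  ## full sort oracle
  sc <- fuse(unname(fun_s), unname(fspe_s), ge_rank(unname(iucn)))
  oracle <- names(fun_s)[order(-sc, -unname(fun_s), names(fun_s))]
  expect_identical(rk$species_id, oracle)
  ## all-LC pool: degenerate, flagged
  expect_warning(
    rk0 <- fuse_ranking(fun_s, fspe_s,
                        setNames(rep("LC", n), names(fun_s))),
    "degenerate")
  expect_true(all(rk0$FUSE == 0))
  expect_true(attr(rk0, "degenerate"))
})

test_that("habitat classes follow the depth cutoffs", {
  expect_equal(habitat_class(c(2, 10, 30, 60, 120, 150, 250, 500)),
               c("shallow", "shallow", "shallow", "MCE", "MCE", "MCE",
                 "deep", "deep"))
})

test_that("species-poor transects are excluded from alpha FD only", {
  meta <- toy_meta(c("A", "B", "C", "D"), band = c(10, 120, 250, 250))
  obs <- rbind(toy_obs("A", sprintf("sp%d", 1:6), 10),
               toy_obs("B", sprintf("sp%d", 1:2), 10),
               toy_obs("C", "sp1", 10),
               toy_obs("D", sprintf("sp%d", 1:3), 10))
  m <- aggregate_matrix(obs, meta, "abundance")
  f <- alpha_fd_filter(m, meta, min_species = 5)
  expect_setequal(f$removed, c("B", "C", "D"))
  expect_equal(as.integer(f$report[c("120", "250")]), c(1L, 2L))
  expect_equal(rownames(f$matrix), "A")
  f0 <- alpha_fd_filter(m, meta, min_species = 0)
  expect_equal(nrow(f0$matrix), 4L)
})

test_that("the metric correlation matrix has unit diagonal and NA for constants", {
  set.seed(27)
  df <- data.frame(a = rnorm(10), b = rnorm(10), const = rep(1, 10))
  cm <- metric_correlation_summary(df)
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_true(is.na(cm["a", "const"]))
  expect_equal(cm["a", "b"], kendall_tau(df$a, df$b)$statistic)
  expect_error(metric_correlation_summary(df[1:2, ]), ">= 3")
})
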