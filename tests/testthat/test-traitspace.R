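test_that("correlated-trait pruning drops the least complete trait", {
  scheme <- list(
    t1 = list(levels = c("a", "b", "c"), ordered = TRUE),
    t2 = list(levels = c("x", "y", "z"), ordered = TRUE),
    t3 = list(levels = c("u", "v"), ordered = FALSE))
  base <- c("a", "a", "b", "b", "c", "c", "a", "b", "c", "a")
  tr <- data.frame(species_id = paste0("s", 1:10),
                   t1 = factor(base, levels = c("a", "b", "c"),
                               ordered = TRUE),
                   t2 = factor(c("x", "y", "z")[match(base, c("a", "b", "c"))],
                               levels = c("x", "y", "z"), ordered = TRUE),
                   t3 = factor(rep(c("u", "v"), 5)),
                   stringsAsFactors = FALSE)
  ## duplicated (perfectly correlated) trait: exactly one copy dropped;
  ## equal completeness, so the later-declared trait (t2) goes
  out <- prune_correlated(tr, scheme)
  expect_setequal(attr(out, "kept_traits"), c("t1", "t3"))
  expect_equal(attr(out, "pruning")$dropped, "t2")
  expect_equal(attr(out, "pruning")$tau, 1)
  ## the less complete member of the pair goes, regardless of order
  tr2 <- tr; tr2$t1[1:3] <- NA
  out2 <- prune_correlated(tr2, scheme)
  expect_setequal(attr(out2, "kept_traits"), c("t2", "t3"))
  ## column order does not change the outcome
  out3 <- prune_correlated(tr2[, c("species_id", "t3", "t2", "t1")], scheme)
  expect_setequal(attr(out3, "kept_traits"),
                  attr(out2, "kept_traits"))
  ## weakly correlated traits are untouched
  set.seed(99)
  tr3 <- tr
  tr3$t2 <- factor(sample(c("x", "y", "z"), 10, TRUE),
                   levels = c("x", "y", "z"), ordered = TRUE)
  tau <- cor(as.integer(tr3$t1), as.integer(tr3$t2), method = "kendall")
  if (abs(tau) <= 0.8)
    expect_equal(nrow(attr(prune_correlated(tr3, scheme), "pruning")), 0L)
})

test_that("three mutually correlated traits collapse to the most complete one", {
  scheme <- list(
    a = list(levels = c("1", "2", "3"), ordered = TRUE),
    b = list(levels = c("1", "2", "3"), ordered = TRUE),
    c = list(levels = c("1", "2", "3"), ordered = TRUE))
  v <- c("1", "1", "2", "2", "3", "3", "1", "2", "3", "2")
  mk <- function(x) factor(x, levels = c("1", "2", "3"), ordered = TRUE)
  tr <- data.frame(species_id = paste0("s", 1:10),
                   a = mk(v), b = mk(v), c = mk(v),
                   stringsAsFactors = FALSE)
  tr$a[1:2] <- NA
  tr$c[1:4] <- NA
  out <- prune_correlated(tr, scheme)
  expect_equal(attr(out, "kept_traits"), "b")
  expect_equal(nrow(attr(out, "pruning")), 2L)
})

test_that("imputation is a no-op on complete data and preserves observed cells", {
  pool <- generate_species_pool(80, seed = 31)
  scheme <- default_trait_scheme()
  traits <- pool[c("species_id", names(scheme), "iucn")]
  traits$iucn[traits$iucn %in% c("DD", "NE")] <- "LC"
  out <- impute_missforest(traits, scheme, seed = 1)
  expect_identical(out[names(scheme)], traits[names(scheme)])
  expect_equal(attr(out, "n_iterations"), 0L)
  expect_equal(attr(out, "oob_error")$PFC, 0)

  masked <- mask_traits(traits, 0.08, seed = 2, cols = names(scheme))
  imp <- impute_missforest(masked, scheme, seed = 3)
  obs_cells <- !is.na(masked[names(scheme)])
  expect_identical(
    as.matrix(as.data.frame(lapply(imp[names(scheme)], as.character)))[obs_cells],
    as.matrix(as.data.frame(lapply(masked[names(scheme)],
                                   as.character)))[obs_cells])
  expect_false(anyNA(imp[names(scheme)]))
  expect_equal(attr(imp, "oob_error")$NRMSE, 0)
})

test_that("a deterministic trait dependency is recovered exactly", {
  scheme <- list(
    b = list(levels = c("1", "2", "3"), ordered = TRUE),
    a = list(levels = c("lo", "hi"), ordered = FALSE),
    filler = list(levels = c("p", "q"), ordered = FALSE))
  set.seed(5)
  bv <- sample(c("1", "2", "3"), 60, TRUE)
  tr <- data.frame(species_id = paste0("s", 1:60),
                   b = factor(bv, levels = c("1", "2", "3"), ordered = TRUE),
                   a = factor(ifelse(bv == "3", "hi", "lo"),
                              levels = c("lo", "hi")),
                   filler = factor(sample(c("p", "q"), 60, TRUE)),
                   stringsAsFactors = FALSE)
  truth <- as.character(tr$a[7])
  tr$a[7] <- NA
  imp <- impute_missforest(tr, scheme, seed = 11, impute_iucn = FALSE)
  expect_equal(as.character(imp$a[7]), truth)
})

test_that("DD/NE risk categories are imputed to assessed categories", {
  pool <- generate_species_pool(120, seed = 41)
  scheme <- default_trait_scheme()
  traits <- pool[c("species_id", names(scheme), "iucn")]
  expect_gt(sum(traits$iucn %in% c("DD", "NE")), 0)
  imp <- impute_missforest(traits, scheme, seed = 1)
  expect_true(all(imp$iucn %in% c("LC", "NT", "VU", "EN", "CR")))
  ## assessed categories are never altered
  assessed <- !traits$iucn %in% c("DD", "NE")
  expect_identical(imp$iucn[assessed], traits$iucn[assessed])
  ## an entirely missing column is a hard error
  bad <- traits; bad$temp_range <- factor(NA, levels = scheme$temp_range$levels)
  expect_error(impute_missforest(bad, scheme, seed = 1), "entirely missing")
})

test_that("Gower distance matches the hand formula and the daisy oracle", {
  sch <- toy_scheme()
  mk <- function(size, diet, depth) {
    data.frame(species_id = paste0("s", seq_along(size)),
               size = factor(size, levels = sch$size$levels, ordered = TRUE),
               diet = factor(diet, levels = sch$diet$levels),
               depth = factor(depth, levels = sch$depth$levels,
                              ordered = TRUE),
               stringsAsFactors = FALSE)
  }
  tr <- mk(c("s", "s"), c("herb", "herb"), c("sh", "mid"))
  d <- gower_distance(tr, sch)
  ## equal unordered + ordered one step of a 3-level + equal ordered
  expect_equal(d["s1", "s2"], (0 + 0 + 0.5) / 3)
  expect_equal(unname(diag(d)), c(0, 0))
  same <- mk(c("m", "m"), c("carn", "carn"), c("dp", "dp"))
  expect_equal(gower_distance(same, sch)["s1", "s2"], 0)
  ## all unordered traits differing -> 1
  sch_u <- list(x = list(levels = c("a", "b"), ordered = FALSE),
                y = list(levels = c("c", "d"), ordered = FALSE))
  tru <- data.frame(species_id = c("s1", "s2"),
                    x = factor(c("a", "b")), y = factor(c("c", "d")))
  expect_equal(gower_distance(tru, sch_u)["s1", "s2"], 1)
  ## daisy oracle on a random table
  set.seed(4)
  trr <- mk(sample(sch$size$levels, 12, TRUE),
            sample(sch$diet$levels, 12, TRUE),
            sample(sch$depth$levels, 12, TRUE))
  expect_equal(max(abs(gower_distance(trr, sch) -
                         as.matrix(cluster::daisy(trr[, -1], "gower")))), 0,
               tolerance = 1e-12)
  ## triangle inequality on random toys
  for (s in 1:5) {
    set.seed(100 + s)
    trt <- mk(sample(sch$size$levels, 6, TRUE),
              sample(sch$diet$levels, 6, TRUE),
              sample(sch$depth$levels, 6, TRUE))
    dd <- gower_distance(trt, sch)
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }
  trna <- mk("s", "herb", "sh"); trna$size <- NA
  expect_error(gower_distance(trna, sch), "impute")
})

test_that("trait space embedding is isometric for Euclidean input", {
  set.seed(9)
  P <- matrix(rnorm(20), 10, 2)
  rownames(P) <- paste0("s", 1:10)
  d <- as.matrix(dist(P))
  sp <- build_trait_space(d, m = 2)
  expect_equal(as.matrix(dist(sp$coords)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(build_trait_space(d, m = 50), "exceeds")
  expect_s3_class(sp, "trait_space")
})

test_that("mAD quality is zero for perfect embeddings and decreasing in m", {
  set.seed(10)
  P <- matrix(rnorm(30), 10, 3)
  rownames(P) <- paste0("s", 1:10)
  d <- as.matrix(dist(P))
  sp <- build_trait_space(d, m = 3)
  q <- quality_mad(d, sp, dims = 1:3)
  expect_equal(unname(q$mad[["3"]]), 0, tolerance = 1e-9)
  expect_lte(q$mad[["3"]], q$mad[["1"]])
  expect_equal(q$best, 3)
  ## on a genuine Gower toy, the full space is at least as good as 1-D
  pool <- generate_species_pool(40, seed = 51)
  scheme <- default_trait_scheme()
  g <- gower_distance(pool[c("species_id", names(scheme))], scheme)
  spg <- build_trait_space(g, m = 4)
  qg <- quality_mad(g, spg, dims = c(1, 4, ncol(spg$full_coords)))
  expect_lte(qg$mad[[as.character(ncol(spg$full_coords))]],
             qg$mad[["1"]] + 1e-12)
  ## eigenvalue signs: Gower on categorical data can have a negative part
  expect_gte(spg$negative_magnitude, 0)
})
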