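test_that("dummy coding is strict at the threshold", {
  p <- rbind(c(26, 74, 0), c(25, 75, 0), c(100, 0, 0), c(20, 20, 60))
  d <- dummy_code(p)
  expect_equal(d[1, ], c(1L, 1L, 0L))
  expect_equal(d[2, 1], 0L)
  expect_equal(sum(d[3, ]), 1L)
  expect_equal(dummy_code(rbind(c(20, 20, 20, 20, 20)))[1, ],
               rep(0L, 5))
})

make_traits <- function(n, seed = 1) {
  set.seed(seed)
  diet <- matrix(runif(n * 4), n, 4)
  diet <- 100 * diet / rowSums(diet)
  colnames(diet) <- paste0("diet_", c("a", "b", "c", "d"))
  data.frame(species = sprintf("sp%03d", seq_len(n)),
             body_mass = exp(rnorm(n, 5, 1)), diet,
             strata_ground = rbinom(n, 1, 0.5),
             strata_arboreal = rbinom(n, 1, 0.5),
             activity_diurnal = rbinom(n, 1, 0.5))
}

test_that("Gower distances are bounded with equalized group contributions", {
  tr <- make_traits(30)
  g <- gower_equal_contrib(tr)
  D <- g$dissim
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 30), tr$species))
  expect_true(all(D >= 0 & D <= 1 + 1e-12))
  # recompute contributions from the returned weights: equal within 1e-6
  expect_lt(diff(range(g$contributions)) / mean(g$contributions), 1e-6)
  expect_equal(sum(g$weights), 1)

  # identical species at distance 0; maximal difference at distance 1
  two <- tr[1:2, ]
  two[2, -1] <- two[1, -1]
  expect_equal(suppressWarnings(gower_equal_contrib(two))$dissim[1, 2], 0)
  opp <- data.frame(species = c("x", "y"), body_mass = c(1, 100),
                    diet_a = c(100, 0), diet_b = c(0, 100),
                    strata_ground = c(0, 1), strata_arboreal = c(1, 0),
                    activity_diurnal = c(0, 1))
  expect_equal(gower_equal_contrib(opp)$dissim[1, 2], 1)
})

test_that("Gower output is invariant to species ordering", {
  tr <- make_traits(20, seed = 2)
  g1 <- gower_equal_contrib(tr)
  perm <- sample(20)
  g2 <- gower_equal_contrib(tr[perm, ])
  expect_equal(g2$dissim[tr$species, tr$species], g1$dissim,
               tolerance = 1e-12)
  # constant group is dropped with a warning
  trc <- tr
  trc$activity_diurnal <- 1
  expect_warning(gc <- gower_equal_contrib(trc), "constant trait group")
  expect_false("activity" %in% names(gc$weights))
})

test_that("principal coordinates reproduce metric configurations", {
  # collinear points embed on one axis; asking for 3 axes must fail
  line <- as.matrix(dist(c(0, 1, 3, 7)))
  expect_error(pcoa_axes(line, 3), "positive eigenvalues")
  # 3-D point cloud: pairwise distances are reproduced exactly
  set.seed(4)
  pts <- matrix(rnorm(30), 10, 3)
  sp <- pcoa_axes(as.matrix(dist(pts)), 3)
  expect_equal(as.matrix(dist(sp$coords)), as.matrix(dist(pts)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sp$negative_fraction, 0, tolerance = 1e-9)
  # permutation equivariance: same eigenvalues
  perm <- sample(10)
  sp2 <- pcoa_axes(as.matrix(dist(pts))[perm, perm], 3)
  expect_equal(sp2$eig, sp$eig, tolerance = 1e-9)
})

test_that("functional richness equals closed-form hull volumes", {
  tet <- structure(list(coords = rbind(c(0, 0, 0), c(1, 0, 0),
                                       c(0, 1, 0), c(0, 0, 1)),
                        eig = NULL), class = "trait_space")
  rownames(tet$coords) <- paste0("s", 1:4)
  expect_equal(fric(tet, paste0("s", 1:4)), 1 / 6, tolerance = 1e-12)
  cube <- structure(list(coords = as.matrix(expand.grid(0:1, 0:1, 0:1))),
                    class = "trait_space")
  rownames(cube$coords) <- paste0("c", 1:8)
  colnames(cube$coords) <- NULL
  expect_equal(fric(cube, paste0("c", 1:8)), 1, tolerance = 1e-12)
  # an interior point changes nothing
  cube9 <- cube
  cube9$coords <- rbind(cube9$coords, c9 = c(0.5, 0.5, 0.5))
  expect_equal(fric(cube9, rownames(cube9$coords)), 1, tolerance = 1e-12)
  # below the species floor, and degenerate flat sets, are missing
  expect_true(is.na(fric(tet, paste0("s", 1:3))))
  flat <- structure(list(coords = cbind(matrix(rnorm(10), 5, 2), 0)),
                    class = "trait_space")
  rownames(flat$coords) <- paste0("f", 1:5)
  expect_true(is.na(fric(flat, paste0("f", 1:5))))
})

test_that("hull volume is monotone under added species", {
  set.seed(6)
  coords <- matrix(rnorm(60), 20, 3,
                   dimnames = list(sprintf("p%02d", 1:20), NULL))
  space <- structure(list(coords = coords), class = "trait_space")
  sub <- rownames(coords)[1:5]
  v_prev <- fric(space, sub)
  for (k in seq(6, 20, by = 3)) {
    v_now <- fric(space, rownames(coords)[1:k])
    expect_gte(v_now, v_prev - 1e-12)
    v_prev <- v_now
  }
})

test_that("traded-cell functional richness never exceeds the overall cell value", {
  w <- small_world
  space <- build_trait_space(small_traits)
  grid <- filter_cells(w$grid)
  scores <- species_scores(w$tree,
                           setNames(w$ledger$iucn_category, w$ledger$species))
  cm <- cell_summaries(w$presence, grid, w$ledger, scores, w$tree,
                       trait_space = space, subset_rule = "traded")
  both <- !is.na(cm$fd) & !is.na(cm$fd_subset)
  expect_gt(sum(both), 5)
  expect_true(all(cm$fd_subset[both] <= cm$fd[both] + 1e-9))
})
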