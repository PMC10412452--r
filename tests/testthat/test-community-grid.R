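test_that("the land filter removes below-threshold cells, boundary retained", {
  g <- data.frame(cell = 1:3, land_fraction = c(0.29, 0.30, 1), realm = 1)
  kept <- filter_cells(g)
  expect_equal(kept$cell, c(2, 3))
  g_all <- data.frame(cell = 1:10, land_fraction = 1, realm = 1)
  expect_equal(nrow(filter_cells(g_all)), 10)
  set.seed(1)
  g_mix <- data.frame(cell = 1:100, land_fraction = runif(100), realm = 1)
  expect_equal(nrow(filter_cells(g_mix)), sum(g_mix$land_fraction >= 0.3))
})

test_that("per-cell summaries reproduce hand-computed PD on a toy world", {
  # 5 species, hand tree, 4 cells
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,E:3);")
  pres <- rbind(c(1, 1, 0, 0, 0),   # {A,B}: 1+1+1+1 = 4
                c(1, 0, 1, 0, 1),   # {A,C,E}: 1+1+1+1+1+3 = 8
                c(0, 0, 0, 0, 1),   # {E}: root path only: 3
                c(1, 1, 1, 1, 1))   # all: total branch length = 10
  colnames(pres) <- c("A", "B", "C", "D", "E")
  grid <- data.frame(cell = 1:4, land_fraction = 1, realm = 1)
  ledger <- data.frame(species = colnames(pres),
                       traded = c(1, 0, 1, 0, 1), pet = c(1, 0, 0, 0, 1),
                       product = c(0, 0, 1, 0, 0),
                       iucn_category = c("LC", "VU", "EN", "DD", "CR"))
  scores <- species_scores(tr, setNames(ledger$iucn_category, ledger$species))
  cm <- cell_summaries(pres, grid, ledger, scores, tr, subset_rule = "traded")
  expect_equal(cm$pd, c(4, 8, 3, 10))
  expect_equal(cm$pd_subset, c(3, 8, 3, 8)) # traded sets {A},{A,C,E},{E},{A,C,E}
  expect_equal(cm$richness, c(2, 3, 1, 5))
  expect_equal(cm$richness_subset, c(1, 3, 1, 3))
  # traded == all species in cell 2 and 3: proportions are 1
  expect_equal(cm$prop_pd[2], 1)
  expect_equal(cm$prop_pd[3], 1)
  # DD species carries no EDGE: cell 4 skips D in the EDGE sum
  expect_equal(cm$sum_edge[4],
               sum(scores$EDGE[!is.na(scores$EDGE)]))

  # no traded species at all: traded PD 0, proportion 0
  ledger0 <- transform(ledger, traded = 0, pet = 0, product = 0)
  cm0 <- cell_summaries(pres, grid, ledger0, scores, tr,
                        subset_rule = "traded")
  expect_equal(cm0$pd_subset, rep(0, 4))
  expect_equal(cm0$prop_pd, rep(0, 4))
})

test_that("every traded metric is bounded by its overall metric", {
  w <- small_world
  scores <- species_scores(w$tree,
                           setNames(w$ledger$iucn_category, w$ledger$species))
  grid <- filter_cells(w$grid)
  cm <- cell_summaries(w$presence, grid, w$ledger, scores, w$tree,
                       subset_rule = "traded")
  eps <- 1e-9
  expect_true(all(cm$richness_subset <= cm$richness))
  expect_true(all(cm$pd_subset <= cm$pd + eps))
  expect_true(all(cm$sum_ed_subset <= cm$sum_ed + eps))
  expect_true(all(cm$sum_edge_subset <= cm$sum_edge + eps))
  pr <- cm[, c("prop_richness", "prop_pd", "prop_ed", "prop_edge")]
  expect_true(all(pr >= -eps & pr <= 1 + eps, na.rm = TRUE))
})

test_that("top-fraction selection is deterministic with the sort oracle", {
  sc <- data.frame(species = paste0("s", 1:4), ED = 1:4, EDGE = 1:4)
  expect_equal(top_fraction_species(sc, 0.25), "s4")
  expect_setequal(top_fraction_species(sc, 1), sc$species)
  set.seed(3)
  scb <- data.frame(species = sprintf("s%04d", 1:1000),
                    ED = runif(1000), EDGE = rnorm(1000))
  top <- top_fraction_species(scb, 0.25)
  expect_length(top, 250)
  expect_gte(min(scb$EDGE[scb$species %in% top]),
             max(scb$EDGE[!scb$species %in% top]))
})

test_that("hotspot flags respect fractions, ties and nesting", {
  v <- sample(1:100)
  hs <- hotspots(v)
  expect_equal(sum(hs$top25), 25)
  expect_equal(sum(hs$top5), 5)
  expect_true(all(hs$top25[hs$top5]))
  # constant input: everything ties at the cutoff and is flagged
  hc <- hotspots(rep(1, 40))
  expect_equal(unname(attr(hc, "flag_counts")["top25"]), 40)
  # missing cells are never flagged
  v[1:10] <- NA
  hna <- hotspots(v)
  expect_true(all(!hna$top25[1:10]))
  set.seed(9)
  for (i in 1:5) {
    vv <- rnorm(57)
    h <- hotspots(vv)
    expect_true(all(h$top25[h$top5]))
  }
})

test_that("realm endemism needs every presence cell in one realm", {
  grid <- data.frame(cell = 1:4, land_fraction = 1, realm = c(1, 1, 2, 2))
  pres <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  colnames(pres) <- c("one_realm", "touches_two", "nowhere")
  ledger <- data.frame(species = colnames(pres), traded = 1, pet = 1,
                       product = 0, iucn_category = "LC")
  led <- filter_endemics(pres, grid, ledger)
  expect_equal(led$realm_endemic, c(1L, 0L, NA_integer_))

  # synthetic world: flags must match a direct scan of the construction
  w <- small_world
  led_w <- filter_endemics(w$presence, w$grid, w$ledger)
  realm_of <- w$grid$realm[match(seq_len(nrow(w$presence)), w$grid$cell)]
  manual <- vapply(w$ledger$species, function(s) {
    r <- unique(realm_of[w$presence[, s] == 1])
    as.integer(length(r) == 1)
  }, integer(1))
  expect_equal(led_w$realm_endemic, unname(manual))
  # endemic filtering can only shrink per-cell traded metrics
  scores <- species_scores(w$tree,
                           setNames(w$ledger$iucn_category, w$ledger$species))
  grid_w <- filter_cells(w$grid)
  cm_tr <- cell_summaries(w$presence, grid_w, led_w, scores, w$tree,
                          subset_rule = "traded")
  cm_en <- cell_summaries(w$presence, grid_w, led_w, scores, w$tree,
                          subset_rule = "endemic-traded")
  expect_true(all(cm_en$pd_subset <= cm_tr$pd_subset + 1e-9))
  expect_true(all(cm_en$richness_subset <= cm_tr$richness_subset))
})
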