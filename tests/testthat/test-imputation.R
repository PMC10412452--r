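test_that("Pagel's lambda recovers signal, its absence, and flags stars", {
  set.seed(21)
  hits_bm <- 0; hits_null <- 0
  for (i in 1:10) {
    tr <- ape::rphylo(100, 1, 0)
    x_bm <- simulate_bm_for_test(tr)
    if (pagel_lambda(tr, x_bm)$lambda >= 0.8) hits_bm <- hits_bm + 1
    x_ind <- setNames(rnorm(100), tr$tip.label)
    if (pagel_lambda(tr, x_ind)$lambda <= 0.2) hits_null <- hits_null + 1
  }
  expect_gte(hits_bm, 8)
  expect_gte(hits_null, 8)

  star <- ape::stree(12, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  res <- pagel_lambda(star, setNames(rnorm(12), star$tip.label))
  expect_false(res$identifiable)
  expect_true(is.na(res$lambda))
  expect_error(pagel_lambda(hand_tree, c(A = 1, B = 2, C = 3)),
               "at least 10")
})

test_that("lambda maximum likelihood agrees with an external implementation", {
  set.seed(77)
  tr <- ape::rphylo(80, 1, 0)
  x <- simulate_bm_for_test(tr) + rnorm(80, 0, 0.5)
  mine <- pagel_lambda(tr, x)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(mine$lambda, min(ref$lambda, 1), tolerance = 0.05)
  if (ref$lambda <= 1)
    expect_equal(mine$loglik, ref$logL, tolerance = 0.01)
})

test_that("the D statistic hits its anchors for shuffled and Brownian traits", {
  set.seed(8)
  tr <- ape::rphylo(120, 1, 0)
  d_rand <- d_bm <- numeric(15)
  for (i in 1:15) {
    x_r <- setNames(sample(rep(c(0, 1), c(60, 60))), tr$tip.label)
    d_rand[i] <- d_statistic(tr, x_r, n_perm = 50)$D
    liab <- simulate_bm_for_test(tr)
    x_b <- setNames(as.numeric(rank(liab) > 60), tr$tip.label)
    d_bm[i] <- d_statistic(tr, x_b, n_perm = 50)$D
  }
  expect_lt(abs(mean(d_rand) - 1), 0.15)
  expect_lt(abs(mean(d_bm)), 0.15)
  expect_error(d_statistic(tr, setNames(rep(1, 120), tr$tip.label), 50),
               "monomorphic")
  expect_error(d_statistic(tr, setNames(rep(c(0, 1), 60), tr$tip.label), 0),
               "n_perm")
})

test_that("Brownian imputation conditions correctly on tree structure", {
  # a missing tip at zero distance from an observed sister copies its value
  tr <- ape::read.tree(
    text = "((A:0.000001,B:0.000001):1,(C:1,D:1):1);")
  traits <- data.frame(species = c("A", "B", "C", "D"),
                       body_mass = c(NA, 20, 400, 300))
  out <- suppressWarnings(bm_impute_single(tr, traits))
  expect_equal(out$body_mass[1], 20, tolerance = 1e-3)

  # star phylogeny: no covariance information, impute the observed mean
  star <- ape::stree(20, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  y <- c(NA, rnorm(19, 3, 1))
  tstar <- data.frame(species = star$tip.label, body_mass = exp(y))
  out_s <- bm_impute_single(star, tstar)
  expect_equal(log(out_s$body_mass[1]), mean(y[-1]), tolerance = 1e-8)
})

test_that("imputation never alters observed values and matches a mode-finding oracle", {
  set.seed(13)
  tr <- ape::rphylo(40, 1, 0)
  cfg <- world_config(n_species = 40, missing_fraction = 0.15, seed = 13)
  tt <- simulate_traits(tr, cfg)
  out <- bm_impute(tr, tt$traits)
  obs <- !is.na(tt$traits$body_mass)
  expect_equal(out$body_mass[obs], tt$traits$body_mass[obs])
  diet_cols <- grep("^diet_", names(out))
  expect_equal(rowSums(out[, diet_cols]), rep(100, 40), tolerance = 1e-6)

  # oracle: the conditional expectation maximizes the joint Gaussian density
  # over the missing entries (numeric optimization, independent route)
  y <- log(tt$traits$body_mass)
  names(y) <- tt$traits$species
  mis <- which(is.na(y))
  C <- ape::vcv(tr)[names(y), names(y)]
  gfit <- gls_profile_for_test(C[-mis, -mis, drop = FALSE], y[-mis])
  Ci <- solve(C)
  nld <- function(v) {
    z <- y; z[mis] <- v
    0.5 * as.numeric(t(z - gfit$mu) %*% Ci %*% (z - gfit$mu))
  }
  opt <- optim(rep(gfit$mu, length(mis)), nld, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(log(out$body_mass[mis])), unname(opt$par),
               tolerance = 1e-4)
})

test_that("model comparison selects the generating process by AIC", {
  set.seed(17)
  bm_ok <- 0; lam_ok <- 0
  for (i in 1:10) {
    tr <- ape::rphylo(80, 1, 0)
    x_bm <- simulate_bm_for_test(tr)
    cmp <- compare_evolutionary_models(tr, x_bm)
    lam_hat <- pagel_lambda(tr, x_bm)$lambda
    if (cmp$chosen == "BM" || lam_hat > 0.9) bm_ok <- bm_ok + 1
    # trait with weak signal: the lambda model should win the AIC race
    C <- ape::vcv(tr)
    V <- 0.3 * C; diag(V) <- diag(C)
    x_l <- setNames(as.numeric(t(chol(V)) %*% rnorm(80)), tr$tip.label)
    cmp_l <- compare_evolutionary_models(tr, x_l)
    if (cmp_l$chosen == "lambda") lam_ok <- lam_ok + 1
  }
  expect_gte(bm_ok, 8)
  expect_gte(lam_ok, 8)
  # AIC arithmetic: 2k - 2 lnL
  tr <- ape::rphylo(30, 1, 0)
  cmp <- compare_evolutionary_models(tr, simulate_bm_for_test(tr),
                                     extended = TRUE)
  expect_equal(cmp$table$AIC, 2 * cmp$table$k - 2 * cmp$table$logLik)
  expect_true(all(c("OU", "kappa") %in% cmp$table$model))
  expect_equal(cmp$chosen, cmp$table$model[which.min(cmp$table$AIC)])
})

test_that("leave-one-out validation reports sensible error summaries", {
  tr <- ape::rphylo(60, 1, 0)
  const <- setNames(rep(4.2, 60), tr$tip.label)
  expect_equal(loocv_impute(tr, const)$mae, 0)
  # on a star tree the predictor collapses to the mean: coefficient near 0
  star <- ape::stree(100, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(3)
  res <- loocv_impute(star, setNames(rnorm(100), star$tip.label))
  expect_lt(abs(res$prediction_coefficient), 0.06)
  # Brownian data: phylogeny is informative, coefficient positive
  set.seed(30)
  pos <- sum(vapply(1:10, function(i) {
    t2 <- ape::rphylo(100, 1, 0)
    loocv_impute(t2, simulate_bm_for_test(t2))$prediction_coefficient > 0
  }, logical(1)))
  expect_gte(pos, 9)
})

test_that("post-imputation sanity rules catch bad diets and fix foraging", {
  tt <- data.frame(species = c("ok", "bad", "forage"),
                   diet_a = c(50, 3, 40), diet_b = c(30, 2, 35),
                   diet_c = c(20, 1, 25),
                   strata_ground = c(1, 0, 0), strata_scansorial = 0,
                   strata_arboreal = c(0, 1, 0), strata_aerial = 0)
  chk <- sanity_check_imputed(tt)
  expect_equal(chk$excluded, "bad")
  expect_true(chk$report$diet_ok[1])
  expect_false(chk$report$diet_ok[2])
  expect_equal(chk$traits$strata_arboreal[3], 1L)
})
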