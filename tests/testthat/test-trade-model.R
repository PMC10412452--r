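test_that("the phylogenetic correlation matrix is unit-diagonal shared-path scaling", {
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  C2 <- build_phylo_corr(t2)
  expect_equal(diag(C2), c(A = 1, B = 1))
  expect_equal(C2["A", "B"], 0)
  sis <- ape::read.tree(text = "((A:0.1,B:0.1):0.9,C:1);")
  expect_equal(build_phylo_corr(sis)["A", "B"], 0.9)
  set.seed(1)
  tr <- ape::rphylo(80, 1, 0)
  C <- build_phylo_corr(tr)
  expect_equal(unname(diag(C)), rep(1, 80))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  nonultra <- ape::rtree(20)
  expect_warning(Cn <- build_phylo_corr(nonultra), "not ultrametric")
  expect_equal(unname(diag(Cn)), rep(1, 20))
})

test_that("MPE counts draw signs with zeros split", {
  expect_equal(mpe(c(1, 2, 3)), 1)
  expect_equal(mpe(c(rep(1, 500), rep(-1, 500))), 0.5)
  expect_equal(mpe(c(-1, 2, 3, 4)), 0.75)
  expect_equal(mpe(c(0, 0, 1, -1)), 0.5)
  x <- rnorm(1000)
  expect_gte(mpe(x), 0.5)
  expect_lte(mpe(x), 1)
})

test_that("highest-density intervals are shortest and correctly sized", {
  set.seed(2)
  u <- runif(1e5)
  h <- hdi(u, 0.9)
  expect_equal(h[2] - h[1], 0.9, tolerance = 0.02)
  z <- rnorm(1e5)
  hz <- hdi(z, 0.9)
  et <- quantile(z, c(0.05, 0.95))
  expect_equal(unname(hz), unname(et), tolerance = 0.03)
  expect_equal(hdi(rep(3.3, 100), 0.9), c(3.3, 3.3))
  expect_error(hdi(z, 1.2), "inside")
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(3)
  one <- rnorm(2000)
  same <- cbind(one, one)
  expect_lt(abs(rhat(same) - 1), 1e-3)
  apart <- cbind(rnorm(1000, -5), rnorm(1000, 5))
  expect_gt(rhat(apart), 2)
  ok <- sum(replicate(20, rhat(matrix(rnorm(8000), 2000, 4)) < 1.02))
  expect_gte(ok, 19)
  expect_error(rhat(matrix(rnorm(10), 10, 1)), "at least 2 chains")
})

test_that("Polya-Gamma draws match analytic moments and a series-construction oracle", {
  set.seed(4)
  for (z in c(0, 0.7, 2.5, 8)) {
    x <- tradediv:::.rpg(rep(z, 40000))
    m_true <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_equal(mean(x), m_true, tolerance = 0.02)
  }
  # oracle: PG(1, z) as the weighted infinite sum of independent gammas
  z <- 1.5
  k <- 1:500
  w <- 1 / ((k - 0.5)^2 + z^2 / (4 * pi^2))
  sums <- replicate(20000,
    sum(rgamma(500, 1) * w)) / (2 * pi^2)
  x <- tradediv:::.rpg(rep(z, 20000))
  expect_equal(mean(x), mean(sums), tolerance = 0.02)
  expect_equal(sd(x), sd(sums), tolerance = 0.05)
})

test_that("with a diagonal correlation and a tiny effect scale the fit matches exact quadrature", {
  set.seed(5)
  n <- 400
  x <- as.numeric(scale(rnorm(n)))
  eta <- 0.4 + 0.9 * x
  y <- rbinom(n, 1, plogis(eta))
  traits <- data.frame(species = sprintf("s%03d", 1:n),
                       body_mass = exp(x))  # log mass standardizes back to x
  ledger <- data.frame(species = traits$species, traded = y)
  corr <- diag(n); dimnames(corr) <- list(traits$species, traits$species)
  fit <- fit_trade_model(ledger, traits, corr, chains = 2, iter = 3000,
                         warmup = 1000, sigma_prior_sd = 1e-6,
                         seed = 11, keep_u = FALSE)
  # oracle: 2-D grid quadrature of the exact posterior (prior sd 0.5)
  b0 <- seq(-0.5, 1.2, length.out = 120)
  b1 <- seq(0, 1.6, length.out = 120)
  logpost <- outer(b0, b1, Vectorize(function(a, b) {
    sum(dbinom(y, 1, plogis(a + b * x), log = TRUE)) +
      dnorm(a, 0, 0.5, log = TRUE) + dnorm(b, 0, 0.5, log = TRUE)
  }))
  w <- exp(logpost - max(logpost))
  post_b1 <- colSums(w) / sum(w)
  mean_b1 <- sum(post_b1 * b1)
  mean_b0 <- sum(rowSums(w) / sum(w) * b0)
  s <- fit$summary
  expect_equal(s$median[s$parameter == "log_mass_z"], mean_b1,
               tolerance = 0.05)
  expect_equal(s$median[s$parameter == "(Intercept)"], mean_b0,
               tolerance = 0.05)
})

test_that("the trade model converges and passes its predictive checks on a synthetic world", {
  cfg <- world_config(n_species = 100, seed = 19)
  tree <- simulate_tree(cfg)
  tt <- simulate_traits(tree, cfg)
  td <- simulate_trade(tree, tt$traits_true, cfg)
  corr <- build_phylo_corr(tree)
  fit <- fit_trade_model(td$ledger, tt$traits_true, corr, chains = 4,
                         iter = 1500, warmup = 500, seed = 7)
  expect_lt(fit$max_rhat, 1.05)
  expect_true(fit$ppc$covered)
  expect_equal(mean(td$ledger$traded), fit$ppc$observed_fraction)
  # the strong positive mass effect is detected with certainty of direction
  s <- fit$summary
  expect_gt(s$mpe[s$parameter == "log_mass_z"], 0.975)
  expect_gt(s$median[s$parameter == "log_mass_z"], 0)
  expect_true(all(s$hdi_lower <= s$median & s$median <= s$hdi_upper))
  # zero-variance predictors are refused by name
  tt_bad <- tt$traits_true
  tt_bad$activity_diurnal <- 1L
  expect_error(fit_trade_model(td$ledger, tt_bad, corr, chains = 1,
                               iter = 10, warmup = 5),
               "activity_diurnal")
})
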