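#' Configuration of a synthetic world
#'
#' Bundles every knob of the synthetic-world generator with defaults chosen
#' to mimic the structure of a global traded-vertebrate dataset at desk
#' scale: a clade-structured trade signal with a strong body-mass effect,
#' spatially contiguous ranges partitioned into 11 biogeographical realms,
#' and IUCN threat categories correlated with trade.
#'
#' @param n_species Number of extant species (tips).
#' @param grid_rows,grid_cols Grid dimensions (>= 2 each).
#' @param n_realms Number of contiguous realm blocks (paper-scale worlds use
#'   11); must not exceed the number of cells.
#' @param birth_rate,death_rate Per-lineage birth-death rates
#'   (`death_rate < birth_rate`).
#' @param trade_intercept Intercept of the trade model on the logit scale.
#' @param trade_effect_mass Logit-scale coefficient on standardized log body
#'   mass.
#' @param trade_effects_binary Named numeric vector of logit-scale
#'   coefficients on binary traits (names must match trait columns).
#' @param phylo_effect_sd Standard deviation of the phylogenetic random
#'   effect (>= 0).
#' @param iucn_trade_correlation Correlation in [-1, 1] between the latent
#'   threat axis and the trade liability.
#' @param dd_fraction Fraction of species labelled data-deficient.
#' @param missing_fraction Fraction of species whose trait rows are masked
#'   (ground truth recorded for imputation tests).
#' @param bm_sd Brownian-motion rate (per unit branch length) for continuous
#'   traits.
#' @param seed Integer seed; every stage is deterministic given the config.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_species = 200, grid_rows = 20, grid_cols = 20,
                         n_realms = 11, birth_rate = 1, death_rate = 0,
                         trade_intercept = -0.5, trade_effect_mass = 1.8,
                         trade_effects_binary = c(diet_fruit = 0.6,
                                                  strata_arboreal = 0.5,
                                                  activity_diurnal = -0.4),
                         phylo_effect_sd = 1,
                         iucn_trade_correlation = 0.5,
                         dd_fraction = 0.05, missing_fraction = 0.065,
                         bm_sd = 1, seed = 1L) {
  stopifnot(n_species >= 2, grid_rows >= 2, grid_cols >= 2,
            n_realms >= 1, n_realms <= grid_rows * grid_cols,
            birth_rate >= 0, death_rate >= 0, death_rate < birth_rate,
            phylo_effect_sd >= 0,
            iucn_trade_correlation >= -1, iucn_trade_correlation <= 1,
            missing_fraction >= 0, missing_fraction < 1, bm_sd >= 0)
  structure(as.list(environment()), class = "world_config")
}

#' Simulate a birth-death phylogeny
#'
#' Wraps a constant-rate birth-death simulation conditioned on the number of
#' extant tips. The result is a rooted binary tree with strictly positive
#' branch lengths and tips labelled `s001, s002, ...`.
#'
#' @param config A [world_config()].
#' @param max_tries Retries if the simulator returns a degenerate tree.
#' @return A `phylo` object with `config$n_species` tips.
#' @export
simulate_tree <- function(config, max_tries = 10) {
  set.seed(config$seed)
  for (k in seq_len(max_tries)) {
    tree <- tryCatch(
      ape::rphylo(config$n_species, birth = config$birth_rate,
                  death = config$death_rate),
      error = function(e) NULL)
    if (!is.null(tree) && length(tree$tip.label) == config$n_species &&
        all(tree$edge.length > 0)) {
      tree$tip.label <- sprintf("s%03d", seq_len(config$n_species))
      return(tree)
    }
  }
  stop("tree simulation failed after ", max_tries,
       " tries (seed ", config$seed, ")")
}

# Brownian motion along the tree: root value + independent normal increments
# per edge, variance = bm_sd^2 * branch length.  Preorder accumulation.
simulate_bm <- function(tree, root = 0, bm_sd = 1) {
  if (bm_sd < 0) stop("Brownian-motion sd must be non-negative")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  val <- numeric(nnode)
  val[ntip + 1] <- root
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  ord <- ord[rev(seq_len(nrow(ord))), , drop = FALSE]  # preorder
  len <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                                paste(tree$edge[, 1], tree$edge[, 2]))]
  inc <- rnorm(nrow(ord), 0, bm_sd * sqrt(len))
  for (k in seq_len(nrow(ord))) val[ord[k, 2]] <- val[ord[k, 1]] + inc[k]
  setNames(val[seq_len(ntip)], tree$tip.label)
}

diet_categories <- c("diet_invertebrate", "diet_fruit", "diet_seed",
                     "diet_vertebrate", "diet_herbage")
strata_categories <- c("strata_ground", "strata_scansorial",
                       "strata_arboreal", "strata_aerial")

#' Simulate species traits under Brownian motion
#'
#' Log body mass evolves under Brownian motion; diet proportions arise from
#' Brownian latent scores pushed through a softmax and scaled to sum to 100;
#' foraging-strata and activity binaries come from thresholded Brownian
#' liabilities. A configurable fraction of species is masked (whole trait
#' rows set `NA`), with the masked truths recorded.
#'
#' @param tree A `phylo` from [simulate_tree()].
#' @param config A [world_config()].
#' @return A list with `traits` (masked table), `traits_true` (complete) and
#'   `truth` (masked species and their withheld values).
#' @export
simulate_traits <- function(tree, config) {
  set.seed(config$seed + 1L)
  n <- length(tree$tip.label)
  log_mass <- simulate_bm(tree, root = log(500), bm_sd = config$bm_sd)
  lat <- vapply(diet_categories, function(d)
    simulate_bm(tree, 0, config$bm_sd), numeric(n))
  ex <- exp(lat - apply(lat, 1, max))
  diet <- 100 * ex / rowSums(ex)
  bin_cols <- c(strata_categories, "activity_diurnal")
  liab <- vapply(bin_cols, function(b)
    simulate_bm(tree, 0, config$bm_sd), numeric(n))
  bins <- apply(liab, 2, function(x) as.integer(x > median(x)))
  traits <- data.frame(species = tree$tip.label,
                       body_mass = exp(log_mass), diet, bins,
                       row.names = NULL, check.names = FALSE,
                       stringsAsFactors = FALSE)
  masked <- traits
  n_mask <- round(config$missing_fraction * n)
  mask_sp <- if (n_mask > 0) sample(tree$tip.label, n_mask) else character(0)
  value_cols <- setdiff(names(traits), "species")
  masked[masked$species %in% mask_sp, value_cols] <- NA
  list(traits = masked, traits_true = traits,
       truth = list(masked_species = mask_sp,
                    masked_values = traits[traits$species %in% mask_sp, ,
                                           drop = FALSE]))
}

#' Simulate contiguous ranges, realms and land fractions
#'
#' Ranges grow by a spreading-dye process: a seed cell plus uniform random
#' choices from the contiguous frontier until a log-uniformly drawn range
#' size (1 cell to half the grid) is reached. Realms partition the grid into
#' contiguous blocks; land fraction is 1 inland and uniform on (0.05, 1) on
#' border cells so that some coastal cells fall under the 30% retention rule.
#'
#' @param tree A `phylo` (supplies species names).
#' @param config A [world_config()].
#' @return A list with `grid` (data.frame: cell, row, col, x, y,
#'   land_fraction, realm) and `presence` (cells x species binary matrix).
#' @export
simulate_ranges_and_realms <- function(tree, config) {
  set.seed(config$seed + 2L)
  nr <- config$grid_rows; nc <- config$grid_cols
  ncell <- nr * nc
  row_id <- rep(seq_len(nr), times = nc)
  col_id <- rep(seq_len(nc), each = nr)
  realm <- integer(ncell)
  if (config$n_realms <= nc) {
    band <- as.integer(cut(seq_len(nc), config$n_realms, labels = FALSE))
    realm <- band[col_id]
  } else {
    realm <- as.integer(cut(seq_len(ncell), config$n_realms, labels = FALSE))
  }
  border <- row_id == 1 | row_id == nr | col_id == 1 | col_id == nc
  land <- rep(1, ncell)
  land[border] <- runif(sum(border), 0.05, 1)
  grid <- data.frame(cell = seq_len(ncell), row = row_id, col = col_id,
                     x = (col_id - 0.5) * 111, y = (row_id - 0.5) * 111,
                     land_fraction = land, realm = realm)

  sp <- tree$tip.label
  presence <- matrix(0L, ncell, length(sp),
                     dimnames = list(NULL, sp))
  max_size <- max(1, floor(ncell / 2))
  sizes <- pmin(round(exp(runif(length(sp), log(1), log(max_size)))), ncell)
  neighbours <- function(cell) {
    r <- row_id[cell]; cc <- col_id[cell]
    out <- c(if (r > 1) cell - 1L, if (r < nr) cell + 1L,
             if (cc > 1) cell - nr, if (cc < nc) cell + nr)
    out
  }
  for (s in seq_along(sp)) {
    target <- sizes[s]
    if (target > ncell) {
      warning("range size clipped to grid for ", sp[s])
      target <- ncell
    }
    occupied <- logical(ncell)
    seed_cell <- sample.int(ncell, 1)
    occupied[seed_cell] <- TRUE
    frontier <- setdiff(neighbours(seed_cell), which(occupied))
    while (sum(occupied) < target && length(frontier) > 0) {
      nxt <- frontier[sample.int(length(frontier), 1)]
      occupied[nxt] <- TRUE
      frontier <- setdiff(unique(c(frontier, neighbours(nxt))),
                          which(occupied))
    }
    presence[occupied, s] <- 1L
  }
  list(grid = grid, presence = presence)
}

#' Simulate trade status, use types and IUCN categories
#'
#' Trade status is Bernoulli with a logit-linear predictor: intercept,
#' standardized log body mass, binary trait effects, and a phylogenetic
#' random effect `u ~ N(0, sigma^2 C)` with `C` the unit-diagonal tree
#' correlation matrix. Pet/product use flags are drawn conditional on trade.
#' IUCN categories come from an ordinal latent correlated with the trade
#' liability; a configured fraction of species is set data-deficient.
#'
#' @param tree A `phylo`.
#' @param traits_true The complete (unmasked) trait table.
#' @param config A [world_config()].
#' @return A list with `ledger` (data.frame: species, traded, pet, product,
#'   iucn_category) and `truth` (coefficients and the simulated phylogenetic
#'   effects).
#' @export
simulate_trade <- function(tree, traits_true, config) {
  if (config$phylo_effect_sd < 0) stop("phylo_effect_sd must be >= 0")
  set.seed(config$seed + 3L)
  n <- length(tree$tip.label)
  stopifnot(identical(traits_true$species, tree$tip.label))
  z_mass <- as.numeric(scale(log(traits_true$body_mass)))
  eta <- config$trade_intercept + config$trade_effect_mass * z_mass
  betas <- config$trade_effects_binary
  for (nm in names(betas)) {
    x <- if (nm %in% diet_categories) {
      as.integer(traits_true[[nm]] > 25)
    } else traits_true[[nm]]
    if (is.null(x)) stop("unknown trait in trade_effects_binary: ", nm)
    eta <- eta + betas[[nm]] * x
  }
  u <- numeric(n)
  if (config$phylo_effect_sd > 0) {
    C <- build_phylo_corr(tree)
    L <- t(chol(C + diag(1e-8, n)))
    u <- config$phylo_effect_sd * as.numeric(L %*% rnorm(n))
  }
  eta <- eta + u
  traded <- rbinom(n, 1, plogis(eta))
  pet <- ifelse(traded == 1, rbinom(n, 1, 0.6), 0L)
  product <- ifelse(traded == 1, rbinom(n, 1, 0.6), 0L)
  neither <- traded == 1 & pet == 0 & product == 0
  product[neither] <- 1L
  # ordinal probit latent for threat, correlated with the trade liability
  rho <- config$iucn_trade_correlation
  z_eta <- if (sd(eta) > 0) as.numeric(scale(eta)) else numeric(n)
  lat <- rho * z_eta + sqrt(1 - rho^2) * rnorm(n)
  cuts <- quantile(lat, c(0.5, 0.7, 0.85, 0.95))
  cat_ <- cut(lat, c(-Inf, cuts, Inf),
              labels = c("LC", "NT", "VU", "EN", "CR"))
  cat_ <- as.character(cat_)
  n_dd <- round(config$dd_fraction * n)
  if (n_dd > 0) cat_[sample.int(n, n_dd)] <- "DD"
  ledger <- data.frame(species = tree$tip.label, traded = traded,
                       pet = as.integer(pet), product = as.integer(product),
                       iucn_category = cat_, stringsAsFactors = FALSE)
  truth <- list(intercept = config$trade_intercept,
                beta_mass = config$trade_effect_mass,
                beta_binary = betas, phylo_effect_sd = config$phylo_effect_sd,
                u = setNames(u, tree$tip.label))
  list(ledger = ledger, truth = truth)
}

#' Simulate a complete synthetic world
#'
#' Runs tree, trait, range/realm and trade simulation in sequence and
#' returns every piece with its ground truth.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` with elements `config`, `tree`,
#'   `traits`, `traits_true`, `grid`, `presence`, `ledger`, `truth`.
#' @export
simulate_world <- function(config = world_config()) {
  tree <- simulate_tree(config)
  tr <- simulate_traits(tree, config)
  rw <- simulate_ranges_and_realms(tree, config)
  td <- simulate_trade(tree, tr$traits_true, config)
  structure(list(config = config, tree = tree,
                 traits = tr$traits, traits_true = tr$traits_true,
                 grid = rw$grid, presence = rw$presence,
                 ledger = td$ledger,
                 truth = c(tr$truth, td$truth)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", x$config$n_species, "species,",
      x$config$grid_rows, "x", x$config$grid_cols, "grid,",
      x$config$n_realms, "realms\n")
  cat("  traded:", sum(x$ledger$traded), "species;",
      "masked traits:", length(x$truth$masked_species), "species\n")
  invisible(x)
}

#' Write a synthetic world to delimited text files
#'
#' Writes the tree (Newick), traits, ledger, grid and presence matrix as
#' plain text, plus a ground-truth manifest, into a directory.
#'
#' @param world A [simulate_world()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.csv"),
             ledger = file.path(dir, "ledger.csv"),
             grid = file.path(dir, "grid.csv"),
             presence = file.path(dir, "presence.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  ape::write.tree(world$tree, files["tree"])
  write.csv(world$traits, files["traits"], row.names = FALSE)
  write.csv(world$ledger, files["ledger"], row.names = FALSE)
  write.csv(world$grid, files["grid"], row.names = FALSE)
  # presence as sparse triplets (cell, species)
  idx <- which(world$presence == 1L, arr.ind = TRUE)
  write.csv(data.frame(cell = idx[, 1],
                       species = colnames(world$presence)[idx[, 2]]),
            files["presence"], row.names = FALSE)
  tv <- data.frame(name = c("intercept", "beta_mass",
                            paste0("beta_", names(world$truth$beta_binary)),
                            "phylo_effect_sd"),
                   value = c(world$truth$intercept, world$truth$beta_mass,
                             unname(world$truth$beta_binary),
                             world$truth$phylo_effect_sd))
  write.csv(tv, files["truth"], row.names = FALSE)
  invisible(files)
}
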