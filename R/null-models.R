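#' Realm-restricted null community for one cell
#'
#' Draws a uniform random subset of the regional species pool — the species
#' present in at least one cell of the cell's realm — with the same richness
#' as the observed (traded) set of the cell. This is the tip-shuffling null
#' restricted to the realm pool, with species richness maintained.
#'
#' @param cell Cell id (must be a row of `grid`).
#' @param presence Binary cells x species matrix.
#' @param grid Grid data.frame with `cell` and `realm` columns.
#' @param target_species Character vector: the observed species set whose
#'   richness the null preserves.
#' @param pool Optional explicit pool (default: species present anywhere in
#'   the cell's realm).
#' @return Character vector of species forming the null community.
#' @export
realm_pool_randomize <- function(cell, presence, grid, target_species,
                                 pool = NULL) {
  k <- length(target_species)
  if (k == 0) return(character(0))
  if (is.null(pool)) {
    realm <- grid$realm[grid$cell == cell]
    if (length(realm) != 1) stop("cell ", cell, " not found in grid")
    realm_cells <- grid$cell[grid$realm == realm]
    pool <- colnames(presence)[colSums(presence[realm_cells, , drop = FALSE]) > 0]
  }
  if (length(pool) < k)
    stop("realm pool (", length(pool), ") smaller than observed richness (",
         k, ") for cell ", cell)
  if (length(pool) == k) return(pool)
  sample(pool, k)
}

#' Standardized effect size
#'
#' `(observed - mean(null)) / sd(null)` with the sample (n-1) standard
#' deviation. The observed value is not pooled into the null set. A zero
#' null SD yields `NA` with a warning.
#'
#' @param observed Observed metric value.
#' @param null_values Numeric vector of null metric values (length >= 2).
#' @return The standardized effect size (scalar).
#' @export
ses <- function(observed, null_values) {
  if (length(null_values) < 2) stop("need at least 2 null values")
  s <- sd(null_values)
  if (!is.finite(s) || s == 0) {
    warning("null distribution has zero standard deviation; ses undefined")
    return(NA_real_)
  }
  (observed - mean(null_values)) / s
}

#' Per-cell standardized effect sizes of PD or FD
#'
#' For each retained cell, the observed metric of the species passing
#' `subset_rule` is compared against `n_null` richness-matched random
#' communities drawn from the cell's realm pool. PD uses the tree (median
#' over an ensemble if one is given); FD uses the shared trait space with
#' the minimum-species rule, cells below it being `NA`.
#'
#' @param presence Binary cells x species matrix.
#' @param grid Grid data.frame (filtered).
#' @param ledger Species ledger.
#' @param tree Tree or ensemble (metric `"pd"`).
#' @param trait_space Trait space from [build_trait_space()] (metric `"fd"`).
#' @param metric `"pd"` or `"fd"`.
#' @param n_null Number of null communities (paper-scale default 999).
#' @param subset_rule Passed to [cell_summaries()] semantics (default
#'   `"traded"`).
#' @param fd_min_species Minimum richness for FD (default 4).
#' @return A data.frame with per-cell `observed`, `null_mean`, `null_sd`,
#'   `ses` and `richness`.
#' @export
ses_map <- function(presence, grid, ledger, tree = NULL, trait_space = NULL,
                    metric = c("pd", "fd"), n_null = 999,
                    subset_rule = "traded", fd_min_species = 4) {
  metric <- match.arg(metric)
  sp_all <- colnames(presence)
  sp_rule <- intersect(rule_species(ledger, subset_rule), sp_all)
  realm_pools <- lapply(split(grid$cell, grid$realm), function(cells)
    sp_all[colSums(presence[cells, , drop = FALSE]) > 0])

  obs_fn <- if (metric == "pd") {
    if (is.null(tree)) stop("metric 'pd' needs a tree")
    trees <- if (inherits(tree, "phylo")) list(tree) else tree
    te_list <- lapply(trees, tip_edge_matrix)   # amortize the traversal
    function(m) {
      vals <- vapply(seq_along(trees), function(i)
        faith_pd_matrix(trees[[i]], m, te = te_list[[i]]),
        numeric(nrow(m)))
      apply(as.matrix(vals), 1, median)
    }
  } else {
    if (is.null(trait_space)) stop("metric 'fd' needs a trait space")
    function(m) fric_cells(trait_space,
                           m[, intersect(colnames(m),
                                         rownames(trait_space$coords)),
                             drop = FALSE],
                           min_species = fd_min_species)
  }

  n_cell <- nrow(grid)
  res <- data.frame(cell = grid$cell, richness = NA_real_,
                    observed = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, ses = NA_real_)
  for (r in seq_len(n_cell)) {
    cell <- grid$cell[r]
    obs_sp <- sp_rule[presence[cell, sp_rule] == 1]
    k <- length(obs_sp)
    res$richness[r] <- k
    if (metric == "fd" && k < fd_min_species) next
    if (k == 0) next
    pool <- realm_pools[[as.character(grid$realm[r])]]
    if (length(pool) < k) {
      warning("realm pool smaller than richness for cell ", cell)
      next
    }
    nulls <- matrix(0L, n_null, length(sp_all),
                    dimnames = list(NULL, sp_all))
    for (b in seq_len(n_null))
      nulls[b, if (length(pool) == k) pool else sample(pool, k)] <- 1L
    obs_m <- matrix(0L, 1, length(sp_all), dimnames = list(NULL, sp_all))
    obs_m[1, obs_sp] <- 1L
    ov <- obs_fn(obs_m)[1]
    nv <- obs_fn(nulls)
    nv <- nv[!is.na(nv)]
    if (is.na(ov) || length(nv) < 2) next
    s <- sd(nv)
    res$observed[r] <- ov
    res$null_mean[r] <- mean(nv)
    res$null_sd[r] <- s
    res$ses[r] <- if (s > 0) (ov - mean(nv)) / s else NA_real_
  }
  res
}
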