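#' Dummy-code proportion traits
#'
#' A category becomes 1 when it makes up strictly more than `threshold`
#' percent of the composition (so 25 maps to 0 and 26 to 1 at the default);
#' all-zero rows are allowed.
#'
#' @param proportions Matrix or data.frame of percentages (rows sum to 100).
#' @param threshold Percentage cutoff (default 25).
#' @return Integer 0/1 matrix of the same shape.
#' @export
dummy_code <- function(proportions, threshold = 25) {
  m <- as.matrix(proportions)
  out <- (m > threshold) * 1L
  dimnames(out) <- dimnames(m)
  out
}

# per-group Gower dissimilarity components, each in [0, 1]
trait_group_dissim <- function(traits, groups, types) {
  n <- nrow(traits)
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in names(groups)) {
    sub <- as.matrix(traits[, groups[[g]], drop = FALSE])
    out[[g]] <- switch(types[[g]],
      continuous = {
        rng <- diff(range(sub))
        if (rng == 0) matrix(0, n, n)
        else as.matrix(stats::dist(sub / rng, method = "manhattan"))
      },
      # fuzzy composition (percentages summing to 100): Manhattan/200 in [0,1]
      fuzzy = as.matrix(stats::dist(sub, method = "manhattan")) / 200,
      # binaries: mean mismatch over the group's columns
      binary = as.matrix(stats::dist(sub, method = "manhattan")) / ncol(sub),
      stop("unknown group type ", types[[g]]))
  }
  out
}

#' Gower dissimilarity with equalized trait-group contributions
#'
#' Builds a Gower-type dissimilarity over four trait groups — log body mass,
#' diet composition (one fuzzy group), foraging strata and activity period —
#' and reweights the groups so that each contributes equally to the mean
#' pairwise dissimilarity. Weights start at the analytic solution (inverse
#' mean raw contribution) and are rebalanced iteratively to a relative
#' spread below `tol`. Constant groups are dropped with a warning.
#'
#' @param traits Complete trait table (columns `body_mass`, diet percentage
#'   columns, strata and activity binaries; a `species` column is used for
#'   labels).
#' @param tol Relative tolerance on the spread of group contributions.
#' @param max_iter Maximum rebalancing iterations.
#' @return A list with `dissim` (symmetric matrix in [0, 1]), `weights`
#'   (per group, summing to 1) and `contributions` (per group, equal within
#'   `tol`).
#' @export
gower_equal_contrib <- function(traits, tol = 1e-6, max_iter = 100) {
  stopifnot(nrow(traits) >= 2)
  value_cols <- setdiff(names(traits), "species")
  if (anyNA(traits[, value_cols]))
    stop("traits contain missing values; impute first")
  labels <- if ("species" %in% names(traits)) traits$species
            else rownames(traits)
  diet_cols <- grep("^diet_", names(traits), value = TRUE)
  strata_cols <- grep("^strata_", names(traits), value = TRUE)
  act_cols <- grep("^activity_", names(traits), value = TRUE)
  groups <- list(mass = "log_body_mass", diet = diet_cols,
                 strata = strata_cols, activity = act_cols)
  types <- list(mass = "continuous", diet = "fuzzy",
                strata = "binary", activity = "binary")
  keep <- vapply(groups, length, integer(1)) > 0
  groups <- groups[keep]; types <- types[keep]
  work <- traits
  work$log_body_mass <- log(traits$body_mass)
  comp <- trait_group_dissim(work, groups, types)
  means <- vapply(comp, mean, numeric(1))
  drop <- means == 0
  if (any(drop)) {
    warning("constant trait group(s) dropped: ",
            paste(names(groups)[drop], collapse = ", "))
    comp <- comp[!drop]
    means <- means[!drop]
  }
  if (length(comp) == 0) {
    # every trait identical across species: all dissimilarities are zero
    D <- matrix(0, nrow(traits), nrow(traits),
                dimnames = list(labels, labels))
    return(list(dissim = D, weights = numeric(0),
                contributions = numeric(0)))
  }
  w <- (1 / means) / sum(1 / means)
  for (it in seq_len(max_iter)) {
    contrib <- w * means            # mean contribution of each group
    spread <- (max(contrib) - min(contrib)) / mean(contrib)
    if (spread < tol) break
    w <- w / contrib
    w <- w / sum(w)
  }
  if (spread >= tol)
    stop("equal-contribution reweighting did not converge; spread = ", spread)
  D <- Reduce(`+`, Map(function(m, wi) wi * m, comp, w))
  dimnames(D) <- list(labels, labels)
  list(dissim = D, weights = w, contributions = w * means / sum(w * means))
}

#' Principal coordinate axes of a dissimilarity matrix
#'
#' Classical metric scaling: eigen-decomposition of the double-centred
#' squared-distance matrix, keeping the `n_axes` largest positive
#' eigenvalues. No negative-eigenvalue correction is applied; the summed
#' absolute negative eigenvalue fraction is reported so distortion can be
#' assessed.
#'
#' @param dissim Symmetric dissimilarity matrix.
#' @param n_axes Number of axes (default 3).
#' @return A list of class `trait_space` with `coords` (species x axes),
#'   `eig` (all eigenvalues) and `negative_fraction`.
#' @export
pcoa_axes <- function(dissim, n_axes = 3) {
  d <- as.matrix(dissim)
  fit <- stats::cmdscale(d, k = n_axes, eig = TRUE)
  n_pos <- sum(fit$eig > 1e-10)
  if (n_pos < n_axes)
    stop("only ", n_pos, " positive eigenvalues; request fewer axes")
  coords <- fit$points
  rownames(coords) <- rownames(d)
  neg <- sum(abs(fit$eig[fit$eig < 0])) / sum(abs(fit$eig))
  structure(list(coords = coords, eig = fit$eig, negative_fraction = neg),
            class = "trait_space")
}

#' Build the shared trait space
#'
#' Gower dissimilarity with equalized group contributions followed by a
#' 3-axis principal coordinate analysis, run once on the full species pool
#' so that per-cell functional richness values are comparable across cells.
#'
#' @param traits Complete trait table.
#' @param n_axes Number of ordination axes (default 3).
#' @param ... Passed to [gower_equal_contrib()].
#' @return A `trait_space` with the Gower `weights` attached.
#' @export
build_trait_space <- function(traits, n_axes = 3, ...) {
  g <- gower_equal_contrib(traits, ...)
  space <- pcoa_axes(g$dissim, n_axes = n_axes)
  space$weights <- g$weights
  space
}

#' Functional richness of a species set
#'
#' Volume of the 3-D convex hull of the set's trait-space coordinates. Sets
#' with fewer than `min_species` species (default 4, matching the rule that
#' richness must exceed the number of axes) or degenerate (coplanar)
#' coordinates return `NA`.
#'
#' @param trait_space A [build_trait_space()] result.
#' @param species Character vector of species.
#' @param min_species Minimum set size (default 4).
#' @return Hull volume (>= 0) or `NA`.
#' @export
fric <- function(trait_space, species, min_species = 4) {
  species <- intersect(species, rownames(trait_space$coords))
  if (length(species) < min_species) return(NA_real_)
  .hull_volume3d(trait_space$coords[species, , drop = FALSE])
}

#' Functional richness for every row of a presence matrix
#'
#' @param trait_space A [build_trait_space()] result.
#' @param presence Binary sets x species matrix (columns named with species
#'   having trait-space coordinates).
#' @param min_species Minimum set size (default 4).
#' @return Numeric vector of hull volumes (`NA` below the species floor or
#'   for degenerate point sets).
#' @export
fric_cells <- function(trait_space, presence, min_species = 4) {
  sp <- colnames(presence)
  apply(presence, 1, function(row)
    fric(trait_space, sp[row == 1], min_species = min_species))
}
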