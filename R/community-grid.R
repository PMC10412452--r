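#' Drop low-land coastal cells
#'
#' Removes grid cells with less than 30% land; a cell at exactly the
#' threshold is retained.
#'
#' @param grid Grid data.frame with a `land_fraction` column.
#' @param threshold Minimum land fraction retained (default 0.30).
#' @return The filtered grid.
#' @export
filter_cells <- function(grid, threshold = 0.30) {
  stopifnot("land_fraction" %in% names(grid))
  grid[grid$land_fraction >= threshold, , drop = FALSE]
}

subset_rules <- c("all", "traded", "pet", "product", "endemic-traded")

# species passing a subset rule
rule_species <- function(ledger, rule) {
  rule <- match.arg(rule, subset_rules)
  switch(rule,
         "all" = ledger$species,
         "traded" = ledger$species[ledger$traded == 1],
         "pet" = ledger$species[ledger$pet == 1],
         "product" = ledger$species[ledger$product == 1],
         "endemic-traded" = {
           if (is.null(ledger$realm_endemic))
             stop("ledger has no realm_endemic flags; run filter_endemics()")
           ledger$species[ledger$traded == 1 & ledger$realm_endemic %in% 1]
         })
}

#' Per-cell diversity summaries
#'
#' For each retained grid cell, computes richness, Faith's PD, summed ED,
#' summed EDGE (species without an EDGE score are skipped), the natural log
#' of the mean EDGE of scored species present, functional richness (if a
#' trait space is supplied), and — for every metric — the proportion
#' contributed by species passing `subset_rule` relative to all species.
#'
#' @param presence Binary cells x species matrix (columns named).
#' @param grid Grid data.frame (already filtered with [filter_cells()] if
#'   desired); rows must align with `presence` via the `cell` column.
#' @param ledger Species ledger (species, traded, pet, product,
#'   iucn_category, optionally realm_endemic).
#' @param scores Per-species scores from [species_scores()].
#' @param tree A `phylo` or tree ensemble used for PD.
#' @param trait_space Optional trait space from [build_trait_space()]; when
#'   supplied, FD (convex-hull functional richness) is computed per cell,
#'   `NA` where fewer than `fd_min_species` species have coordinates.
#' @param subset_rule One of `"all"`, `"traded"`, `"pet"`, `"product"`,
#'   `"endemic-traded"`.
#' @param fd_min_species Minimum species for FD (default 4).
#' @return A data.frame of per-cell metrics (class `cell_metrics`), one row
#'   per grid row.
#' @export
cell_summaries <- function(presence, grid, ledger, scores, tree,
                           trait_space = NULL, subset_rule = "traded",
                           fd_min_species = 4) {
  rule <- match.arg(subset_rule, subset_rules)
  sp_all <- intersect(colnames(presence), ledger$species)
  sp_rule <- intersect(rule_species(ledger, rule), sp_all)
  pres <- presence[grid$cell, sp_all, drop = FALSE]
  sub <- pres
  sub[, setdiff(sp_all, sp_rule)] <- 0L

  pd_all <- pd_over_trees(tree, pres)
  pd_sub <- pd_over_trees(tree, sub)

  sc <- scores[match(sp_all, scores$species), ]
  edv <- setNames(sc$ED, sp_all)
  edgev <- setNames(sc$EDGE, sp_all)
  in_rule <- as.numeric(sp_all %in% sp_rule)

  sum_ed_all <- as.numeric(pres %*% edv)
  sum_ed_sub <- as.numeric(pres %*% (edv * in_rule))
  edge0 <- ifelse(is.na(edgev), 0, edgev)
  scored <- as.numeric(!is.na(edgev))
  sum_edge_all <- as.numeric(pres %*% edge0)
  sum_edge_sub <- as.numeric(pres %*% (edge0 * in_rule))
  n_scored_sub <- as.numeric(pres %*% (scored * in_rule))
  log_mean_edge <- ifelse(n_scored_sub > 0,
                          log(sum_edge_sub / n_scored_sub), NA_real_)

  rich_all <- rowSums(pres)
  rich_sub <- rowSums(sub)

  out <- data.frame(cell = grid$cell, realm = grid$realm,
                    richness = rich_all, richness_subset = rich_sub,
                    pd = pd_all, pd_subset = pd_sub,
                    sum_ed = sum_ed_all, sum_ed_subset = sum_ed_sub,
                    sum_edge = sum_edge_all, sum_edge_subset = sum_edge_sub,
                    log_mean_edge = log_mean_edge)
  if (!is.null(trait_space)) {
    have <- intersect(sp_all, rownames(trait_space$coords))
    out$fd <- fric_cells(trait_space, pres[, have, drop = FALSE],
                         min_species = fd_min_species)
    sub_have <- sub[, have, drop = FALSE]
    out$fd_subset <- fric_cells(trait_space, sub_have,
                                min_species = fd_min_species)
  }
  prop <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  out$prop_richness <- prop(rich_sub, rich_all)
  out$prop_pd <- prop(pd_sub, pd_all)
  out$prop_ed <- prop(sum_ed_sub, sum_ed_all)
  out$prop_edge <- prop(sum_edge_sub, sum_edge_all)
  if (!is.null(trait_space))
    out$prop_fd <- ifelse(!is.na(out$fd) & out$fd > 0,
                          ifelse(is.na(out$fd_subset), 0, out$fd_subset) / out$fd,
                          NA_real_)
  empty <- rich_sub == 0
  out[empty, c("log_mean_edge")] <- NA_real_
  class(out) <- c("cell_metrics", "data.frame")
  out
}

# PD per row of a presence matrix, median over an ensemble when given one
pd_over_trees <- function(tree, presence) {
  if (inherits(tree, "phylo")) return(faith_pd_matrix(tree, presence))
  vals <- vapply(tree, function(t) faith_pd_matrix(t, presence),
                 numeric(nrow(presence)))
  apply(as.matrix(vals), 1, median)
}

#' Top fraction of scored species
#'
#' Selects `ceiling(fraction * n)` species by score; ties at the cutoff are
#' broken by higher ED and then species id, so the set is deterministic.
#'
#' @param scores A data.frame with `species`, `ED` and the score column.
#' @param fraction Fraction in (0, 1].
#' @param metric Score column used (default `"EDGE"`); rows with `NA` score
#'   are excluded first.
#' @return Character vector of selected species.
#' @export
top_fraction_species <- function(scores, fraction, metric = "EDGE") {
  stopifnot(fraction > 0, fraction <= 1)
  sc <- scores[!is.na(scores[[metric]]), ]
  if (nrow(sc) == 0) stop("no scored species")
  ord <- order(-sc[[metric]], -sc$ED, sc$species)
  k <- ceiling(fraction * nrow(sc))
  sc$species[ord][seq_len(k)]
}

#' Hotspot flags from per-cell values
#'
#' Flags the top 25% and top 5% of cells by value. The cutoffs are the
#' `ceiling(fraction * m)`-th largest values over the `m` non-missing cells;
#' every cell tied with the cutoff is flagged, so flag counts can exceed the
#' nominal fraction on tied inputs (the counts are reported as attributes).
#' Missing cells are never flagged.
#'
#' @param values Numeric per-cell values (may contain `NA`).
#' @param fractions Hotspot fractions (default `c(0.25, 0.05)`).
#' @return A data.frame with logical columns `top25`, `top5` (or `top<f>` for
#'   other fractions); `top5` implies `top25`.
#' @export
hotspots <- function(values, fractions = c(0.25, 0.05)) {
  ok <- !is.na(values)
  if (!any(ok)) stop("no non-missing cell values")
  out <- data.frame(row.names = seq_along(values))
  counts <- integer(0)
  for (f in fractions) {
    k <- ceiling(f * sum(ok))
    cutoff <- sort(values[ok], decreasing = TRUE)[k]
    flag <- ok & values >= cutoff
    nm <- paste0("top", round(100 * f))
    out[[nm]] <- flag
    counts[nm] <- sum(flag)
  }
  attr(out, "flag_counts") <- counts
  out
}

#' Flag realm-endemic species
#'
#' A species is realm-endemic when every cell of its range lies in a single
#' biogeographical realm; touching a second realm by even one cell removes
#' the flag. Species with no presence cells get `NA` and are excluded from
#' endemic analyses.
#'
#' @param presence Binary cells x species matrix.
#' @param grid Grid data.frame with `cell` and `realm`.
#' @param ledger Species ledger.
#' @return The ledger with a `realm_endemic` column (1, 0 or `NA`).
#' @export
filter_endemics <- function(presence, grid, ledger) {
  realm_of_cell <- grid$realm[match(seq_len(nrow(presence)), grid$cell)]
  flags <- vapply(ledger$species, function(s) {
    if (!s %in% colnames(presence)) return(NA_integer_)
    cells <- which(presence[, s] == 1)
    if (length(cells) == 0) return(NA_integer_)
    realms <- unique(realm_of_cell[cells])
    realms <- realms[!is.na(realms)]
    as.integer(length(realms) == 1)
  }, integer(1))
  ledger$realm_endemic <- unname(flags)
  ledger
}
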