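#' Read a Newick tree or tree ensemble
#'
#' Reads one or more rooted trees with branch lengths from a Newick file and
#' validates them: tip labels must be unique and branch lengths non-negative.
#' Zero-length branches are legal but noted in the validation report attached
#' to the result (attribute `"validation"`).
#'
#' @param path Path to a Newick file containing one or more trees.
#' @return A `phylo` object, or a `multiPhylo` list if the file holds several
#'   trees (all sharing the same tip set).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("could not parse Newick in ", path)
  single <- inherits(trees, "phylo")
  lst <- if (single) list(trees) else trees
  reports <- lapply(lst, validate_tree)
  if (!single) {
    tips <- lapply(lst, function(t) sort(t$tip.label))
    if (!all(vapply(tips, identical, logical(1), y = tips[[1]])))
      stop("trees in ", path, " do not share an identical tip set")
  }
  out <- if (single) lst[[1]] else trees
  attr(out, "validation") <- if (single) reports[[1]] else reports
  out
}

#' Validate a phylogenetic tree
#'
#' @param tree A `phylo` object.
#' @return A list with elements `n_tip`, `zero_length_branches` (edge indices)
#'   and `ok`. Errors on duplicate tip labels or negative branch lengths,
#'   naming the offender.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  neg <- which(tree$edge.length < 0)
  if (length(neg))
    stop("negative branch length on edge(s) ", paste(neg, collapse = ", "))
  list(n_tip = length(tree$tip.label),
       zero_length_branches = which(tree$edge.length == 0),
       ok = TRUE)
}

# Sparse tip-by-edge incidence: entry (t, e) = 1 iff tip t descends from
# (the child end of) edge e.  Lets PD and ED be computed by matrix products.
tip_edge_matrix <- function(tree) {
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nnode <- ntip + tree$Nnode
  # tips below each node, accumulated in postorder
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", nnode)
  for (t in seq_len(ntip)) below[[t]] <- t
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chl <- po$edge[k, 2]
    below[[par]] <- c(below[[par]], below[[chl]])
  }
  child <- tree$edge[, 2]
  i <- unlist(below[child])
  j <- rep.int(seq_len(nedge), vapply(below[child], length, integer(1)))
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(ntip, nedge),
                       dimnames = list(tree$tip.label, NULL))
}

#' Faith's phylogenetic diversity of a species set
#'
#' Sum of branch lengths of the minimal subtree connecting the species set.
#' By default the subtree includes the path to the root, so a single species
#' has PD equal to its root-to-tip distance; with `include_root = FALSE`
#' branches above the most recent common ancestor of the set are dropped.
#'
#' @param tree A `phylo` object.
#' @param species Character vector of tip labels (non-empty, unless you want
#'   the defined value 0 for the empty set).
#' @param include_root Keep the root-to-MRCA path in the subtree (default
#'   `TRUE`).
#' @return A single non-negative number.
#' @export
faith_pd <- function(tree, species, include_root = TRUE) {
  if (length(species) == 0) return(0)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  m <- matrix(0, 1, length(tree$tip.label),
              dimnames = list(NULL, tree$tip.label))
  m[1, species] <- 1
  faith_pd_matrix(tree, m, include_root = include_root)[1]
}

#' Faith's PD for many species sets at once
#'
#' @param tree A `phylo` object.
#' @param presence A binary matrix, sets (rows) by species (columns named with
#'   tip labels; extra tips absent from the matrix count as absent).
#' @param include_root See [faith_pd()].
#' @param te Precomputed [tip_edge_matrix()] of the tree (internal use, to
#'   amortize the tree traversal over many calls).
#' @return Numeric vector of PD values, one per row; 0 for empty rows.
#' @export
faith_pd_matrix <- function(tree, presence, include_root = TRUE, te = NULL) {
  if (is.null(te)) te <- tip_edge_matrix(tree)
  sp <- colnames(presence)
  unknown <- setdiff(sp, rownames(te))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "))
  P <- methods::as(Matrix::Matrix(presence[, sp, drop = FALSE], sparse = TRUE),
                   "dMatrix")
  counts <- P %*% te[sp, , drop = FALSE]   # sets x edges: tips of set below edge
  counts <- as(counts, "CsparseMatrix")
  len <- tree$edge.length
  rich <- Matrix::rowSums(P)
  if (include_root) {
    covered <- counts
    covered@x <- as.numeric(covered@x > 0)
    pd <- as.numeric(covered %*% len)
  } else {
    # drop edges whose descendant count equals the whole set (root-MRCA path)
    pd <- numeric(nrow(presence))
    cm <- as.matrix(counts)
    for (r in seq_len(nrow(cm))) {
      keep <- cm[r, ] > 0 & cm[r, ] < rich[r]
      if (rich[r] == 1) keep <- rep(FALSE, ncol(cm))
      pd[r] <- sum(len[keep])
    }
  }
  pd[rich == 0] <- 0
  pd
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch length is divided equally among the tips descending from it;
#' a tip's ED is the sum of its shares along the root-to-tip path. ED summed
#' over all tips equals the total branch length of the tree.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector of ED values (tree time units), one per tip.
#' @export
fair_proportion_ed <- function(tree) {
  te <- tip_edge_matrix(tree)
  ntips_per_edge <- Matrix::colSums(te)
  ed <- as.numeric(te %*% (tree$edge.length / ntips_per_edge))
  names(ed) <- tree$tip.label
  ed
}

#' Global endangerment weight of an IUCN category
#'
#' LC = 0, NT = 1, VU = 2, EN = 3, CR = 4; DD is `NA` (data-deficient species
#' carry no EDGE score).
#'
#' @param category Character vector of IUCN category codes.
#' @return Integer weights (NA for DD).
#' @export
ge_weight <- function(category) {
  map <- c(LC = 0, NT = 1, VU = 2, EN = 3, CR = 4, DD = NA)
  bad <- setdiff(unique(category), names(map))
  if (length(bad))
    stop("unknown IUCN category code(s): ", paste(bad, collapse = ", "))
  unname(map[category])
}

#' EDGE score
#'
#' `EDGE = ln(1 + ED) + GE * ln(2)` with GE the global-endangerment weight of
#' the IUCN category; data-deficient species get `NA`.
#'
#' @param ed Non-negative evolutionary distinctiveness value(s).
#' @param category IUCN category code(s) (`LC`, `NT`, `VU`, `EN`, `CR`, `DD`).
#' @return Numeric vector of EDGE scores (`NA` where DD).
#' @export
edge_score <- function(ed, category) {
  if (any(ed < 0, na.rm = TRUE)) stop("ED must be non-negative")
  log(1 + ed) + ge_weight(category) * log(2)
}

#' Elementwise median of a metric over a tree ensemble
#'
#' Applies `metric_fn` to each tree of the ensemble and returns the
#' elementwise median (for an even number of trees, the mean of the two
#' central order statistics, i.e. [stats::median()]).
#'
#' @param ensemble A `multiPhylo` object or list of `phylo` trees over one tip
#'   set.
#' @param metric_fn Function of a single tree returning a numeric vector of a
#'   fixed length (and naming) across trees.
#' @param ... Passed on to `metric_fn`.
#' @return Numeric vector of medians.
#' @export
median_over_ensemble <- function(ensemble, metric_fn, ...) {
  if (inherits(ensemble, "phylo")) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1)
  tips <- lapply(ensemble, function(t) sort(t$tip.label))
  if (!all(vapply(tips, identical, logical(1), y = tips[[1]])))
    stop("ensemble trees do not share an identical tip set")
  vals <- lapply(ensemble, metric_fn, ...)
  m <- do.call(rbind, vals)
  out <- apply(m, 2, median)
  if (!is.null(names(vals[[1]]))) names(out) <- names(vals[[1]])
  out
}

#' Per-species ED, GE and EDGE scores, with ensemble medians
#'
#' Computes fair-proportion ED on each tree of an ensemble, takes the
#' per-species median, and combines it with IUCN categories into EDGE scores.
#'
#' @param ensemble A `phylo`, `multiPhylo`, or list of trees on one tip set.
#' @param iucn Named character vector of IUCN categories (names = species).
#' @return A data.frame with columns `species`, `ED`, `GE`, `EDGE`.
#' @export
species_scores <- function(ensemble, iucn) {
  if (inherits(ensemble, "phylo")) ensemble <- list(ensemble)
  ed <- median_over_ensemble(ensemble, fair_proportion_ed)
  sp <- names(ed)
  missing_iucn <- setdiff(sp, names(iucn))
  if (length(missing_iucn))
    stop("no IUCN category for: ", paste(head(missing_iucn, 5), collapse = ", "))
  cat_ <- iucn[sp]
  data.frame(species = sp, ED = unname(ed), GE = ge_weight(cat_),
             EDGE = edge_score(unname(ed), cat_),
             row.names = NULL, stringsAsFactors = FALSE)
}
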