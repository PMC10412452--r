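# Shared fixtures, built once per test run.

# three-tip hand tree: ((A:1,B:1):1,C:2);
hand_tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")

# small synthetic world reused across modules
small_world <- simulate_world(world_config(n_species = 60, grid_rows = 8,
                                           grid_cols = 8, n_realms = 4,
                                           seed = 101))

# brute-force Faith's PD: union of root-to-tip edge paths
brute_pd <- function(tree, species) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2]] <- tree$edge[k, 1]
    edge_of[tree$edge[k, 2]] <- k
  }
  root <- ntip + 1
  edges <- integer(0)
  for (s in species) {
    node <- match(s, tree$tip.label)
    while (node != root) {
      edges <- c(edges, edge_of[node])
      node <- parent[node]
    }
  }
  sum(tree$edge.length[unique(edges)])
}

# edge-credit oracle for fair-proportion ED: loop over every edge crediting
# length / n_descendant_tips to each descendant tip
brute_ed <- function(tree) {
  ntip <- length(tree$tip.label)
  ed <- setNames(numeric(ntip), tree$tip.label)
  for (k in seq_len(nrow(tree$edge))) {
    tips <- ape::extract.clade
    node <- tree$edge[k, 2]
    desc <- if (node <= ntip) tree$tip.label[node] else
      ape::extract.clade(tree, node)$tip.label
    ed[desc] <- ed[desc] + tree$edge.length[k] / length(desc)
  }
  ed
}

# complete trait table of the small world (ground truth, no masking)
small_traits <- small_world$traits_true

# internal-function shims used by oracles
simulate_bm_for_test <- function(tree) tradediv:::simulate_bm(tree, 0, 1)
gls_profile_for_test <- function(C, y) tradediv:::gls_profile(C, y)
bm_impute_single <- function(tree, traits) bm_impute(tree, traits)
.hull_volume3d_test <- function(m) tradediv:::.hull_volume3d(m)
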