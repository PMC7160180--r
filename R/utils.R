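# Internal helpers shared across modules.

# Node depths measured from the root (Myr since root) and node ages
# (Myr before present, assuming tips at age 0 for ultrametric trees).
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

# Descendant tip indices for every node (tips included), as a list
# indexed by node number.
descendant_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  out <- vector("list", n_node)
  for (i in seq_len(n_tip)) out[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

# Children of each node as a list indexed by node number.
node_children <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  out <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    out[[tree$edge[k, 1]]] <- c(out[[tree$edge[k, 1]]], tree$edge[k, 2])
  }
  out
}

root_node <- function(tree) {
  ape::Ntip(tree) + 1L
}

# Sister node of `node` (NA for the root or under a basal polytomy where
# "the" sister is undefined).
sister_node <- function(tree, node) {
  parent <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(parent) == 0) return(NA_integer_)
  sibs <- tree$edge[tree$edge[, 1] == parent, 2]
  sibs <- sibs[sibs != node]
  if (length(sibs) != 1) return(NA_integer_)
  sibs
}

is_ultrametric_tree <- function(tree, tol = 1e-6) {
  isTRUE(ape::is.ultrametric(tree, option = 2, tol = tol))
}

assert_ultrametric <- function(tree, what = "this computation") {
  if (!is_ultrametric_tree(tree)) {
    abort(paste0("Tree must be ultrametric (within 1e-6 relative tolerance) for ",
                 what, "."))
  }
  invisible(tree)
}

# Collapse a character vector of host labels into a canonical state label.
host_set_label <- function(hosts) {
  paste(sort(hosts), collapse = "+")
}

# Seed handling: every stochastic entry point routes through this so a
# single integer makes the whole call reproducible without touching the
# caller's RNG state.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}
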