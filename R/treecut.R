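#' Drop rarely used hosts from a host table
#'
#' Removes every host used by fewer than `min_users` taxa from all host
#' sets. Taxa left with an empty repertoire are reported (they must be
#' excluded from reconstruction, since DEC* has no null state).
#'
#' @param hosts Named list mapping taxon to host vectors.
#' @param min_users Minimum number of using taxa for a host to be retained
#'   (1 = keep everything).
#' @return A list with `hosts` (reduced mapping, emptied taxa removed),
#'   `dropped_hosts`, and `emptied_taxa` (taxa whose whole repertoire was
#'   removed).
#' @export
filter_hosts <- function(hosts, min_users = 2L) {
  if (min_users < 1) abort("`min_users` must be >= 1.")
  long <- host_table_to_long(hosts)
  users <- table(long$host)
  dropped <- sort(names(users)[users < min_users])
  reduced <- lapply(hosts, function(h) setdiff(h, dropped))
  emptied <- sort(names(reduced)[lengths(reduced) == 0 & lengths(hosts) > 0])
  reduced <- reduced[lengths(reduced) > 0]
  list(hosts = reduced, dropped_hosts = dropped, emptied_taxa = emptied)
}

#' Drop taxa whose host breadth exceeds a cap
#'
#' Over-breadth taxa are removed outright, never truncated: silently
#' trimming a polyphage's repertoire would fabricate data.
#'
#' @param hosts Named list mapping taxon to host vectors.
#' @param max_breadth Breadth cap B.
#' @param truncate If `TRUE`, instead of dropping a taxon its repertoire is
#'   truncated to its `max_breadth` most commonly used hosts (ties broken
#'   alphabetically). Off by default.
#' @return A list with `hosts` and `dropped_taxa` (empty when
#'   `truncate = TRUE`).
#' @export
apply_breadth_cap <- function(hosts, max_breadth, truncate = FALSE) {
  if (max_breadth < 1) abort("`max_breadth` must be >= 1.")
  over <- names(hosts)[lengths(hosts) > max_breadth]
  if (!truncate) {
    return(list(hosts = hosts[setdiff(names(hosts), over)],
                dropped_taxa = sort(over)))
  }
  long <- host_table_to_long(hosts)
  usage <- sort(table(long$host), decreasing = TRUE)
  rank <- seq_along(usage)
  names(rank) <- names(usage)
  out <- hosts
  for (t in over) {
    h <- out[[t]]
    out[[t]] <- sort(h[order(rank[h])][seq_len(max_breadth)])
  }
  list(hosts = out, dropped_taxa = character(0), truncated_taxa = sort(over))
}

#' Decompose a phylogeny into the most inclusive analyzable clades
#'
#' Cuts a tree into the most inclusive set of nonoverlapping clades such
#' that each clade (i) contains at least `min_tips` tips with host data and
#' (ii) implies a DEC* state space below `max_states` states, where the
#' state space is built from the hosts used by the clade's own tips under
#' breadth cap `max_breadth`. The search is a pre-order traversal from the
#' root that accepts the first (shallowest) qualifying clade on each path
#' and otherwise recurses into the children, which realizes "most inclusive
#' and nonoverlapping" deterministically: no accepted clade's ancestor can
#' qualify, or it would have been accepted first.
#'
#' @param tree An [ape::phylo] object.
#' @param hosts Named list mapping taxon to host vectors (already filtered,
#'   e.g. by [filter_hosts()] and [apply_breadth_cap()]).
#' @param min_tips Minimum number of host-covered tips per clade.
#' @param max_states State-count cap (clades qualify strictly below it).
#' @param max_breadth Breadth cap used in the state count.
#' @return An object of class `hostshift_decomposition`: list with
#'   `subtrees` (list of phylo objects), `manifest` (tibble: subtree id,
#'   root node in the input tree, n tips with data, n hosts, state count)
#'   and `excluded_tips` (tips outside every selected clade).
#' @export
decompose_tree <- function(tree, hosts, min_tips = 10L, max_states = 1600L,
                           max_breadth = 5L) {
  if (min_tips < 2) abort("`min_tips` must be >= 2.")
  if (max_states < 2) abort("`max_states` must be >= 2.")
  desc <- descendant_tips(tree)
  kids <- node_children(tree)
  covered <- intersect(tree$tip.label, names(hosts))

  clade_stats <- function(node) {
    tips <- tree$tip.label[desc[[node]]]
    tips <- intersect(tips, covered)
    hs <- sort(unique(unlist(hosts[tips], use.names = FALSE)))
    list(n_tips = length(tips),
         n_hosts = length(hs),
         states = if (length(hs) > 0) state_count(length(hs), max_breadth) else 0)
  }

  accepted <- integer(0)
  stack <- root_node(tree)
  while (length(stack) > 0) {
    node <- stack[1]
    stack <- stack[-1]
    if (node <= ape::Ntip(tree)) next
    st <- clade_stats(node)
    if (st$n_tips >= min_tips && st$states > 0 && st$states < max_states) {
      accepted <- c(accepted, node)
    } else {
      stack <- c(kids[[node]], stack)
    }
  }

  subtrees <- lapply(accepted, function(node) ape::extract.clade(tree, node))
  stats <- lapply(accepted, clade_stats)
  manifest <- tibble::tibble(
    subtree = seq_along(accepted),
    root = accepted,
    n_tips = vapply(stats, `[[`, integer(1), "n_tips"),
    n_hosts = vapply(stats, `[[`, integer(1), "n_hosts"),
    n_states = vapply(stats, function(s) as.integer(s$states), integer(1))
  )
  in_clades <- unlist(lapply(accepted, function(n) tree$tip.label[desc[[n]]]))
  excluded <- sort(setdiff(covered, in_clades))
  structure(list(subtrees = subtrees, manifest = manifest,
                 excluded_tips = excluded,
                 config = list(min_tips = min_tips, max_states = max_states,
                               max_breadth = max_breadth)),
            class = "hostshift_decomposition")
}

#' @export
print.hostshift_decomposition <- function(x, ...) {
  cat("Tree decomposition:", length(x$subtrees), "subtrees,",
      length(x$excluded_tips), "covered tips excluded\n")
  print(x$manifest)
  invisible(x)
}

#' Write a decomposition to disk
#'
#' One Newick file per subtree plus a TSV manifest.
#'
#' @param decomp A `hostshift_decomposition`.
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(decomp$subtrees)) {
    write_tree(decomp$subtrees[[i]],
               file.path(dir, sprintf("subtree_%02d.nwk", i)))
  }
  manifest <- decomp$manifest
  manifest$excluded_tips <- paste(decomp$excluded_tips, collapse = ",")
  path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}
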