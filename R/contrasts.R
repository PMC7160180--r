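# Sister-clade contrasts: the three response variables of the
# diversification models. All contrasts are signed focal minus sister, so
# exchanging focal and sister negates the value; a negative model
# coefficient for a class of events therefore reads "clades with that
# event have fewer species / shorter values than their sisters".

#' Map a node of a pruned tree onto the complete tree
#'
#' Returns the MRCA, in the full tree, of the descendant tip set of a node
#' in a pruned tree (tips of the pruned tree must be a subset of the full
#' tree's tips). When the full-tree MRCA subtends extra tips absent from the
#' pruned clade, the mapping still returns the MRCA but flags the absorbed
#' tips, since contrast sums on the complete tree will include them.
#'
#' @param pruned_tree,full_tree [ape::phylo] objects.
#' @param node Node number in `pruned_tree`.
#' @return A list with `node` (number in `full_tree`) and `absorbed`
#'   (character vector of extra tips, possibly empty).
#' @export
map_clade_node <- function(pruned_tree, full_tree, node) {
  if (!all(pruned_tree$tip.label %in% full_tree$tip.label)) {
    abort("Pruned tree tips must be a subset of the full tree tips.")
  }
  desc <- descendant_tips(pruned_tree)
  tips <- pruned_tree$tip.label[desc[[node]]]
  fn <- if (length(tips) == 1) {
    match(tips, full_tree$tip.label)
  } else {
    ape::getMRCA(full_tree, tips)
  }
  full_tips <- full_tree$tip.label[descendant_tips(full_tree)[[fn]]]
  list(node = fn, absorbed = sort(setdiff(full_tips, tips)))
}

#' Speciation waiting-time contrast at a node
#'
#' The focal value is the mean of the branch lengths leading to the node's
#' two immediate descendants (the average waiting time to the next
#' speciation); the contrast is focal minus the same quantity at the sister
#' node. Undefined (NA) when either the node or its sister is a tip, or
#' when the sister is ambiguous under a polytomy; such cases are skipped by
#' [sister_contrasts()].
#'
#' @param tree An [ape::phylo] object.
#' @param node Internal node number.
#' @return A one-row tibble (`node`, `sister`, `value`) or `NULL`.
#' @export
waiting_time_contrast <- function(tree, node) {
  sis <- sister_node(tree, node)
  n_tip <- ape::Ntip(tree)
  if (is.na(sis) || node <= n_tip || sis <= n_tip) return(NULL)
  mean_child_branch <- function(v) {
    mean(tree$edge.length[tree$edge[, 1] == v])
  }
  tibble::tibble(node = node, sister = sis,
                 value = mean_child_branch(node) - mean_child_branch(sis))
}

# Summed richness of a set of tip labels (tips missing from the richness
# table raise an error; richness NULL means one species per tip).
sum_richness <- function(tips, richness) {
  if (length(tips) == 0) return(0)
  if (is.null(richness)) return(length(tips))
  miss <- setdiff(tips, names(richness))
  if (length(miss) > 0) {
    abort(paste0("Tips without richness entries: ", paste(miss, collapse = ", ")))
  }
  sum(richness[tips])
}

#' Diversity contrast spanning a node of the complete tree
#'
#' Inclusive contrasts compare total extant species richness of the focal
#' clade against its sister clade, regardless of current host use.
#' Exclusive contrasts restrict the counts by current host use: after a
#' gain of host set H, the focal side counts species in tips that still use
#' any host of H while the sister side counts species in tips that do not;
#' after a loss the focal side counts tips that do not use the lost hosts
#' and the sister side tips that do. For `none` (and `complex`) events both
#' sides count all descendants.
#'
#' @param full_tree The complete tree (richness is summed on it).
#' @param node,sister Node numbers in `full_tree`.
#' @param type `"inclusive"` or `"exclusive"`.
#' @param event_class,event_hosts Event class at the node and the gained
#'   (for `gain`) or lost (for `loss`) host labels; only used for exclusive
#'   contrasts.
#' @param hosts Current host table (named list); only used for exclusive
#'   contrasts — host membership is assessed from extant usage, not from
#'   reconstructed states.
#' @param richness Named vector of per-tip species counts (NULL = 1 each).
#' @return The signed contrast (focal minus sister).
#' @export
diversity_contrast <- function(full_tree, node, sister,
                               type = c("inclusive", "exclusive"),
                               event_class = "none", event_hosts = character(0),
                               hosts = NULL, richness = NULL) {
  type <- match.arg(type)
  desc <- descendant_tips(full_tree)
  focal_tips <- full_tree$tip.label[desc[[node]]]
  sister_tips <- full_tree$tip.label[desc[[sister]]]
  if (type == "inclusive" || !(event_class %in% c("gain", "loss"))) {
    return(sum_richness(focal_tips, richness) - sum_richness(sister_tips, richness))
  }
  if (is.null(hosts)) abort("Exclusive contrasts need the current host table.")
  uses <- function(tip) {
    length(intersect(hosts[[tip]] %||% character(0), event_hosts)) > 0
  }
  focal_use <- vapply(focal_tips, uses, logical(1))
  sister_use <- vapply(sister_tips, uses, logical(1))
  if (event_class == "gain") {
    sum_richness(focal_tips[focal_use], richness) -
      sum_richness(sister_tips[!sister_use], richness)
  } else {
    sum_richness(focal_tips[!focal_use], richness) -
      sum_richness(sister_tips[sister_use], richness)
  }
}

#' Sister-clade contrasts for every classified event
#'
#' Assembles the response table of the diversification models: for each
#' internal-node event (on the reconstruction tree), the waiting-time,
#' exclusive-diversity and inclusive-diversity contrasts against the
#' node's sister clade, computed on the complete tree (nodes are mapped
#' with [map_clade_node()] so that taxa pruned before reconstruction still
#' contribute their species counts). The event's confidence weight is
#' attached to every contrast row.
#'
#' @param events A `hostshift_events` tibble from [classify_events()].
#' @param tree The (possibly pruned) tree the events were classified on.
#' @param full_tree The complete tree; defaults to `tree`.
#' @param hosts Current host table (named list) for exclusive contrasts.
#' @param richness Named per-tip species counts (NULL = 1 per tip).
#' @param responses Which contrasts to compute.
#' @return A tibble with columns `node`, `sister` (numbers in `tree`),
#'   `full_node`, `full_sister` (numbers in `full_tree`), `class`,
#'   `response`, `value`, `weight`. Waiting-time rows are dropped (with a
#'   message) where the node or sister is a tip.
#' @export
sister_contrasts <- function(events, tree, full_tree = tree, hosts = NULL,
                             richness = NULL,
                             responses = c("waiting_time", "exclusive", "inclusive")) {
  responses <- match.arg(responses, several.ok = TRUE)
  same_tree <- identical(tree$tip.label, full_tree$tip.label)
  rows <- list()
  skipped_wt <- 0L
  for (i in seq_len(nrow(events))) {
    v <- events$node[i]
    sis <- sister_node(tree, v)
    if (is.na(sis)) next
    if (same_tree) {
      fv <- v; fs <- sis
    } else {
      fv <- map_clade_node(tree, full_tree, v)$node
      fs <- map_clade_node(tree, full_tree, sis)$node
    }
    cls <- events$class[i]
    ev_hosts <- split_hosts(if (cls == "loss") events$lost[i] else events$gained[i])
    if ("waiting_time" %in% responses) {
      wt <- waiting_time_contrast(tree, v)
      if (is.null(wt)) {
        skipped_wt <- skipped_wt + 1L
      } else {
        rows[[length(rows) + 1]] <- tibble::tibble(
          node = v, sister = sis, full_node = fv, full_sister = fs,
          class = cls, response = "waiting_time", value = wt$value,
          weight = events$weight[i])
      }
    }
    for (type in intersect(responses, c("exclusive", "inclusive"))) {
      val <- diversity_contrast(full_tree, fv, fs, type = type,
                                event_class = cls, event_hosts = ev_hosts,
                                hosts = hosts, richness = richness)
      rows[[length(rows) + 1]] <- tibble::tibble(
        node = v, sister = sis, full_node = fv, full_sister = fs,
        class = cls, response = type, value = val,
        weight = events$weight[i])
    }
  }
  if (skipped_wt > 0) {
    inform(paste0(skipped_wt,
                  " waiting-time contrasts skipped (node or sister is a tip)."))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(node = integer(0), sister = integer(0),
                          full_node = integer(0), full_sister = integer(0),
                          class = character(0), response = character(0),
                          value = numeric(0), weight = numeric(0))
  }
  class(out) <- c("hostshift_contrasts", class(out))
  out
}
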