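#' Classify host-use change events at internal nodes
#'
#' Compares the MAP (highest proportional likelihood) host repertoire of
#' every non-root internal node with that of its immediate ancestor. Hosts
#' present at the node but not the ancestor were gained; hosts present at
#' the ancestor but not the node were lost. Nodes where both sets are
#' nonempty are labelled `complex` (a simultaneous gain and loss): they do
#' not fit a three-level gain/loss/none factor and are excluded from the
#' factor-based models, but their gains still count toward host volatility.
#'
#' Each event carries a confidence weight: by default the product of the
#' MAP proportional likelihoods at the node and at its parent (both states
#' define the event); `weight = "node"` uses the node's MAP probability
#' alone.
#'
#' @param recon A `dec_recon` from [dec_ancestral_states()].
#' @param tree The tree the reconstruction was computed on.
#' @param weight `"product"` (default) or `"node"`.
#' @return A tibble of class `hostshift_events` with columns `node`,
#'   `class` (`gain`/`loss`/`none`/`complex`), `gained`, `lost`
#'   (`+`-joined host labels, `""` when empty), and `weight`.
#' @export
classify_events <- function(recon, tree, weight = c("product", "node")) {
  weight <- match.arg(weight)
  map <- recon$map
  if (nrow(map) != tree$Nnode) {
    abort("Reconstruction does not cover all internal nodes of the tree.")
  }
  map_state <- setNames(map$state, map$node)
  map_prob <- setNames(map$prob, map$node)
  root <- root_node(tree)
  internal <- setdiff(map$node, root)
  parent_of <- setNames(tree$edge[, 1], tree$edge[, 2])

  rows <- lapply(internal, function(v) {
    p <- parent_of[[as.character(v)]]
    sv <- strsplit(map_state[[as.character(v)]], "+", fixed = TRUE)[[1]]
    sp <- strsplit(map_state[[as.character(p)]], "+", fixed = TRUE)[[1]]
    gained <- setdiff(sv, sp)
    lost <- setdiff(sp, sv)
    cls <- if (length(gained) > 0 && length(lost) > 0) "complex"
      else if (length(gained) > 0) "gain"
      else if (length(lost) > 0) "loss"
      else "none"
    w <- if (weight == "product") {
      map_prob[[as.character(v)]] * map_prob[[as.character(p)]]
    } else {
      map_prob[[as.character(v)]]
    }
    tibble::tibble(node = v, class = cls,
                   gained = host_set_label(gained),
                   lost = host_set_label(lost),
                   weight = w)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hostshift_events", class(out))
  out
}

# Split a "+"-joined host label back into a character vector.
split_hosts <- function(label) {
  if (is.na(label) || label == "") return(character(0))
  strsplit(label, "+", fixed = TRUE)[[1]]
}
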