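#' Enumerate a bounded-breadth host state space
#'
#' The state space of a DEC* model over host repertoires: every nonempty
#' subset of the host list with size at most `max_breadth`. The empty
#' repertoire is excluded entirely (all ancestors must have a host), which
#' is what distinguishes DEC* from plain DEC. States are deterministically
#' ordered by subset size, then lexicographically by host index, so state
#' indices are stable under serialization.
#'
#' @param hosts Character vector of host-taxon labels (order fixed).
#' @param max_breadth Maximum repertoire size B (>= 1). Capping B is what
#'   keeps rate matrices tractable: with 12 hosts and B = 5 the space has
#'   1,585 states rather than 4,095.
#' @return An object of class `host_state_space`: a list with `hosts`,
#'   `max_breadth`, `states` (list of integer index vectors), `masks`
#'   (bitmask encoding, usable for |hosts| <= 30), `labels`
#'   (canonical `"a+b"` labels) and `n_states`.
#' @examples
#' sp <- host_state_space(c("Fabaceae", "Rosaceae", "Solanaceae"), 2)
#' sp$n_states # 6
#' @export
host_state_space <- function(hosts, max_breadth) {
  hosts <- as.character(hosts)
  if (length(hosts) < 1) abort("Need at least one host.")
  if (anyDuplicated(hosts)) abort("Host labels must be unique.")
  max_breadth <- as.integer(max_breadth)
  if (max_breadth < 1) abort("`max_breadth` must be >= 1.")
  n <- length(hosts)
  if (n > 30) abort("State spaces over more than 30 hosts are not supported.")
  b <- min(max_breadth, n)
  states <- list()
  for (k in seq_len(b)) {
    cmb <- combn(n, k)
    # combn returns columns in lexicographic order already
    states <- c(states, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  masks <- vapply(states, function(s) sum(bitwShiftL(1L, s - 1L)), integer(1))
  labels <- vapply(states, function(s) paste(hosts[s], collapse = "+"),
                   character(1))
  structure(
    list(hosts = hosts, max_breadth = max_breadth, states = states,
         masks = masks, labels = labels, n_states = length(states)),
    class = "host_state_space"
  )
}

#' @export
print.host_state_space <- function(x, ...) {
  cat("Host state space: ", length(x$hosts), " hosts, breadth cap ",
      x$max_breadth, ", ", x$n_states, " states\n", sep = "")
  invisible(x)
}

#' Number of states implied by a host count and breadth cap
#'
#' \eqn{\sum_{k=1}^{B} \binom{n}{k}} without enumerating; used by the tree
#' decomposition to screen clades against a state-count cap.
#'
#' @param n_hosts Number of hosts.
#' @param max_breadth Breadth cap B.
#' @return Integer state count.
#' @export
state_count <- function(n_hosts, max_breadth) {
  b <- min(max_breadth, n_hosts)
  sum(choose(n_hosts, seq_len(b)))
}

# Index of the state matching a host subset (character vector); NA if the
# subset is not representable (over-breadth, unknown host, or empty).
state_index <- function(space, host_set) {
  idx <- match(host_set, space$hosts)
  if (anyNA(idx) || length(idx) == 0 || length(idx) > space$max_breadth) {
    return(NA_integer_)
  }
  match(sum(bitwShiftL(1L, sort(idx) - 1L)), space$masks)
}

# Look up indices for a named list of tip host sets; errors informatively
# when a tip's repertoire is not representable in the space.
tip_state_indices <- function(space, tip_states, tips) {
  miss <- setdiff(tips, names(tip_states))
  if (length(miss) > 0) {
    abort(paste0("No host data for tips: ", paste(miss, collapse = ", ")))
  }
  idx <- vapply(tips, function(t) state_index(space, tip_states[[t]]),
                integer(1))
  bad <- tips[is.na(idx)]
  if (length(bad) > 0) {
    abort(paste0("Tip host sets not representable in the state space ",
                 "(unknown host, empty set, or breadth over the cap): ",
                 paste(bad, collapse = ", ")))
  }
  idx
}
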