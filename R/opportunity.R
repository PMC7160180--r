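# Ecological-opportunity indices attached to host-gain events. All four
# are simple functions of the host metadata table, the event table and
# node ages; they are computed per gain event, so a host gained k times
# contributes k design rows sharing its host-level values.

#' Stem age of a host taxon
#'
#' @param host Host label.
#' @param meta Host metadata tibble (`host`, `stem_age`, `diversity`).
#' @return Stem age in Myr.
#' @export
host_age <- function(host, meta) {
  i <- match(host, meta$host)
  if (is.na(i)) abort(paste0("No metadata for host: ", host))
  meta$stem_age[i]
}

#' Early-adoption index of a gain event
#'
#' Stem age of the gained host minus the age of the node at which the gain
#' is reconstructed (T_O - T_C): how early in the host lineage's
#' independent history the insect lineage colonized it. Negative values
#' (reconstruction places the colonization before the host's stem age —
#' possible when host ages and the insect tree come from different
#' calibrations) are retained but flagged with a warning.
#'
#' @param host Gained host label.
#' @param node_age Age (Myr before present) of the gain node.
#' @param meta Host metadata tibble.
#' @return Early-adoption index in Myr.
#' @export
early_adoption <- function(host, node_age, meta) {
  ea <- host_age(host, meta) - node_age
  if (ea < 0) {
    warn(paste0("Gain of ", host, " reconstructed before its stem age (",
                "early adoption ", signif(ea, 4), " Myr)."))
  }
  ea
}

#' Volatility of a host taxon
#'
#' Number of reconstructed gains of the host across the analysis (gains at
#' `complex` nodes included) divided by the host's stem age.
#'
#' @param host Host label.
#' @param events Event tibble(s) from [classify_events()]; a list of
#'   tibbles (one per subtree) is accepted and concatenated.
#' @param meta Host metadata tibble.
#' @return Gains per Myr (0 when the host was never gained).
#' @export
host_volatility <- function(host, events, meta) {
  if (is.data.frame(events)) events <- list(events)
  all_ev <- dplyr::bind_rows(events)
  gains <- sum(vapply(all_ev$gained[all_ev$class %in% c("gain", "complex")],
                      function(g) host %in% split_hosts(g), logical(1)))
  gains / host_age(host, meta)
}

#' Opportunity indices for every host-gain event
#'
#' One row per (gain event x gained host): host age, early adoption, host
#' diversity and volatility. Events whose host lacks metadata are dropped
#' and reported via a message.
#'
#' @param events Event tibble from [classify_events()] (gains at `complex`
#'   nodes contribute to volatility counts but only `gain`-class nodes get
#'   design rows).
#' @param tree Tree the events were classified on (for node ages).
#' @param meta Host metadata tibble.
#' @param all_events Optional list of event tibbles across all subtrees for
#'   the volatility count; defaults to `events`.
#' @return A tibble with columns `node`, `host`, `host_age`,
#'   `early_adoption`, `host_diversity`, `volatility`, `weight`.
#' @export
opportunity_indices <- function(events, tree, meta, all_events = events) {
  ages <- node_ages(tree)
  gains <- events[events$class == "gain", ]
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(gains))) {
    for (h in split_hosts(gains$gained[i])) {
      if (!h %in% meta$host) {
        dropped <- dropped + 1L
        next
      }
      node_age_i <- ages[gains$node[i]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        node = gains$node[i],
        host = h,
        host_age = host_age(h, meta),
        early_adoption = suppressWarnings(early_adoption(h, node_age_i, meta)),
        host_diversity = meta$diversity[match(h, meta$host)],
        volatility = host_volatility(h, all_events, meta),
        weight = gains$weight[i]
      )
    }
  }
  if (dropped > 0) {
    inform(paste0(dropped, " gain rows dropped: host missing from metadata."))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(node = integer(0), host = character(0),
                          host_age = numeric(0), early_adoption = numeric(0),
                          host_diversity = numeric(0), volatility = numeric(0),
                          weight = numeric(0))
  }
  out
}

#' Join opportunity indices to gain-event contrasts
#'
#' Builds the design table for the ecological-opportunity models: response
#' contrast value, the four indices, and the event weight, one row per
#' (gain event x gained host x response). Rows with any missing index are
#' dropped and counted in a message.
#'
#' @param contrasts A `hostshift_contrasts` tibble.
#' @param indices Output of [opportunity_indices()].
#' @return A tibble ready for [wls_origin()].
#' @export
assemble_design <- function(contrasts, indices) {
  gains <- contrasts[contrasts$class == "gain", ]
  out <- dplyr::inner_join(gains, indices,
                           by = "node", suffix = c("", ".idx"),
                           relationship = "many-to-many")
  out <- dplyr::select(out, "node", "host", "response", "value",
                       "host_age", "early_adoption", "host_diversity",
                       "volatility", "weight")
  complete <- stats::complete.cases(out[, c("host_age", "early_adoption",
                                            "host_diversity", "volatility")])
  if (any(!complete)) {
    inform(paste0(sum(!complete), " design rows dropped for missing indices."))
  }
  out[complete, ]
}
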