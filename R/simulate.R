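# Synthetic-data generator. Emulates the four empirical inputs the
# analysis consumes — an ultrametric time tree, tip host repertoires, per-
# tip species richness, and host metadata — together with the full ground
# truth (ancestral repertoires and true gain/loss nodes), so that every
# stage of the pipeline can be tested and calibrated without external
# data.

#' Simulate a constant-rate birth-death tree
#'
#' Extant-only ultrametric tree conditioned on the number of tips
#' (delegates to [ape::rphylo()]). Also serves as the null simulator of the
#' MCCR test.
#'
#' @param n_tips Number of extant tips.
#' @param birth,death Speciation and extinction rates per Myr
#'   (`birth > death >= 0`).
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] object.
#' @export
sim_bd_tree <- function(n_tips, birth = 0.1, death = 0, seed = NULL) {
  if (birth <= death || death < 0) abort("Need birth > death >= 0.")
  if (n_tips < 2) abort("Need at least 2 tips.")
  with_seed_if(seed, ape::rphylo(n_tips, birth = birth, death = death,
                                 fossils = FALSE))
}

# One anagenetic trajectory along a branch: event-driven simulation of the
# DEC* gain/loss process starting from state index `s0` for duration `t`.
sim_branch_states <- function(space, d, e, scale_gain, s0, t) {
  s <- s0
  nh <- length(space$hosts)
  remaining <- t
  repeat {
    A <- space$states[[s]]
    k <- length(A)
    gain_rate <- if (scale_gain) k * d else d
    gain_targets <- if (k < space$max_breadth) setdiff(seq_len(nh), A) else integer(0)
    loss_targets <- if (k >= 2) A else integer(0)
    total <- gain_rate * length(gain_targets) + e * length(loss_targets)
    if (total <= 0) return(s)
    wait <- rexp(1, total)
    if (wait > remaining) return(s)
    remaining <- remaining - wait
    rates <- c(rep(gain_rate, length(gain_targets)), rep(e, length(loss_targets)))
    pick <- sample.int(length(rates), 1, prob = rates)
    if (pick <= length(gain_targets)) {
      h <- gain_targets[pick]
      s <- match(space$masks[s] + bitwShiftL(1L, h - 1L), space$masks)
    } else {
      h <- loss_targets[pick - length(gain_targets)]
      s <- match(space$masks[s] - bitwShiftL(1L, h - 1L), space$masks)
    }
  }
}

#' Simulate a host-repertoire history on a tree
#'
#' Forward simulation of the DEC* process: the root repertoire is drawn
#' from the root prior; at every speciation event the two daughter
#' repertoires are drawn from the cladogenetic outcome distribution
#' ([clado_pairs()]); along every branch gains and losses follow the
#' anagenetic generator ([dec_generator()]) event-by-event. This is the
#' exact generative counterpart of the likelihood, which is what makes the
#' generator-versus-likelihood consistency test possible.
#'
#' @param tree An [ape::phylo] object with branch lengths.
#' @param space A [host_state_space()].
#' @param d,e,scale_gain DEC* rate parameters (see [dec_generator()]).
#' @param root_prior `"uniform"` (over all non-null states) or
#'   `"stationary"`.
#' @param seed Integer seed.
#' @return A list with `tip_states` (named list of host vectors), `truth`:
#'   a tibble (`node`, `state`, `state_idx`) of true pre-speciation states
#'   for every node (tips included), and `events`: the true gain/loss
#'   classification of internal non-root nodes (same columns as
#'   [classify_events()], all weights 1).
#' @export
sim_host_history <- function(tree, space, d, e, scale_gain = TRUE,
                             root_prior = "uniform", seed = NULL) {
  if (any(tree$edge.length < 0)) abort("Tree has negative branch lengths.")
  with_seed_if(seed, {
    n_tip <- ape::Ntip(tree)
    n_node <- n_tip + tree$Nnode
    state <- integer(n_node)
    Q <- dec_generator(space, d, e, scale_gain = scale_gain)
    prior <- root_prior_vec(space, root_prior, Q = Q)
    root <- root_node(tree)
    state[root] <- sample.int(space$n_states, 1, prob = prior)
    po <- ape::reorder.phylo(tree, "postorder")
    node_order <- rev(unique(po$edge[, 1])) # preorder over internal nodes
    for (p in node_order) {
      ke <- which(tree$edge[, 1] == p)
      # cladogenetic inheritance (polytomies: successive splits, left
      # daughter of each pseudo-split carries on)
      current <- state[p]
      daughters <- integer(length(ke))
      if (length(ke) == 1) {
        daughters <- current
      } else {
        for (j in seq_len(length(ke) - 1)) {
          cp <- clado_pairs(space, current)
          pick <- sample.int(nrow(cp), 1, prob = cp$prob)
          daughters[j] <- cp$right[pick]
          current <- cp$left[pick]
        }
        daughters[length(ke)] <- current
        daughters <- rev(daughters)
      }
      for (j in seq_along(ke)) {
        k <- ke[j]
        state[tree$edge[k, 2]] <- sim_branch_states(
          space, d, e, scale_gain, daughters[j], tree$edge.length[k])
      }
    }
    tip_states <- lapply(seq_len(n_tip),
                         function(i) space$hosts[space$states[[state[i]]]])
    names(tip_states) <- tree$tip.label
    truth <- tibble::tibble(node = seq_len(n_node),
                            state_idx = as.integer(state),
                            state = space$labels[state])
    truth <- truth[, c("node", "state", "state_idx")]
    parent_of <- setNames(tree$edge[, 1], tree$edge[, 2])
    internal <- setdiff((n_tip + 1L):n_node, root)
    ev_rows <- lapply(internal, function(v) {
      sv <- space$states[[state[v]]]
      sp <- space$states[[state[parent_of[[as.character(v)]]]]]
      gained <- space$hosts[setdiff(sv, sp)]
      lost <- space$hosts[setdiff(sp, sv)]
      cls <- if (length(gained) > 0 && length(lost) > 0) "complex"
        else if (length(gained) > 0) "gain"
        else if (length(lost) > 0) "loss"
        else "none"
      tibble::tibble(node = v, class = cls, gained = host_set_label(gained),
                     lost = host_set_label(lost), weight = 1)
    })
    list(tip_states = tip_states, truth = truth,
         events = dplyr::bind_rows(ev_rows))
  })
}

#' Simulate per-tip species richness
#'
#' Each tip is a genus whose species count is drawn from the geometric law
#' implied by a within-genus pure-birth process of fixed crown age `tau`
#' and rate `lambda_g`: `1 + Geometric(p)` with `p = exp(-lambda_g * tau)`,
#' so the mean count is `exp(lambda_g * tau)` and counts are always >= 1.
#' Tips descending from a true host-gain node have `lambda_g` multiplied by
#' `s_gain`, which injects a known diversification effect of host gains
#' (`s_gain = 1` is neutral). `model = "nbinom"` draws instead from a
#' negative binomial with the same mean (size `nb_size`).
#'
#' @param tree An [ape::phylo] object.
#' @param gain_nodes Integer vector of true gain nodes (from
#'   [sim_host_history()]'s `events`, class `gain`); tips descending from
#'   any of them get the boosted rate.
#' @param lambda_g Within-genus speciation rate per Myr.
#' @param tau Within-genus crown age (Myr).
#' @param s_gain Multiplicative effect of a host gain on `lambda_g`.
#' @param model `"geometric"` (default) or `"nbinom"`.
#' @param nb_size Negative-binomial size parameter.
#' @param seed Integer seed.
#' @return Named integer vector of species counts.
#' @export
sim_richness <- function(tree, gain_nodes = integer(0), lambda_g = 0.1,
                         tau = 10, s_gain = 1,
                         model = c("geometric", "nbinom"), nb_size = 2,
                         seed = NULL) {
  model <- match.arg(model)
  if (s_gain <= 0) abort("`s_gain` must be > 0.")
  n_tip <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  boosted <- rep(FALSE, n_tip)
  for (v in gain_nodes) boosted[desc[[v]]] <- TRUE
  lam <- ifelse(boosted, lambda_g * s_gain, lambda_g)
  mean_n <- exp(lam * tau)
  with_seed_if(seed, {
    counts <- if (model == "geometric") {
      1L + rgeom(n_tip, prob = exp(-lam * tau))
    } else {
      pmax(1L, stats::rnbinom(n_tip, size = nb_size, mu = mean_n))
    }
    setNames(as.integer(counts), tree$tip.label)
  })
}

#' Simulate host metadata
#'
#' Stem ages uniform on `age_range` (Myr), diversities log-uniform on
#' `diversity_range`.
#'
#' @param hosts Character vector of host labels.
#' @param age_range,diversity_range Ranges for the draws.
#' @param seed Integer seed.
#' @return A host metadata tibble (`host`, `stem_age`, `diversity`).
#' @export
sim_host_meta <- function(hosts, age_range = c(40, 150),
                          diversity_range = c(50, 20000), seed = NULL) {
  with_seed_if(seed, tibble::tibble(
    host = hosts,
    stem_age = runif(length(hosts), age_range[1], age_range[2]),
    diversity = round(exp(runif(length(hosts), log(diversity_range[1]),
                                log(diversity_range[2]))))
  ))
}

#' Simulate a complete synthetic dataset
#'
#' Bundles the four generators under one configuration and seed. Defaults
#' describe a moderate desk-scale study: a 150-tip pure-birth genus tree,
#' six host taxa under breadth cap 3, gain/loss rates of 0.05 per Myr
#' relative to a tree rescaled to depth 50 Myr, and neutral richness
#' (`s_gain = 1`).
#'
#' @param n_tips,birth,death Tree parameters ([sim_bd_tree()]); the tree is
#'   rescaled to `tree_depth` Myr.
#' @param tree_depth Root age of the (rescaled) tree in Myr.
#' @param hosts Host labels.
#' @param max_breadth Breadth cap B of the simulated state space.
#' @param d,e,scale_gain DEC* rates.
#' @param lambda_g,tau,s_gain Richness model ([sim_richness()]).
#' @param age_range,diversity_range Host metadata ranges.
#' @param seed Master seed; all stages draw from streams derived from it.
#' @return A list with `tree`, `space`, `tip_states`, `truth`, `events`
#'   (true events), `richness`, `host_meta`, and `config`.
#' @export
sim_dataset <- function(n_tips = 150, birth = 0.1, death = 0,
                        tree_depth = 50,
                        hosts = paste0("H", 1:6), max_breadth = 3,
                        d = 0.05, e = 0.05, scale_gain = TRUE,
                        lambda_g = 0.1, tau = 10, s_gain = 1,
                        age_range = c(40, 150),
                        diversity_range = c(50, 20000), seed = 1) {
  seed <- as.integer(seed)
  tree <- sim_bd_tree(n_tips, birth, death, seed = seed)
  depth <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length * tree_depth / depth
  space <- host_state_space(hosts, max_breadth)
  hist <- sim_host_history(tree, space, d, e, scale_gain = scale_gain,
                           seed = seed + 1L)
  gain_nodes <- hist$events$node[hist$events$class == "gain"]
  richness <- sim_richness(tree, gain_nodes, lambda_g, tau, s_gain,
                           seed = seed + 2L)
  meta <- sim_host_meta(hosts, age_range, diversity_range, seed = seed + 3L)
  list(tree = tree, space = space, tip_states = hist$tip_states,
       truth = hist$truth, events = hist$events, richness = richness,
       host_meta = meta,
       config = list(n_tips = n_tips, birth = birth, death = death,
                     tree_depth = tree_depth, hosts = hosts,
                     max_breadth = max_breadth, d = d, e = e,
                     scale_gain = scale_gain, lambda_g = lambda_g,
                     tau = tau, s_gain = s_gain, age_range = age_range,
                     diversity_range = diversity_range, seed = seed))
}

#' Write a synthetic dataset to disk
#'
#' Emits `tree.nwk`, `hosts.tsv` (long format), `richness.tsv`,
#' `host_meta.tsv`, `truth.json` (true states and events) and
#' `manifest.json` (configuration and seed). Files are schema-identical to
#' empirical inputs and re-readable by the readers in this package;
#' regenerating with the same configuration and seed reproduces them
#' byte-identically.
#'
#' @param dataset Output of [sim_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tree(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(host_table_to_long(dataset$tip_states),
                   file.path(dir, "hosts.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(taxon = names(dataset$richness),
                                  richness = unname(dataset$richness)),
                   file.path(dir, "richness.tsv"), progress = FALSE)
  readr::write_tsv(dataset$host_meta, file.path(dir, "host_meta.tsv"),
                   progress = FALSE)
  jsonlite::write_json(list(truth = dataset$truth, events = dataset$events),
                       file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(dataset$config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
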