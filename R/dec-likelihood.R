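# Pruning machinery for the DEC* likelihood.
#
# Conditional likelihoods are computed tip-to-root ("down pass"): tip
# vectors are state indicators; along each branch a vector is propagated
# through exp(Q t); at each internal node the two daughter branch vectors
# are convolved through the cladogenetic event table. Every vector is
# rescaled to a maximum of one and the log scale factor accumulated, which
# prevents underflow on large trees.

dec_prune <- function(tree, tip_idx, space, d, e, scale_gain = TRUE,
                      root_prior = "uniform", prop = NULL, ct = NULL) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  ns <- space$n_states
  if (is.null(prop)) {
    Q <- dec_generator(space, d, e, scale_gain = scale_gain)
    prop <- make_propagator(Q)
  }
  if (is.null(ct)) ct <- clado_table(space)
  prior <- root_prior_vec(space, root_prior, Q = prop$Q)

  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  elen <- po$edge.length

  D <- matrix(0, ns, n_node)
  logscale <- numeric(n_node)
  for (i in seq_len(n_tip)) D[tip_idx[i], i] <- 1

  A <- matrix(0, ns, nrow(edges)) # per-edge propagated daughter vectors
  # postorder internal-node sequence: parents in edge order, deduplicated
  node_seq <- unique(edges[, 1])
  edge_of_child <- integer(n_node)
  edge_of_child[edges[, 2]] <- seq_len(nrow(edges))

  # tip branches all carry indicator vectors, so their propagation batches
  # into a single matrix product (roughly halves the per-likelihood cost)
  tip_e <- which(edges[, 2] <= n_tip)
  if (prop$diagonalizable && length(tip_e) > 0) {
    W <- prop$Vinv[, tip_idx[edges[tip_e, 2]], drop = FALSE] *
      exp(outer(prop$lambda, elen[tip_e]))
    At <- Re(prop$V %*% W)
    At[At < 0] <- 0
    A[, tip_e] <- At
  } else {
    for (k in tip_e) A[, k] <- propagate(prop, elen[k], D[, edges[k, 2]])
  }

  for (p in node_seq) {
    ke <- which(edges[, 1] == p)
    Acc <- NULL
    acc_scale <- 0
    for (k in ke) {
      ch <- edges[k, 2]
      if (ch > n_tip) A[, k] <- propagate(prop, elen[k], D[, ch])
      if (is.null(Acc)) {
        Acc <- A[, k]
        acc_scale <- logscale[ch]
      } else {
        # cladogenetic convolution of the accumulated daughter with the next
        # (polytomies resolve as successive zero-length bifurcations)
        contrib <- ct$prob * Acc[ct$left] * A[, k][ct$right]
        Dp <- as.vector(rowsum(contrib, ct$parent, reorder = TRUE))
        Acc <- Dp
        acc_scale <- acc_scale + logscale[ch]
      }
    }
    m <- max(Acc)
    if (!is.finite(m) || m <= 0) {
      return(list(loglik = -Inf, prop = prop, ct = ct))
    }
    D[, p] <- Acc / m
    logscale[p] <- acc_scale + log(m)
  }

  root <- root_node(tree)
  lik_root <- sum(prior * D[, root])
  loglik <- log(lik_root) + logscale[root]
  list(loglik = loglik, D = D, A = A, logscale = logscale, edges = edges,
       elen = elen, prop = prop, ct = ct, prior = prior,
       edge_of_child = edge_of_child)
}

#' DEC* log-likelihood of tip host repertoires on a tree
#'
#' Felsenstein pruning combined with the DEC cladogenetic model: at every
#' internal node the daughter likelihood vectors, each propagated along its
#' branch through the anagenetic process, are convolved over the ordered
#' cladogenetic daughter pairs of [clado_pairs()]; the root vector is
#' averaged over the root prior. Polytomies are tolerated (treated as
#' successive zero-length bifurcations).
#'
#' @param tree An [ape::phylo] object with branch lengths in Myr.
#' @param tip_states Named list mapping every tip label to its observed host
#'   repertoire (character vector). Repertoires must be representable in
#'   `space`; over-breadth tips must be excluded upstream
#'   ([apply_breadth_cap()]), never truncated silently.
#' @param space A [host_state_space()].
#' @param d,e Gain and loss rates (see [dec_generator()]).
#' @param scale_gain,root_prior Passed to [dec_generator()] and the root
#'   prior (`"uniform"` over all non-null states, or `"stationary"`).
#' @return The log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, tip_states, space, d, e, scale_gain = TRUE,
                       root_prior = "uniform") {
  idx <- tip_state_indices(space, tip_states, tree$tip.label)
  res <- dec_prune(tree, idx, space, d, e, scale_gain = scale_gain,
                   root_prior = root_prior)
  if (!is.finite(res$loglik)) abort("Non-finite DEC* likelihood.")
  res$loglik
}

#' Maximum-likelihood estimation of DEC* gain and loss rates
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization on (log d, log e), restarted
#' from `n_starts` log-uniform draws; the best fit across restarts is
#' returned, so the attained log-likelihood is non-decreasing in
#' `n_starts`. Deterministic given `seed`.
#'
#' @inheritParams dec_loglik
#' @param n_starts Number of optimizer restarts (the first start is a fixed
#'   moderate-rate point, the rest are log-uniform draws).
#' @param seed Integer seed controlling the restart draws.
#' @param lower,upper Box bounds on both rates.
#' @return An object of class `dec_fit`: list with `d`, `e`, `loglik`,
#'   `convergence` (0 = converged), `starts` (per-restart results tibble),
#'   plus the call configuration.
#' @export
fit_dec <- function(tree, tip_states, space, n_starts = 5, seed = 1,
                    scale_gain = TRUE, root_prior = "uniform",
                    lower = 1e-9, upper = 10) {
  if (ape::Ntip(tree) < 3) abort("DEC* fitting needs at least 3 tips.")
  idx <- tip_state_indices(space, tip_states, tree$tip.label)
  ct <- clado_table(space)

  nll <- function(par) {
    res <- dec_prune(tree, idx, space, exp(par[1]), exp(par[2]),
                     scale_gain = scale_gain, root_prior = root_prior,
                     ct = ct)
    if (!is.finite(res$loglik)) return(1e10)
    -res$loglik
  }

  # crude initial scale: one expected event per unit of total tree length
  tot <- sum(tree$edge.length)
  base_rate <- max(lower * 10, min(upper / 10, 1 / max(tot / ape::Ntip(tree), 1e-6)))
  starts <- with_seed_if(seed, {
    s1 <- log(c(base_rate, base_rate))
    more <- if (n_starts > 1) {
      matrix(runif(2 * (n_starts - 1), log(1e-4), log(1)), ncol = 2)
    } else NULL
    rbind(s1, more)
  })

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B",
            lower = log(lower), upper = log(upper),
            control = list(factr = 1e8, maxit = 200)),
      error = function(err) NULL
    )
    if (!is.null(fit)) {
      runs[[i]] <- tibble::tibble(
        start_d = exp(starts[i, 1]), start_e = exp(starts[i, 2]),
        d = exp(fit$par[1]), e = exp(fit$par[2]),
        loglik = -fit$value, convergence = fit$convergence
      )
    }
  }
  runs <- dplyr::bind_rows(runs)
  if (nrow(runs) == 0) abort("DEC* optimizer failed to converge in all restarts.")
  best <- runs[which.max(runs$loglik), ]
  structure(
    list(d = best$d, e = best$e, loglik = best$loglik,
         convergence = best$convergence, starts = runs,
         scale_gain = scale_gain, root_prior = root_prior,
         n_starts = n_starts, seed = seed,
         space = list(n_hosts = length(space$hosts),
                      max_breadth = space$max_breadth,
                      n_states = space$n_states)),
    class = "dec_fit"
  )
}

#' @export
print.dec_fit <- function(x, ...) {
  cat("DEC* fit: d =", signif(x$d, 4), " e =", signif(x$e, 4),
      " loglik =", round(x$loglik, 3), "\n")
  invisible(x)
}

#' @method tidy dec_fit
#' @export
tidy.dec_fit <- function(x, ...) {
  tibble::tibble(term = c("d", "e"), estimate = c(x$d, x$e))
}

#' @method glance dec_fit
#' @export
glance.dec_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_states = x$space$n_states,
                 convergence = x$convergence)
}

#' Marginal ancestral host-repertoire probabilities
#'
#' Exact per-node marginal (proportional) likelihoods of each host-repertoire
#' state, combining the tip-to-root conditional likelihoods with a
#' root-to-tip pass that carries the information from the rest of the tree
#' down through the cladogenetic model. Each node's vector sums to one. Node
#' states refer to the repertoire of the lineage immediately before its own
#' speciation event. Requires a fully bifurcating tree (resolve polytomies
#' with [ape::multi2di()] first).
#'
#' @inheritParams dec_loglik
#' @param d,e DEC* rates, typically the MLEs from [fit_dec()].
#' @return An object of class `dec_recon`: list with `node_probs` (matrix,
#'   internal nodes x states, rows summing to 1), `map` (tibble: node,
#'   state label, MAP probability), `loglik`, `params`, and the state
#'   space labels.
#' @export
dec_ancestral_states <- function(tree, tip_states, space, d, e,
                                 scale_gain = TRUE, root_prior = "uniform") {
  if (!ape::is.binary.phylo(tree)) {
    abort("Marginal reconstruction requires a fully bifurcating tree.")
  }
  idx <- tip_state_indices(space, tip_states, tree$tip.label)
  res <- dec_prune(tree, idx, space, d, e, scale_gain = scale_gain,
                   root_prior = root_prior)
  if (!is.finite(res$loglik)) abort("Non-finite DEC* likelihood.")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  ns <- space$n_states
  edges <- res$edges
  ct <- res$ct
  prop <- res$prop

  U <- matrix(0, ns, n_node)
  U[, root_node(tree)] <- res$prior
  # preorder = reverse postorder on parents
  node_seq <- rev(unique(edges[, 1]))
  for (p in node_seq) {
    ke <- which(edges[, 1] == p)
    ch <- edges[ke, 2]
    A1 <- res$A[, ke[1]]
    A2 <- res$A[, ke[2]]
    up <- U[, p]
    # message to each daughter branch top, then down the branch
    for (side in 1:2) {
      sib_A <- if (side == 1) A2 else A1
      own <- if (side == 1) ct$left else ct$right
      oth <- if (side == 1) ct$right else ct$left
      contrib <- ct$prob * up[ct$parent] * sib_A[oth]
      top <- numeric(ns)
      agg <- rowsum(contrib, own, reorder = TRUE)
      top[as.integer(rownames(agg))] <- agg
      ub <- propagate_up(prop, res$elen[ke[side]], top)
      m <- max(ub)
      U[, ch[side]] <- if (m > 0) ub / m else ub
    }
  }

  internal <- (n_tip + 1L):n_node
  probs <- t(vapply(internal, function(v) {
    p <- res$D[, v] * U[, v]
    s <- sum(p)
    if (s <= 0 || !is.finite(s)) abort("Numerical failure in marginal reconstruction.")
    p / s
  }, numeric(ns)))
  rownames(probs) <- internal
  colnames(probs) <- space$labels
  map_idx <- apply(probs, 1, which.max)
  map <- tibble::tibble(
    node = internal,
    state = space$labels[map_idx],
    state_idx = as.integer(map_idx),
    prob = probs[cbind(seq_along(internal), map_idx)]
  )
  structure(
    list(node_probs = probs, map = map, loglik = res$loglik,
         params = list(d = d, e = e), labels = space$labels,
         scale_gain = scale_gain, root_prior = root_prior),
    class = "dec_recon"
  )
}

#' @export
print.dec_recon <- function(x, ...) {
  cat("DEC* ancestral reconstruction:", nrow(x$node_probs),
      "internal nodes,", length(x$labels), "states, loglik",
      round(x$loglik, 3), "\n")
  invisible(x)
}

#' @method tidy dec_recon
#' @export
tidy.dec_recon <- function(x, ...) {
  probs <- x$node_probs
  tibble::tibble(
    node = rep(as.integer(rownames(probs)), times = ncol(probs)),
    state = rep(colnames(probs), each = nrow(probs)),
    prob = as.vector(probs)
  ) |> dplyr::filter(.data$prob > 0) |> dplyr::arrange(.data$node, dplyr::desc(.data$prob))
}

#' Export a reconstruction as TSV tables
#'
#' Writes the full per-node state probabilities and the MAP summary as TSV,
#' and the fitted parameters with the log-likelihood as JSON.
#'
#' @param recon A `dec_recon` object.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_reconstruction <- function(recon, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  probs_path <- file.path(dir, "node_state_probs.tsv")
  map_path <- file.path(dir, "map_states.tsv")
  json_path <- file.path(dir, "dec_params.json")
  readr::write_tsv(tidy(recon), probs_path, progress = FALSE)
  readr::write_tsv(recon$map, map_path, progress = FALSE)
  jsonlite::write_json(list(d = recon$params$d, e = recon$params$e,
                            loglik = recon$loglik,
                            root_prior = recon$root_prior,
                            scale_gain = recon$scale_gain),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(probs_path, map_path, json_path))
}
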