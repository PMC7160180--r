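# Independent oracles used across the suite. Each is a deliberately naive
# implementation (explicit enumeration or closed form) kept structurally
# unrelated to the package's production code paths.

# Brute-force DEC* likelihood and node posteriors by explicit enumeration
# over every assignment of states to internal nodes and every cladogenetic
# pair choice. Exponential in tree size: only for tiny trees.
oracle_dec <- function(tree, tip_idx, space, d, e, scale_gain = TRUE) {
  Q <- dec_generator(space, d, e, scale_gain)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  internal <- (n_tip + 1):n_node
  ns <- space$n_states
  Pmats <- lapply(seq_len(nrow(tree$edge)),
                  function(k) dec_transition_probs(Q, tree$edge.length[k]))
  cps <- lapply(seq_len(ns), function(i) clado_pairs(space, i))
  prior <- rep(1 / ns, ns)

  assign_grid <- expand.grid(rep(list(seq_len(ns)), length(internal)))
  total <- 0
  node_post <- matrix(0, length(internal), ns)
  for (r in seq_len(nrow(assign_grid))) {
    st <- integer(n_node)
    st[internal] <- as.integer(assign_grid[r, ])
    pair_lists <- lapply(internal, function(v) cps[[st[v]]])
    pair_grid <- expand.grid(lapply(pair_lists, function(cp) seq_len(nrow(cp))))
    for (q in seq_len(nrow(pair_grid))) {
      prob <- prior[st[n_tip + 1]]
      for (ii in seq_along(internal)) {
        v <- internal[ii]
        cp <- pair_lists[[ii]][as.integer(pair_grid[q, ii]), ]
        prob <- prob * cp$prob
        kids <- tree$edge[tree$edge[, 1] == v, 2]
        tops <- c(cp$left, cp$right)
        for (j in 1:2) {
          ch <- kids[j]
          eidx <- which(tree$edge[, 2] == ch)
          target <- if (ch <= n_tip) tip_idx[ch] else st[ch]
          prob <- prob * Pmats[[eidx]][tops[j], target]
        }
      }
      total <- total + prob
      for (ii in seq_along(internal)) {
        node_post[ii, st[internal[ii]]] <- node_post[ii, st[internal[ii]]] + prob
      }
    }
  }
  list(loglik = log(total), post = node_post / total, internal = internal)
}

# Gamma statistic from first principles: extract internode intervals by
# sorting node ages, then apply the closed form.
oracle_gamma <- function(tree) {
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  node_times <- sort(depths[(n + 1):(n + tree$Nnode)]) # speciation times
  tip_time <- max(depths[1:n])
  # g_k = interval during which k lineages existed, k = 2..n
  g <- diff(c(node_times, tip_time))
  k <- 2:n
  T_total <- sum(k * g)
  T_i <- cumsum(k * g) # T_i for i = 2..n
  num <- sum(T_i[seq_len(n - 2)]) / (n - 2) - T_total / 2
  num / (T_total * sqrt(1 / (12 * (n - 2))))
}

# Weighted through-origin least squares by direct normal equations.
oracle_wls <- function(X, y, w) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% y)
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  se <- sqrt(diag(solve(XtWX)) * sigma2)
  tstat <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tstat,
       p = 2 * pt(-abs(tstat), df))
}

# Closed-form 2x2 CTMC transition matrix for a generator with
# off-diagonals q12, q21 (analytic solution).
oracle_ctmc2 <- function(q12, q21, t) {
  s <- q12 + q21
  if (s == 0) return(diag(2))
  E <- exp(-s * t)
  rbind(c((q21 + q12 * E) / s, (q12 - q12 * E) / s),
        c((q21 - q21 * E) / s, (q12 + q21 * E) / s))
}

# Brute-force binary Mk likelihood: sum over all internal-node state
# assignments (no cladogenetic component).
oracle_mk <- function(tree, states01, rate, root_prior = c(0.5, 0.5)) {
  n_tip <- ape::Ntip(tree)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  P <- function(t) {
    stay <- (1 + exp(-2 * rate * t)) / 2
    rbind(c(stay, 1 - stay), c(1 - stay, stay))
  }
  grid <- expand.grid(rep(list(1:2), length(internal)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(n_tip + tree$Nnode)
    st[internal] <- as.integer(grid[r, ])
    st[1:n_tip] <- states01 + 1L
    prob <- root_prior[st[n_tip + 1]]
    for (k in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      prob <- prob * P(tree$edge.length[k])[st[pa], st[ch]]
    }
    total <- total + prob
  }
  log(total)
}

# Random host assignment helper for DEC fixtures.
random_tip_states <- function(tree, space) {
  st <- lapply(seq_len(ape::Ntip(tree)), function(i) {
    k <- sample(seq_len(space$max_breadth), 1)
    sample(space$hosts, min(k, length(space$hosts)))
  })
  names(st) <- tree$tip.label
  st
}

state_idx_of <- function(space, host_set) {
  which(space$labels == paste(sort(host_set), collapse = "+"))
}
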