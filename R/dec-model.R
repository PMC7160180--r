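#' Anagenetic rate generator of the DEC* model
#'
#' Builds the instantaneous rate matrix Q over a bounded-breadth host state
#' space. Off-diagonal rates: a repertoire A gains a host h not in A at rate
#' `|A| * d` (each occupied host contributes a dispersal path; set
#' `scale_gain = FALSE` for a flat rate `d`), provided the enlarged set
#' respects the breadth cap; A loses an occupied host at rate `e` per host,
#' but only when `|A| >= 2` — DEC* has no null state, so singleton
#' repertoires cannot lose their last host. Rows sum to zero.
#'
#' @param space A [host_state_space()].
#' @param d Host-gain rate (per occupied-host/gainable-host pair per Myr).
#' @param e Host-loss rate (per occupied host per Myr).
#' @param scale_gain If `TRUE` (default) gain rate is `|A| * d`, mirroring
#'   the DEC dispersal sum with all multipliers equal to one; if `FALSE`
#'   every gain has flat rate `d`.
#' @return A dense base matrix (n_states x n_states) with state labels as
#'   dimnames.
#' @export
dec_generator <- function(space, d, e, scale_gain = TRUE) {
  if (d < 0 || e < 0) abort("Rates d and e must be >= 0.")
  n <- space$n_states
  nh <- length(space$hosts)
  Q <- matrix(0, n, n, dimnames = list(space$labels, space$labels))
  for (i in seq_len(n)) {
    A <- space$states[[i]]
    k <- length(A)
    gain_rate <- if (scale_gain) k * d else d
    if (k < space$max_breadth) {
      for (h in setdiff(seq_len(nh), A)) {
        j <- match(space$masks[i] + bitwShiftL(1L, h - 1L), space$masks)
        Q[i, j] <- Q[i, j] + gain_rate
      }
    }
    if (k >= 2) {
      for (h in A) {
        j <- match(space$masks[i] - bitwShiftL(1L, h - 1L), space$masks)
        Q[i, j] <- Q[i, j] + e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Eigen-decomposition based propagator. Q = V diag(lambda) Vinv; the action
# exp(Qt) x is then two matrix-vector products per branch instead of a fresh
# matrix exponential. DEC generators are generically diagonalizable; if the
# decomposition reconstructs Q poorly we fall back to scaling-and-squaring.
make_propagator <- function(Q) {
  eg <- eigen(Q)
  V <- eg$vectors
  lambda <- eg$values
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(Vinv)) {
    recon <- Re(V %*% (lambda * Vinv))
    ok <- max(abs(recon - Q)) <= 1e-8 * max(1, max(abs(Q)))
  }
  list(Q = Q, V = V, lambda = lambda, Vinv = Vinv, diagonalizable = ok)
}

# exp(Q t) %*% x  (x may be a matrix of column vectors).
propagate <- function(prop, t, x) {
  if (t == 0) return(x)
  if (prop$diagonalizable) {
    out <- Re(prop$V %*% (exp(prop$lambda * t) * (prop$Vinv %*% x)))
  } else {
    out <- expm_pade(prop$Q * t) %*% x
  }
  out[out < 0] <- 0
  out
}

# t(exp(Q t)) %*% x, used by the up-pass of the marginal reconstruction.
propagate_up <- function(prop, t, x) {
  if (t == 0) return(x)
  if (prop$diagonalizable) {
    out <- Re(t(prop$Vinv) %*% (exp(prop$lambda * t) * (t(prop$V) %*% x)))
  } else {
    out <- crossprod(expm_pade(prop$Q * t), x)
  }
  out[out < 0] <- 0
  out
}

# Scaling-and-squaring Pade matrix exponential (fallback path only).
expm_pade <- function(A) {
  n <- nrow(A)
  s <- max(0, ceiling(log2(max(1e-300, norm(A, "1")))) + 1)
  A <- A / 2^s
  c <- 0.5; q <- 6L
  X <- A
  E <- diag(n) + c * A
  D <- diag(n) - c * A
  p <- TRUE
  for (k in 2:q) {
    c <- c * (q - k + 1) / (k * (2 * q - k + 1))
    X <- A %*% X
    E <- E + c * X
    D <- D + (if (p) c else -c) * X
    p <- !p
  }
  E <- solve(D, E)
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Transition probability matrix of the DEC* anagenetic process
#'
#' `P(t) = exp(Q t)`, row-stochastic; tiny negative entries from roundoff
#' are clipped to zero.
#'
#' @param Q Generator from [dec_generator()].
#' @param t Elapsed time (Myr), >= 0.
#' @return Row-stochastic matrix.
#' @export
dec_transition_probs <- function(Q, t) {
  if (t < 0) abort("Elapsed time must be >= 0.")
  prop <- make_propagator(Q)
  P <- propagate(prop, t, diag(nrow(Q)))
  dimnames(P) <- dimnames(Q)
  P
}

#' Cladogenetic outcomes of a repertoire at a speciation event
#'
#' Under the DEC convention, a singleton repertoire is inherited identically
#' by both daughters. A repertoire A with two or more hosts splits into one
#' of the equiprobable ordered daughter pairs: subset sympatry — one
#' daughter keeps A, the other a single host y in A — and vicariance — one
#' daughter takes a single host y, the other the remainder A \\ y.
#' Duplicate ordered pairs (which arise for |A| = 2, where sympatry and
#' vicariance overlap in no pair but vicariance generates each split twice)
#' are deduplicated before probabilities are assigned.
#'
#' @param space A [host_state_space()].
#' @param state_idx Index of the parental state in `space`.
#' @return A tibble with columns `left`, `right` (state indices) and `prob`
#'   (summing to 1).
#' @export
clado_pairs <- function(space, state_idx) {
  A <- space$states[[state_idx]]
  if (length(A) == 0) abort("Empty state has no cladogenetic outcomes.")
  if (length(A) == 1) {
    return(tibble::tibble(left = state_idx, right = state_idx, prob = 1))
  }
  mask <- space$masks[state_idx]
  singles <- match(bitwShiftL(1L, A - 1L), space$masks)
  rests <- match(mask - bitwShiftL(1L, A - 1L), space$masks)
  left <- c(singles, rep(state_idx, length(A)), singles, rests)
  right <- c(rep(state_idx, length(A)), singles, rests, singles)
  key <- paste(left, right)
  keep <- !duplicated(key)
  left <- left[keep]; right <- right[keep]
  tibble::tibble(left = left, right = right, prob = 1 / length(left))
}

# Flattened cladogenetic event table for a whole space: parallel vectors
# (parent, left, right, prob) across all states, used to vectorize the
# pruning recursion via rowsum().
clado_table <- function(space) {
  parts <- lapply(seq_len(space$n_states), function(i) {
    cp <- clado_pairs(space, i)
    cbind(parent = rep(i, nrow(cp)), left = cp$left, right = cp$right,
          prob = cp$prob)
  })
  tab <- do.call(rbind, parts)
  list(parent = as.integer(tab[, "parent"]), left = as.integer(tab[, "left"]),
       right = as.integer(tab[, "right"]), prob = tab[, "prob"])
}

# Root prior over states: uniform over all non-null states (default), or
# the stationary distribution of Q.
root_prior_vec <- function(space, root_prior = c("uniform", "stationary"),
                           Q = NULL) {
  root_prior <- match.arg(root_prior)
  n <- space$n_states
  if (root_prior == "uniform") return(rep(1 / n, n))
  if (is.null(Q)) abort("Stationary root prior needs the generator Q.")
  # left null vector of Q
  ns <- eigen(t(Q))
  i <- which.min(abs(ns$values))
  v <- abs(Re(ns$vectors[, i]))
  v / sum(v)
}
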