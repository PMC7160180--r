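# Binary-trait (use / nonuse) models: symmetric single-rate Mk with either
# a constant rate or an early-burst rate that decays exponentially with
# time since the root, r(t) = r0 * exp(a * t), a <= 0. The early-burst
# model is fitted by rescaling every branch segment to the integral of the
# rate over its time span and running the constant-rate pruning on the
# rescaled tree, so the two models coincide exactly at a = 0.

# 2-state symmetric transition probability: P(stay) = (1 + exp(-2 r t))/2.
mk2_loglik <- function(tree, states01, rate, root_prior = c(0.5, 0.5)) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge
  elen <- po$edge.length
  L <- matrix(0, 2, n_node)
  L[cbind(states01 + 1L, seq_len(n_tip))] <- 1
  logscale <- 0
  for (p in unique(edges[, 1])) {
    ke <- which(edges[, 1] == p)
    acc <- c(1, 1)
    for (k in ke) {
      ch <- edges[k, 2]
      stay <- (1 + exp(-2 * rate * elen[k])) / 2
      v <- L[, ch]
      acc <- acc * c(stay * v[1] + (1 - stay) * v[2],
                     (1 - stay) * v[1] + stay * v[2])
    }
    m <- max(acc)
    if (m <= 0) return(-Inf)
    L[, p] <- acc / m
    logscale <- logscale + log(m)
  }
  log(sum(root_prior * L[, root_node(tree)])) + logscale
}

# Early-burst branch rescaling: each edge spanning depths [t1, t2] from the
# root is replaced by integral_{t1}^{t2} exp(a s) ds.
eb_rescale <- function(tree, a) {
  if (a == 0) return(tree)
  depth <- node_depths(tree)
  t1 <- depth[tree$edge[, 1]]
  t2 <- depth[tree$edge[, 2]]
  out <- tree
  out$edge.length <- (exp(a * t2) - exp(a * t1)) / a
  out
}

#' Fit a binary host-use trait model
#'
#' Maximum-likelihood fit of the symmetric single-rate Mk model to a binary
#' (use / nonuse) trait, either with a constant rate or with an
#' early-burst rate decaying as `r0 * exp(a * t)` with time `t` since the
#' root (`a` bounded in `[a_min, 0]`; default `a_min = log(0.01) / T`
#' allows a hundredfold decay over the tree depth `T`). An invariant trait
#' (all 0 or all 1) drives the rate to its lower bound and is flagged.
#'
#' @param tree An [ape::phylo] object.
#' @param states Named vector (by tip label) of 0/1 trait values, no
#'   missing values.
#' @param model `"constant"` or `"early_burst"`.
#' @param a_min Lower bound for the early-burst exponent (default
#'   `log(0.01) / depth`).
#' @param rate_bounds Box bounds for the rate.
#' @return An object of class `hostshift_mk`: list with `model`, `rate`,
#'   `a` (0 for the constant model), `loglik`, `boundary` flag.
#' @export
fit_mk <- function(tree, states, model = c("constant", "early_burst"),
                   a_min = NULL, rate_bounds = c(1e-9, 100)) {
  model <- match.arg(model)
  if (is.null(names(states))) abort("`states` must be named by tip label.")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss) > 0) abort(paste0("Missing trait values for: ",
                                     paste(miss, collapse = ", ")))
  x <- as.integer(states[tree$tip.label])
  if (anyNA(x) || !all(x %in% c(0L, 1L))) abort("Trait values must be 0/1.")
  invariant <- length(unique(x)) == 1
  depth <- max(node_depths(tree))
  if (is.null(a_min)) a_min <- log(0.01) / depth

  if (model == "constant") {
    nll <- function(lr) -mk2_loglik(tree, x, exp(lr))
    opt <- stats::optimize(nll, interval = log(rate_bounds))
    rate <- exp(opt$minimum)
    ll <- -opt$objective
    a_hat <- 0
  } else {
    nll2 <- function(par) {
      tr <- eb_rescale(tree, par[2])
      -mk2_loglik(tr, x, exp(par[1]))
    }
    cst <- fit_mk(tree, states, "constant", rate_bounds = rate_bounds)
    starts <- rbind(c(log(cst$rate), 0),
                    c(log(cst$rate), a_min / 2),
                    c(log(max(rate_bounds[1] * 10, cst$rate / 10)), a_min / 4))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(starts[i, ], nll2, method = "L-BFGS-B",
              lower = c(log(rate_bounds[1]), a_min),
              upper = c(log(rate_bounds[2]), 0),
              control = list(factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) abort("Early-burst optimizer failed to converge.")
    # the constant model is nested at a = 0: never report a worse likelihood
    if (-best$value < cst$loglik) {
      best <- list(par = c(log(cst$rate), 0), value = -cst$loglik)
    }
    rate <- exp(best$par[1])
    a_hat <- best$par[2]
    ll <- -best$value
  }
  boundary <- invariant || rate <= rate_bounds[1] * 1.0001
  if (invariant) {
    warn("Invariant trait: rate estimate is at its lower bound.")
  }
  structure(list(model = model, rate = rate, a = a_hat, loglik = ll,
                 boundary = boundary, a_min = a_min, n_tips = ape::Ntip(tree)),
            class = "hostshift_mk")
}

#' @export
print.hostshift_mk <- function(x, ...) {
  cat("Mk fit (", x$model, "): rate =", signif(x$rate, 4),
      if (x$model == "early_burst") paste0(" a = ", signif(x$a, 4)) else "",
      " loglik =", round(x$loglik, 3), "\n")
  invisible(x)
}

#' @method tidy hostshift_mk
#' @export
tidy.hostshift_mk <- function(x, ...) {
  if (x$model == "constant") {
    tibble::tibble(term = "rate", estimate = x$rate)
  } else {
    tibble::tibble(term = c("rate", "a"), estimate = c(x$rate, x$a))
  }
}

#' @method glance hostshift_mk
#' @export
glance.hostshift_mk <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, boundary = x$boundary,
                 nobs = x$n_tips)
}

#' Likelihood-ratio test of nested trait models
#'
#' @param ll_null,ll_alt Log-likelihoods of the nested (null) and nesting
#'   (alternative) models; `ll_alt` may not be below `ll_null` by more than
#'   numerical noise (1e-6).
#' @param df Degrees of freedom of the test (>= 1).
#' @return A tibble with `statistic` (2 * (ll_alt - ll_null), clipped at 0)
#'   and `p.value` from the chi-square distribution.
#' @export
lr_test <- function(ll_null, ll_alt, df = 1) {
  if (df < 1) abort("`df` must be >= 1.")
  if (ll_alt < ll_null - 1e-6) {
    abort("`ll_alt` is below `ll_null`: the models are not nested or the alternative fit failed.")
  }
  stat <- max(0, 2 * (ll_alt - ll_null))
  tibble::tibble(statistic = stat,
                 p.value = pchisq(stat, df, lower.tail = FALSE))
}

#' Early-burst screen across binary host-use traits
#'
#' For every host in the table, codes use/nonuse across the tips, fits the
#' constant and early-burst models, and reports the likelihood-ratio test.
#' Hosts with invariant usage are skipped.
#'
#' @param tree An [ape::phylo] object.
#' @param hosts Named list mapping taxon to host vectors.
#' @return A tibble: `host`, `n_users`, `rate_constant`, `rate_eb`, `a`,
#'   `loglik_constant`, `loglik_eb`, `statistic`, `p.value`.
#' @export
eb_screen <- function(tree, hosts) {
  all_hosts <- sort(unique(unlist(hosts, use.names = FALSE)))
  rows <- list()
  for (h in all_hosts) {
    x <- vapply(tree$tip.label,
                function(t) as.integer(h %in% (hosts[[t]] %||% character(0))),
                integer(1))
    if (length(unique(x)) == 1) next
    cst <- fit_mk(tree, x, "constant")
    eb <- fit_mk(tree, x, "early_burst")
    lrt <- lr_test(cst$loglik, eb$loglik, df = 1)
    rows[[length(rows) + 1]] <- tibble::tibble(
      host = h, n_users = sum(x),
      rate_constant = cst$rate, rate_eb = eb$rate, a = eb$a,
      loglik_constant = cst$loglik, loglik_eb = eb$loglik,
      statistic = lrt$statistic, p.value = lrt$p.value)
  }
  dplyr::bind_rows(rows)
}
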