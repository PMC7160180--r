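# Bayesian phylogenetic ("pedigree") mixed model via Gibbs sampling.
#
# Model: y = X beta + u + m + eps, with
#   u   ~ MVN(0, sigma2_a * A)   phylogenetic random effect; A is the
#                                 shared-path-length correlation among the
#                                 tree nodes carrying observations,
#   m_i ~ N(0, mev_i)            fixed, known measurement-error variances
#                                 (the channel the MCCR z-weights enter by),
#   eps ~ N(0, sigma2_e I).
# Priors: improper flat on beta; inverse-gamma(shape, scale) on both
# variance components. All full conditionals are conjugate, so the chain
# is a pure Gibbs sampler and bit-reproducible under a seed.

# Shared-path-length correlation among arbitrary nodes of a tree.
node_correlation <- function(tree, nodes) {
  depth <- node_depths(tree)
  mr <- ape::mrca(tree, full = TRUE)
  V <- matrix(0, length(nodes), length(nodes))
  for (i in seq_along(nodes)) {
    for (j in seq_len(i)) {
      V[i, j] <- V[j, i] <- depth[mr[nodes[i], nodes[j]]]
    }
  }
  diag(V) <- depth[nodes]
  if (any(diag(V) <= 0)) {
    # the root itself has zero depth; give it a nugget so the correlation exists
    diag(V)[diag(V) <= 0] <- 1e-8
  }
  stats::cov2cor(V)
}

#' Bayesian phylogenetic mixed model
#'
#' Gibbs sampler for a Gaussian mixed model whose random-effect covariance
#' is the phylogenetic relatedness (shared path length, scaled to a
#' correlation) between the tree nodes the observations are attached to,
#' with an optional per-observation measurement-error variance (`mev`)
#' through which gamma-statistic MCCR weights enter. Posterior summaries
#' use `pMCMC` = twice the smaller tail probability of a fixed effect's
#' chain crossing zero.
#'
#' @param data Data frame with the response, predictors, and a column of
#'   node numbers linking rows to `tree`.
#' @param formula Model formula for the fixed effects (intercept allowed).
#' @param tree An [ape::phylo] object.
#' @param node_col Name of the column holding node numbers.
#' @param mev Optional column name of per-observation measurement-error
#'   variances (>= 0; 0 disables the term for that row), or NULL.
#' @param n_iter Total MCMC iterations.
#' @param thin Thinning interval.
#' @param burnin Iterations discarded before sampling (default 10 percent).
#' @param seed Integer seed; chains are bit-reproducible given it.
#' @param prior_shape,prior_scale Inverse-gamma hyperparameters for both
#'   variance components (weakly informative defaults 0.001, 0.001).
#' @return An object of class `hostshift_mixed`: posterior chains
#'   (`beta`, `sigma2_a`, `sigma2_e`), summaries, Geweke diagnostics and
#'   the sampler configuration.
#' @export
phylo_mixed <- function(data, formula, tree, node_col = "node", mev = NULL,
                        n_iter = 1e6, thin = 100, burnin = floor(n_iter / 10),
                        seed = 1, prior_shape = 0.001, prior_scale = 0.001) {
  data <- as.data.frame(data)
  X <- stats::model.matrix(formula, data)
  y <- stats::model.response(stats::model.frame(formula, data))
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) abort("Too few observations for the mixed model.")
  nodes <- data[[node_col]]
  if (is.null(nodes)) abort(paste0("No node column '", node_col, "'."))
  A <- node_correlation(tree, nodes)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    inform("Relatedness matrix not positive definite; adding 1e-8 jitter.")
    A <- A + diag(1e-8, n)
    ch <- chol(A)
  }
  Ainv <- chol2inv(ch)
  mev_v <- if (is.null(mev)) rep(0, n) else {
    mv <- data[[mev]]
    if (is.null(mv)) abort(paste0("No mev column '", mev, "'."))
    if (any(mv < 0) || anyNA(mv)) abort("`mev` variances must be >= 0.")
    mv
  }
  has_m <- mev_v > 0

  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)

  keep <- floor((n_iter - burnin) / thin)
  if (keep < 10) abort("Chain too short: increase n_iter or decrease thin.")
  beta_chain <- matrix(NA_real_, keep, p, dimnames = list(NULL, colnames(X)))
  s2a_chain <- numeric(keep)
  s2e_chain <- numeric(keep)

  with_seed_if(seed, {
    beta <- drop(XtX_inv %*% crossprod(X, y))
    u <- rep(0, n)
    m <- rep(0, n)
    s2a <- max(var(y) / 2, 1e-4)
    s2e <- max(var(y) / 2, 1e-4)
    stored <- 0L
    for (it in seq_len(n_iter)) {
      # beta | .
      r <- y - u - m
      mu_b <- drop(XtX_inv %*% crossprod(X, r))
      beta <- mu_b + drop(backsolve(chol(XtX / s2e), rnorm(p)))
      # u | .
      Prec <- Ainv / s2a + diag(1 / s2e, n)
      cu <- chol(Prec)
      r <- y - drop(X %*% beta) - m
      mu_u <- backsolve(cu, forwardsolve(t(cu), r / s2e))
      u <- mu_u + backsolve(cu, rnorm(n))
      # m | . (only rows with mev > 0)
      if (any(has_m)) {
        r <- y - drop(X %*% beta) - u
        post_var <- 1 / (1 / mev_v[has_m] + 1 / s2e)
        post_mean <- post_var * r[has_m] / s2e
        m[has_m] <- rnorm(sum(has_m), post_mean, sqrt(post_var))
      }
      # variance components | .
      quad_u <- drop(crossprod(u, Ainv %*% u))
      s2a <- 1 / stats::rgamma(1, prior_shape + n / 2,
                               prior_scale + quad_u / 2)
      resid <- y - drop(X %*% beta) - u - m
      s2e <- 1 / stats::rgamma(1, prior_shape + n / 2,
                               prior_scale + sum(resid^2) / 2)
      if (it > burnin && (it - burnin) %% thin == 0 && stored < keep) {
        stored <- stored + 1L
        beta_chain[stored, ] <- beta
        s2a_chain[stored] <- s2a
        s2e_chain[stored] <- s2e
      }
    }
  })

  summarise_param <- function(ch) {
    tibble::tibble(
      estimate = mean(ch), median = median(ch),
      conf.low = unname(quantile(ch, 0.025)),
      conf.high = unname(quantile(ch, 0.975)),
      pMCMC = max(2 * min(mean(ch > 0), mean(ch < 0)), 1 / length(ch))
    )
  }
  fixed <- dplyr::bind_cols(
    tibble::tibble(term = colnames(X)),
    dplyr::bind_rows(lapply(seq_len(p), function(j) summarise_param(beta_chain[, j])))
  )
  gz <- c(vapply(seq_len(p), function(j) geweke_diag(beta_chain[, j]), numeric(1)),
          geweke_diag(s2a_chain), geweke_diag(s2e_chain))
  names(gz) <- c(colnames(X), "sigma2_phylo", "sigma2_resid")
  structure(
    list(fixed = fixed,
         vc = tibble::tibble(component = c("sigma2_phylo", "sigma2_resid"),
                             estimate = c(mean(s2a_chain), mean(s2e_chain)),
                             conf.low = c(quantile(s2a_chain, 0.025),
                                          quantile(s2e_chain, 0.025)),
                             conf.high = c(quantile(s2a_chain, 0.975),
                                           quantile(s2e_chain, 0.975))),
         geweke = gz,
         chains = list(beta = beta_chain, sigma2_phylo = s2a_chain,
                       sigma2_resid = s2e_chain),
         config = list(n_iter = n_iter, thin = thin, burnin = burnin,
                       seed = seed, mev = mev, n = n,
                       prior = c(shape = prior_shape, scale = prior_scale))),
    class = "hostshift_mixed"
  )
}

#' @export
print.hostshift_mixed <- function(x, ...) {
  cat("Phylogenetic mixed model (", x$config$n, " observations, ",
      nrow(x$chains$beta), " retained samples)\n", sep = "")
  print(x$fixed)
  invisible(x)
}

#' @method tidy hostshift_mixed
#' @export
tidy.hostshift_mixed <- function(x, ...) {
  out <- x$fixed
  out$geweke_z <- x$geweke[seq_len(nrow(out))]
  out
}

#' @method glance hostshift_mixed
#' @export
glance.hostshift_mixed <- function(x, ...) {
  tibble::tibble(
    nobs = x$config$n,
    n_samples = nrow(x$chains$beta),
    sigma2_phylo = x$vc$estimate[1],
    sigma2_resid = x$vc$estimate[2],
    max_abs_geweke = max(abs(x$geweke))
  )
}

#' Export posterior chains as CSV
#'
#' @param x A `hostshift_mixed` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(x, path) {
  df <- tibble::as_tibble(x$chains$beta)
  df$sigma2_phylo <- x$chains$sigma2_phylo
  df$sigma2_resid <- x$chains$sigma2_resid
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of the first and last fractions of a chain with a
#' z-score whose variances are spectral-density-at-zero estimates from an
#' AIC-selected autoregressive fit (robust to autocorrelation).
#'
#' @param chain Numeric vector of MCMC samples (length >= 20).
#' @param first,last Fractions of the chain to compare.
#' @return The z statistic (NaN for a constant chain, with a warning).
#' @export
geweke_diag <- function(chain, first = 0.1, last = 0.5) {
  n <- length(chain)
  if (n < 20) abort("Chain too short for the Geweke diagnostic (need >= 20).")
  if (sd(chain) == 0) {
    warn("Constant chain: Geweke z undefined.")
    return(NaN)
  }
  a <- chain[seq_len(floor(first * n))]
  b <- chain[seq.int(n - floor(last * n) + 1L, n)]
  s0 <- function(x) {
    if (var(x) == 0) return(0)
    fit <- tryCatch(ar(x, aic = TRUE, order.max = min(20, length(x) - 1)),
                    error = function(e) NULL)
    if (is.null(fit) || length(fit$ar) == 0) return(var(x))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  (mean(a) - mean(b)) / sqrt(s0(a) / length(a) + s0(b) / length(b))
}
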