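#' Gamma statistic of an ultrametric clade
#'
#' Pybus & Harvey's standardized measure of departure from constant-rate
#' diversification, computed from the internode intervals of an ultrametric
#' tree. Negative values indicate nodes concentrated toward the root (an
#' early burst of speciation); under a pure-birth process gamma is
#' asymptotically standard normal. Defined only for ultrametric trees with
#' at least 3 tips.
#'
#' @param tree An ultrametric [ape::phylo] object.
#' @return The gamma statistic (scalar).
#' @export
gamma_stat <- function(tree) {
  if (ape::Ntip(tree) < 3) abort("Gamma statistic needs at least 3 tips.")
  assert_ultrametric(tree, "the gamma statistic")
  ape::gammaStat(tree)
}

#' Gamma statistics for all sufficiently large clades
#'
#' One gamma value per internal node whose clade holds at least `min_tips`
#' tips. Nested clades are all reported (no disjointness requirement).
#'
#' @param tree An ultrametric [ape::phylo] object.
#' @param min_tips Minimum clade size (>= 3).
#' @return A tibble with columns `node`, `n_tips`, `gamma`.
#' @export
clade_gammas <- function(tree, min_tips = 10L) {
  if (min_tips < 3) abort("`min_tips` must be >= 3 for the gamma statistic.")
  assert_ultrametric(tree, "the gamma statistic")
  desc <- descendant_tips(tree)
  n_tip <- ape::Ntip(tree)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  sizes <- lengths(desc)[internal]
  keep <- internal[sizes >= min_tips]
  if (length(keep) == 0) {
    return(tibble::tibble(node = integer(0), n_tips = integer(0),
                          gamma = numeric(0)))
  }
  root <- root_node(tree)
  g <- vapply(keep, function(v) {
    cl <- if (v == root) tree else ape::extract.clade(tree, v)
    gamma_stat(cl)
  }, numeric(1))
  tibble::tibble(node = keep, n_tips = as.integer(sizes[match(keep, internal)]),
                 gamma = g)
}

#' MCCR correction for a gamma statistic under incomplete sampling
#'
#' Monte-Carlo constant-rates test: simulates `reps` trees with `n_total`
#' tips under a constant-rate null (pure birth by default), prunes each
#' uniformly at random to `n_sampled` tips, and computes the null
#' distribution of gamma under the same incomplete sampling as the data.
#' Returns the distance of the empirical gamma from the null mean in null
#' standard deviations (`z`, used downstream as a measurement-error weight)
#' and a one-tailed rank probability for the early-burst (lower) tail.
#'
#' @param gamma_emp Empirical gamma statistic.
#' @param n_total True number of lineages in the clade (e.g. summed species
#'   richness over genus tips).
#' @param n_sampled Number of sampled tips the empirical gamma was computed
#'   from (`n_sampled <= n_total`).
#' @param reps Number of null simulations (>= 2).
#' @param seed Integer seed.
#' @param extinction_fraction Death rate as a fraction of the birth rate in
#'   the null model (0 = pure birth).
#' @return A list with `z`, `p`, `null_mean`, `null_sd`, `reps`.
#' @export
mccr_weight <- function(gamma_emp, n_total, n_sampled, reps = 100, seed = 1,
                        extinction_fraction = 0) {
  if (n_sampled > n_total) abort("`n_sampled` must be <= `n_total`.")
  if (n_sampled < 3) abort("`n_sampled` must be >= 3.")
  if (reps < 2) abort("`reps` must be >= 2.")
  null_g <- with_seed_if(seed, {
    vapply(seq_len(reps), function(i) {
      sim <- ape::rphylo(n_total, birth = 1, death = extinction_fraction,
                         fossils = FALSE)
      if (n_sampled < n_total) {
        drop <- sample(sim$tip.label, n_total - n_sampled)
        sim <- ape::drop.tip(sim, drop)
      }
      ape::gammaStat(sim)
    }, numeric(1))
  })
  m <- mean(null_g)
  s <- sd(null_g)
  if (!is.finite(s) || s == 0) abort("Degenerate MCCR null distribution (sd = 0).")
  list(z = abs(gamma_emp - m) / s,
       p = (1 + sum(null_g <= gamma_emp)) / (reps + 1),
       null_mean = m, null_sd = s, reps = reps)
}

#' Per-clade gamma statistics with MCCR weights
#'
#' Convenience wrapper: [clade_gammas()] plus one [mccr_weight()] call per
#' clade, taking `n_total` as the summed richness of the clade's tips and
#' `n_sampled` as its tip count. Each clade gets a sub-seed derived
#' deterministically from `seed`.
#'
#' @inheritParams clade_gammas
#' @param richness Named per-tip species counts (NULL = complete sampling,
#'   `n_total = n_sampled`).
#' @param mccr If `FALSE`, skip the correction (columns `z`, `p` are NA).
#' @param reps,seed,extinction_fraction Passed to [mccr_weight()].
#' @return A tibble with columns `node`, `n_tips`, `n_total`, `gamma`, `z`,
#'   `p`.
#' @export
clade_gammas_mccr <- function(tree, min_tips = 10L, richness = NULL,
                              mccr = TRUE, reps = 100, seed = 1,
                              extinction_fraction = 0) {
  cg <- clade_gammas(tree, min_tips)
  if (nrow(cg) == 0) {
    return(tibble::tibble(node = integer(0), n_tips = integer(0),
                          n_total = integer(0), gamma = numeric(0),
                          z = numeric(0), p = numeric(0)))
  }
  desc <- descendant_tips(tree)
  n_total <- vapply(cg$node, function(v) {
    as.integer(sum_richness(tree$tip.label[desc[[v]]], richness))
  }, integer(1))
  cg$n_total <- n_total
  if (!mccr) {
    cg$z <- NA_real_
    cg$p <- NA_real_
    return(cg[, c("node", "n_tips", "n_total", "gamma", "z", "p")])
  }
  zs <- numeric(nrow(cg)); ps <- numeric(nrow(cg))
  for (i in seq_len(nrow(cg))) {
    w <- mccr_weight(cg$gamma[i], n_total = cg$n_total[i],
                     n_sampled = cg$n_tips[i], reps = reps,
                     seed = seed + i, extinction_fraction = extinction_fraction)
    zs[i] <- w$z; ps[i] <- w$p
  }
  cg$z <- zs
  cg$p <- ps
  cg[, c("node", "n_tips", "n_total", "gamma", "z", "p")]
}
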