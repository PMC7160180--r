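# The pruning likelihood and marginal reconstruction against the explicit
# enumeration oracle, plus structural identities. The exhaustive
# grid-over-rates versions of these checks live in test-acceptance.R; the
# versions here are the smaller per-module spot checks.

test_that("pruning likelihood equals enumeration on small trees", {
  set.seed(11)
  sp <- host_state_space(c("a", "b"), 2)
  tr <- ape::rtree(4)
  ts <- random_tip_states(tr, sp)
  tidx <- vapply(ts, function(h) state_idx_of(sp, h), integer(1))
  for (d in c(0.05, 0.6)) {
    for (e in c(0.1, 0.9)) {
      bf <- oracle_dec(tr, tidx, sp, d, e)
      expect_equal(dec_loglik(tr, ts, sp, d, e), bf$loglik,
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate no-change limit returns the root prior mass", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  sp <- host_state_space(c("a", "b"), 2)
  ts <- list(A = "a", B = "a")
  # d = e = 0: both tips must inherit the root state {a}; likelihood is the
  # prior probability of {a} (singletons inherit identically at cladogenesis)
  expect_equal(dec_loglik(tr, ts, sp, 0, 0), log(1 / 3), tolerance = 1e-12)
})

test_that("likelihood is invariant under time/rate rescaling and host relabeling", {
  set.seed(5)
  sp <- host_state_space(c("a", "b", "c"), 2)
  tr <- ape::rtree(8)
  ts <- random_tip_states(tr, sp)
  ll <- dec_loglik(tr, ts, sp, 0.2, 0.4)
  # multiply branch lengths by c, divide rates by c
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 3.7
  expect_equal(dec_loglik(tr2, ts, sp, 0.2 / 3.7, 0.4 / 3.7), ll,
               tolerance = 1e-9)
  # permute host labels
  perm <- c(a = "c", b = "a", c = "b")
  ts_p <- lapply(ts, function(h) unname(perm[h]))
  expect_equal(dec_loglik(tr, ts_p, sp, 0.2, 0.4), ll, tolerance = 1e-9)
})

test_that("marginal reconstruction matches enumeration posteriors and normalizes", {
  set.seed(23)
  sp <- host_state_space(c("a", "b"), 2)
  for (rep in 1:3) {
    tr <- ape::rtree(4)
    ts <- random_tip_states(tr, sp)
    tidx <- vapply(ts, function(h) state_idx_of(sp, h), integer(1))
    bf <- oracle_dec(tr, tidx, sp, 0.15, 0.3)
    rec <- dec_ancestral_states(tr, ts, sp, 0.15, 0.3)
    expect_equal(unname(rec$node_probs), unname(bf$post), tolerance = 1e-8)
    expect_true(all(abs(rowSums(rec$node_probs) - 1) < 1e-8))
  }
})

test_that("marginals collapse to the shared state in the no-event limit", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  sp <- host_state_space(c("a", "b"), 2)
  ts <- list(A = "a", B = "a", C = "a", D = "a")
  rec <- dec_ancestral_states(tr, ts, sp, 1e-8, 1e-8)
  expect_true(all(rec$node_probs[, "a"] > 0.999))
  expect_true(all(rec$map$state == "a"))
})

test_that("reconstruction exports are tidy and re-readable", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  sp <- host_state_space(c("a", "b"), 2)
  rec <- dec_ancestral_states(tr, list(A = "a", B = c("a", "b"), C = "b"),
                              sp, 0.1, 0.1)
  td <- tidy(rec)
  expect_true(all(c("node", "state", "prob") %in% names(td)))
  dir <- withr::local_tempdir()
  write_reconstruction(rec, dir)
  back <- readr::read_tsv(file.path(dir, "map_states.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), tr$Nnode)
  pars <- jsonlite::read_json(file.path(dir, "dec_params.json"))
  expect_equal(pars$loglik, rec$loglik, tolerance = 1e-12)
})

test_that("rate fitting is deterministic, bounded, and monotone in restarts", {
  set.seed(3)
  tr <- ape::rphylo(25, 1, 0)
  sp <- host_state_space(c("a", "b", "c"), 2)
  h <- sim_host_history(tr, sp, 0.3, 0.3, seed = 9)
  f1 <- fit_dec(tr, h$tip_states, sp, n_starts = 3, seed = 42)
  f2 <- fit_dec(tr, h$tip_states, sp, n_starts = 3, seed = 42)
  expect_identical(f1$d, f2$d)
  expect_identical(f1$e, f2$e)
  expect_identical(f1$loglik, f2$loglik)
  # best-of-restarts is at least as good as every individual restart
  expect_true(all(f1$loglik >= f1$starts$loglik - 1e-9))

  # identical singleton tips everywhere: no gain signal, d driven to its
  # lower bound; the reported optimum dominates other rate combinations
  ts0 <- setNames(rep(list("a"), 25), tr$tip.label)
  f0 <- fit_dec(tr, ts0, sp, n_starts = 2, seed = 1)
  expect_lt(f0$d, 1e-6)
  expect_gte(f0$loglik, dec_loglik(tr, ts0, sp, 0.01, 0.5) - 1e-9)
  # under a uniform root prior the all-singleton likelihood is bounded by
  # the prior mass of the shared state (multi-host roots can only leak)
  # (roots containing "a" are the only ones that can funnel to all-{a})
  expect_lte(f0$loglik, log(3 / sp$n_states) + 1e-6)
})

test_that("over-breadth or unknown tip repertoires are refused, not truncated", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  sp <- host_state_space(c("a", "b", "c"), 2)
  expect_error(dec_loglik(tr, list(A = "a", B = "b", C = c("a", "b", "c")),
                          sp, 0.1, 0.1), "not representable")
  expect_error(dec_loglik(tr, list(A = "a", B = "z", C = "b"), sp, 0.1, 0.1),
               "not representable")
  expect_error(dec_loglik(tr, list(A = "a", B = "b"), sp, 0.1, 0.1),
               "No host data")
})
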