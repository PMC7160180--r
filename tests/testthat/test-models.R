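# Weighted through-origin regression, the phylogenetic mixed model, the
# Geweke diagnostic, and the binary-trait models.

test_that("through-origin WLS reproduces the normal equations", {
  set.seed(19)
  for (rep in 1:3) {
    n <- 20
    df <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                     w = runif(n, 0.2, 1))
    fit <- wls_origin(df, y ~ x1 + x2 + 0, weights = "w")
    orc <- oracle_wls(as.matrix(df[, c("x1", "x2")]), df$y, df$w)
    td <- tidy(fit)
    expect_equal(td$estimate, unname(orc$beta), tolerance = 1e-10)
    expect_equal(td$std.error, unname(orc$se), tolerance = 1e-10)
    expect_equal(td$p.value, unname(orc$p), tolerance = 1e-10)
  }
})

test_that("indicator-column coefficients are weighted class means", {
  df <- data.frame(
    value = c(2, 4, 10, 20, 5),
    class = factor(c("gain", "gain", "loss", "loss", "none")),
    weight = c(1, 1, 0.5, 1, 1)
  )
  fit <- wls_origin(df, value ~ class + 0, weights = "weight")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "classgain"], 3) # unweighted mean here
  expect_equal(td$estimate[td$term == "classloss"],
               (0.5 * 10 + 1 * 20) / 1.5)
  expect_equal(td$estimate[td$term == "classnone"], 5)
  # an intercept is removed with a message
  expect_message(wls_origin(df, value ~ class, weights = "weight"),
                 "origin")
  # degenerate all-zero response
  df0 <- data.frame(value = 0, class = factor(rep(c("a", "b"), 3)))
  fit0 <- wls_origin(df0, value ~ class + 0)
  expect_true(all(tidy(fit0)$estimate == 0))
  expect_true(all(tidy(fit0)$p.value == 1))
  # guards
  expect_error(wls_origin(df[0, ], value ~ class + 0), "empty")
  df$x1 <- rnorm(5)
  df$x2 <- 2 * df$x1
  expect_error(wls_origin(df, value ~ x1 + x2 + 0), "Rank-deficient")
})

test_that("Geweke diagnostic is calibrated on iid chains and catches trends", {
  set.seed(8)
  z <- replicate(60, geweke_diag(rnorm(2000)))
  expect_gt(mean(abs(z) < 1.96), 0.85) # ~95% nominal
  # a drifting chain fails loudly
  expect_gt(abs(geweke_diag(seq(0, 5, length.out = 2000) +
                              rnorm(2000, sd = 0.1))), 5)
  expect_warning(zc <- geweke_diag(rep(1, 100)), "Constant")
  expect_true(is.nan(zc))
  expect_error(geweke_diag(rnorm(10)), "20")
})

test_that("phylogenetic mixed model recovers fixed effects and respects mev", {
  set.seed(101)
  tr <- ape::rcoal(25)
  n <- 25
  x <- rnorm(n)
  beta_true <- 1.5
  df <- data.frame(node = 1:25, x = x,
                   y = beta_true * x + rnorm(n, sd = 0.5))
  fit <- phylo_mixed(df, y ~ x, tr, node_col = "node",
                     n_iter = 6000, thin = 5, burnin = 1000, seed = 2)
  td <- tidy(fit)
  est <- td[td$term == "x", ]
  expect_lt(abs(est$estimate - beta_true), 0.5)
  expect_true(est$conf.low < beta_true && beta_true < est$conf.high)
  # bit-identical chains under the same seed
  fit2 <- phylo_mixed(df, y ~ x, tr, node_col = "node",
                      n_iter = 6000, thin = 5, burnin = 1000, seed = 2)
  expect_identical(fit$chains$beta, fit2$chains$beta)

  # inflating one observation's mev wipes out its influence on beta
  df2 <- df
  df2$y[1] <- df2$y[1] + 50 # gross outlier
  df2$mev <- 0
  f_raw <- phylo_mixed(df2, y ~ x, tr, node_col = "node", mev = "mev",
                       n_iter = 4000, thin = 5, burnin = 500, seed = 3)
  df3 <- df2
  df3$mev[1] <- 1e6
  f_damped <- phylo_mixed(df3, y ~ x, tr, node_col = "node", mev = "mev",
                          n_iter = 4000, thin = 5, burnin = 500, seed = 3)
  b_raw <- tidy(f_raw)$estimate[2]
  b_damped <- tidy(f_damped)$estimate[2]
  # the damped fit must sit closer to the truth than the contaminated one
  expect_lt(abs(b_damped - beta_true), abs(b_raw - beta_true))
  # diagnostics exported
  expect_true(all(is.finite(fit$geweke)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_chains(fit, p)
  expect_equal(nrow(readr::read_csv(p, show_col_types = FALSE)),
               nrow(fit$chains$beta))
})

test_that("binary Mk pruning equals enumeration and EB nests the constant model", {
  set.seed(55)
  tr <- ape::rtree(4)
  x <- setNames(c(0L, 1L, 1L, 0L), tr$tip.label)
  for (r in c(0.05, 0.4, 2)) {
    expect_equal(hostshift:::mk2_loglik(tr, unname(x[tr$tip.label]), r),
                 oracle_mk(tr, unname(x[tr$tip.label]), r),
                 tolerance = 1e-8)
  }
  # EB with a = 0 is exactly the constant model
  tru <- ape::rcoal(40)
  xx <- setNames(rbinom(40, 1, 0.5), tru$tip.label)
  cst <- fit_mk(tru, xx, "constant")
  ll_eb0 <- -hostshift:::mk2_loglik(hostshift:::eb_rescale(tru, 0), xx[tru$tip.label], cst$rate)
  expect_equal(-ll_eb0, cst$loglik, tolerance = 1e-10)
  eb <- fit_mk(tru, xx, "early_burst")
  expect_gte(eb$loglik, cst$loglik - 1e-6)
  expect_lte(eb$a, 0)

  # invariant trait flagged at the boundary
  expect_warning(inv <- fit_mk(tru, setNames(rep(1L, 40), tru$tip.label),
                               "constant"), "Invariant")
  expect_true(inv$boundary)
})

test_that("likelihood-ratio test follows the chi-square reference", {
  expect_equal(lr_test(-10, -10)$statistic, 0)
  expect_equal(lr_test(-10, -10)$p.value, 1)
  expect_equal(lr_test(0, 3.841 / 2, df = 1)$p.value, 0.05, tolerance = 1e-3)
  expect_error(lr_test(-5, -9), "nested")
  expect_error(lr_test(-5, -4, df = 0), "df")
})

test_that("early-burst screen reports one testable row per variable host", {
  set.seed(66)
  tr <- ape::rcoal(30)
  hosts <- setNames(lapply(1:30, function(i)
    sample(c("F1", "F2"), sample(1:2, 1))), tr$tip.label)
  scr <- eb_screen(tr, hosts)
  expect_true(all(scr$p.value >= 0 & scr$p.value <= 1))
  expect_true(all(scr$loglik_eb >= scr$loglik_constant - 1e-6))
  expect_lte(nrow(scr), 2)
})
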