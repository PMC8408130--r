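test_that("ensemble bookkeeping matches the configuration", {
  cfg <- ensemble_config(S_grid = 10, C_grid = 0.12, d_grid = 0.01,
                         z_grid = 0, webs_per_cell = 1, master_seed = 3)
  res <- run_ensemble(cfg)
  expect_equal(nrow(res), 1)
  expect_equal(nrow(attr(res, "failures")), 0)

  cfg2 <- ensemble_config(S_grid = c(10, 12), C_grid = c(0.12, 0.14),
                          d_grid = c(0.01, 0.1), z_grid = c(-0.5, 0.5),
                          webs_per_cell = 1, master_seed = 3)
  res2 <- run_ensemble(cfg2)
  expect_equal(nrow(res2), 2 * 2 * 2 * 2)
  expect_true(all(res2$stable == (res2$lambda1 < 0)))
  expect_true(all(res2$prop_local_stable %in% ((0:10) / 10)))
})

test_that("ensembles are bit-reproducible under the master seed", {
  cfg <- ensemble_config(S_grid = c(10, 14), C_grid = 0.16,
                         d_grid = c(0.001, 0.1), z_grid = c(-0.25, 0.25),
                         webs_per_cell = 2, n_perm = 5, master_seed = 77)
  a <- run_ensemble(cfg)
  b <- run_ensemble(cfg)
  expect_identical(a, b)
})

test_that("grid values outside the study ranges are rejected", {
  expect_error(ensemble_config(S_grid = 5))
  expect_error(ensemble_config(C_grid = 0.4))
  expect_error(ensemble_config(d_grid = 2))
  expect_error(ensemble_config(z_grid = 1))
})

test_that("stability fractions by bin match a hand tally", {
  fixture <- data.frame(
    d = 0.1, z = 0,
    prop_local_stable = c(0.5, 0.5, 0.5, 0.5, 1, 1, 1, 0.2, 0.2, 0.2),
    stable = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE,
               FALSE, FALSE, TRUE))
  tab <- stability_by_local_proportion(fixture)
  expect_equal(nrow(tab), 3)
  half <- tab[tab$prop_local_stable == 0.5, ]
  expect_equal(half$n, 4)
  expect_equal(half$frac_stable, 0.5)
  expect_equal(half$sem, sqrt(0.5 * 0.5 / 4))
  expect_equal(tab[tab$prop_local_stable == 1, ]$frac_stable, 1)
  expect_equal(tab[tab$prop_local_stable == 0.2, ]$frac_stable, 1 / 3)
  # all-unstable records give zero everywhere
  fixture$stable <- FALSE
  tab0 <- stability_by_local_proportion(fixture)
  expect_true(all(tab0$frac_stable == 0))
})

test_that("more locally stable patches raise metacommunity stability", {
  cfg <- ensemble_config(S_grid = 10, C_grid = 0.12, d_grid = 0.01,
                         z_grid = 0, webs_per_cell = 150, master_seed = 8)
  res <- run_ensemble(cfg)
  # record-level association; bin-level curves are checked at study scale
  expect_gt(cor(res$prop_local_stable, res$stable), 0.2)
  tab <- stability_by_local_proportion(res)
  big <- tab[tab$n >= 10, ]
  expect_gt(cor(big$prop_local_stable, big$frac_stable), 0)
})

test_that("the GLM machinery recovers known logistic coefficients", {
  set.seed(461)
  truth <- c(x1 = 1, x2 = -1, x3 = 0.5)
  hits <- 0
  for (rep in 1:5) {
    n <- 5000
    dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      x4 = rnorm(n))
    eta <- -0.3 + dat$x1 * truth["x1"] + dat$x2 * truth["x2"] +
      dat$x3 * truth["x3"]
    dat$stable <- runif(n) < plogis(eta)
    fit <- fit_stability_glm(dat, candidates = c("x1", "x2", "x3", "x4"),
                             standardize = FALSE)
    est <- fit$coefficients
    for (nm in names(truth)) {
      expect_lt(abs(est[nm, "Estimate"] - truth[nm]),
                3 * est[nm, "Std. Error"])
    }
    if (setequal(fit$best_terms, names(truth))) hits <- hits + 1
  }
  expect_gte(hits, 3)   # true support selected in the majority of replicates
})

test_that("a response independent of the predictors selects the null model", {
  set.seed(462)
  hits <- 0
  for (rep in 1:15) {
    n <- 1000
    dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                      stable = runif(n) < 0.4)
    fit <- suppressWarnings(
      fit_stability_glm(dat, candidates = c("x1", "x2")))
    if (length(fit$best_terms) == 0) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("AIC bookkeeping is internally consistent", {
  set.seed(463)
  n <- 200
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  dat$stable <- runif(n) < plogis(dat$x1)
  fit <- fit_stability_glm(dat, candidates = c("x1", "x2"))
  # AIC = 2k - 2 log-likelihood for the selected fit
  expect_equal(AIC(fit$fit),
               2 * length(coef(fit$fit)) - 2 * as.numeric(logLik(fit$fit)))
  best_row <- fit$aic_table[1, ]
  expect_equal(best_row$aic, AIC(fit$fit))
  expect_true(all(diff(fit$aic_table$aic) >= 0))
  # constant predictors are dropped with a warning
  dat$x3 <- 1
  expect_warning(fit_stability_glm(dat, candidates = c("x1", "x3")),
                 "constant")
})

test_that("GLM preconditions are enforced", {
  small <- data.frame(x1 = rnorm(10), stable = rep(c(TRUE, FALSE), 5))
  expect_error(fit_stability_glm(small, candidates = "x1"))
  onesided <- data.frame(x1 = rnorm(100), stable = TRUE)
  expect_error(fit_stability_glm(onesided, candidates = "x1"))
})

test_that("YAML configurations round trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("S_grid: [10, 20]", "C_grid: [0.12, 0.18]",
               "d_grid: [0.001, 0.1]", "z_grid: [-0.5, 0.5]",
               "webs_per_cell: 2", "master_seed: 42"), path)
  cfg <- read_ensemble_config(path)
  expect_equal(cfg$S_grid, c(10, 20))
  expect_equal(cfg$webs_per_cell, 2)
  expect_equal(cfg$N, 10)           # defaults fill the rest
  writeLines("bogus_key: 1", path)
  expect_error(read_ensemble_config(path), "unknown configuration")
})

test_that("derived seeds are deterministic, distinct and within range", {
  s <- vapply(1:1000, function(i) derive_seed(123, i), 1L)
  expect_equal(length(unique(s)), 1000)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(derive_seed(123, 7), derive_seed(123, 7))
})
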