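test_that("marginal cell log-likelihood matches closed forms and quadrature", {
  # single geometric component: P(N=0) = beta/(beta+E) = 1/2
  expect_equal(marginal_cell_loglik(0, 1, gps_model(1, 1, 2, 4, 1)), log(0.5))

  # normalization: probabilities over n sum to one
  th <- canonical_theta()
  for (e in c(0.5, 3, 20)) {
    total <- sum(exp(marginal_cell_loglik(0:5000, rep(e, 5001), th)))
    expect_gte(total, 1 - 1e-8)
    expect_lte(total, 1 + 1e-8)
  }

  # quadrature oracle at a representative cell
  direct <- integrate(oracle_post_density, 0, Inf, n = 7, e = 10, th = th,
                      rel.tol = 1e-12, abs.tol = 0)$value
  expect_equal(marginal_cell_loglik(7, 10, th), log(direct), tolerance = 1e-8)

  # numerically stable at large counts
  expect_true(is.finite(marginal_cell_loglik(1e5, 9e4, th)))
  expect_error(marginal_cell_loglik(3, -1, th), "positive")
  expect_error(gps_model(0, 1, 1, 1, 0.5), "positive")
})

test_that("posterior weight reduces correctly and matches quadrature", {
  th <- canonical_theta()
  # identical components: data cannot update the mixture weight
  same <- gps_model(2, 3, 2, 3, 0.37)
  expect_equal(posterior_weight(c(0, 5, 50), rep(4, 3), same), rep(0.37, 3))
  # single-component models are degenerate at 0/1
  expect_equal(posterior_weight(10, 5, gps_model(1, 1, 2, 2, 1)), 1)
  expect_equal(posterior_weight(10, 5, gps_model(1, 1, 2, 2, 0)), 0)

  q0 <- posterior_weight(0, 10, th)
  q50 <- posterior_weight(50, 10, th)
  expect_equal(q0, oracle_qn(0, 10, th), tolerance = 1e-8)
  expect_equal(q50, oracle_qn(50, 10, th), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(q0, q50)))
})

test_that("EBGM matches quadrature and behaves as a shrinkage estimator", {
  th <- canonical_theta()
  expect_equal(ebgm_score(20, 10, th), oracle_ebgm(20, 10, th),
               tolerance = 1e-6)

  # digamma asymptotics: with a huge posterior shape the geometric mean
  # coincides with the posterior mean
  one <- gps_model(5, 2, 5, 2, 1)
  n <- 5000
  expect_equal(ebgm_score(n, 10, one) / ((5 + n) / (2 + 10)), 1,
               tolerance = 1e-3)

  # shrinkage vanishes for large counts at fixed true ratio n/E
  ratio <- vapply(c(10, 100, 1000), function(e) {
    n <- 3 * e
    ebgm_score(n, e, th) / relative_reporting_ratio(n, e)
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
  expect_equal(ratio[3], 1, tolerance = 0.01)

  # small-count shrinkage pulls log scores toward zero for elevated cells
  set.seed(31)
  e <- runif(200, 1, 3)
  n <- rpois(200, 4 * e) + 1
  rr <- relative_reporting_ratio(n, e)
  keep <- rr > 1.5
  expect_true(all(abs(log(ebgm_score(n, e, th)[keep])) < abs(log(rr[keep]))))
})

test_that("posterior quantiles solve the mixture CDF and bracket EBGM", {
  th <- canonical_theta()
  # single component: plain gamma quantile
  one <- gps_model(2, 3, 9, 9, 1)
  expect_equal(eb_quantile(7, 4, one, 0.05),
               qgamma(0.05, shape = 9, rate = 7), tolerance = 1e-8)

  # self-consistency: mixture CDF evaluated at the returned quantile
  for (p in c(0.05, 0.5, 0.95)) {
    q <- eb_quantile(20, 10, th, p)
    qn <- posterior_weight(20, 10, th)
    cdf <- qn * pgamma(q, th$alpha1 + 20, rate = th$beta1 + 10) +
      (1 - qn) * pgamma(q, th$alpha2 + 20, rate = th$beta2 + 10)
    expect_equal(cdf, p, tolerance = 1e-7)
  }
  expect_equal(eb_quantile(20, 10, th, 0.05),
               oracle_eb_quantile(20, 10, th, 0.05), tolerance = 1e-6)

  # order property on a grid of random cells
  set.seed(32)
  n <- rpois(1000, 8)
  e <- runif(1000, 0.5, 30)
  eb05 <- eb_quantile(n, e, th, 0.05)
  eb95 <- eb_quantile(n, e, th, 0.95)
  ebgm <- ebgm_score(n, e, th)
  expect_true(all(eb05 < ebgm & ebgm < eb95))

  expect_error(eb_quantile(5, 5, th, 1), "probability")
  expect_error(eb_quantile(5, 5, th, 0), "probability")
})

test_that("GPS fits are deterministic and flag degenerate mixtures", {
  cfg <- sim_config(n_drugs = 20, n_ades = 30, blocks = list(),
                    drug_scale = rep(3, 20), ade_scale = rep(3, 30), seed = 33)
  sim <- gen_gps_counts(cfg)
  f1 <- fit_gps(sim$counts, seed = 7)
  f2 <- fit_gps(sim$counts, seed = 7)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$model, f2$model)
  expect_true(all(tidy(f1)$estimate > 0))

  # single-gamma data: the two fitted components collapse (equal means)
  # or the weight runs to its boundary; either way the fit is degenerate
  single <- sim_config(n_drugs = 20, n_ades = 40, blocks = list(),
                       theta_true = gps_model(2, 2, 2, 2, 1),
                       drug_scale = rep(3, 20), ade_scale = rep(3, 40),
                       seed = 34)
  fs <- fit_gps(gen_gps_counts(single)$counts, seed = 8)
  m <- fs$model
  # degenerate signatures: the weight runs to a boundary, or the two
  # fitted components collapse onto the same prior mean
  collapsed <- abs(m$alpha1 / m$beta1 - m$alpha2 / m$beta2) < 0.2
  expect_true(fs$boundary || collapsed)

  expect_error(fit_gps(subset_counts(sim$counts, drugs = sim$counts$drugs[1])),
               "at least")
})

test_that("score_table matches per-cell operations, including zero counts", {
  cfg <- sim_config(n_drugs = 12, n_ades = 9, blocks = list(),
                    drug_scale = rep(1, 12), ade_scale = rep(1, 9), seed = 36)
  sim <- gen_gps_counts(cfg)
  th <- canonical_theta()
  st <- score_table(sim$counts, th)
  expect_identical(nrow(st), 12L * 9L)

  zero <- st[st$n == 0, ]
  expect_gt(nrow(zero), 0)
  expect_true(all(is.finite(zero$ebgm)))
  expect_equal(zero$ebgm, ebgm_score(0, zero$e, th))

  i <- which(st$n == max(st$n))[1]
  expect_identical(st$rr[i], relative_reporting_ratio(st$n[i], st$e[i]))
  expect_identical(st$qn[i], posterior_weight(st$n[i], st$e[i], th))
  expect_identical(st$ebgm[i], ebgm_score(st$n[i], st$e[i], th))
  expect_identical(st$eb05[i], eb_quantile(st$n[i], st$e[i], th, 0.05))

  # table-wide scoring stays fast at the 500 x 30 scale
  big <- sim_config(n_drugs = 500, n_ades = 30, blocks = list(),
                    drug_scale = rep(3, 500), ade_scale = rep(3, 30), seed = 37)
  simb <- gen_gps_counts(big)
  elapsed <- system.time(score_table(simb$counts, th))[["elapsed"]]
  expect_lt(elapsed, 5)
})

test_that("relative reporting ratio follows its definition and guards E", {
  expect_equal(relative_reporting_ratio(200, 2), 100)
  expect_equal(relative_reporting_ratio(5, 5), 1)
  expect_equal(relative_reporting_ratio(0, 3), 0)
  expect_error(relative_reporting_ratio(3, 0), "positive")
})

test_that("PCA of log expected counts is a proper centered decomposition", {
  set.seed(38)
  # rank-one positive matrix: first component carries all the variance
  r1 <- exp(outer(rnorm(20), rep(1, 6)) + outer(rep(1, 20), rnorm(6)))
  p1 <- pca_log_expected(r1)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-10)

  m <- matrix(exp(rnorm(134 * 25)), 134, 25)
  pc <- pca_log_expected(m)
  expect_equal(sum(pc$var_explained), 1)
  cross <- crossprod(pc$scores[, 1:5])
  expect_lt(max(abs(cross - diag(diag(cross)))), 1e-8)

  expect_error(pca_log_expected(matrix(c(1, -2, 3, 4), 2)), "positive")
})
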