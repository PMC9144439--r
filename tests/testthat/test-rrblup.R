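test_that("an all-zero Z collapses to ordinary least squares", {
  set.seed(1)
  y <- rnorm(20)
  Z <- matrix(0, 20, 5)
  fit <- rrblup(y, Z)
  expect_true(fit$boundary)
  expect_equal(unname(fit$u), rep(0, 5))
  expect_equal(unname(fit$beta), mean(y))
  expect_equal(fit$var_u, 0)
  expect_equal(unname(fitted(fit)), rep(mean(y), 20))
  expect_equal(unname(predict(fit, Z)), rep(0, 20))
})

test_that("identical marker columns receive identical effect estimates", {
  inst <- random_instance(40, 10, h2 = 0.6, seed = 2)
  Z <- cbind(inst$Z, inst$Z[, 3])
  fit <- rrblup(inst$y, Z)
  expect_equal(fit$u[3], fit$u[11], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("REML optimum matches the direct-likelihood grid oracle", {
  grid <- seq(-8, 8, length.out = 101)
  step <- diff(grid)[1]
  for (s in 1:5) {
    inst <- random_instance(50, 30, h2 = 0.5, seed = 100 + s)
    fit <- rrblup(inst$y, inst$Z)
    oracle <- reml_grid_argmax(inst$y, inst$Z, grid)
    expect_lte(abs(fit$log_lambda - oracle), step + 1e-9)
    # the solver's optimum is at least as good as every oracle grid point,
    # comparing on the oracle's own likelihood surface
    ll_solver <- reml_ll_direct(fit$log_lambda, inst$y, inst$Z)
    ll_best_grid <- reml_ll_direct(oracle, inst$y, inst$Z)
    expect_gte(ll_solver, ll_best_grid - 1e-6)
  }
})

test_that("marker-effect and kernel (GBLUP) predictions agree", {
  for (s in 1:5) {
    inst <- random_instance(45, 60, h2 = 0.5, seed = 200 + s)
    tr <- 1:35; te <- 36:45
    Ztr <- inst$Z[tr, ]; Zte <- inst$Z[te, ]
    fit <- rrblup(inst$y[tr], Ztr)
    p_marker <- predict(fit, Zte)
    p_kernel <- gblup_predict(inst$y[tr], Ztr, Zte, fit$lambda, fit$beta[[1]])
    expect_equal(unname(p_marker), p_kernel, tolerance = 1e-8)
  }
})

test_that("phenotype scaling scales effects and leaves lambda and r unchanged", {
  inst <- random_instance(50, 25, h2 = 0.5, seed = 31)
  tr <- 1:40; te <- 41:50
  f1 <- rrblup(inst$y[tr], inst$Z[tr, ])
  f2 <- rrblup(5 * inst$y[tr], inst$Z[tr, ])
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-5)
  expect_equal(unname(f2$beta), 5 * unname(f1$beta), tolerance = 1e-6)
  expect_equal(unname(f2$u), 5 * unname(f1$u), tolerance = 1e-6)
  p1 <- predict(f1, inst$Z[te, ])
  p2 <- predict(f2, inst$Z[te, ])
  expect_equal(predictive_ability(p2, 5 * inst$y[te]),
               predictive_ability(p1, inst$y[te]), tolerance = 1e-6)
})

test_that("predictions behave on reference points of the centered scale", {
  inst <- random_instance(40, 15, h2 = 0.7, seed = 41)
  fit <- rrblup(inst$y, inst$Z)
  # an accession identical to a training accession gets its fitted genetic value
  expect_equal(predict(fit, inst$Z[7, , drop = FALSE]),
               drop(inst$Z[7, ] %*% fit$u), ignore_attr = TRUE)
  # the population-mean genotype has GEBV zero
  expect_equal(unname(predict(fit, matrix(0, 1, 15))), 0)
  # intercept shifts phenotype-scale predictions only
  expect_equal(unname(predict(fit, inst$Z[1:3, ], include_fixed = TRUE)),
               unname(predict(fit, inst$Z[1:3, ])) + fit$beta[[1]])
})

test_that("degenerate inputs are rejected or flagged", {
  Z <- matrix(rnorm(30), 10, 3)
  expect_error(rrblup(rnorm(9), Z), "nrow")
  expect_error(rrblup(c(rnorm(9), NA), Z), "missing")
  expect_error(rrblup(rnorm(10), Z, X = cbind(1, 1)[rep(1, 10), ]),
               "rank deficient")
  expect_warning(fit <- rrblup(rep(2, 10), Z), "zero variance")
  expect_true(fit$boundary)
  expect_equal(unname(fit$u), rep(0, 3))
})

test_that("the shared-decomposition multi-trait engine matches per-trait rrblup fits", {
  set.seed(61)
  inst1 <- random_instance(50, 40, h2 = 0.6, seed = 61)
  inst2 <- random_instance(50, 40, h2 = 0.3, seed = 62)
  Y <- cbind(t1 = inst1$y, t2 = inst2$y, flat = rep(1, 50))
  tr <- 1:38; te <- 39:50
  eng <- structgp:::rrblup_engine(Y[tr, ], inst1$Z[tr, ], inst1$Z[te, ])
  for (t in 1:2) {
    fit <- rrblup(Y[tr, t], inst1$Z[tr, ])
    expect_equal(eng$lambda[t], fit$lambda, tolerance = 1e-6)
    expect_equal(eng$var_u[t], fit$var_u, tolerance = 1e-6)
    expect_equal(unname(eng$gebv[, t]), unname(predict(fit, inst1$Z[te, ])),
                 tolerance = 1e-6)
  }
  # a zero-variance trait degrades to a zero GEBV instead of erroring
  expect_equal(unname(eng$gebv[, 3]), rep(0, 12))
})

test_that("simulate() regenerates phenotypes with the fitted variance structure", {
  inst <- random_instance(60, 40, h2 = 0.6, seed = 51)
  fit <- rrblup(inst$y, inst$Z)
  sims <- simulate(fit, nsim = 30, seed = 99)
  expect_equal(dim(sims), c(60, 30))
  v_emp <- mean(apply(sims, 2, var))
  v_model <- fit$var_u * fit$tr_K / fit$n + fit$var_e
  expect_lt(abs(v_emp / v_model - 1), 0.5)
})
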