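test_that("unconstrained MLE recovers generating parameters and is stationary", {
  spec <- scenario_spec("I")
  set.seed(41)
  dat <- simulate_cohort(spec, 1e5, "target")
  co <- cml_cohort(dat$y, dat[c("x1", "x2", "x3", "x4")], dat$z)
  m <- cml_mle(co)
  expect_lt(m$grad_norm, 1e-6)
  # recovery within 3 reported standard errors
  fit <- structure(list(theta_hat = m$theta), class = "cml_fit")
  fit$active_plus <- integer(0); fit$active_minus <- integer(0)
  co_small <- co
  inf <- cmlrisk:::unconstrained_inference(fit, co_small, "categorized")
  truth <- as.numeric(cml_theta(spec$beta0, spec$beta_x, spec$beta_z,
                                spec$tau_mean, spec$sigma))
  expect_true(all(abs(as.numeric(m$theta) - truth) <= 3 * inf$ase))
})

test_that("logistic block agrees with an independent IRLS solver", {
  co <- cohort_fixture(800, seed = 42)
  m <- cml_mle(co)
  # hand-written iteratively reweighted least squares
  X <- cbind(1, co$x, co$z_cat)
  b <- rep(0, ncol(X))
  for (it in 1:50) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    zv <- eta + (co$y - mu) / w
    b_new <- solve(crossprod(X, w * X), crossprod(X, w * zv))
    if (max(abs(b_new - b)) < 1e-12) { b <- b_new; break }
    b <- b_new
  }
  got <- as.numeric(m$theta)[1:6]
  expect_equal(got, drop(b), tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(cml_mle(cml_cohort(rep(1, 5), matrix(rnorm(10), 5),
                                  runif(5, 0.1, 0.9))), "classes")
})

test_that("vacuous constraints reproduce the unconstrained solution", {
  fx <- cml_fit_fixture()
  cs_loose <- cml_constraints(fx$fx$intervals, fx$fx$targets, d = 1e6)
  fit <- fit_cml(fx$cohort, cs_loose, fx$fx$pop, fx$fx$base)
  mle <- cml_mle(fx$cohort)
  expect_true(all(abs(as.numeric(fit$theta_hat) -
                        as.numeric(mle$theta)) < 1e-5))
  expect_length(fit$active_plus, 0)
  expect_length(fit$active_minus, 0)
})

test_that("constrained solution satisfies the KKT contract", {
  fx <- cml_fit_fixture()
  fit <- fx$fit
  expect_true(fit$converged)
  cv <- fit$constraint_values
  vals <- c(cv$cplus, cv$cminus)
  expect_lte(max(vals[is.finite(vals)]), 1e-8)
  # stationarity of the full-scale likelihood gradient against the
  # multiplier-weighted constraint gradients, with nonnegative multipliers
  ctx <- cmlrisk:::constraint_context(fx$cs, fx$fx$pop, fx$fx$base,
                                      "categorized")
  g <- cml_score(fit$theta_hat, fx$cohort)$gradient
  J <- cmlrisk:::constraint_jacobian(fit$theta_hat, ctx)
  lam_full <- fit$lambda * fx$cohort$n
  expect_true(all(fit$lambda >= 0))
  expect_lt(max(abs(g - drop(lam_full %*% J))), 1e-5)
  # complementary slackness
  cc <- cmlrisk:::constraint_vector(fit$theta_hat, ctx)
  expect_lt(max(abs(fit$lambda * cc)), 1e-6)
  # the constrained optimum cannot beat the unconstrained one
  expect_lte(fit$loglik, fit$loglik_unconstrained + 1e-8)
})

test_that("no feasible grid point on the (beta0, beta_z) slice beats the fit", {
  fx <- cml_fit_fixture()
  fit <- fx$fit
  ctx <- cmlrisk:::constraint_context(fx$cs, fx$fx$pop, fx$fx$base,
                                      "categorized")
  v0 <- as.numeric(fit$theta_hat)
  b0s <- v0[1] + seq(-0.25, 0.25, length.out = 41)
  bzs <- v0[6] + seq(-0.25, 0.25, length.out = 41)
  best <- -Inf
  for (b0 in b0s) for (bz in bzs) {
    v <- v0; v[1] <- b0; v[6] <- bz
    th <- theta_from_vector(v, fit$theta_hat)
    if (max(cmlrisk:::constraint_vector(th, ctx)) <= 0) {
      ll <- cml_loglik(th, fx$cohort)
      if (ll > best) best <- ll
    }
  }
  # grid resolution slack: the grid cannot exceed the optimum materially
  expect_lte(best, fit$loglik + 1e-6)
})

test_that("loglik is nondecreasing as the tolerance relaxes", {
  fx <- cml_fit_fixture()
  lls <- vapply(c(0.05, 0.1, 0.5, 10), function(dd) {
    cs <- cml_constraints(fx$fx$intervals, fx$fx$targets, d = dd)
    fit_cml(fx$cohort, cs, fx$fx$pop, fx$fx$base)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-7))
  expect_equal(lls[4], cml_mle(fx$cohort)$loglik, tolerance = 1e-8)
})

test_that("active sets are identified and disjoint", {
  fx <- cml_fit_fixture()
  # interior solution: nothing active
  cs_loose <- cml_constraints(fx$fx$intervals, fx$fx$targets, d = 1e6)
  fit_loose <- fit_cml(fx$cohort, cs_loose, fx$fx$pop, fx$fx$base)
  as_loose <- active_set(fit_loose)
  expect_length(as_loose$plus, 0)
  expect_length(as_loose$minus, 0)
  # shifting targets below the model risk pins the upper bound
  mle <- cml_mle(fx$cohort)
  er <- expected_model_risk(mle$theta, fx$fx$pop, fx$fx$intervals,
                            fx$fx$base)
  cs_low <- cml_constraints(fx$fx$intervals, 0.9 * er, d = 0.05)
  fit_low <- fit_cml(fx$cohort, cs_low, fx$fx$pop, fx$fx$base)
  as_low <- active_set(fit_low)
  expect_gt(length(as_low$plus), 0)
  expect_length(intersect(as_low$plus, as_low$minus), 0)
  # disabled intervals are never active
  cs_dis <- cml_constraints(fx$fx$intervals, 0.9 * er,
                            d = c(0.05, Inf, Inf, 0.05))
  fit_dis <- fit_cml(fx$cohort, cs_dis, fx$fx$pop, fx$fx$base)
  expect_true(all(!active_set(fit_dis)$plus %in% c(2, 3)))
})

test_that("identical inputs give identical fits; infeasible bands error", {
  fx <- cml_fit_fixture()
  f1 <- fit_cml(fx$cohort, fx$cs, fx$fx$pop, fx$fx$base)
  f2 <- fit_cml(fx$cohort, fx$cs, fx$fx$pop, fx$fx$base)
  expect_identical(as.numeric(f1$theta_hat), as.numeric(f2$theta_hat))
  # targets far outside anything the model can reach, with a tiny band
  iv <- fx$fx$intervals
  cs_bad <- cml_constraints(iv, pmin(fx$fx$targets * c(0.2, 5, 0.2, 5),
                                     0.99), d = 1e-6)
  expect_error(fit_cml(fx$cohort, cs_bad, fx$fx$pop, fx$fx$base),
               "feasible")
})

test_that("freezing the conditional model only moves the beta block", {
  fx <- cml_fit_fixture()
  ctl <- cml_control(freeze_tau = TRUE)
  fit <- fit_cml(fx$cohort, fx$cs, fx$fx$pop, fx$fx$base, control = ctl)
  mle <- cml_mle(fx$cohort)
  v_f <- as.numeric(fit$theta_hat)
  v_m <- as.numeric(mle$theta)
  expect_identical(v_f[7:12], v_m[7:12])
  cv <- fit$constraint_values
  vals <- c(cv$cplus, cv$cminus)
  expect_lte(max(vals[is.finite(vals)]), 1e-8)
})
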