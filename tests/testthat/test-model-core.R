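test_that("logistic risk matches the direct expit formula", {
  th <- theta_fixture()
  # all-zero parameters give risk 1/2 everywhere
  th0 <- cml_theta(0, rep(0, 4), 0, rep(0, 5), 1)
  expect_equal(logistic_risk(th0, c(3, 1, 0, 2), 7), 0.5)
  # baseline covariate pattern isolates the intercept
  expect_equal(logistic_risk(th, c(0, 0, 0, 0), 0), plogis(-2.4))
  # random parameter/covariate draws against an independent evaluation
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(12); v[12] <- abs(v[12]) + 0.1
    thr <- theta_from_vector(v, th)
    x <- rnorm(4); z <- rnorm(1)
    eta <- v[1] + sum(v[2:5] * x) + v[6] * z
    expect_equal(logistic_risk(thr, x, z), exp(eta) / (1 + exp(eta)),
                 tolerance = 1e-12)
  }
  expect_error(logistic_risk(th, c(1, 2), 0), "beta_x")
})

test_that("truncated log-normal density normalizes and matches closed forms", {
  # integrates to one over (0, 1)
  for (pars in list(c(-2, 0.6), c(0, 1), c(-0.3, 0.4), c(1, 2))) {
    I <- integrate(function(z) dtrunclognorm(z, pars[1], pars[2]),
                   0, 1, rel.tol = 1e-10)
    expect_equal(I$value, 1, tolerance = 1e-8)
  }
  # closed form at u = 0, sigma = 1, z = exp(-1): Phi(0) = 1/2
  z0 <- exp(-1)
  expect_equal(dtrunclognorm(z0, 0, 1, log = TRUE),
               log(dnorm(-1) / (z0 * 0.5)), tolerance = 1e-12)
  # density equals the numerical derivative of the truncated CDF
  ptrunc <- function(q, u, s) pnorm((log(q) - u) / s) / pnorm(-u / s)
  set.seed(2)
  for (i in 1:10) {
    u <- rnorm(1); s <- runif(1, 0.3, 1.5); z <- runif(1, 0.05, 0.95)
    h <- 1e-6
    expect_equal(dtrunclognorm(z, u, s),
                 (ptrunc(z + h, u, s) - ptrunc(z - h, u, s)) / (2 * h),
                 tolerance = 1e-5)
  }
  expect_error(dtrunclognorm(1, 0, 1), "support")
  expect_error(dtrunclognorm(0, 0, 1), "support")
})

test_that("decile category probabilities partition the support", {
  expect_equal(sum(zcat_probs(-0.5, 0.8)), 1, tolerance = 1e-10)
  expect_equal(rowSums(zcat_probs(c(-3, 0, 2), 0.7)), rep(1, 3),
               tolerance = 1e-10)
  # extreme negative mean concentrates all mass in category 0
  expect_equal(zcat_probs(-30, 0.6)[1], 1, tolerance = 1e-12)
  # category probabilities agree with quadrature of the density
  for (pars in list(c(-2, 0.6), c(-0.5, 1.1))) {
    pr <- zcat_probs(pars[1], pars[2])
    qr <- vapply(0:9, function(t)
      integrate(function(z) dtrunclognorm(z, pars[1], pars[2]),
                t / 10, (t + 1) / 10, rel.tol = 1e-10)$value, numeric(1))
    expect_equal(pr, qr, tolerance = 1e-6)
  }
  # and with Monte-Carlo frequencies of truncated draws
  set.seed(3)
  u <- -1.2; s <- 0.9
  z <- rtrunclognorm(1e6, rep(u, 1e6), s)
  freq <- tabulate(pmin(floor(10 * z), 9) + 1L, 10) / 1e6
  pr <- zcat_probs(u, s)
  se <- sqrt(pr * (1 - pr) / 1e6)
  expect_true(all(abs(freq - pr) <= 3 * se + 1e-12))
})

test_that("log-likelihood composes logistic and conditional-density terms", {
  th <- cml_theta(0, rep(0, 4), 0, rep(0, 5), 1)
  co1 <- cml_cohort(1, matrix(c(1, 0, 2, 1), 1), 0.4)
  expect_equal(cml_loglik(th, co1),
               -log(2) + dtrunclognorm(0.4, 0, 1, log = TRUE),
               tolerance = 1e-12)
  # additivity over disjoint blocks of rows
  co <- cohort_fixture(200)
  coA <- cml_cohort(co$y[1:80], co$x[1:80, ], co$z[1:80])
  coB <- cml_cohort(co$y[81:200], co$x[81:200, ], co$z[81:200])
  th2 <- theta_fixture()
  expect_equal(cml_loglik(th2, co), cml_loglik(th2, coA) +
                 cml_loglik(th2, coB), tolerance = 1e-10)
  # term-by-term oracle from the exported pieces
  set.seed(4)
  v <- rnorm(12); v[12] <- 0.7
  thr <- theta_from_vector(v, th2)
  co20 <- cml_cohort(co$y[1:20], co$x[1:20, ], co$z[1:20])
  ll <- 0
  for (i in 1:20) {
    g <- logistic_risk(thr, co20$x[i, ], co20$z_cat[i])
    u <- sum(thr$tau_mean * c(1, co20$x[i, ]))
    ll <- ll + co20$y[i] * log(g) + (1 - co20$y[i]) * log(1 - g) +
      dtrunclognorm(co20$z[i], u, thr$sigma, log = TRUE)
  }
  expect_equal(cml_loglik(thr, co20), ll, tolerance = 1e-10)
})

test_that("analytic score matches finite differences; Hessian symmetric", {
  co <- cohort_fixture(300)
  set.seed(5)
  for (i in 1:5) {
    v <- as.numeric(theta_fixture()) + rnorm(12, sd = 0.2)
    v[12] <- abs(v[12]) + 0.3
    th <- theta_from_vector(v, theta_fixture())
    g <- cml_score(th, co)$gradient
    gn <- num_grad(function(vv)
      cml_loglik(theta_from_vector(vv, th), co), v)
    expect_equal(g, gn, tolerance = 1e-5, ignore_attr = TRUE)
  }
  sh <- cml_score_hessian(theta_fixture(), co)
  expect_lt(max(abs(sh$hessian - t(sh$hessian))), 1e-8)
  # the Hessian is the derivative of the score
  Hn <- pracma::jacobian(function(vv)
    cml_score(theta_from_vector(vv, theta_fixture()), co)$gradient,
    as.numeric(theta_fixture()))
  expect_equal(sh$hessian, (Hn + t(Hn)) / 2, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("true parameters dominate perturbed ones on large samples", {
  spec <- scenario_spec("I")
  set.seed(6)
  dat <- simulate_cohort(spec, 2e4, "target")
  co <- cml_cohort(dat$y, dat[c("x1", "x2", "x3", "x4")], dat$z)
  th <- cml_theta(spec$beta0, spec$beta_x, spec$beta_z, spec$tau_mean,
                  spec$sigma)
  ll0 <- cml_loglik(th, co)
  v0 <- as.numeric(th)
  for (i in 1:20) {
    u <- rnorm(12); u <- u / sqrt(sum(u^2)) * 0.5
    vp <- v0 + u
    if (vp[12] <= 0.05) next
    expect_lt(cml_loglik(theta_from_vector(vp, th), co), ll0)
  }
})

test_that("cohort validation rejects boundary and malformed input", {
  expect_error(cml_cohort(c(0, 1), matrix(0, 2, 2), c(0.5, 1)), "0, 1")
  expect_error(cml_cohort(c(0, 2), matrix(0, 2, 2), c(0.5, 0.5)), "binary")
  co <- cml_cohort(c(0, 1), matrix(1:4, 2), c(0.05, 0.9999))
  expect_equal(co$z_cat, c(0, 9))
  expect_equal(cml_cohort(1, matrix(1, 1, 1), 0.31)$z_cat, 3)
})
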