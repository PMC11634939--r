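test_that("quantile intervals partition the base risk range", {
  # two equiprobable support points: the median cut yields a degenerate
  # first interval holding the minimum and a second covering the rest
  x <- cbind(x1 = c(0, 1))
  pop <- cml_population(x, c(0.5, 0.5))
  base <- cml_base_model(table = data.frame(x1 = c(0, 1),
                                            risk = c(0.1, 0.3)))
  iv <- risk_intervals(base, pop, probs = 0.5)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$lower, c(0.1, 0.1))
  expect_equal(iv$upper, c(0.1, 0.3))
  expect_equal(interval_avg_base_risk(base, pop, iv), c(0.1, 0.3))

  # quartiles of a 100-row synthetic table carry about 1/4 mass each
  set.seed(7)
  x100 <- cbind(x1 = sample(0:9, 100, TRUE), x2 = sample(0:4, 100, TRUE))
  x100 <- x100[!duplicated(x100), , drop = FALSE]
  w <- runif(nrow(x100)); w <- w / sum(w)
  pop100 <- cml_population(x100, w)
  risk <- plogis(-3 + 0.3 * x100[, 1] + 0.2 * x100[, 2] +
                   rnorm(nrow(x100), sd = 0.05))
  base100 <- cml_base_model(table = data.frame(x100, risk = risk))
  iv4 <- risk_intervals(base100, pop100)
  idx <- findInterval(risk, c(iv4$lower[1] - 1e-15, iv4$upper),
                      left.open = TRUE)
  mass <- vapply(1:4, function(r) sum(w[idx == r]), numeric(1))
  expect_equal(sum(mass), 1, tolerance = 1e-12)
  expect_true(all(abs(mass - 0.25) <= max(w) + 1e-12))

  # upper-tail percentile set gives four intervals, finer in the tail
  iv_tail <- risk_intervals(base100, pop100, probs = c(0.5, 0.7, 0.9))
  expect_equal(nrow(iv_tail), 4L)
  expect_true(all(iv_tail$lower[-1] == iv_tail$upper[-4]))

  expect_error(risk_intervals(cml_base_model(
    table = data.frame(x1 = c(0, 1), risk = c(0.2, 0.2))), pop),
    "degenerate")
})

test_that("interval-averaged base risk equals a two-pass weighted mean", {
  toy <- toy_population()
  iv <- data.frame(lower = c(0.05, 0.1), upper = c(0.1, 0.35))
  # singleton intervals return the support point's risk
  expect_equal(interval_avg_base_risk(toy$base, toy$pop, iv)[1], 0.05)
  set.seed(8)
  x <- cbind(x1 = seq_len(50))
  w <- runif(50); w <- w / sum(w)
  risk <- sort(runif(50, 0.01, 0.5))
  pop <- cml_population(x, w)
  base <- cml_base_model(table = data.frame(x, risk = risk))
  iv2 <- risk_intervals(base, pop)
  got <- interval_avg_base_risk(base, pop, iv2)
  idx <- interval_index(risk, iv2)
  for (r in 1:4) {
    inr <- which(idx == r)
    num <- 0; den <- 0
    for (i in inr) { num <- num + risk[i] * w[i]; den <- den + w[i] }
    expect_equal(got[r], num / den, tolerance = 1e-12)
    expect_gte(got[r], min(risk[inr]))
    expect_lte(got[r], max(risk[inr]))
  }
})

test_that("empirical benchmark reproduces loop-based counting", {
  iv <- data.frame(lower = c(0.0, 0.1), upper = c(0.1, 0.9))
  y <- rep(1, 10); risk <- seq(0.02, 0.88, length.out = 10)
  expect_equal(empirical_benchmark(y, risk, iv), c(1, 1))
  set.seed(9)
  y200 <- rbinom(200, 1, 0.3)
  r200 <- runif(200, 0.01, 0.89)
  got <- empirical_benchmark(y200, r200, iv)
  for (r in 1:2) {
    inr <- if (r == 1) r200 >= 0 & r200 <= 0.1 else r200 > 0.1 & r200 <= 0.9
    expect_identical(got[r], sum(y200 == 1 & inr) / sum(inr))
  }
  expect_error(empirical_benchmark(1, 0.95, iv), "interval")
})

test_that("benchmark converges to the population case rate", {
  fx <- constraint_fixture()
  set.seed(10)
  dat <- simulate_cohort(fx$spec, 1e5, "target")
  phi <- predict(fx$base, as.matrix(dat[c("x1", "x2", "x3", "x4")]))
  bench <- empirical_benchmark(dat$y, phi, fx$intervals)
  # population quantity: Pr(Y=1 | interval) from the exact generator sums
  th <- cml_theta(fx$spec$beta0, fx$spec$beta_x, fx$spec$beta_z,
                  fx$spec$tau_mean, fx$spec$sigma)
  er <- expected_model_risk(th, fx$pop, fx$intervals, fx$base)
  n_r <- vapply(seq_len(4), function(r) {
    idx <- interval_index(phi, fx$intervals)
    sum(idx == r, na.rm = TRUE)
  }, numeric(1))
  se <- sqrt(er * (1 - er) / n_r)
  expect_true(all(abs(bench - er) <= 3 * se))
})

test_that("expected model risk matches exhaustive and Monte-Carlo oracles", {
  toy <- toy_population()
  iv <- data.frame(lower = c(0.05, 0.1), upper = c(0.1, 0.35))
  th <- theta_fixture()
  # beta_z = 0 collapses the inner expectation: independent of tau
  th0 <- cml_theta(-1, c(0.2, -0.1, 0.3, 0), 0, c(-2, 0, 0, 0, 0), 0.5)
  th0b <- cml_theta(-1, c(0.2, -0.1, 0.3, 0), 0, c(-1, 0.3, 0, 0.1, 0), 1.2)
  e0 <- expected_model_risk(th0, toy$pop, iv, toy$base)
  expect_equal(e0, expected_model_risk(th0b, toy$pop, iv, toy$base),
               tolerance = 1e-12)
  g <- plogis(-1 + as.matrix(toy$pop$x) %*% c(0.2, -0.1, 0.3, 0))
  expect_equal(e0[2], sum(g[2:3] * c(0.3, 0.2)) / 0.5, tolerance = 1e-12)

  # categorized feature: double loop over support x 10 categories
  er <- expected_model_risk(th, toy$pop, iv, toy$base)
  for (r in 1:2) {
    rows <- if (r == 1) 1 else 2:3
    num <- 0; den <- 0
    for (i in rows) {
      u <- sum(th$tau_mean * c(1, toy$pop$x[i, ]))
      pz <- zcat_probs(u, th$sigma)
      ez <- 0
      for (t in 0:9)
        ez <- ez + pz[t + 1] * logistic_risk(th, toy$pop$x[i, ], t)
      num <- num + ez * toy$pop$weight[i]
      den <- den + toy$pop$weight[i]
    }
    expect_equal(er[r], num / den, tolerance = 1e-12)
  }

  # raw feature: Gauss-Legendre vs a large simulation
  er_raw <- expected_model_risk(th, toy$pop, iv, toy$base, "raw")
  set.seed(12)
  i <- 2:3
  pick <- sample(i, 1e6, TRUE, prob = c(0.3, 0.2))
  u <- drop(cbind(1, toy$pop$x) %*% th$tau_mean)[pick]
  z <- rtrunclognorm(1e6, u, th$sigma)
  gmc <- logistic_risk(th, toy$pop$x[pick, ], z)
  expect_lt(abs(er_raw[2] - mean(gmc)), 3 * sd(gmc) / 1000)
})

test_that("constraint values form the tolerance band around targets", {
  toy <- toy_population()
  iv <- data.frame(lower = c(0.05, 0.1), upper = c(0.1, 0.35))
  th <- theta_fixture()
  er <- expected_model_risk(th, toy$pop, iv, toy$base)
  # centering the targets on the model risk puts both sides at -d * target
  cs0 <- cml_constraints(iv, er, d = 0.2)
  cv0 <- constraint_values(th, cs0, toy$pop, toy$base)
  expect_equal(cv0$cplus, -0.2 * er, tolerance = 1e-12)
  expect_equal(cv0$cminus, -0.2 * er, tolerance = 1e-12)
  # infinite tolerance disables the constraint entirely
  cs_inf <- cml_constraints(iv, c(0.07, 0.2), d = c(0.1, Inf))
  cv_inf <- constraint_values(th, cs_inf, toy$pop, toy$base)
  expect_identical(cv_inf$cplus[2], -Inf)
  expect_identical(cv_inf$cminus[2], -Inf)
  # random parameters against a hand-composed oracle
  set.seed(13)
  targets <- c(0.06, 0.18); d <- c(0.15, 0.3); oe <- c(1, 0.9)
  cs <- cml_constraints(iv, targets, d = d, oe = oe)
  for (k in 1:5) {
    v <- as.numeric(th) + rnorm(12, sd = 0.3); v[12] <- abs(v[12]) + 0.2
    thr <- theta_from_vector(v, th)
    cv <- constraint_values(thr, cs, toy$pop, toy$base)
    err <- expected_model_risk(thr, toy$pop, iv, toy$base)
    expect_equal(cv$cplus, err - (1 + d) * oe * targets, tolerance = 1e-12)
    expect_equal(cv$cminus, (1 - d) * oe * targets - err, tolerance = 1e-12)
  }
})

test_that("population invariants: mass conservation and monotonicity", {
  fx <- constraint_fixture()
  phi <- predict(fx$base, fx$pop$x)
  idx <- interval_index(phi, fx$intervals)
  expect_false(anyNA(idx))
  mass <- vapply(1:4, function(r) sum(fx$pop$weight[idx == r]), numeric(1))
  expect_equal(sum(mass), 1, tolerance = 1e-10)
  # expected model risk increases with the intercept
  th <- theta_fixture()
  e1 <- expected_model_risk(th, fx$pop, fx$intervals, fx$base)
  v <- as.numeric(th); v[1] <- v[1] + 0.3
  e2 <- expected_model_risk(theta_from_vector(v, th), fx$pop,
                            fx$intervals, fx$base)
  expect_true(all(e2 > e1))
  # weights must sum to one, rows must be unique
  expect_error(cml_population(cbind(1:2), c(0.6, 0.5)), "sum to 1")
  expect_error(cml_population(cbind(c(1, 1)), c(0.5, 0.5)), "duplicated")
})

test_that("analytic constraint Jacobian matches finite differences", {
  fx <- constraint_fixture()
  cs <- cml_constraints(fx$intervals, fx$targets, d = 0.1)
  for (zf in c("categorized", "raw")) {
    ctx <- cmlrisk:::constraint_context(cs, fx$pop, fx$base, zf)
    th <- theta_fixture()
    J <- cmlrisk:::constraint_jacobian(th, ctx)
    Jn <- pracma::jacobian(function(v)
      cmlrisk:::constraint_vector(theta_from_vector(v, th), ctx),
      as.numeric(th))
    expect_equal(J, Jn, tolerance = 1e-6, ignore_attr = TRUE)
  }
})
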