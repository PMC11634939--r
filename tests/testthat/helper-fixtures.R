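# Shared fixtures built in code. Heavy replication studies are memoised so
# several tests can share one run.

theta_fixture <- function() {
  cml_theta(-2.4, c(-0.5, 0.4, 0.3, 0.65), 0.1,
            c(-2, 0.1, -0.1, 0.1, 0.1), 0.6)
}

# small source cohort drawn from the Scenario I generator
cohort_fixture <- function(n = 500, seed = 11) {
  spec <- scenario_spec("I", N = n)
  set.seed(seed)
  dat <- simulate_cohort(spec, n, "source")
  cml_cohort(dat$y, dat[c("x1", "x2", "x3", "x4")], dat$z)
}

# three-row toy population with a hand-set base model, small enough for
# exhaustive double-loop oracles
toy_population <- function() {
  x <- rbind(c(0, 0, 0, 0), c(1, 1, 0, 1), c(2, 1, 2, 0))
  colnames(x) <- paste0("x", 1:4)
  pop <- cml_population(x, c(0.5, 0.3, 0.2))
  base <- cml_base_model(table = data.frame(x, risk = c(0.05, 0.12, 0.3)))
  list(pop = pop, base = base)
}

# full constraint setup on the Scenario I target population: base model
# from a moderate draw, quartile intervals, population-average targets
constraint_fixture <- function(seed = 21, n_phi = 2e5) {
  spec <- scenario_spec("I")
  set.seed(seed)
  pop <- target_population(spec)
  base <- fit_base_model(spec, n_phi)
  intervals <- risk_intervals(base, pop)
  targets <- interval_avg_base_risk(base, pop, intervals)
  list(spec = spec, pop = pop, base = base, intervals = intervals,
       targets = targets)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- make()
  .fixture_cache[[key]]
}

# one constrained fit on Scenario I data, shared across test files
cml_fit_fixture <- function() {
  cached("fit_I", function() {
    fx <- constraint_fixture()
    co <- cohort_fixture(n = 2000, seed = 31)
    cs <- cml_constraints(fx$intervals, fx$targets, d = 0.1)
    fit <- fit_cml(co, cs, fx$pop, fx$base)
    list(fx = fx, cohort = co, cs = cs, fit = fit)
  })
}

# replication studies for the acceptance suite (memoised; seeds fixed)
study_result <- function(scenario, ab = c(0.5, 1.2), n_reps = 200L) {
  key <- paste("study", scenario, paste(ab, collapse = "_"), n_reps,
               sep = "|")
  seeds <- c(I = 4101L, II = 4202L, III = 4303L)
  cached(key, function() {
    spec <- scenario_spec(scenario, ab = ab)
    run_replication_study(spec, n_reps = n_reps, seed = seeds[[scenario]],
                          n_phi = 1e6)
  })
}

# pull (method, parameter) cells out of a study summary
study_cell <- function(st, method, parameter, col) {
  s <- st$summary
  s[s$method == method & s$parameter == parameter, col]
}

# numeric central-difference gradient used as an independent oracle
num_grad <- function(f, v, h = 1e-6) {
  vapply(seq_along(v), function(j) {
    hp <- h * (1 + abs(v[j]))
    vp <- v; vp[j] <- vp[j] + hp
    vm <- v; vm[j] <- vm[j] - hp
    (f(vp) - f(vm)) / (2 * hp)
  }, numeric(1))
}
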