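#' Target-population distribution table
#'
#' Finite discrete joint distribution \eqn{\delta(x)} of the conventional
#' predictors in the target population (optionally joint with auxiliary
#' covariates used in the conditional model for Z). All population-level
#' integrals in the package are sums over this support.
#'
#' @param x Matrix or data frame of covariate support rows (one per row).
#' @param weight Probabilities, nonnegative, summing to 1 (tolerance 1e-10).
#' @param aux Optional matrix/data frame of auxiliary covariate values per
#'   support row.
#' @return An object of class `"cml_population"`.
#' @export
cml_population <- function(x, weight, aux = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  weight <- as.numeric(weight)
  if (nrow(x) != length(weight))
    stop("one weight per support row required", call. = FALSE)
  if (any(weight < 0)) stop("negative population weights", call. = FALSE)
  if (abs(sum(weight) - 1) > 1e-10)
    stop("population weights must sum to 1 (got ", format(sum(weight)), ")",
         call. = FALSE)
  if (!is.null(aux)) {
    aux <- as.matrix(aux)
    storage.mode(aux) <- "double"
    if (nrow(aux) != nrow(x))
      stop("'aux' must have one row per support row", call. = FALSE)
  }
  key <- apply(if (is.null(aux)) x else cbind(x, aux), 1L, paste,
               collapse = "\r")
  if (anyDuplicated(key))
    stop("duplicated support rows in population table", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(list(x = x, aux = aux, weight = weight), class = "cml_population")
}

#' @export
print.cml_population <- function(x, ...) {
  cat("Target population table: ", nrow(x$x), " support rows, ",
      ncol(x$x), " predictors\n", sep = "")
  invisible(x)
}

#' Base risk model
#'
#' The externally validated model \eqn{\varphi(x)} on the conventional
#' predictors, supplied either as a lookup table over the population support
#' (the canonical form: no functional form is assumed) or as logistic
#' regression coefficients `(intercept, slopes)`.
#'
#' @param table Data frame with the covariate columns plus a `risk` column
#'   in (0, 1).
#' @param coef Named or plain numeric vector of logistic coefficients, the
#'   first element the intercept.
#' @return An object of class `"cml_base_model"`.
#' @export
cml_base_model <- function(table = NULL, coef = NULL) {
  if (is.null(table) == is.null(coef))
    stop("supply exactly one of 'table' or 'coef'", call. = FALSE)
  if (!is.null(table)) {
    table <- as.data.frame(table)
    if (!"risk" %in% names(table))
      stop("lookup table needs a 'risk' column", call. = FALSE)
    risk <- table$risk
    if (any(!(risk > 0 & risk < 1)))
      stop("base-model risks must lie in (0, 1)", call. = FALSE)
    xcols <- setdiff(names(table), "risk")
    key <- apply(as.matrix(table[xcols]), 1L, paste, collapse = "\r")
    if (anyDuplicated(key)) stop("duplicated covariate rows in lookup table",
                                 call. = FALSE)
    obj <- list(type = "lookup", key = key, risk = risk, xcols = xcols)
  } else {
    obj <- list(type = "coef", coef = as.numeric(coef))
  }
  structure(obj, class = "cml_base_model")
}

#' Evaluate the base model on covariate rows
#'
#' @param object A [cml_base_model()].
#' @param newdata Matrix or data frame of covariate rows.
#' @param ... Unused.
#' @return Risks in (0, 1); an error if a lookup row is not covered.
#' @export
predict.cml_base_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (object$type == "coef") {
    if (ncol(x) != length(object$coef) - 1L)
      stop("covariate dimension does not match base-model coefficients",
           call. = FALSE)
    return(stats::plogis(drop(cbind(1, x) %*% object$coef)))
  }
  key <- apply(x, 1L, paste, collapse = "\r")
  idx <- match(key, object$key)
  if (anyNA(idx))
    stop("base-model lookup does not cover ", sum(is.na(idx)),
         " covariate row(s)", call. = FALSE)
  object$risk[idx]
}

#' Risk intervals from weighted quantiles of the base model
#'
#' Cuts the base-model risk distribution over the target population into
#' half-open intervals \eqn{(a_r, b_r]} at delta-weighted quantiles of
#' \eqn{\varphi(x)}. The lowest interval additionally includes its left
#' endpoint \eqn{a_1 = \min \varphi} so the intervals cover the support;
#' each quantile is the smallest support value whose cumulative weight
#' reaches the level, and boundary values belong to the lower interval.
#'
#' @param base A [cml_base_model()].
#' @param pop A [cml_population()].
#' @param probs Strictly increasing quantile levels in (0, 1); the default
#'   quartiles give four intervals.
#' @return A data frame with columns `lower`, `upper` (one row per
#'   interval).
#' @export
risk_intervals <- function(base, pop, probs = c(0.25, 0.5, 0.75)) {
  if (any(diff(probs) <= 0) || any(probs <= 0 | probs >= 1))
    stop("'probs' must be strictly increasing inside (0, 1)", call. = FALSE)
  phi <- predict(base, pop$x)
  if (length(unique(phi)) < 2L)
    stop("degenerate base model: a single distinct risk value", call. = FALSE)
  o <- order(phi)
  cum <- cumsum(pop$weight[o])
  qs <- vapply(probs, function(pr) phi[o][which(cum >= pr - 1e-12)[1L]],
               numeric(1))
  # collapse coinciding quantiles (ties in phi), but keep a quantile equal
  # to the minimum: it forms a degenerate first interval holding min(phi)
  uppers <- unique(c(qs, max(phi)))
  data.frame(lower = c(min(phi), uppers[-length(uppers)]), upper = uppers)
}

# interval index per risk value; lowest interval is closed on the left,
# values outside all intervals get NA
interval_index <- function(risk, intervals) {
  idx <- rep(NA_integer_, length(risk))
  for (r in seq_len(nrow(intervals))) {
    lo <- intervals$lower[r]; up <- intervals$upper[r]
    inr <- if (r == 1L) risk >= lo & risk <= up else risk > lo & risk <= up
    idx[inr] <- r
  }
  idx
}

#' Average base-model risk per interval in the target population
#'
#' The delta-weighted mean of \eqn{\varphi(x)} over the support rows whose
#' base risk falls in each interval: the calibration target
#' \eqn{P^e_r} in its population (expected) form.
#'
#' @inheritParams risk_intervals
#' @param intervals Data frame from [risk_intervals()] (columns `lower`,
#'   `upper`).
#' @return Numeric vector of per-interval average risks.
#' @export
interval_avg_base_risk <- function(base, pop, intervals) {
  phi <- predict(base, pop$x)
  idx <- interval_index(phi, intervals)
  vapply(seq_len(nrow(intervals)), function(r) {
    inr <- which(idx == r)
    if (!length(inr) || sum(pop$weight[inr]) <= 0)
      stop("interval ", r, " (", intervals$lower[r], ", ",
           intervals$upper[r], "] carries no population mass", call. = FALSE)
    sum(phi[inr] * pop$weight[inr]) / sum(pop$weight[inr])
  }, numeric(1))
}

#' Empirical calibration benchmark from a target-population sample
#'
#' Per-interval observed case fraction \eqn{\hat P^e_r}: among sampled
#' subjects whose base risk falls in the interval, the proportion with
#' Y = 1. This is the finite-sample benchmark used in place of the
#' population average when a cross-sectional target sample is available.
#'
#' @param y Binary outcomes of the target sample.
#' @param risk Base-model risks of the target sample.
#' @param intervals Data frame of intervals (`lower`, `upper`).
#' @return Numeric vector of per-interval benchmarks.
#' @export
empirical_benchmark <- function(y, risk, intervals) {
  idx <- interval_index(risk, intervals)
  vapply(seq_len(nrow(intervals)), function(r) {
    inr <- idx == r & !is.na(idx)
    if (!any(inr))
      stop("no sampled subjects in interval ", r, call. = FALSE)
    sum(y[inr] == 1) / sum(inr)
  }, numeric(1))
}

#' Calibration constraint set
#'
#' Intervals of base-model risk with per-interval targets, relative
#' tolerances and optional observed-to-expected multipliers. Constraint r
#' requires the fitted model's interval-averaged target-population risk to
#' lie within `(1 - d[r])` and `(1 + d[r])` times `oe[r] * targets[r]`;
#' `d[r] = Inf` disables the constraint for that interval.
#'
#' @param intervals Data frame with columns `lower`, `upper`, ordered and
#'   non-overlapping.
#' @param targets Per-interval calibration targets in (0, 1).
#' @param d Positive relative tolerances (recycled; `Inf` allowed).
#' @param oe Positive observed-to-expected multipliers (recycled, default 1).
#' @return An object of class `"cml_constraints"`.
#' @export
cml_constraints <- function(intervals, targets, d = 0.1, oe = 1) {
  intervals <- as.data.frame(intervals)
  I <- nrow(intervals)
  if (!all(c("lower", "upper") %in% names(intervals)))
    stop("'intervals' needs 'lower' and 'upper' columns", call. = FALSE)
  if (any(intervals$upper <= intervals$lower))
    stop("intervals must have upper > lower", call. = FALSE)
  if (I > 1L && any(intervals$lower[-1] < intervals$upper[-I] - 1e-12))
    stop("intervals must be ordered and non-overlapping", call. = FALSE)
  if (length(targets) != I)
    stop("one target per interval required", call. = FALSE)
  if (any(!(targets > 0 & targets < 1)))
    stop("targets must lie in (0, 1)", call. = FALSE)
  d <- rep_len(as.numeric(d), I)
  oe <- rep_len(as.numeric(oe), I)
  if (any(d <= 0)) stop("'d' must be positive (Inf allowed)", call. = FALSE)
  if (any(!(oe > 0 & is.finite(oe))))
    stop("'oe' multipliers must be positive and finite", call. = FALSE)
  structure(list(intervals = intervals, targets = as.numeric(targets),
                 d = d, oe = oe),
            class = "cml_constraints")
}

#' @export
print.cml_constraints <- function(x, digits = 4L, ...) {
  df <- cbind(x$intervals,
              target = x$oe * x$targets, d = x$d)
  cat("Calibration constraints (", nrow(df), " intervals):\n", sep = "")
  print(round(df, digits))
  invisible(x)
}

#' Interval-averaged risk of the fitted model in the target population
#'
#' For each risk interval of the base model, the delta-weighted average
#' over member support rows of the conditional expectation of the fitted
#' logistic risk over Z given x (and any auxiliary covariates). With the
#' categorized Z feature the inner expectation is the exact 10-term sum
#' over decile categories; with raw Z it is fixed-order Gauss-Legendre
#' quadrature on (0, 1).
#'
#' @param theta A [cml_theta()] object.
#' @param pop A [cml_population()].
#' @param intervals Data frame of intervals (`lower`, `upper`).
#' @param base A [cml_base_model()] defining interval membership.
#' @param z_feature `"categorized"` or `"raw"`.
#' @param nodes Gauss-Legendre order for raw Z (default 64).
#' @return Numeric vector of per-interval model-averaged risks.
#' @export
expected_model_risk <- function(theta, pop, intervals, base,
                                z_feature = "categorized", nodes = 64L) {
  ctx <- constraint_context(cml_constraints(intervals,
                                            rep(0.5, nrow(intervals))),
                            pop, base, z_feature, nodes)
  interval_model_risk(theta, ctx)
}

# Precomputed quantities for fast repeated constraint evaluation: interval
# membership, per-interval weights, tau design of the support, quadrature
# nodes. `keep` drops intervals with d = Inf (disabled constraints).
constraint_context <- function(constraints, pop, base,
                               z_feature = "categorized", nodes = 64L) {
  z_feature <- match.arg(z_feature, c("categorized", "raw"))
  phi <- predict(base, pop$x)
  idx <- interval_index(phi, constraints$intervals)
  I <- nrow(constraints$intervals)
  for (r in seq_len(I))
    if (!any(idx == r, na.rm = TRUE))
      stop("constraint interval ", r, " carries no population mass",
           call. = FALSE)
  gl <- if (z_feature == "raw") pracma::gaussLegendre(nodes, 0, 1) else NULL
  mass <- vapply(seq_len(I), function(r)
    sum(pop$weight[idx == r & !is.na(idx)]), numeric(1))
  list(pop = pop, idx = idx, I = I, mass = mass,
       W = tau_design(pop$x, pop$aux),
       targets = constraints$oe * constraints$targets,
       d = constraints$d, z_feature = z_feature, gl = gl)
}

# per-interval average E_{Z|x}[g(beta; x, zfeat)] under delta weights
interval_model_risk <- function(theta, ctx) {
  mz <- marginal_model_risk(theta, ctx)
  num <- vapply(seq_len(ctx$I), function(r) {
    inr <- ctx$idx == r & !is.na(ctx$idx)
    sum(mz[inr] * ctx$pop$weight[inr])
  }, numeric(1))
  num / ctx$mass
}

# per-support-row conditional expectation of the fitted risk over Z
marginal_model_risk <- function(theta, ctx) {
  u <- drop(ctx$W %*% theta$tau_mean)
  eta0 <- theta$beta0 + drop(ctx$pop$x %*% theta$beta_x)
  if (ctx$z_feature == "categorized") {
    P <- zcat_probs(u, theta$sigma)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    G <- stats::plogis(outer(eta0, theta$beta_z * (0:9), `+`))
    rowSums(P * G)
  } else {
    fz <- outer(u, ctx$gl$x, function(uu, zz)
      dtrunclognorm(zz, uu, theta$sigma))
    G <- stats::plogis(outer(eta0, theta$beta_z * ctx$gl$x, `+`))
    drop((fz * G) %*% ctx$gl$w)
  }
}

#' Constraint functions of the calibration band
#'
#' Evaluates the upper and lower calibration constraints
#' \eqn{C^+_r(\theta) = E_r(\theta) - (1 + d_r) P^e_r} and
#' \eqn{C^-_r(\theta) = (1 - d_r) P^e_r - E_r(\theta)}, where
#' \eqn{E_r(\theta)} is the fitted model's interval-averaged risk and the
#' targets are pre-multiplied by the observed-to-expected adjustment. The
#' parameter is feasible when every entry is nonpositive; disabled
#' intervals (`d = Inf`) return `-Inf`.
#'
#' @param theta A [cml_theta()] object.
#' @param constraints A [cml_constraints()] object.
#' @param pop A [cml_population()].
#' @param base A [cml_base_model()].
#' @inheritParams expected_model_risk
#' @return A list with vectors `cplus`, `cminus` and `model_risk`.
#' @export
constraint_values <- function(theta, constraints, pop, base,
                              z_feature = "categorized", nodes = 64L) {
  ctx <- constraint_context(constraints, pop, base, z_feature, nodes)
  er <- interval_model_risk(theta, ctx)
  list(cplus = er - (1 + ctx$d) * ctx$targets,
       cminus = (1 - ctx$d) * ctx$targets - er,
       model_risk = er)
}

# stacked enabled-constraint vector c(theta) <= 0 in the order
# (C+_1..C+_I, C-_1..C-_I) restricted to finite-d intervals
constraint_vector <- function(theta, ctx) {
  er <- interval_model_risk(theta, ctx)
  keep <- is.finite(ctx$d)
  c((er - (1 + ctx$d) * ctx$targets)[keep],
    ((1 - ctx$d) * ctx$targets - er)[keep])
}

# labels matching constraint_vector
constraint_labels <- function(ctx) {
  keep <- which(is.finite(ctx$d))
  c(paste0("C+_", keep), paste0("C-_", keep))
}

# analytic Jacobian of the enabled-constraint vector wrt theta
constraint_jacobian <- function(theta, ctx) {
  u <- drop(ctx$W %*% theta$tau_mean)
  eta0 <- theta$beta0 + drop(ctx$pop$x %*% theta$beta_x)
  n <- length(eta0)
  d_theta <- 2L + length(theta$beta_x) + length(theta$tau_mean) + 1L
  if (ctx$z_feature == "categorized") {
    zv <- 0:9
    P <- zcat_probs(u, theta$sigma)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    Pg <- zcat_probs_grad(u, theta$sigma)
    G <- stats::plogis(outer(eta0, theta$beta_z * zv, `+`))
    Gp <- G * (1 - G)
    # d/d(beta0, beta_x): sum_t P_t g'(eta) * (1, x)
    mb <- rowSums(P * Gp)
    # d/d(beta_z): sum_t P_t g' * z_t
    mbz <- drop((P * Gp) %*% zv)
    # d/d(u): sum_t dP_t/du * g ; d/d(sigma): sum_t dP_t/dsigma * g
    mu <- rowSums(Pg$du * G)
    msig <- rowSums(Pg$dsig * G)
  } else {
    zv <- ctx$gl$x
    w <- ctx$gl$w
    lf <- outer(u, zv, function(uu, zz)
      dtrunclognorm(zz, uu, theta$sigma, log = TRUE))
    fz <- exp(lf)
    # d log f / du and / dsigma at each (row, node)
    s <- (matrix(base::log(zv), n, length(zv), byrow = TRUE) - u) / theta$sigma
    mr <- mills_ratio(-u / theta$sigma)
    dl_du <- s / theta$sigma + mr / theta$sigma
    dl_ds <- (-1 + s^2 - mr * u / theta$sigma) / theta$sigma
    G <- stats::plogis(outer(eta0, theta$beta_z * zv, `+`))
    Gp <- G * (1 - G)
    mb <- drop((fz * Gp) %*% w)
    mbz <- drop((fz * Gp * matrix(zv, n, length(zv), byrow = TRUE)) %*% w)
    mu <- drop((fz * dl_du * G) %*% w)
    msig <- drop((fz * dl_ds * G) %*% w)
  }
  # assemble per-row gradient of the conditional expectation, then average
  D <- cbind(mb, mb * ctx$pop$x, mbz, mu * ctx$W, msig)
  JE <- matrix(0, ctx$I, d_theta)
  for (r in seq_len(ctx$I)) {
    inr <- ctx$idx == r & !is.na(ctx$idx)
    JE[r, ] <- colSums(D[inr, , drop = FALSE] * ctx$pop$weight[inr]) /
      ctx$mass[r]
  }
  keep <- is.finite(ctx$d)
  rbind(JE[keep, , drop = FALSE], -JE[keep, , drop = FALSE])
}
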