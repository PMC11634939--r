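#' Fit a calibrated risk model by constrained maximum likelihood
#'
#' Fits the logistic working model for a binary outcome on conventional
#' predictors plus a new predictor Z in (0, 1), together with a truncated
#' log-normal conditional model for Z, by maximum likelihood subject to
#' calibration constraints: within risk intervals of a well-calibrated
#' base model, the fitted model's average predicted risk in the target
#' population must stay within a relative tolerance band of the base
#' model's. With `constraints = NULL` and no population/base model the
#' unconstrained ("standard") maximum likelihood fit is returned.
#'
#' The constraint configuration can be given explicitly via `constraints`,
#' or assembled from `quantiles` (interval endpoints as weighted quantiles
#' of the base risk over the target population), `targets` (defaults to
#' the population interval-averaged base risk) and the tolerance `d`.
#'
#' @param formula Model formula `y ~ x1 + ... + xp` naming the outcome and
#'   the conventional predictors in `data`.
#' @param data Data frame containing the cohort.
#' @param z Name of the column holding the new predictor (values strictly
#'   inside (0, 1)).
#' @param aux Optional column names of auxiliary covariates entering the
#'   conditional model for Z only (e.g. age).
#' @param population A [cml_population()] over the conventional-predictor
#'   support (required for a constrained fit).
#' @param base_model A [cml_base_model()] (required for a constrained fit).
#' @param constraints A [cml_constraints()] object, or `NULL` to build one
#'   from `quantiles`/`targets`/`d`, or `NULL` with no population for an
#'   unconstrained fit.
#' @param quantiles Quantile levels for interval endpoints (default
#'   quartiles).
#' @param targets Optional per-interval calibration targets; default: the
#'   delta-weighted average base risk per interval.
#' @param d Relative tolerance(s) of the calibration band.
#' @param oe Observed-to-expected multipliers for the targets.
#' @param z_feature `"categorized"` (decile category of Z enters the
#'   linear predictor; the default) or `"raw"`.
#' @param control A [cml_control()] list.
#' @return An object of class `"cml"` with methods `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' spec <- scenario_spec("I", N = 400)
#' set.seed(7)
#' dat <- simulate_cohort(spec, 400, "source")
#' fit <- cml(y ~ x1 + x2 + x3 + x4, data = dat, z = "z")  # unconstrained
#' coef(fit)
#' @export
cml <- function(formula, data, z, aux = NULL,
                population = NULL, base_model = NULL, constraints = NULL,
                quantiles = c(0.25, 0.5, 0.75), targets = NULL,
                d = 0.1, oe = 1, z_feature = c("categorized", "raw"),
                control = cml_control()) {
  z_feature <- match.arg(z_feature)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  xmat <- stats::model.matrix(stats::terms(formula, data = data), mf)
  xmat <- xmat[, colnames(xmat) != "(Intercept)", drop = FALSE]
  if (!is.character(z) || !z %in% names(data))
    stop("'z' must name a column of 'data'", call. = FALSE)
  auxmat <- if (!is.null(aux)) as.matrix(data[aux]) else NULL
  cohort <- cml_cohort(y, xmat, data[[z]], auxmat)
  constrained <- !is.null(constraints) || !is.null(population) ||
    !is.null(base_model)
  if (constrained && (is.null(population) || is.null(base_model)))
    stop("a constrained fit needs both 'population' and 'base_model'",
         call. = FALSE)
  if (constrained && is.null(constraints)) {
    intervals <- risk_intervals(base_model, population, quantiles)
    if (is.null(targets))
      targets <- interval_avg_base_risk(base_model, population, intervals)
    constraints <- cml_constraints(intervals, targets, d = d, oe = oe)
  }
  if (constrained) {
    fit <- fit_cml(cohort, constraints, population, base_model, z_feature,
                   control)
    inference <- cml_inference(fit, cohort, constraints, population,
                               base_model, z_feature, control$quad_nodes)
  } else {
    mle <- cml_mle(cohort, z_feature)
    fit <- structure(
      list(theta_hat = mle$theta, loglik = mle$loglik, converged = TRUE,
           message = "converged (unconstrained)",
           active_plus = integer(0), active_minus = integer(0),
           lambda = numeric(0), lambda_labels = character(0),
           constraint_values = NULL, kkt_residual = mle$grad_norm,
           n_outer = 0L, theta_init = mle$theta,
           loglik_unconstrained = mle$loglik, z_feature = z_feature),
      class = "cml_fit")
    inference <- unconstrained_inference(fit, cohort, z_feature)
  }
  structure(
    list(fit = fit, inference = inference, cohort = cohort,
         constraints = constraints, population = population,
         base_model = base_model, z_feature = z_feature, z_name = z,
         constrained = constrained, call = match.call()),
    class = "cml")
}

# classical sandwich (no active constraints): V I V^T / N with V = H^{-1}
unconstrained_inference <- function(fit, cohort, z_feature) {
  theta <- fit$theta_hat
  info <- empirical_information(theta, cohort, z_feature)
  H <- cml_score_hessian(theta, cohort, z_feature)$hessian / cohort$n
  V <- solve(H)
  cov <- V %*% info %*% t(V) / cohort$n
  cov <- (cov + t(cov)) / 2
  v0 <- as.numeric(theta)
  dimnames(cov) <- list(names(v0), names(v0))
  ase <- sqrt(pmax(diag(cov), 0))
  zstat <- v0 / ase
  structure(list(vcov = cov, ase = ase,
                 wald = data.frame(estimate = v0, ase = ase, z = zstat,
                                   p = 2 * stats::pnorm(-abs(zstat)),
                                   row.names = names(v0)),
                 xi = diag(length(v0)), info = info, hessian_mean = H,
                 active = list(plus = integer(0), minus = integer(0))),
            class = "cml_inference")
}

#' @export
print.cml <- function(x, digits = 4L, ...) {
  cat(if (x$constrained) "Constrained" else "Unconstrained",
      "maximum likelihood risk model\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(coef(x), digits))
  if (x$constrained) {
    a <- x$fit
    cat("\nactive constraints: K+ = {",
        paste(a$active_plus, collapse = ","), "}, K- = {",
        paste(a$active_minus, collapse = ","), "}\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.cml <- function(object, ...) as.numeric(object$fit$theta_hat)

#' @export
vcov.cml <- function(object, ...) object$inference$vcov

#' @export
logLik.cml <- function(object, ...) {
  structure(object$fit$loglik,
            df = length(as.numeric(object$fit$theta_hat)) -
              length(object$fit$active_plus) -
              length(object$fit$active_minus),
            nobs = object$cohort$n, class = "logLik")
}

#' @export
summary.cml <- function(object, ...) {
  structure(list(call = object$call, wald = object$inference$wald,
                 loglik = object$fit$loglik,
                 constrained = object$constrained,
                 message = object$fit$message,
                 active = list(plus = object$fit$active_plus,
                               minus = object$fit$active_minus),
                 report = if (object$constrained)
                   calibration_report(object$fit, object$constraints,
                                      object$population, object$base_model,
                                      object$z_feature) else NULL),
            class = "summary.cml")
}

#' @export
print.summary.cml <- function(x, digits = 4L, ...) {
  cat("Call: ", deparse(x$call), "\n\n")
  w <- x$wald
  w$estimate <- round(w$estimate, digits)
  w$ase <- round(w$ase, digits)
  w$z <- round(w$z, 2L)
  w$p <- signif(w$p, 3L)
  print(w)
  cat("\nlog-likelihood:", format(x$loglik, digits = 8), "-", x$message,
      "\n")
  if (!is.null(x$report)) {
    cat("\nCalibration by risk interval:\n")
    r <- x$report
    r$target <- round(r$target, 5L)
    r$model_risk <- round(r$model_risk, 5L)
    r$ratio <- round(r$ratio, 3L)
    r$mass <- round(r$mass, 3L)
    print(r[c("interval", "mass", "target", "model_risk", "ratio",
              "active")], row.names = FALSE)
  }
  invisible(x)
}

#' Predicted risks from a fitted model
#'
#' @param object A `"cml"` fit.
#' @param newdata Data frame with the conventional predictors and, unless
#'   `marginal = TRUE`, the Z column used at fit time.
#' @param marginal If `TRUE`, return the conditional expectation of the
#'   risk over Z given the covariates instead of plugging in observed Z.
#' @param ... Unused.
#' @return Vector of predicted risks.
#' @export
predict.cml <- function(object, newdata = NULL, marginal = FALSE, ...) {
  theta <- object$fit$theta_hat
  if (is.null(newdata)) {
    co <- object$cohort
    zf <- z_feature_values(co, object$z_feature)
    return(logistic_risk(theta, co$x, zf))
  }
  xs <- theta$x_names
  X <- as.matrix(newdata[xs])
  if (marginal) {
    auxm <- if (length(theta$aux_names)) as.matrix(newdata[theta$aux_names])
            else NULL
    w <- rep(1 / nrow(X), nrow(X))
    # per-row marginalization: reuse the population machinery rowwise
    ctx <- list(pop = list(x = X, aux = auxm, weight = w),
                W = tau_design(X, auxm), z_feature = object$z_feature,
                gl = if (object$z_feature == "raw")
                  pracma::gaussLegendre(64L, 0, 1) else NULL)
    return(marginal_model_risk(theta, ctx))
  }
  if (!object$z_name %in% names(newdata))
    stop("'newdata' lacks the Z column '", object$z_name,
         "'; use marginal = TRUE to average over Z", call. = FALSE)
  zcol <- as.numeric(newdata[[object$z_name]])
  zf <- if (object$z_feature == "categorized") pmin(floor(10 * zcol), 9)
        else zcol
  logistic_risk(theta, X, zf)
}

#' @export
fitted.cml <- function(object, ...) predict(object)

#' @export
residuals.cml <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$cohort$y - mu
  if (type == "pearson") r <- r / sqrt(mu * (1 - mu))
  r
}

#' Calibration plot of a fitted model
#'
#' Plots expected case counts under the fitted model against "observed"
#' counts under the benchmark base model across deciles of fitted risk in
#' the target population (both per 100,000), with the identity line.
#'
#' @param x A constrained `"cml"` fit.
#' @param ... Passed to [graphics::plot()].
#' @return The decile table, invisibly.
#' @export
plot.cml <- function(x, ...) {
  if (!x$constrained)
    stop("calibration plot needs the population and base model of a ",
         "constrained fit", call. = FALSE)
  tab <- decile_calibration(x, x$population, x$base_model,
                            z_feature = x$z_feature)
  lim <- range(c(tab$expected, tab$observed))
  graphics::plot(tab$expected, tab$observed, xlim = lim, ylim = lim,
                 xlab = "expected cases per 100,000 (fitted model)",
                 ylab = "observed cases per 100,000 (benchmark)",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(tab)
}
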