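#' Empirical information matrix of the per-observation score
#'
#' The average outer product \eqn{(1/N) \sum_i s_i s_i^T} of the
#' per-observation scores of the single-subject log-likelihood, evaluated
#' at a given parameter value. Symmetric and positive semi-definite by
#' construction.
#'
#' @inheritParams cml_loglik
#' @return A dim(theta) x dim(theta) matrix.
#' @export
empirical_information <- function(theta, cohort, z_feature = "categorized") {
  S <- cml_score(theta, cohort, z_feature)$scores
  if (any(!is.finite(S)))
    stop("nonfinite score at row ",
         which(!apply(is.finite(S), 1L, all))[1L], call. = FALSE)
  crossprod(S) / cohort$n
}

#' Orthonormal basis of the null space of a constraint Jacobian
#'
#' Columns form an orthonormal basis of \eqn{\{v : J v = 0\}} for the
#' Jacobian J of the active constraints. The active constraints must be a
#' regular point: J is required to have full row rank (checked
#' numerically), and the basis has dim(theta) - nrow(J) columns. For an
#' empty Jacobian (no active constraints) the identity is returned.
#'
#' @param jac Active-constraint Jacobian (rows = constraints); `NULL` or a
#'   zero-row matrix means no active constraints.
#' @param d Parameter dimension (needed when `jac` is empty).
#' @return A dim x (dim - k) matrix with orthonormal columns.
#' @export
null_space_basis <- function(jac, d = ncol(jac)) {
  if (is.null(jac) || nrow(jac) == 0L) return(diag(d))
  k <- nrow(jac)
  sv <- svd(t(jac), nu = d, nv = k)
  tol <- max(dim(jac)) * .Machine$double.eps * sv$d[1L]
  if (sum(sv$d > tol) < k)
    stop("active-constraint Jacobian is rank deficient: the solution is ",
         "not a regular point of the active constraints", call. = FALSE)
  sv$u[, (k + 1L):d, drop = FALSE]
}

#' Active-set sandwich covariance and standard errors
#'
#' Large-sample covariance of the constrained estimator: with Xi an
#' orthonormal basis of the null space of the active-constraint Jacobian
#' and H the mean Hessian of the single-subject log-likelihood,
#' \deqn{V = \Xi (\Xi^T H \Xi)^{-1} \Xi^T, \qquad
#'       \mathrm{cov} = V \mathcal{I} V^T / N,}
#' where \eqn{\mathcal{I}} is the empirical information. Directions along
#' active-constraint gradients have zero asymptotic variance; with no
#' active constraints the expression reduces to the classical sandwich.
#' The active-constraint Jacobian is computed by central finite
#' differences (step `1e-6 * (1 + |theta|)`).
#'
#' @param fit A `"cml_fit"` object from [fit_cml()].
#' @param cohort The fitted [cml_cohort()].
#' @param constraints,pop,base The constraint configuration used in the fit.
#' @param z_feature `"categorized"` or `"raw"`.
#' @param nodes Gauss-Legendre order for raw-Z marginalization.
#' @return A list of class `"cml_inference"`: `vcov`, `ase`, `wald`
#'   (data frame with z and two-sided p-values), `xi`, `info`,
#'   `hessian_mean`, `active`.
#' @export
cml_inference <- function(fit, cohort, constraints, pop, base,
                          z_feature = "categorized", nodes = 64L) {
  theta <- fit$theta_hat
  v0 <- as.numeric(theta)
  d <- length(v0)
  info <- empirical_information(theta, cohort, z_feature)
  H <- cml_score_hessian(theta, cohort, z_feature)$hessian / cohort$n
  act <- list(plus = fit$active_plus, minus = fit$active_minus)
  J <- active_jacobian_fd(theta, constraints, pop, base, act, z_feature,
                          nodes)
  xi <- null_space_basis(J, d)
  A <- crossprod(xi, H %*% xi)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("projected Hessian is singular; the curvature condition of the ",
         "active-set asymptotics fails at the solution", call. = FALSE))
  V <- xi %*% Ainv %*% t(xi)
  cov <- V %*% info %*% t(V) / cohort$n
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(names(v0), names(v0))
  ase <- sqrt(pmax(diag(cov), 0))
  zstat <- v0 / ase
  wald <- data.frame(estimate = v0, ase = ase, z = zstat,
                     p = 2 * stats::pnorm(-abs(zstat)), row.names = names(v0))
  structure(list(vcov = cov, ase = ase, wald = wald, xi = xi, info = info,
                 hessian_mean = H, active = act),
            class = "cml_inference")
}

# central finite-difference Jacobian of the active constraints (rows:
# active C+ then active C-)
active_jacobian_fd <- function(theta, constraints, pop, base, act,
                               z_feature = "categorized", nodes = 64L) {
  k <- length(act$plus) + length(act$minus)
  v0 <- as.numeric(theta)
  if (k == 0L) return(matrix(0, 0L, length(v0)))
  ctx <- constraint_context(constraints, pop, base, z_feature, nodes)
  val <- function(v) {
    er <- interval_model_risk(theta_from_vector(v, theta), ctx)
    c((er - (1 + ctx$d) * ctx$targets)[act$plus],
      ((1 - ctx$d) * ctx$targets - er)[act$minus])
  }
  J <- matrix(0, k, length(v0))
  for (j in seq_along(v0)) {
    h <- 1e-6 * (1 + abs(v0[j]))
    vp <- v0; vp[j] <- vp[j] + h
    vm <- v0; vm[j] <- vm[j] - h
    J[, j] <- (val(vp) - val(vm)) / (2 * h)
  }
  J
}
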