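#' Predicted risk under the logistic working model
#'
#' Evaluates \eqn{g(\beta; x, z) = \mathrm{expit}(\beta_0 + \beta_X^T x +
#' \beta_Z z)}, where z is the configured Z feature (raw Z in (0,1) or its
#' decile category 0..9).
#'
#' @param theta A [cml_theta()] object.
#' @param x Covariate row (length p) or matrix (N x p).
#' @param z_value Z-feature value(s), recycled against rows of `x`.
#' @return Risk(s) in (0, 1).
#' @export
logistic_risk <- function(theta, x, z_value) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(x) != length(theta$beta_x))
    stop("covariate row has ", ncol(x), " columns but 'beta_x' has length ",
         length(theta$beta_x), call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(z_value)))
    stop("nonfinite covariate or z value", call. = FALSE)
  eta <- theta$beta0 + drop(x %*% theta$beta_x) + theta$beta_z * z_value
  stats::plogis(eta)
}

# log Mills-type ratio phi(m)/Phi(m), stable for very negative m
mills_ratio <- function(m) {
  exp(stats::dnorm(m, log = TRUE) - stats::pnorm(m, log.p = TRUE))
}

#' Truncated log-normal density on (0, 1)
#'
#' Density of Z where \eqn{\log Z \sim N(\mathrm{meanlog}, \mathrm{sdlog}^2)}
#' truncated on \eqn{(-\infty, 0)}, i.e. Z restricted to (0, 1):
#' \deqn{f(z) = \phi\{(\log z - u)/\sigma\} / \{z \sigma \Phi(-u/\sigma)\}.}
#' The normalizing constant is evaluated in log space so that extreme
#' mean/sd combinations do not underflow.
#'
#' @param z Values strictly in (0, 1).
#' @param meanlog Mean(s) of log Z before truncation.
#' @param sdlog Positive standard deviation of log Z before truncation.
#' @param log If `TRUE`, return the log density.
#' @return Density (or log density) values.
#' @export
dtrunclognorm <- function(z, meanlog, sdlog, log = FALSE) {
  if (any(!(z > 0 & z < 1)))
    stop("'z' outside the support (0, 1)", call. = FALSE)
  if (any(sdlog <= 0)) stop("'sdlog' must be positive", call. = FALSE)
  s <- (base::log(z) - meanlog) / sdlog
  lp <- stats::dnorm(s, log = TRUE) - base::log(z) - base::log(sdlog) -
    stats::pnorm(-meanlog / sdlog, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Random draws from the truncated log-normal
#'
#' Inverse-CDF sampling of Z in (0, 1) with log Z normal truncated above
#' at 0.
#'
#' @inheritParams dtrunclognorm
#' @param n Number of draws (ignored if `meanlog` is a vector: one draw per
#'   element).
#' @return Numeric vector in (0, 1).
#' @export
rtrunclognorm <- function(n, meanlog, sdlog) {
  if (length(meanlog) > 1L) n <- length(meanlog)
  u <- stats::runif(n)
  cap <- stats::pnorm(-meanlog / sdlog)
  z <- exp(meanlog + sdlog * stats::qnorm(u * cap))
  # guard against numerically hitting the closed boundary
  pmin(pmax(z, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Decile-category probabilities of the truncated log-normal
#'
#' Probability that Z falls in each interval \eqn{(0.1t, 0.1(t+1)]},
#' t = 0..9, computed from CDF differences of the truncated distribution.
#'
#' @inheritParams dtrunclognorm
#' @return A vector of length 10 (or an n x 10 matrix for vector `meanlog`);
#'   rows sum to 1.
#' @export
zcat_probs <- function(meanlog, sdlog) {
  if (any(sdlog <= 0)) stop("'sdlog' must be positive", call. = FALSE)
  brk <- c(-Inf, base::log(seq(0.1, 1, by = 0.1)))  # log-scale boundaries
  a <- outer(meanlog, brk, function(u, b) (b - u) / sdlog)
  cdf <- stats::pnorm(a)
  pr <- (cdf[, 2:11, drop = FALSE] - cdf[, 1:10, drop = FALSE]) /
    stats::pnorm(-meanlog / sdlog)
  if (length(meanlog) == 1L) drop(pr) else pr
}

# d/d(meanlog) and d/d(sdlog) of the 10 category probabilities; returns
# list(du = n x 10, dsig = n x 10). Used for analytic constraint Jacobians.
zcat_probs_grad <- function(meanlog, sdlog) {
  brk <- c(-Inf, base::log(seq(0.1, 1, by = 0.1)))
  a <- outer(meanlog, brk, function(u, b) (b - u) / sdlog)
  cdf <- stats::pnorm(a)
  pdf <- stats::dnorm(a)
  apdf <- a * pdf
  apdf[, 1] <- 0                       # a = -Inf contributes nothing
  m <- -meanlog / sdlog                # upper truncation boundary, std scale
  D <- stats::pnorm(m)
  Ncat <- cdf[, 2:11, drop = FALSE] - cdf[, 1:10, drop = FALSE]
  dN_du <- (pdf[, 1:10, drop = FALSE] - pdf[, 2:11, drop = FALSE]) / sdlog
  dN_ds <- (apdf[, 1:10, drop = FALSE] - apdf[, 2:11, drop = FALSE]) / sdlog
  dD_du <- -stats::dnorm(m) / sdlog
  dD_ds <- -stats::dnorm(m) * m / sdlog
  list(du = dN_du / D - Ncat * dD_du / D^2,
       dsig = dN_ds / D - Ncat * dD_ds / D^2)
}

#' Observed-data log-likelihood
#'
#' Sum over observations of the logistic Bernoulli log-likelihood (with the
#' configured Z feature in the linear predictor) plus the truncated
#' log-normal log density of the continuous Z given the conditional-model
#' covariates. The marginal distribution of the conventional predictors is
#' ignored, so the likelihood separates into a beta block and a tau block.
#'
#' @param theta A [cml_theta()] object.
#' @param cohort A [cml_cohort()] object.
#' @param z_feature `"categorized"` (default) or `"raw"`: the Z feature used
#'   in the logistic linear predictor.
#' @return The log-likelihood value.
#' @export
cml_loglik <- function(theta, cohort, z_feature = "categorized") {
  zf <- z_feature_values(cohort, z_feature)
  eta <- theta$beta0 + drop(cohort$x %*% theta$beta_x) + theta$beta_z * zf
  ll_logit <- cohort$y * eta - log1p(exp(pmin(eta, 700)))
  u <- drop(tau_design(cohort$x, cohort$aux) %*% theta$tau_mean)
  ll_tau <- dtrunclognorm(cohort$z, u, theta$sigma, log = TRUE)
  ll <- ll_logit + ll_tau
  if (any(!is.finite(ll)))
    stop("nonfinite log-likelihood contribution at row ",
         which(!is.finite(ll))[1L], call. = FALSE)
  sum(ll)
}

#' Per-observation score and total gradient of the log-likelihood
#'
#' Analytic first derivatives of [cml_loglik()] in the canonical parameter
#' order (beta0, beta_x, beta_z, tau_mean, sigma). Because the likelihood
#' separates, the beta block depends only on the logistic part and the tau
#' block only on the conditional density of Z.
#'
#' @inheritParams cml_loglik
#' @return A list with `scores` (N x dim matrix of per-row scores) and
#'   `gradient` (their column sums).
#' @export
cml_score <- function(theta, cohort, z_feature = "categorized") {
  zf <- z_feature_values(cohort, z_feature)
  eta <- theta$beta0 + drop(cohort$x %*% theta$beta_x) + theta$beta_z * zf
  g <- stats::plogis(eta)
  res <- cohort$y - g
  W <- tau_design(cohort$x, cohort$aux)
  u <- drop(W %*% theta$tau_mean)
  sig <- theta$sigma
  s <- (base::log(cohort$z) - u) / sig
  mr <- mills_ratio(-u / sig)
  dll_du <- s / sig + mr / sig
  dll_dsig <- (-1 + s^2 - mr * u / sig) / sig
  scores <- cbind(res, res * cohort$x, res * zf, dll_du * W, dll_dsig)
  colnames(scores) <- theta_names(theta)
  list(scores = scores, gradient = colSums(scores))
}

#' Gradient and Hessian of the log-likelihood
#'
#' The gradient is analytic ([cml_score()]). The Hessian is block diagonal
#' (the likelihood separates in beta and tau): the logistic block is the
#' usual analytic \eqn{-\sum g(1-g) u u^T}; the tau block is, by default,
#' obtained by central finite differences of the analytic tau gradient,
#' which is directly verifiable against a finite-difference oracle.
#'
#' @inheritParams cml_loglik
#' @param tau_hessian `"numeric"` (default) for central differences of the
#'   analytic tau-score, the only mode currently implemented.
#' @param step Relative step for the central differences.
#' @return A list with `gradient` and `hessian` (symmetric matrix).
#' @export
cml_score_hessian <- function(theta, cohort, z_feature = "categorized",
                              tau_hessian = "numeric", step = 1e-6) {
  sc <- cml_score(theta, cohort, z_feature)
  d <- length(sc$gradient)
  p <- length(theta$beta_x)
  nb <- p + 2L                     # beta block size
  H <- matrix(0, d, d, dimnames = list(names(sc$gradient), names(sc$gradient)))
  zf <- z_feature_values(cohort, z_feature)
  eta <- theta$beta0 + drop(cohort$x %*% theta$beta_x) + theta$beta_z * zf
  g <- stats::plogis(eta)
  U <- cbind(1, cohort$x, zf)
  H[1:nb, 1:nb] <- -crossprod(U * (g * (1 - g)), U)
  # tau block: central differences of the analytic tau gradient
  idx <- (nb + 1L):d
  v0 <- as.numeric(theta)
  Ht <- matrix(0, length(idx), length(idx))
  for (j in seq_along(idx)) {
    h <- step * (1 + abs(v0[idx[j]]))
    vp <- v0; vp[idx[j]] <- vp[idx[j]] + h
    vm <- v0; vm[idx[j]] <- vm[idx[j]] - h
    gp <- cml_score(theta_from_vector(vp, theta), cohort, z_feature)$gradient
    gm <- cml_score(theta_from_vector(vm, theta), cohort, z_feature)$gradient
    Ht[, j] <- (gp[idx] - gm[idx]) / (2 * h)
  }
  H[idx, idx] <- (Ht + t(Ht)) / 2
  if (any(!is.finite(H)))
    stop("nonfinite Hessian entries; parameters may be on the boundary",
         call. = FALSE)
  list(gradient = sc$gradient, hessian = H)
}
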