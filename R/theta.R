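#' Full parameter vector for the constrained risk model
#'
#' Bundles the logistic regression parameters (intercept, coefficients of the
#' conventional predictors, coefficient of the new predictor) with the
#' parameters of the truncated log-normal conditional model for the new
#' predictor Z: the linear-predictor coefficients for the mean of log Z
#' (its own intercept, the conventional predictors, and optionally auxiliary
#' covariates such as age) and the pre-truncation standard deviation of log Z.
#'
#' @param beta0 Log-odds intercept of the logistic model.
#' @param beta_x Numeric vector of coefficients for the conventional
#'   predictors (length p).
#' @param beta_z Coefficient of the new predictor (raw Z or its categorized
#'   version, depending on the model configuration).
#' @param tau_mean Numeric vector of coefficients for the mean of log Z:
#'   first element the intercept, then one per conventional predictor, then
#'   one per auxiliary covariate.
#' @param sigma Positive standard deviation of log Z before truncation.
#' @param x_names Optional names for the conventional predictors.
#' @param aux_names Optional names of auxiliary covariates entering the
#'   conditional model only.
#' @return An object of class `"cml_theta"`.
#' @examples
#' th <- cml_theta(-2.4, c(-0.5, 0.4, 0.3, 0.65), 0.1,
#'                 c(-2, 0.1, -0.1, 0.1, 0.1), 0.6)
#' all.equal(theta_from_vector(as.numeric(th), th), th)
#' @export
cml_theta <- function(beta0, beta_x, beta_z, tau_mean, sigma,
                      x_names = NULL, aux_names = NULL) {
  beta0 <- as.numeric(beta0)
  beta_x <- as.numeric(beta_x)
  beta_z <- as.numeric(beta_z)
  tau_mean <- as.numeric(tau_mean)
  sigma <- as.numeric(sigma)
  if (length(beta0) != 1L || length(beta_z) != 1L || length(sigma) != 1L)
    stop("'beta0', 'beta_z' and 'sigma' must be scalars", call. = FALSE)
  if (!all(is.finite(c(beta0, beta_x, beta_z, tau_mean, sigma))))
    stop("all parameters must be finite", call. = FALSE)
  if (sigma <= 0)
    stop("'sigma' must be positive", call. = FALSE)
  p <- length(beta_x)
  if (is.null(x_names)) x_names <- paste0("x", seq_len(p))
  if (length(x_names) != p)
    stop("'x_names' length does not match 'beta_x' (", p, ")", call. = FALSE)
  n_aux <- length(tau_mean) - 1L - p
  if (n_aux < 0L)
    stop("'tau_mean' must have length >= 1 + length(beta_x); got ",
         length(tau_mean), " for p = ", p, call. = FALSE)
  if (is.null(aux_names) && n_aux > 0L) aux_names <- paste0("a", seq_len(n_aux))
  if (length(aux_names) != n_aux)
    stop("'aux_names' length does not match the auxiliary block of 'tau_mean'",
         call. = FALSE)
  names(beta_x) <- x_names
  names(tau_mean) <- c("(Intercept)", x_names, aux_names)
  structure(
    list(beta0 = beta0, beta_x = beta_x, beta_z = beta_z,
         tau_mean = tau_mean, sigma = sigma,
         x_names = x_names, aux_names = aux_names),
    class = "cml_theta")
}

#' @export
as.double.cml_theta <- function(x, ...) {
  v <- c(x$beta0, x$beta_x, x$beta_z, x$tau_mean, x$sigma)
  names(v) <- theta_names(x)
  v
}

theta_names <- function(theta) {
  c("beta0", paste0("beta_", theta$x_names), "beta_z",
    paste0("tau_", names(theta$tau_mean)), "sigma")
}

#' Rebuild a parameter object from its flattened form
#'
#' Inverse of `as.numeric()` on a [cml_theta()] object: the round trip is
#' lossless.
#'
#' @param v Numeric vector in the canonical order
#'   (beta0, beta_x, beta_z, tau_mean, sigma).
#' @param template A `"cml_theta"` object fixing dimensions and names.
#' @return An object of class `"cml_theta"`.
#' @export
theta_from_vector <- function(v, template) {
  p <- length(template$beta_x)
  k <- length(template$tau_mean)
  if (length(v) != 2L + p + k + 1L)
    stop("parameter vector has length ", length(v), ", expected ",
         2L + p + k + 1L, call. = FALSE)
  cml_theta(v[1L], v[2L:(1L + p)], v[2L + p], v[(3L + p):(2L + p + k)],
            v[3L + p + k],
            x_names = template$x_names, aux_names = template$aux_names)
}

#' @export
print.cml_theta <- function(x, digits = 4L, ...) {
  cat("Risk model parameters (logistic + truncated log-normal)\n")
  print(round(as.numeric(x), digits))
  invisible(x)
}

#' Cohort data for constrained maximum likelihood fitting
#'
#' Validates and packages an observed cohort: binary outcome, integer-coded
#' conventional predictors, a new predictor Z strictly inside (0, 1), and
#' optional auxiliary covariates used only in the conditional model for Z.
#' Z values of exactly 0 or 1 are rejected (not clamped); pre-clip upstream
#' if the measurement process can produce boundary values.
#'
#' @param y Binary outcome vector (0/1).
#' @param x Matrix or data frame of conventional predictors (N x p).
#' @param z New-predictor values in the open interval (0, 1).
#' @param aux Optional matrix/data frame of auxiliary conditional-model
#'   covariates (e.g. age).
#' @return An object of class `"cml_cohort"` with components `y`, `x`, `z`,
#'   `z_cat` (the decile category `floor(10 z)` capped at 9), `aux`, `n`.
#' @export
cml_cohort <- function(y, x, z, aux = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  z <- as.numeric(z)
  n <- length(y)
  if (n < 1L) stop("empty cohort", call. = FALSE)
  if (nrow(x) != n || length(z) != n)
    stop("'y', 'x' and 'z' must have matching lengths", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("'y' must be binary 0/1", call. = FALSE)
  bad <- which(!(z > 0 & z < 1))
  if (length(bad))
    stop("'z' must lie strictly in (0, 1); offending rows: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (!is.null(aux)) {
    aux <- as.matrix(aux)
    storage.mode(aux) <- "double"
    if (nrow(aux) != n)
      stop("'aux' must have one row per observation", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  structure(
    list(y = y, x = x, z = z, z_cat = pmin(floor(10 * z), 9),
         aux = aux, n = n),
    class = "cml_cohort")
}

#' @export
print.cml_cohort <- function(x, ...) {
  cat("Cohort: ", x$n, " observations, ", ncol(x$x),
      " conventional predictors, ",
      if (is.null(x$aux)) 0L else ncol(x$aux), " auxiliary covariates\n",
      "cases: ", sum(x$y), " (", round(100 * mean(x$y), 2), "%)\n", sep = "")
  invisible(x)
}

# z feature entering the logistic linear predictor: categorized Z (decile
# integer) or raw Z; the conditional density is always on the continuous Z.
z_feature_values <- function(cohort, z_feature) {
  switch(match.arg(z_feature, c("categorized", "raw")),
         categorized = cohort$z_cat,
         raw = cohort$z)
}

# design matrix of the conditional-model linear predictor: (1, x, aux)
tau_design <- function(x, aux = NULL) {
  if (is.null(aux)) cbind(1, x) else cbind(1, x, aux)
}
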