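#' Control parameters for the constrained fit
#'
#' @param max_outer Maximum augmented-Lagrangian outer iterations.
#' @param inner_maxit Maximum BFGS iterations per inner solve.
#' @param tol_kkt Tolerance on the max-norm of the first-order (KKT)
#'   residual of the mean log-likelihood.
#' @param tol_feas Feasibility tolerance: all constraint values must not
#'   exceed this at the solution.
#' @param tol_act Absolute constraint-value threshold below which a
#'   constraint is reported active. Must be well below the typical
#'   magnitude of `d * P^e` (around 1e-3).
#' @param rho0,rho_mult Initial penalty parameter and its growth factor.
#' @param n_starts Number of optimization starts (the first from the
#'   unconstrained MLE, the rest from perturbed copies).
#' @param seed Optional seed used only when `n_starts > 1`.
#' @param freeze_tau If `TRUE`, hold the conditional-model parameters at
#'   their unconstrained estimates during the constrained solve.
#' @param quad_nodes Gauss-Legendre order for raw-Z marginalization.
#' @param polish Run the active-set Newton refinement of the KKT system
#'   after the augmented-Lagrangian phase (recommended).
#' @return A list of class `"cml_control"`.
#' @export
cml_control <- function(max_outer = 40L, inner_maxit = 300L,
                        tol_kkt = 1e-8, tol_feas = 1e-8, tol_act = 1e-6,
                        rho0 = 500, rho_mult = 10, n_starts = 1L,
                        seed = NULL, freeze_tau = FALSE, quad_nodes = 64L,
                        polish = TRUE) {
  structure(list(max_outer = max_outer, inner_maxit = inner_maxit,
                 tol_kkt = tol_kkt, tol_feas = tol_feas, tol_act = tol_act,
                 rho0 = rho0, rho_mult = rho_mult, n_starts = n_starts,
                 seed = seed, freeze_tau = freeze_tau,
                 quad_nodes = quad_nodes, polish = polish),
            class = "cml_control")
}

#' Unconstrained maximum likelihood fit
#'
#' Maximizes the observed-data log-likelihood without calibration
#' constraints. The likelihood separates: the beta block is an ordinary
#' logistic regression of the outcome on the conventional predictors and
#' the Z feature; the tau block is a truncated log-normal fit of Z on its
#' conditional-model design, initialized at method-of-moments values from
#' an untruncated log-scale regression. Both blocks are Newton-polished so
#' the score vanishes to high precision.
#'
#' @param cohort A [cml_cohort()] object.
#' @param z_feature `"categorized"` or `"raw"`.
#' @return A list with `theta` (the MLE as a [cml_theta()]), `loglik`, and
#'   `grad_norm` (max-norm of the score at the solution).
#' @export
cml_mle <- function(cohort, z_feature = "categorized") {
  if (length(unique(cohort$y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  zf <- z_feature_values(cohort, z_feature)
  X <- cbind(1, cohort$x, zf)
  gfit <- stats::glm.fit(X, cohort$y, family = stats::binomial(),
                         control = list(epsilon = 1e-12, maxit = 100L))
  if (!gfit$converged)
    stop("logistic block failed to converge after ", gfit$iter,
         " IRLS iterations (possible separation)", call. = FALSE)
  beta <- gfit$coefficients
  W <- tau_design(cohort$x, cohort$aux)
  lz <- log(cohort$z)
  tm <- stats::lm.fit(W, lz)$coefficients
  sig <- stats::sd(lz - drop(W %*% tm))
  p <- ncol(cohort$x)
  aux_names <- if (is.null(cohort$aux)) NULL else
    colnames(cohort$aux, do.NULL = FALSE, prefix = "a")
  mk <- function(b, t, s)
    cml_theta(b[1L], b[2:(p + 1L)], b[p + 2L], t, s,
              x_names = colnames(cohort$x), aux_names = aux_names)
  # tau block: BFGS on (tau_mean, log sigma) with analytic gradient
  tau_obj <- function(par) {
    th <- mk(beta, par[-length(par)], exp(par[length(par)]))
    -cml_loglik(th, cohort, z_feature) / cohort$n
  }
  tau_gr <- function(par) {
    sg <- exp(par[length(par)])
    th <- mk(beta, par[-length(par)], sg)
    g <- cml_score(th, cohort, z_feature)$gradient
    k <- length(par)
    -c(g[(p + 3L):(p + 1L + k)], g[p + 2L + k] * sg) / cohort$n
  }
  opt <- stats::optim(c(tm, log(sig)), tau_obj, tau_gr, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-14))
  theta <- mk(beta, opt$par[-length(opt$par)], exp(opt$par[length(opt$par)]))
  theta <- newton_polish_unconstrained(theta, cohort, z_feature)
  g <- cml_score(theta, cohort, z_feature)$gradient
  list(theta = theta, loglik = cml_loglik(theta, cohort, z_feature),
       grad_norm = max(abs(g)))
}

# a few damped Newton steps on the full score to drive it below 1e-8
newton_polish_unconstrained <- function(theta, cohort, z_feature,
                                        max_iter = 10L) {
  v <- as.numeric(theta)
  for (it in seq_len(max_iter)) {
    sh <- cml_score_hessian(theta_from_vector(v, theta), cohort, z_feature)
    if (max(abs(sh$gradient)) < 1e-9) break
    step <- tryCatch(solve(sh$hessian, -sh$gradient),
                     error = function(e) NULL)
    if (is.null(step)) break
    vn <- v + step
    if (vn[length(vn)] <= 0) vn[length(vn)] <- v[length(v)] / 2
    gn <- cml_score(theta_from_vector(vn, theta), cohort, z_feature)$gradient
    if (max(abs(gn)) >= max(abs(sh$gradient))) break
    v <- vn
  }
  theta_from_vector(v, theta)
}

#' Constrained maximum likelihood fit (workhorse)
#'
#' Maximizes the observed-data log-likelihood subject to the calibration
#' band constraints \eqn{C^+_r(\theta) \le 0}, \eqn{C^-_r(\theta) \le 0}.
#' The solve starts from the unconstrained MLE; if that point violates the
#' band, a feasibility-restoration phase (minimizing the squared violation)
#' precedes the main solve. The main solve is an augmented-Lagrangian
#' ascent with analytic likelihood and constraint gradients, followed by a
#' Newton refinement of the active-set KKT system, so that the returned
#' point satisfies the first-order conditions and feasibility to tight
#' tolerances (see [cml_control()]).
#'
#' @param cohort A [cml_cohort()] object.
#' @param constraints A [cml_constraints()] object.
#' @param pop A [cml_population()].
#' @param base A [cml_base_model()].
#' @param z_feature `"categorized"` or `"raw"`.
#' @param control A [cml_control()] list.
#' @param init Optional starting [cml_theta()]; defaults to the
#'   unconstrained MLE.
#' @return A list of class `"cml_fit"`: `theta_hat`, `loglik`, `converged`,
#'   `message`, `active_plus`, `active_minus`, `lambda` (multipliers on the
#'   mean log-likelihood scale), `constraint_values`, `kkt_residual`,
#'   `n_outer`, `theta_init`, `loglik_unconstrained`.
#' @export
fit_cml <- function(cohort, constraints, pop, base,
                    z_feature = "categorized", control = cml_control(),
                    init = NULL) {
  ctx <- constraint_context(constraints, pop, base, z_feature,
                            control$quad_nodes)
  mle <- cml_mle(cohort, z_feature)
  if (is.null(init)) init <- mle$theta
  n <- cohort$n
  template <- init
  d_theta <- length(as.numeric(template))
  free <- if (control$freeze_tau) seq_len(length(template$beta_x) + 2L)
          else seq_len(d_theta)
  v_fix <- as.numeric(init)

  fobj <- function(v) -cml_loglik(theta_from_vector(v, template), cohort,
                                  z_feature) / n
  gobj <- function(v) -cml_score(theta_from_vector(v, template), cohort,
                                 z_feature)$gradient / n
  cfun <- function(v) constraint_vector(theta_from_vector(v, template), ctx)
  jfun <- function(v) constraint_jacobian(theta_from_vector(v, template), ctx)

  solve_once <- function(v0) {
    res <- auglag_solve(v0, fobj, gobj, cfun, jfun, free, d_theta, control)
    if (control$polish)
      res <- kkt_polish(res, fobj, gobj, cfun, jfun, free, control)
    res
  }
  starts <- list(v_fix)
  if (control$n_starts > 1L) {
    if (!is.null(control$seed)) set.seed(control$seed)
    for (s in seq_len(control$n_starts - 1L)) {
      v <- v_fix
      v[free] <- v[free] + stats::rnorm(length(free), sd = 0.1)
      if (v[d_theta] <= 0) v[d_theta] <- v_fix[d_theta]
      starts <- c(starts, list(v))
    }
  }
  best <- NULL
  for (v0 in starts) {
    res <- solve_once(v0)
    if (is.null(best) || (res$feas <= control$tol_feas &&
                          (best$feas > control$tol_feas ||
                           -res$f > -best$f)))
      best <- res
  }
  res <- best
  theta_hat <- theta_from_vector(res$v, template)
  cv <- constraint_values(theta_hat, constraints, pop, base, z_feature,
                          control$quad_nodes)
  feas_ok <- max(c(cv$cplus, cv$cminus)[is.finite(c(cv$cplus, cv$cminus))]) <=
    control$tol_feas
  kkt_ok <- res$kkt <= max(control$tol_kkt, 1e-6)
  if (!feas_ok)
    stop("no feasible point found: the calibration band may be empty; ",
         "consider larger tolerances 'd' (max violation ",
         format(res$feas, digits = 3), ")", call. = FALSE)
  acts <- (function() {
    ap <- which(is.finite(constraints$d) & abs(cv$cplus) <= control$tol_act)
    am <- which(is.finite(constraints$d) & abs(cv$cminus) <= control$tol_act)
    if (length(intersect(ap, am)))
      stop("upper and lower constraints active simultaneously in interval ",
           intersect(ap, am)[1L], "; 'd' is degenerate (near zero)",
           call. = FALSE)
    list(plus = ap, minus = am)
  })()
  structure(
    list(theta_hat = theta_hat, loglik = cml_loglik(theta_hat, cohort,
                                                    z_feature),
         converged = feas_ok && kkt_ok,
         message = if (feas_ok && kkt_ok) "converged" else
           paste0("KKT residual ", format(res$kkt, digits = 3),
                  " above tolerance"),
         active_plus = acts$plus, active_minus = acts$minus,
         lambda = res$lambda, lambda_labels = constraint_labels(ctx),
         constraint_values = cv, kkt_residual = res$kkt,
         n_outer = res$n_outer, theta_init = init,
         loglik_unconstrained = mle$loglik, z_feature = ctx$z_feature),
    class = "cml_fit")
}

# augmented Lagrangian with inequality constraints c(v) <= 0; free = indices
# of parameters allowed to move; internal coordinates use log(sigma)
auglag_solve <- function(v0, fobj, gobj, cfun, jfun, free, d_theta, control) {
  last <- d_theta            # sigma position
  to_int <- function(v) { vi <- v[free]
    if (last %in% free) vi[match(last, free)] <- log(v[last]); vi }
  to_nat <- function(vi, vbase) { v <- vbase; v[free] <- vi
    if (last %in% free) v[last] <- exp(vi[match(last, free)]); v }
  chain <- function(v) { ch <- rep(1, length(free))
    if (last %in% free) ch[match(last, free)] <- v[last]; ch }

  vbase <- v0
  c0 <- cfun(v0)
  m <- length(c0)
  # feasibility restoration if the warm start violates the band
  if (max(c0) > 0) {
    margin <- 1e-4 * max(abs(c0))
    pen_f <- function(vi) { v <- to_nat(vi, vbase)
      sum(pmax(cfun(v) + margin, 0)^2) }
    pen_g <- function(vi) { v <- to_nat(vi, vbase)
      a <- pmax(cfun(v) + margin, 0)
      drop(2 * (a %*% jfun(v)))[free] * chain(v) }
    op <- stats::optim(to_int(v0), pen_f, pen_g, method = "BFGS",
                       control = list(maxit = control$inner_maxit,
                                      reltol = 1e-14))
    v0 <- to_nat(op$par, vbase)
  }
  lambda <- rep(0, m)
  rho <- control$rho0
  v <- v0
  prev_viol <- Inf
  kkt <- Inf; feas <- Inf
  # the outer loop only needs to localize the solution and the active set;
  # the Newton refinement afterwards drives the residuals to the contract
  tol_feas_c <- if (control$polish) 1e-5 else max(control$tol_feas, 1e-8)
  tol_kkt_c <- if (control$polish) 1e-3 else max(control$tol_kkt, 1e-6)
  reltol_c <- if (control$polish) 1e-9 else 1e-12
  cc_cache <- list(key = NULL, val = NULL)
  cfun_c <- function(vv) {
    if (!identical(vv, cc_cache$key))
      cc_cache <<- list(key = vv, val = cfun(vv))
    cc_cache$val
  }
  for (outer in seq_len(control$max_outer)) {
    al_f <- function(vi) { vv <- to_nat(vi, vbase)
      cc <- cfun_c(vv)
      fobj(vv) + sum(pmax(lambda + rho * cc, 0)^2 - lambda^2) / (2 * rho) }
    al_g <- function(vi) { vv <- to_nat(vi, vbase)
      cc <- cfun_c(vv)
      mult <- pmax(lambda + rho * cc, 0)
      (gobj(vv)[free] + drop(mult %*% jfun(vv))[free]) * chain(vv) }
    op <- stats::optim(to_int(v), al_f, al_g, method = "BFGS",
                       control = list(maxit = control$inner_maxit,
                                      reltol = reltol_c))
    v <- to_nat(op$par, vbase)
    cc <- cfun(v)
    lambda <- pmax(lambda + rho * cc, 0)
    viol <- max(c(cc, 0))
    kkt <- max(abs(gobj(v) + drop(lambda %*% jfun(v))))
    feas <- viol
    comp <- max(abs(lambda * cc))
    if (feas <= tol_feas_c && kkt <= tol_kkt_c &&
        comp <= (if (control$polish) 1e-4 else 1e-8))
      break
    if (viol > 0.25 * prev_viol) rho <- rho * control$rho_mult
    prev_viol <- viol
  }
  list(v = v, lambda = lambda, f = fobj(v), kkt = kkt, feas = feas,
       n_outer = outer)
}

# Newton refinement of the KKT system for the working active set; falls
# back to the augmented-Lagrangian iterate if it does not improve
kkt_polish <- function(res, fobj, gobj, cfun, jfun, free, control,
                       max_iter = 25L) {
  v <- res$v; lambda <- res$lambda
  cc <- cfun(v)
  act <- which(lambda > 1e-10 | cc > -control$tol_act)
  for (rebuild in 1:4) {
    Ffun <- function(par) {
      vv <- v; vv[free] <- par[seq_along(free)]
      la <- par[-seq_along(free)]
      J <- jfun(vv)
      r1 <- gobj(vv)[free]
      if (length(act))
        r1 <- r1 + drop(la %*% J[act, , drop = FALSE])[free]
      c(r1, cfun(vv)[act])
    }
    par <- c(v[free], if (length(act)) pmax(lambda[act], 0) else numeric(0))
    Fv <- tryCatch(Ffun(par), error = function(e) NULL)
    if (is.null(Fv) || any(!is.finite(Fv))) return(res)
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      if (max(abs(Fv)) < 1e-11) break
      Jf <- tryCatch(pracma::jacobian(Ffun, par), error = function(e) NULL)
      if (is.null(Jf) || any(!is.finite(Jf))) { ok <- FALSE; break }
      step <- tryCatch(solve(Jf, -Fv), error = function(e) NULL)
      if (is.null(step)) { ok <- FALSE; break }
      sig_free <- length(v) %in% free
      t <- 1
      improved <- FALSE
      while (t >= 1e-6) {
        parn <- par + t * step
        if (!sig_free || parn[length(free)] > 0) {
          Fn <- tryCatch(Ffun(parn), error = function(e) NULL)
          if (!is.null(Fn) && max(abs(Fn)) < max(abs(Fv))) {
            improved <- TRUE
            break
          }
        }
        t <- t / 2
      }
      if (!improved) { ok <- max(abs(Fv)) < 1e-9; break }
      par <- parn; Fv <- Fn
    }
    vn <- v; vn[free] <- par[seq_along(free)]
    lan <- rep(0, length(lambda))
    if (length(act)) lan[act] <- par[-seq_along(free)]
    ccn <- cfun(vn)
    # verify the working set: multipliers nonnegative, inactive feasible
    drop_idx <- if (length(act)) act[lan[act] < -1e-9] else integer(0)
    add_idx <- setdiff(which(ccn > control$tol_feas), act)
    if (ok && !length(drop_idx) && !length(add_idx)) {
      lan <- pmax(lan, 0)
      kkt <- max(abs(gobj(vn) + drop(lan %*% jfun(vn))))
      feas <- max(c(ccn, 0))
      if (feas <= max(res$feas, control$tol_feas) &&
          kkt <= max(res$kkt, control$tol_kkt))
        return(list(v = vn, lambda = lan, f = fobj(vn), kkt = kkt,
                    feas = feas, n_outer = res$n_outer))
      break
    }
    act <- sort(union(setdiff(act, drop_idx), add_idx))
  }
  res
}

#' Active constraint sets of a fitted model
#'
#' Indices of intervals whose upper (`K+`) or lower (`K-`) calibration
#' constraint holds with equality at the solution, within an absolute
#' tolerance on the constraint value. Disabled intervals (`d = Inf`) are
#' never active. An interval active on both sides signals a degenerate
#' (near-zero) tolerance and raises an error.
#'
#' @param fit A `"cml_fit"` object (or a `"cml"` model fit).
#' @param tol_act Absolute threshold on the constraint value.
#' @return A list with integer vectors `plus` and `minus`.
#' @export
active_set <- function(fit, tol_act = 1e-6) {
  if (inherits(fit, "cml")) fit <- fit$fit
  cv <- fit$constraint_values
  ap <- which(is.finite(cv$cplus) & abs(cv$cplus) <= tol_act)
  am <- which(is.finite(cv$cminus) & abs(cv$cminus) <= tol_act)
  both <- intersect(ap, am)
  if (length(both))
    stop("constraint ", both[1L], " active on both sides: tolerance 'd' ",
         "is degenerate", call. = FALSE)
  list(plus = ap, minus = am)
}

#' @export
print.cml_fit <- function(x, digits = 4L, ...) {
  cat("Constrained ML fit:", x$message, "\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      "(unconstrained:", format(x$loglik_unconstrained, digits = 8), ")\n")
  cat("active constraints: K+ = {",
      paste(x$active_plus, collapse = ","), "}, K- = {",
      paste(x$active_minus, collapse = ","), "}\n", sep = "")
  print(round(as.numeric(x$theta_hat), digits))
  invisible(x)
}
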