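#' Expected cases per 100,000 in population subgroups
#'
#' The delta-weighted average predicted risk over a subgroup of the target
#' population, scaled to a count per `per` persons. For a fitted risk model
#' the per-row risk is the conditional expectation of the logistic risk
#' over Z given the covariates; for a base model it is simply
#' \eqn{\varphi(x)}.
#'
#' @param object A [cml_theta()] (or a fitted `"cml"`/`"cml_fit"` object)
#'   or a [cml_base_model()].
#' @param pop A [cml_population()].
#' @param subset Optional logical vector over support rows, or a function
#'   of the covariate data frame returning one; default: all rows.
#' @param per Population size the count refers to (default 100,000).
#' @param z_feature `"categorized"` or `"raw"` (fitted models only).
#' @param nodes Gauss-Legendre order for raw-Z marginalization.
#' @return Expected number of cases per `per` persons in the subgroup.
#' @export
expected_cases <- function(object, pop, subset = NULL, per = 1e5,
                           z_feature = "categorized", nodes = 64L) {
  risk <- population_risk(object, pop, z_feature, nodes)
  keep <- resolve_subset(subset, pop)
  w <- pop$weight[keep]
  if (!length(w) || sum(w) <= 0)
    stop("subgroup carries no population mass", call. = FALSE)
  per * sum(risk[keep] * w) / sum(w)
}

# per-support-row predicted risk for a model object (Z marginalized) or a
# base model
population_risk <- function(object, pop, z_feature = "categorized",
                            nodes = 64L) {
  if (inherits(object, "cml")) object <- object$fit
  if (inherits(object, "cml_fit")) object <- object$theta_hat
  if (inherits(object, "cml_base_model")) return(predict(object, pop$x))
  if (!inherits(object, "cml_theta"))
    stop("'object' must be a parameter vector, fit, or base model",
         call. = FALSE)
  zf <- match.arg(z_feature, c("categorized", "raw"))
  ctx <- list(pop = pop, W = tau_design(pop$x, pop$aux), z_feature = zf,
              gl = if (zf == "raw") pracma::gaussLegendre(nodes, 0, 1)
                   else NULL)
  marginal_model_risk(object, ctx)
}

resolve_subset <- function(subset, pop) {
  if (is.null(subset)) return(rep(TRUE, nrow(pop$x)))
  if (is.function(subset)) subset <- subset(as.data.frame(pop$x))
  if (!is.logical(subset) || length(subset) != nrow(pop$x))
    stop("'subset' must select support rows (logical of length ",
         nrow(pop$x), ")", call. = FALSE)
  subset
}

#' Decile calibration table
#'
#' Splits the target population into deciles of the fitted model's
#' (Z-marginalized) risk and tabulates, per decile, the expected case
#' count under the fitted model against the "observed" count under the
#' benchmark base model — the construction used for calibration plots when
#' no independent validation cohort exists. Deciles are delta-weighted
#' population deciles of fitted risk with ties assigned to the lower bin;
#' when fewer than 10 distinct risk values exist, bins are merged with a
#' warning.
#'
#' @param object A fitted model ([cml_theta()], `"cml"`, `"cml_fit"`).
#' @param pop A [cml_population()].
#' @param benchmark A [cml_base_model()] providing the "observed" risk.
#' @param per Scale of the counts (default 100,000).
#' @inheritParams expected_cases
#' @return A data frame with columns `bin`, `mass`, `expected`, `observed`.
#' @export
decile_calibration <- function(object, pop, benchmark, per = 1e5,
                               z_feature = "categorized", nodes = 64L) {
  risk <- population_risk(object, pop, z_feature, nodes)
  obs <- predict(benchmark, pop$x)
  o <- order(risk)
  cum <- cumsum(pop$weight[o])
  # decile bin of each support row: ties to the lower bin via risk cutpoints
  edges <- vapply(seq_len(9L) / 10, function(pr)
    risk[o][which(cum >= pr - 1e-12)[1L]], numeric(1))
  edges <- unique(edges)
  if (length(unique(risk)) < 10L)
    warning("fewer than 10 distinct risk values; bins merged", call. = FALSE)
  bin <- findInterval(risk, edges, left.open = TRUE) + 1L
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    inb <- bin == b
    w <- pop$weight[inb]
    data.frame(bin = b, mass = sum(w),
               expected = per * sum(risk[inb] * w) / sum(w),
               observed = per * sum(obs[inb] * w) / sum(w))
  }))
  rownames(out) <- NULL
  out
}

#' Observed-to-expected adjustment of calibration targets
#'
#' Returns a constraint set whose targets are multiplied by per-interval
#' observed-to-expected ratios, correcting known mis-calibration of the
#' base model (for instance over-estimation in the high-risk tail) before
#' the targets are used as constraints.
#'
#' @param constraints A [cml_constraints()] object.
#' @param ratios Positive per-interval multipliers (recycled).
#' @return A new [cml_constraints()] object.
#' @export
oe_adjust <- function(constraints, ratios) {
  ratios <- rep_len(as.numeric(ratios), nrow(constraints$intervals))
  if (any(!(ratios > 0)))
    stop("observed-to-expected ratios must be positive", call. = FALSE)
  cml_constraints(constraints$intervals, constraints$targets,
                  d = constraints$d, oe = constraints$oe * ratios)
}

#' Per-interval calibration report of a constrained fit
#'
#' One row per risk interval: population mass, the calibration target
#' (after any observed-to-expected adjustment), the fitted model's
#' interval-averaged risk, their ratio, and whether either band constraint
#' is active.
#'
#' @param fit A `"cml_fit"` or `"cml"` object.
#' @param constraints,pop,base The constraint configuration used in the fit.
#' @inheritParams expected_cases
#' @return A data frame with one row per interval.
#' @export
calibration_report <- function(fit, constraints, pop, base,
                               z_feature = "categorized", nodes = 64L) {
  if (inherits(fit, "cml")) fit <- fit$fit
  ctx <- constraint_context(constraints, pop, base, z_feature, nodes)
  er <- interval_model_risk(fit$theta_hat, ctx)
  I <- ctx$I
  act <- rep("", I)
  act[fit$active_plus] <- "upper"
  act[fit$active_minus] <- "lower"
  data.frame(interval = seq_len(I),
             lower = constraints$intervals$lower,
             upper = constraints$intervals$upper,
             mass = ctx$mass,
             target = ctx$targets,
             model_risk = er,
             ratio = er / ctx$targets,
             d = ctx$d,
             active = act)
}
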