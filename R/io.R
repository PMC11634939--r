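#' Read a cohort from delimited text
#'
#' Reads a CSV/TSV file with a header row and assembles a [cml_cohort()]
#' using an explicit column mapping.
#'
#' @param file Path to the delimited file.
#' @param y,x,z Column names of the outcome, the conventional predictors
#'   (character vector) and the new predictor.
#' @param aux Optional auxiliary-covariate column names.
#' @param sep Field separator; `""` lets [utils::read.table()] use any
#'   whitespace, `","` reads CSV.
#' @return A [cml_cohort()].
#' @export
read_cohort <- function(file, y, x, z, aux = NULL, sep = ",") {
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE)
  need <- c(y, x, z, aux)
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("file ", file, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cml_cohort(dat[[y]], dat[x], dat[[z]],
             if (!is.null(aux)) dat[aux] else NULL)
}

#' Read a target-population table from delimited text
#'
#' Expects covariate columns plus a `weight` column of probabilities.
#'
#' @param file Path to the delimited file.
#' @param sep Field separator.
#' @param aux Optional auxiliary-covariate column names.
#' @return A [cml_population()].
#' @export
read_population <- function(file, sep = ",", aux = NULL) {
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!"weight" %in% names(dat))
    stop("population table needs a 'weight' column", call. = FALSE)
  xcols <- setdiff(names(dat), c("weight", aux))
  cml_population(dat[xcols], dat$weight,
                 if (!is.null(aux)) dat[aux] else NULL)
}

#' Read a base risk model from delimited text
#'
#' Expects covariate columns plus a `risk` column: the lookup form of the
#' base model.
#'
#' @param file Path to the delimited file.
#' @param sep Field separator.
#' @return A [cml_base_model()] lookup.
#' @export
read_base_model <- function(file, sep = ",") {
  dat <- utils::read.table(file, header = TRUE, sep = sep,
                           check.names = FALSE)
  cml_base_model(table = dat)
}

#' Serialize fit results to JSON
#'
#' Writes estimates, asymptotic standard errors, Wald tests, the active
#' constraint set, the covariance matrix and the calibration report (for
#' constrained fits) as machine-readable JSON.
#'
#' @param object A `"cml"` fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cml_json <- function(object, path) {
  theta <- as.numeric(object$fit$theta_hat)
  out <- list(
    estimate = as.list(theta),
    ase = as.list(stats::setNames(object$inference$ase, names(theta))),
    wald_p = as.list(stats::setNames(object$inference$wald$p,
                                     names(theta))),
    loglik = object$fit$loglik,
    converged = object$fit$converged,
    active_plus = object$fit$active_plus,
    active_minus = object$fit$active_minus,
    covariance = object$inference$vcov)
  if (object$constrained)
    out$calibration <- calibration_report(object$fit, object$constraints,
                                          object$population,
                                          object$base_model,
                                          object$z_feature)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
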