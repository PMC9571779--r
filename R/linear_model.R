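#' Fit an ordinary least squares model on a descriptor table
#'
#' Thin wrapper around [stats::lm()] that fits
#' `y = b0 + b1*x1 + ... + bn*xn` on all columns of `table` and returns a
#' compact, serialisable model object.  The design must be full rank; a
#' rank-deficient design is an error naming the dependent columns rather
#' than a silently dropped coefficient.
#'
#' @param table Numeric data.frame of descriptors (rows = samples).
#' @param y Numeric response vector, `length(y) == nrow(table)`.
#' @return An object of class `mlr_model`: list with `intercept`,
#'   named `coefficients`, `descriptor_names`, `provenance` (`"fitted"`),
#'   `fitted`, `residuals`, `r2`, `n`.
#' @seealso [predict.mlr_model()], [forward_stepwise_mlr()]
#' @examples
#' d <- data.frame(a = 1:6, b = c(2, 1, 4, 3, 6, 5))
#' m <- fit_ols(d, 1 + 2 * d$a - d$b)
#' m$coefficients
#' @export
fit_ols <- function(table, y) {
  stopifnot(is.data.frame(table), nrow(table) == length(y))
  if (nrow(table) < ncol(table) + 1L)
    stop("need at least p + 1 rows to fit an OLS model with p descriptors")
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("descriptor table must be numeric")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1L) {
    dep <- colnames(X)[is.na(fit$coefficients[-1])]
    stop("singular design: column(s) ", paste(dep, collapse = ", "),
         " are linearly dependent on the others")
  }
  co <- fit$coefficients
  structure(list(intercept = unname(co[1]),
                 coefficients = co[-1],
                 descriptor_names = colnames(X),
                 provenance = "fitted",
                 fitted = unname(fit$fitted.values),
                 residuals = unname(fit$residuals),
                 r2 = if (length(y) >= 3L && stats::sd(y) > 0 &&
                          stats::sd(fit$fitted.values) > 0)
                        r_squared(y, fit$fitted.values) else NA_real_,
                 n = length(y)),
            class = "mlr_model")
}

#' Predict from a linear QSAR model
#'
#' Applies `b0 + sum(bj * xj)` row-wise.  Every coefficient name must be
#' present as a column of `newdata`; extra columns are ignored.
#'
#' @param object An `mlr_model` (from [fit_ols()], [forward_stepwise_mlr()]
#'   or a published model constructor).
#' @param newdata Data.frame containing the model's descriptor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlr_model <- function(object, newdata, ...) {
  need <- names(object$coefficients)
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("newdata is missing descriptor column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[need])
  drop(object$intercept + X %*% object$coefficients)
}

#' @export
print.mlr_model <- function(x, ...) {
  cat("Linear QSAR model (", x$provenance, ")\n", sep = "")
  cat("  intercept:", format(x$intercept), "\n")
  for (nm in names(x$coefficients))
    cat(sprintf("  %-12s %s\n", nm, format(x$coefficients[[nm]])))
  if (!is.null(x$r2)) cat("  training R2:", format(x$r2, digits = 4), "n =", x$n, "\n")
  invisible(x)
}

#' Published linear model for individual-compound toxicity
#'
#' The fixed five-descriptor MLR model for the pEC50 of the 35 individual
#' compounds, with coefficients stored at full printed precision:
#' `pEC50 = 155.63 - 1.2453*Min-C - 7.7850*Rn-N + 0.27723*Tot-pc
#'  - 0.33616*Max-C-H + 0.23028*HOMO`.
#'
#' The descriptor values of the 35 compounds are not distributed with this
#' package (they are outputs of a proprietary quantum-chemical pipeline), so
#' this model is provided for prediction on user-supplied descriptor tables
#' with matching column names and units.
#'
#' @return An immutable `mlr_model` with provenance `"published_individual"`.
#' @export
published_mlr_individual <- function() {
  structure(list(intercept = 155.63,
                 coefficients = c("Min-C" = -1.2453, "Rn-N" = -7.7850,
                                  "Tot-pc" = 0.27723, "Max-C-H" = -0.33616,
                                  "HOMO" = 0.23028),
                 descriptor_names = c("Min-C", "Rn-N", "Tot-pc", "Max-C-H", "HOMO"),
                 provenance = "published_individual"),
            class = "mlr_model")
}

#' Published linear model for binary-mixture toxicity
#'
#' The fixed five-descriptor MLR model for the pEC50 of binary mixtures,
#' built on rule-9 hypothetical mixture descriptors:
#' `pEC50mix = 93.276 + 6.874*DRn-N + 0.003*DHOMO - 0.011*DTot-pc
#'  - 0.0000779*DMin-C - 0.00001334*DMax-C-H`.
#'
#' @return An immutable `mlr_model` with provenance `"published_mixture"`.
#' @export
published_mlr_mixture <- function() {
  structure(list(intercept = 93.276,
                 coefficients = c("DRn-N" = 6.874, "DHOMO" = 0.003,
                                  "DTot-pc" = -0.011, "DMin-C" = -0.0000779,
                                  "DMax-C-H" = -0.00001334),
                 descriptor_names = c("DRn-N", "DHOMO", "DTot-pc", "DMin-C", "DMax-C-H"),
                 provenance = "published_mixture"),
            class = "mlr_model")
}

#' Write a linear model to JSON
#'
#' @param model An `mlr_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, c("mlr_model", "rbf_network")))
  obj <- unclass(model)
  obj$class <- class(model)[1]
  # named atomic vectors must become lists to keep their names in JSON
  if (!is.null(obj$coefficients)) obj$coefficients <- as.list(obj$coefficients)
  if (!is.null(obj$scaler)) obj$scaler <- lapply(obj$scaler, as.list)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a model written by [write_model_json()]
#'
#' @param path JSON file path.
#' @return An `mlr_model` or `rbf_network`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  if (identical(cls, "mlr_model")) {
    obj$coefficients <- unlist(obj$coefficients)
  } else if (identical(cls, "rbf_network")) {
    obj$centers <- as.matrix(obj$centers)
    obj$weights <- as.numeric(obj$weights)
    if (!is.null(obj$scaler)) obj$scaler <- lapply(obj$scaler, unlist)
  } else stop("unrecognised model class in ", path)
  structure(obj, class = cls)
}
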