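#' Leverage of query samples against a training design
#'
#' Leverage of a query row x is `h = x' (X'X)^-1 x` with X the training
#' descriptor design including an intercept column.  For training rows this
#' is the hat-matrix diagonal: values lie in \[1/n, 1\] and sum to m + 1
#' (m descriptors plus the intercept); the minimum 1/n is attained at the
#' training centroid.
#'
#' @param train_table Training descriptor data.frame (full rank with
#'   intercept).
#' @param query_table Descriptor data.frame to evaluate (defaults to the
#'   training table itself).
#' @return Numeric vector of leverages, one per query row.
#' @export
leverages <- function(train_table, query_table = train_table) {
  Xt <- cbind(1, .as_descriptor_matrix(train_table))
  Xq <- cbind(1, .as_descriptor_matrix(query_table,
                                       colnames(.as_descriptor_matrix(train_table))))
  qrX <- qr(Xt)
  if (qrX$rank < ncol(Xt)) stop("singular training design: leverages undefined")
  R <- qr.R(qrX)[seq_len(qrX$rank), , drop = FALSE]
  # h_q = || R^-T x_q ||^2 since X'X = R'R
  B <- backsolve(R, t(Xq), transpose = TRUE)
  colSums(B^2)
}

#' Williams-plot applicability-domain report
#'
#' Flags training and test samples against the model's applicability domain:
#' the leverage axis uses the warning threshold `h* = 3 m / n` (m selected
#' descriptors, n training samples), and the residual axis the band
#' `+/- 3 sigma` of standardized residuals.  Training residuals are
#' leave-one-out (cross-validated) OLS residuals; test residuals are plain
#' prediction residuals of the supplied model.  By default sigma is the RMS
#' of the training LOO residuals; a fixed sigma can be supplied instead.
#'
#' The `3*m/n` threshold is used as stated for this model family; the more
#' common `3*(m+1)/n` variant (counting the intercept) is available via
#' `h_star_mode = "conventional"`.
#'
#' @param model An `mlr_model` used for test-set predictions; if `NULL`, an
#'   OLS model is fitted on `(train, y_train)`.
#' @param train,test Descriptor data.frames (test may be `NULL`).
#' @param y_train,y_test Response vectors.
#' @param m Number of model descriptors (default `ncol(train)`).
#' @param sigma Fixed sigma for the residual band; default `NULL` computes
#'   the RMS of the training LOO residuals.
#' @param h_star_mode `"3m_over_n"` (default) or `"conventional"`.
#' @return An `ad_report` list: `h_star`, `sigma`, and a data.frame
#'   `samples` with `role`, `leverage`, `std_residual`, `flag`
#'   (`in_domain`, `high_leverage`, `outlier_response`, `both`).
#' @export
williams_report <- function(model = NULL, train, test = NULL,
                            y_train, y_test = NULL,
                            m = ncol(train), sigma = NULL,
                            h_star_mode = c("3m_over_n", "conventional")) {
  h_star_mode <- match.arg(h_star_mode)
  stopifnot(nrow(train) == length(y_train))
  if (is.null(model)) model <- fit_ols(train, y_train)
  n <- nrow(train)
  h_star <- if (h_star_mode == "3m_over_n") 3 * m / n else 3 * (m + 1) / n

  pr <- press_ols(train[names(model$coefficients)], y_train)
  if (is.null(sigma)) sigma <- sqrt(mean(pr$loo_residuals^2))
  if (sigma <= 0) stop("sigma must be positive")

  h_tr <- leverages(train)
  std_tr <- pr$loo_residuals / sigma
  roles <- rep("train", n)
  lev <- h_tr; std <- std_tr
  if (!is.null(test)) {
    stopifnot(nrow(test) == length(y_test))
    h_te <- leverages(train, test)
    std_te <- (y_test - stats::predict(model, test)) / sigma
    roles <- c(roles, rep("test", nrow(test)))
    lev <- c(lev, h_te); std <- c(std, std_te)
  }
  high <- lev > h_star
  outl <- abs(std) > 3
  flag <- ifelse(high & outl, "both",
                 ifelse(high, "high_leverage",
                        ifelse(outl, "outlier_response", "in_domain")))
  structure(list(h_star = h_star, sigma = sigma,
                 samples = data.frame(role = roles, leverage = lev,
                                      std_residual = std, flag = flag)),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat("Applicability domain: h* =", format(x$h_star, digits = 4),
      " sigma =", format(x$sigma, digits = 4), "\n")
  print(table(x$samples$role, x$samples$flag))
  invisible(x)
}
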