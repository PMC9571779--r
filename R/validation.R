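#' Squared correlation between observed and predicted responses
#'
#' The determination coefficient used throughout the package is the squared
#' Pearson correlation of observed versus predicted values.  With this form,
#' the companion F statistic `R2 * (n - 2) / (1 - R2)` reproduces the
#' published F values of both models on both splits, which is the evidence
#' for the reconstruction (see the methods vignette).
#'
#' @param obs,pred Numeric vectors of equal length (n >= 3).
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 3L)
  if (stats::sd(obs) == 0) stop("R2 undefined: observed values are constant")
  stats::cor(obs, pred)^2
}

#' Root-mean-square error
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return `sqrt(mean((obs - pred)^2))`, in response units.
#' @export
rms_error <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1L)
  sqrt(mean((obs - pred)^2))
}

#' Mean absolute error
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return `mean(abs(obs - pred))`, in response units.
#' @export
mae <- function(obs, pred) {
  stopifnot(length(obs) == length(pred), length(obs) >= 1L)
  mean(abs(obs - pred))
}

#' Correlation-form F statistic
#'
#' `F = R2 * (n - 2) / (1 - R2)`, the F statistic of the simple regression of
#' observed on predicted values.
#'
#' @param obs,pred Numeric vectors.
#' @return F value; `Inf` when R2 = 1.
#' @seealso [f_from_r2()] for the closed form on a given (R2, n) pair.
#' @export
f_statistic <- function(obs, pred) {
  f_from_r2(r_squared(obs, pred), length(obs))
}

#' @rdname f_statistic
#' @param r2 Determination coefficient.
#' @param n Sample size.
#' @export
f_from_r2 <- function(r2, n) {
  stopifnot(r2 >= 0, r2 <= 1, n > 2)
  if (r2 == 1) return(Inf)
  r2 * (n - 2) / (1 - r2)
}

#' External predictive squared correlation q2_ext
#'
#' `1 - sum((obs - pred)^2) / sum((obs - train_mean)^2)` over the external
#' test set, with the training-set mean as the no-model baseline.
#'
#' @param obs_test,pred_test Test-set observed and predicted responses
#'   (n >= 3).
#' @param train_mean Mean response of the training set.
#' @return q2_ext (at most 1; negative when worse than the baseline).
#' @export
q2_ext <- function(obs_test, pred_test, train_mean) {
  stopifnot(length(obs_test) == length(pred_test), length(obs_test) >= 3L)
  denom <- sum((obs_test - train_mean)^2)
  if (denom == 0) stop("q2_ext undefined: test responses all equal the training mean")
  1 - sum((obs_test - pred_test)^2) / denom
}

#' Slope of the regression line through the origin
#'
#' `k = sum(obs * pred) / sum(pred^2)`, the no-intercept slope of observed on
#' predicted; a well-behaved model has k close to 1.
#'
#' @param obs,pred Numeric vectors.
#' @return The slope k.
#' @export
k_slope <- function(obs, pred) {
  stopifnot(length(obs) == length(pred))
  s <- sum(pred^2)
  if (s == 0) stop("k undefined: predictions are all zero")
  sum(obs * pred) / s
}

#' Leave-one-out PRESS and Q2 of an OLS fit via the hat matrix
#'
#' For ordinary least squares the leave-one-out residual of row i equals
#' `e_i / (1 - h_ii)` with `h_ii` the hat-matrix diagonal, so PRESS is
#' available without n refits.  `Q2 = 1 - PRESS / TSS` with TSS about the
#' full-sample mean.
#'
#' @param table Numeric descriptor data.frame.
#' @param y Response vector.
#' @return List with `press`, `q2` and the vector of `loo_residuals`.
#' @seealso [q2_loo()] for the generic refitting version.
#' @export
press_ols <- function(table, y) {
  X <- cbind(1, as.matrix(table))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design in press_ols")
  res <- qr.resid(qrX, y)
  h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  h <- pmin(h, 1 - 1e-10)
  loo <- res / (1 - h)
  press <- sum(loo^2)
  list(press = press, q2 = 1 - press / sum((y - mean(y))^2), loo_residuals = loo)
}

#' Leave-one-out cross-validated Q2 of an arbitrary trainer
#'
#' Refits the supplied trainer n times, each time leaving one row out, and
#' returns `Q2 = 1 - PRESS / TSS` where PRESS sums the squared held-out
#' prediction errors and TSS is about the full-sample mean.
#'
#' @param trainer Function `(table, y) -> model` where the model has a
#'   `predict(model, table)` method (see [ols_trainer()], [rbfnn_trainer()]).
#' @param table Descriptor data.frame (n >= 5 rows).
#' @param y Response vector.
#' @return List with `q2`, `press` and `loo_predictions`.
#' @export
q2_loo <- function(trainer, table, y) {
  n <- nrow(table)
  stopifnot(n == length(y), n >= 5L)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- tryCatch(trainer(table[-i, , drop = FALSE], y[-i]),
                  error = function(e) stop("LOO fold ", i, " failed: ",
                                           conditionMessage(e)))
    pred[i] <- stats::predict(m, table[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  list(q2 = 1 - press / sum((y - mean(y))^2), press = press, loo_predictions = pred)
}

#' OLS trainer for the cross-validation and randomization helpers
#'
#' @return A function `(table, y) -> mlr_model` wrapping [fit_ols()].
#' @export
ols_trainer <- function() function(table, y) fit_ols(table, y)

#' RBFNN trainer factory for the cross-validation and randomization helpers
#'
#' @param width_grid,max_centers,standardize Passed to [train_rbfnn()].
#' @return A function `(table, y) -> rbf_network`.
#' @export
rbfnn_trainer <- function(width_grid = seq(0.1, 4, by = 0.1),
                          max_centers = NULL, standardize = TRUE) {
  function(table, y) train_rbfnn(table, y, width_grid = width_grid,
                                 max_centers = max_centers,
                                 standardize = standardize)
}

#' Y-randomization (response scrambling) test
#'
#' Estimates the chance-correlation level of a modelling procedure: the
#' response is randomly permuted `n_reps` times (descriptors untouched), the
#' trainer is refitted on each scrambled response with the descriptor set
#' frozen, and the training-set R2, RMS and MAE of each refit are reported.
#' A sound model shows near-zero scrambled R2 and inflated errors.
#'
#' @param trainer Model-fitting function (see [q2_loo()]).
#' @param table Descriptor data.frame.
#' @param y Response vector.
#' @param n_reps Number of scrambling repetitions (default 10).
#' @param seed Integer seed; identical seeds give identical reports.
#' @return Data.frame with columns `rep`, `r2`, `rms`, `mae`, `failed`.
#' @export
y_randomization <- function(trainer, table, y, n_reps = 10L, seed = 20220927L) {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- data.frame(rep = seq_len(n_reps), r2 = NA_real_, rms = NA_real_,
                    mae = NA_real_, failed = FALSE)
  for (k in seq_len(n_reps)) {
    y_perm <- sample(y)
    m <- tryCatch(trainer(table, y_perm), error = function(e) NULL)
    if (is.null(m)) { out$failed[k] <- TRUE; next }
    p <- stats::predict(m, table)
    # a degenerate constant refit (e.g. an RBF net that selects no centres
    # on scrambled data) has zero chance correlation by definition
    out$r2[k] <- if (stats::sd(p) > 0) r_squared(y_perm, p) else 0
    out$rms[k] <- rms_error(y_perm, p)
    out$mae[k] <- mae(y_perm, p)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Blocked k-fold cross-validation
#'
#' Each block serves once as the held-out test set while the remaining
#' blocks train the model; per-fold and averaged R2, F and RMS are reported
#' for both the training and test role of each fold.
#'
#' @param trainer Model-fitting function (see [q2_loo()]).
#' @param table Descriptor data.frame.
#' @param y Response vector.
#' @param blocks Fold labels (factor or character), one per row; at least
#'   two distinct non-empty blocks.
#' @return List with `folds` (data.frame: `block`, `n_train`, `n_test`,
#'   `r2_train`, `f_train`, `rms_train`, `r2_test`, `f_test`, `rms_test`)
#'   and `average` (means over folds of the six statistics).
#' @export
blocked_kfold <- function(trainer, table, y, blocks) {
  stopifnot(nrow(table) == length(y), length(blocks) == length(y))
  blocks <- as.character(blocks)
  if (anyNA(blocks)) stop("unknown (NA) block label")
  labs <- unique(blocks)
  if (length(labs) < 2L) stop("need at least 2 blocks")
  folds <- data.frame(block = labs, n_train = NA_integer_, n_test = NA_integer_,
                      r2_train = NA_real_, f_train = NA_real_, rms_train = NA_real_,
                      r2_test = NA_real_, f_test = NA_real_, rms_test = NA_real_)
  for (i in seq_along(labs)) {
    te <- blocks == labs[i]
    m <- trainer(table[!te, , drop = FALSE], y[!te])
    p_tr <- stats::predict(m, table[!te, , drop = FALSE])
    p_te <- stats::predict(m, table[te, , drop = FALSE])
    folds$n_train[i] <- sum(!te); folds$n_test[i] <- sum(te)
    if (stats::sd(p_tr) > 0) {   # a degenerate (constant) model has no R2
      folds$r2_train[i] <- r_squared(y[!te], p_tr)
      folds$f_train[i] <- f_from_r2(folds$r2_train[i], sum(!te))
    }
    folds$rms_train[i] <- rms_error(y[!te], p_tr)
    if (sum(te) >= 3L && stats::sd(y[te]) > 0 && stats::sd(p_te) > 0) {
      folds$r2_test[i] <- r_squared(y[te], p_te)
      folds$f_test[i] <- f_from_r2(folds$r2_test[i], sum(te))
    }
    folds$rms_test[i] <- rms_error(y[te], p_te)
  }
  avg <- colMeans(folds[c("r2_train", "f_train", "rms_train",
                          "r2_test", "f_test", "rms_test")], na.rm = TRUE)
  list(folds = folds, average = avg)
}

#' Summary validation report for an (observed, predicted) pairing
#'
#' Convenience bundle of the scalar statistics: n, R2, RMS, F, MAE, and --
#' when `train_mean` is supplied (external-set role) -- q2_ext and the
#' through-origin slopes of observed-on-predicted (`k`) and
#' predicted-on-observed (`k_prime`).
#'
#' @param obs,pred Observed and predicted responses.
#' @param train_mean Optional training-set mean response enabling the
#'   external statistics.
#' @return Named list of statistics.
#' @export
validation_report <- function(obs, pred, train_mean = NULL) {
  out <- list(n = length(obs),
              r2 = r_squared(obs, pred),
              rms = rms_error(obs, pred),
              f = f_statistic(obs, pred),
              mae = mae(obs, pred))
  if (!is.null(train_mean)) {
    out$q2_ext <- q2_ext(obs, pred, train_mean)
    out$k <- k_slope(obs, pred)
    out$k_prime <- k_slope(pred, obs)
  }
  out
}
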