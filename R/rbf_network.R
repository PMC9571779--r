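#' Radial basis function network regression
#'
#' A three-layer RBF network for QSAR regression: an input layer of p
#' descriptors, a hidden layer of Gaussian units centred on selected
#' training samples, and a single linear output unit with bias
#' (architecture p-nk-1).  Hidden unit j responds to input x with
#' `h_j(x) = exp(-||x - c_j||^2 / r^2)`, a shared width r across units; the
#' output is `y(x) = sum_j w_j h_j(x) + b`, fitted by least squares.
#' Centres are chosen from the training rows by forward subset selection and
#' the width by grid search (see [train_rbfnn()]).
#'
#' @name rbf_network
NULL

.as_descriptor_matrix <- function(table, names_needed = NULL) {
  X <- as.matrix(table)
  if (!is.numeric(X)) stop("descriptor table must be numeric")
  if (!is.null(names_needed)) {
    miss <- setdiff(names_needed, colnames(X))
    if (length(miss))
      stop("table is missing descriptor column(s): ", paste(miss, collapse = ", "))
    X <- X[, names_needed, drop = FALSE]
  }
  X
}

# Gaussian activations of rows of X (matrix) against rows of centers
.rbf_act <- function(X, centers, width) {
  if (width <= 0) stop("RBF width must be positive")
  d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) - 2 * X %*% t(centers)
  d2[d2 < 0] <- 0  # numerical noise
  exp(-d2 / width^2)
}

#' Hidden-layer activations of an RBF network
#'
#' Entry (i, j) is `exp(-||x_i - c_j||^2 / r^2)` for row i of `table` and
#' centre j, in (0, 1]; an input equal to a centre activates that unit at
#' exactly 1.  If the network was trained on standardized descriptors the
#' stored scaler is applied first.
#'
#' @param net An `rbf_network` from [train_rbfnn()].
#' @param table Descriptor data.frame with the network's input columns.
#' @return Numeric matrix, rows of `table` by hidden units.
#' @export
rbf_activations <- function(net, table) {
  stopifnot(inherits(net, "rbf_network"))
  X <- .as_descriptor_matrix(table, net$descriptor_names)
  if (!is.null(net$scaler))
    X <- scale(X, center = net$scaler$center, scale = net$scaler$scale)
  .rbf_act(X, net$centers, net$width)
}

# least-squares output layer on an activation design; min-norm fallback when
# the Gaussian design is numerically rank deficient (tiny widths)
.fit_output_layer <- function(A, y, cond_limit = 1e12) {
  D <- cbind(1, A)
  sv <- svd(D)
  if (sv$d[1] / max(sv$d[length(sv$d)], .Machine$double.xmin) > cond_limit) {
    warning("ill-conditioned activation matrix; minimum-norm least squares used")
    pos <- sv$d > sv$d[1] * 1e-14
    co <- sv$v[, pos, drop = FALSE] %*% ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  } else {
    co <- qr.coef(qr(D), y)
  }
  co <- unname(drop(co))
  list(bias = co[1], weights = co[-1])
}

#' Fit the output weights of an RBF network by least squares
#'
#' Given fixed centres and width, regresses the response on the Gaussian
#' activations plus an intercept column.  When the activation design is
#' numerically ill-conditioned (condition number above `1e12`, as happens
#' for very small widths) a warning is raised and the minimum-norm solution
#' is returned.
#'
#' @param centers Numeric matrix of centres (rows) in the same descriptor
#'   space as `table` (no standardization is applied here).
#' @param width Shared Gaussian width r > 0.
#' @param table Descriptor data.frame (rows >= number of centres + 1).
#' @param y Response vector.
#' @return List with `weights` (one per centre) and `bias`.
#' @export
fit_output_weights <- function(centers, width, table, y) {
  centers <- as.matrix(centers)
  X <- .as_descriptor_matrix(table)
  stopifnot(nrow(X) == length(y), nrow(X) >= nrow(centers) + 1L)
  A <- .rbf_act(X, centers, width)
  .fit_output_layer(A, y)
}

# LOO PRESS of the linear output fit for a given activation design
.press_of_activations <- function(A, y) {
  D <- cbind(1, A)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) return(Inf)
  res <- qr.resid(qrD, y)
  h <- rowSums(qr.Q(qrD)[, seq_len(qrD$rank), drop = FALSE]^2)
  if (any(h > 1 - 1e-8)) return(Inf)  # an effectively interpolated point: LOO blows up
  sum((res / (1 - h))^2)
}

#' Forward subset selection of RBF centres from the training rows
#'
#' Greedily grows the centre set: at each step the training row whose
#' addition most reduces the selection criterion is added; selection stops
#' at `max_centers` or when no candidate improves the criterion.  The
#' default criterion is the leave-one-out SSE (PRESS) of the linear output
#' fit, which guards against the interpolation trap of the in-sample SSE.
#' Ties are broken by row index, so selection is deterministic.
#'
#' @param table Descriptor data.frame (raw space; standardize beforehand if
#'   desired).
#' @param y Response vector.
#' @param width Shared Gaussian width.
#' @param max_centers Maximum number of hidden units (default
#'   `min(nrow - 2, 30)`).
#' @param criterion `"loo"` (PRESS, default) or `"sse"` (in-sample SSE).
#' @return Integer vector of selected row indices, in selection order.
#' @export
forward_subset_select_centers <- function(table, y, width,
                                          max_centers = NULL,
                                          criterion = c("loo", "sse")) {
  criterion <- match.arg(criterion)
  X <- .as_descriptor_matrix(table)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (is.null(max_centers)) max_centers <- min(n - 2L, 30L)
  max_centers <- min(max_centers, n)
  score <- function(A) {
    if (criterion == "loo") .press_of_activations(A, y)
    else {
      D <- cbind(1, A)
      qrD <- qr(D)
      if (qrD$rank < ncol(D)) Inf else sum(qr.resid(qrD, y)^2)
    }
  }
  A_full <- .rbf_act(X, X, width)  # column j = activations of candidate centre j
  sel <- integer(0)
  best_score <- sum((y - mean(y))^2)  # intercept-only baseline
  while (length(sel) < max_centers) {
    cand <- setdiff(seq_len(n), sel)
    sc <- vapply(cand, function(j)
      score(A_full[, c(sel, j), drop = FALSE]), numeric(1))
    j_best <- cand[which.min(sc)]
    if (min(sc) >= best_score - 1e-12 * max(1, best_score)) break
    sel <- c(sel, j_best)
    best_score <- min(sc)
  }
  sel
}

#' Train an RBF neural network with width grid search
#'
#' For each candidate width, centres are chosen by forward subset selection
#' and the output layer fitted by least squares; the network minimising the
#' leave-one-out SSE of the output fit is returned.  By default descriptors
#' are standardized (z-score on the training set) before any distance is
#' computed, since Euclidean distance over raw molecular descriptors of
#' wildly different scales would be dominated by the largest-scaled column;
#' the scaler is stored in the model and reapplied at prediction time.
#'
#' @param table Training descriptor data.frame.
#' @param y Training response vector.
#' @param width_grid Candidate widths (default `seq(0.1, 4, by = 0.1)`, the
#'   conventional scan for standardized descriptors).
#' @param max_centers Cap on hidden units (default `min(nrow - 2, 30)`).
#' @param standardize Standardize descriptors before training (default TRUE).
#' @return An `rbf_network`: `centers` (matrix, scaled space), `center_idx`
#'   (training row indices), `width`, `weights`, `bias`, `n_hidden`,
#'   `scaler`, `descriptor_names`, `fitted`, `residuals`, `loo_sse`, `r2`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
#' y <- sin(d$x1) + 0.1 * rnorm(40)
#' net <- train_rbfnn(d, y, width_grid = c(1, 2), max_centers = 6)
#' net$width
#' @export
train_rbfnn <- function(table, y, width_grid = seq(0.1, 4, by = 0.1),
                        max_centers = NULL, standardize = TRUE) {
  if (!length(width_grid)) stop("width_grid must not be empty")
  if (any(width_grid <= 0)) stop("RBF widths must be positive")
  X_raw <- .as_descriptor_matrix(table)
  stopifnot(nrow(X_raw) == length(y), nrow(X_raw) >= 4L)
  scaler <- NULL
  X <- X_raw
  if (standardize) {
    ctr <- colMeans(X_raw)
    scl <- apply(X_raw, 2, stats::sd)
    scl[scl == 0] <- 1
    scaler <- list(center = ctr, scale = scl)
    X <- scale(X_raw, center = ctr, scale = scl)
  }
  Xdf <- as.data.frame(X)
  best <- NULL
  for (w in width_grid) {
    sel <- forward_subset_select_centers(Xdf, y, w, max_centers = max_centers)
    if (!length(sel)) {  # constant-response degenerate case: intercept only
      loo <- sum((y - mean(y))^2) * nrow(X) / max(1, nrow(X) - 1)
      cand <- list(width = w, sel = sel, loo = loo)
    } else {
      A <- .rbf_act(X, X[sel, , drop = FALSE], w)
      cand <- list(width = w, sel = sel, loo = .press_of_activations(A, y))
    }
    if (is.null(best) || cand$loo < best$loo) best <- cand
  }
  sel <- best$sel
  if (length(sel)) {
    A <- .rbf_act(X, X[sel, , drop = FALSE], best$width)
    out <- .fit_output_layer(A, y)
    fitted <- drop(cbind(1, A) %*% c(out$bias, out$weights))
  } else {
    out <- list(bias = mean(y), weights = numeric(0))
    fitted <- rep(mean(y), length(y))
  }
  structure(list(centers = X[sel, , drop = FALSE],
                 center_idx = sel,
                 width = best$width,
                 weights = unname(out$weights),
                 bias = unname(out$bias),
                 n_hidden = length(sel),
                 scaler = scaler,
                 descriptor_names = colnames(X_raw),
                 fitted = fitted,
                 residuals = y - fitted,
                 loo_sse = best$loo,
                 r2 = if (stats::sd(y) > 0 && stats::sd(fitted) > 0)
                        r_squared(y, fitted) else NA_real_,
                 n = length(y)),
            class = "rbf_network")
}

#' Predict from a trained RBF network
#'
#' @param object An `rbf_network`.
#' @param newdata Descriptor data.frame with the network's input columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rbf_network <- function(object, newdata, ...) {
  if (object$n_hidden == 0L)
    return(rep(object$bias, nrow(newdata)))
  A <- rbf_activations(object, newdata)
  drop(object$bias + A %*% object$weights)
}

#' @export
print.rbf_network <- function(x, ...) {
  cat("RBF network ", length(x$descriptor_names), "-", x$n_hidden, "-1",
      ", width r = ", format(x$width), "\n", sep = "")
  if (!is.na(x$r2)) cat("  training R2:", format(x$r2, digits = 4),
                        " LOO SSE:", format(x$loo_sse, digits = 4), "\n")
  invisible(x)
}
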