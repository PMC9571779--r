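#' Screen a descriptor pool before model building
#'
#' Two-stage pre-screen of a raw descriptor table, mirroring the usual
#' heuristic cascade of QSAR descriptor software.  First, *nonconforming*
#' columns are removed: any column with missing values, zero variance, or
#' (when a response is supplied) absolute correlation with the response
#' below `response_floor`.  Second, *inter-correlated* columns are pruned:
#' among every pair with `|Pearson r| >= corr_threshold`, the member less
#' correlated with the response is dropped (ties, or no response, keep the
#' earlier column).  Retained columns are pairwise `|r| < corr_threshold`.
#'
#' @param table Descriptor data.frame.
#' @param y Optional response vector guiding the correlated-pair tie-break
#'   and the relevance floor.
#' @param corr_threshold Pairwise correlation cut-off (default 0.8).
#' @param response_floor Minimum `|cor(descriptor, y)|` to count as
#'   conforming (default 0.01; ignored when `y` is `NULL`).
#' @return List with `table` (the pruned data.frame) and `report`, a
#'   `screening_report` with counts `n_input`, `n_removed_invalid`,
#'   `n_removed_correlated`, `n_retained` and the name lists.
#' @export
screen_descriptors <- function(table, y = NULL, corr_threshold = 0.8,
                               response_floor = 0.01) {
  stopifnot(is.data.frame(table), ncol(table) >= 1L)
  if (!is.null(y)) stopifnot(length(y) == nrow(table))
  nms <- names(table)
  invalid <- vapply(nms, function(nm) {
    col <- table[[nm]]
    if (!is.numeric(col) || anyNA(col)) return(TRUE)
    if (stats::sd(col) == 0) return(TRUE)
    if (!is.null(y) && stats::sd(y) > 0 && abs(stats::cor(col, y)) < response_floor)
      return(TRUE)
    FALSE
  }, logical(1))
  keep <- nms[!invalid]
  if (!length(keep)) stop("empty descriptor pool: all columns removed as nonconforming")

  # prune correlated pairs, dropping the member less correlated with y
  removed_cor <- character(0)
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(stats::cor(table[keep]))
    diag(cm) <- 0
    if (max(cm) < corr_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- keep[sort(idx)]
    drop_nm <- if (!is.null(y)) {
      ry <- abs(c(stats::cor(table[[pair[1]]], y), stats::cor(table[[pair[2]]], y)))
      if (ry[2] < ry[1]) pair[2] else if (ry[1] < ry[2]) pair[1] else pair[2]
    } else pair[2]
    removed_cor <- c(removed_cor, drop_nm)
    keep <- setdiff(keep, drop_nm)
  }
  if (!length(keep)) stop("empty descriptor pool: all columns removed")
  report <- structure(list(n_input = length(nms),
                           n_removed_invalid = sum(invalid),
                           n_removed_correlated = length(removed_cor),
                           n_retained = length(keep),
                           removed_names = c(nms[invalid], removed_cor),
                           retained_names = keep),
                      class = "screening_report")
  list(table = table[keep], report = report)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Descriptor screening:", x$n_input, "in ->",
      x$n_removed_invalid, "nonconforming removed,",
      x$n_removed_correlated, "inter-correlated removed,",
      x$n_retained, "retained\n")
  invisible(x)
}

#' Forward stepwise multiple linear regression
#'
#' Greedy descriptor selection for an OLS model: at each step the candidate
#' descriptor giving the largest increase in R-squared is added, provided
#' its partial F-to-enter exceeds `f_to_enter`; selection stops at
#' `max_terms` descriptors or when no candidate qualifies.  Ties are broken
#' by column order, so the selection path is deterministic.  Candidates that
#' would make the design singular are skipped and recorded.
#'
#' @param table Descriptor data.frame.
#' @param y Response vector (`nrow(table) > max_terms + 1` required).
#' @param max_terms Maximum number of descriptors to select (default 5).
#' @param f_to_enter Partial-F threshold for inclusion (default 4.0).
#' @return List with `selected` (ordered names), `model` (the final
#'   `mlr_model`), `steps` (data.frame: `step`, `name`, `r2`, `partial_f`)
#'   and `skipped` (names skipped for collinearity, if any).
#' @examples
#' set.seed(1)
#' d <- as.data.frame(matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("d", 1:5))))
#' sel <- forward_stepwise_mlr(d, 2 * d$d2 - d$d4 + rnorm(60, sd = 0.1))
#' sel$selected
#' @export
forward_stepwise_mlr <- function(table, y, max_terms = 5L, f_to_enter = 4.0) {
  stopifnot(is.data.frame(table), length(y) == nrow(table))
  max_terms <- min(as.integer(max_terms), ncol(table))
  if (nrow(table) <= max_terms + 1L)
    stop("need more than max_terms + 1 rows for stepwise selection")
  selected <- character(0)
  skipped <- character(0)
  steps <- data.frame(step = integer(0), name = character(0),
                      r2 = numeric(0), partial_f = numeric(0))
  rss <- function(cols) {
    X <- cbind(1, as.matrix(table[cols]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) return(NA_real_)
    sum(qr.resid(qrX, y)^2)
  }
  tss <- sum((y - mean(y))^2)
  rss_cur <- tss
  n <- length(y)
  while (length(selected) < max_terms) {
    cand <- setdiff(names(table), c(selected, skipped))
    if (!length(cand)) break
    rss_new <- vapply(cand, function(nm) rss(c(selected, nm)), numeric(1))
    bad <- is.na(rss_new)
    if (any(bad)) {
      skipped <- c(skipped, cand[bad])
      warning("skipping collinear candidate(s): ", paste(cand[bad], collapse = ", "))
      cand <- cand[!bad]; rss_new <- rss_new[!bad]
      if (!length(cand)) break
    }
    best <- which.min(rss_new)  # max R2 increase = min RSS; first index on ties
    p_new <- length(selected) + 1L
    df_resid <- n - p_new - 1L
    if (df_resid <= 0L) break
    partial_f <- if (rss_new[best] <= 0) Inf else
      (rss_cur - rss_new[best]) / (rss_new[best] / df_resid)
    if (partial_f < f_to_enter) break
    selected <- c(selected, cand[best])
    rss_cur <- rss_new[best]
    steps <- rbind(steps, data.frame(step = length(selected), name = cand[best],
                                     r2 = 1 - rss_cur / tss, partial_f = partial_f))
    if (rss_cur <= .Machine$double.eps * tss) break
  }
  if (!length(selected)) stop("no descriptor met the F-to-enter threshold")
  list(selected = selected,
       model = fit_ols(table[selected], y),
       steps = steps,
       skipped = skipped)
}
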