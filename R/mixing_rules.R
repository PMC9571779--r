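#' The eleven hypothetical-descriptor mixing rules
#'
#' A binary mixture does not have measured molecular descriptors of its own;
#' instead a *hypothetical* mixture descriptor DMIX is computed from the two
#' components' descriptors D1, D2 and their composition fractions X1, X2
#' (X1 + X2 = 1) under one of eleven candidate mixing rules.  Rule 4 is the
#' linear, concentration-addition-like weighting X1*D1 + X2*D2; rule 9
#' (the package default) is the cubic weighting X1*D1^3 + X2*D2^3, which lets
#' the component with the larger descriptor magnitude dominate the mixture
#' descriptor.
#'
#' The registry returned here is the single source of the rule formulas used
#' by [apply_rule()] and [build_mixture_descriptor_table()].
#'
#' @return A data.frame with columns `rule_id` (1--11) and `label`
#'   (canonical formula text).
#' @examples
#' mixing_rules()
#' @export
mixing_rules <- function() {
  data.frame(rule_id = 1:11,
             label = vapply(.rule_registry, `[[`, "", "label"))
}

# registry: each entry combines vectors d1, d2, x1, x2 -> DMIX.
# Even-root rules (3, 11) and the root-compensated cubic rule 10 refuse
# negative radicands; rule 7 uses the real (signed) cube root, which is
# defined for all real radicands.
.cbrt <- function(v) sign(v) * abs(v)^(1 / 3)

.sqrt_checked <- function(v, rule_id) {
  if (any(v < 0))
    stop(sprintf("mixing rule %d: negative radicand (min %.6g); rule undefined for these inputs",
                 rule_id, min(v)))
  sqrt(v)
}

.cbrt_checked <- function(v, rule_id) {
  if (any(v < 0))
    stop(sprintf("mixing rule %d: negative radicand (min %.6g); rule undefined for these inputs",
                 rule_id, min(v)))
  v^(1 / 3)
}

.rule_registry <- list(
  list(label = "DMIX = D1 + D2",
       fn = function(d1, d2, x1, x2) d1 + d2),
  list(label = "DMIX = (X1*D1 + X2*D2)^2",
       fn = function(d1, d2, x1, x2) (x1 * d1 + x2 * d2)^2),
  list(label = "DMIX = sqrt(X1*D1 + X2*D2)",
       fn = function(d1, d2, x1, x2) .sqrt_checked(x1 * d1 + x2 * d2, 3L)),
  list(label = "DMIX = X1*D1 + X2*D2",
       fn = function(d1, d2, x1, x2) x1 * d1 + x2 * d2),
  list(label = "DMIX = X1^2*D1 + X2^2*D2",
       fn = function(d1, d2, x1, x2) x1^2 * d1 + x2^2 * d2),
  list(label = "DMIX = X1^3*D1 + X2^3*D2",
       fn = function(d1, d2, x1, x2) x1^3 * d1 + x2^3 * d2),
  list(label = "DMIX = cbrt(X1^3*D1 + X2^3*D2)",
       fn = function(d1, d2, x1, x2) .cbrt(x1^3 * d1 + x2^3 * d2)),
  list(label = "DMIX = X1*D1^2 + X2*D2^2",
       fn = function(d1, d2, x1, x2) x1 * d1^2 + x2 * d2^2),
  list(label = "DMIX = X1*D1^3 + X2*D2^3",
       fn = function(d1, d2, x1, x2) x1 * d1^3 + x2 * d2^3),
  list(label = "DMIX = cbrt(X1*D1^3 + X2*D2^3)",
       fn = function(d1, d2, x1, x2) .cbrt_checked(x1 * d1^3 + x2 * d2^3, 10L)),
  list(label = "DMIX = sqrt(X1*D1^2 + X2*D2^2)",
       fn = function(d1, d2, x1, x2) .sqrt_checked(x1 * d1^2 + x2 * d2^2, 11L))
)

#' Apply a mixing rule to two component descriptor values
#'
#' Computes the hypothetical mixture descriptor DMIX for component descriptor
#' values `d1`, `d2` and composition fractions `x1`, `x2` under the chosen
#' rule (see [mixing_rules()]).  All arguments are vectorised and recycled.
#'
#' Every rule is symmetric in its two components: swapping `(d1, x1)` with
#' `(d2, x2)` leaves the result unchanged.
#'
#' @param rule_id Integer 1--11.
#' @param d1,d2 Component descriptor values.
#' @param x1,x2 Composition fractions; `x1 + x2` must equal 1 within `1e-9`.
#' @return Numeric vector of mixture descriptor values.
#' @examples
#' apply_rule(9, d1 = 2, d2 = 1, x1 = 0.75, x2 = 0.25)  # 6.25
#' apply_rule(4, d1 = 2, d2 = 4, x1 = 0.25, x2 = 0.75)  # 3.5
#' @export
apply_rule <- function(rule_id, d1, d2, x1, x2) {
  rule_id <- as.integer(rule_id)
  if (length(rule_id) != 1L || is.na(rule_id) || rule_id < 1L || rule_id > 11L)
    stop("rule_id must be a single integer in 1..11")
  if (any(abs(x1 + x2 - 1) > 1e-9))
    stop("composition fractions must satisfy x1 + x2 = 1 (tolerance 1e-9)")
  .rule_registry[[rule_id]]$fn(d1, d2, x1, x2)
}

#' Build the mixture descriptor table under a mixing rule
#'
#' Combines a per-compound descriptor table with a mixture composition table
#' into one row of hypothetical mixture descriptors per mixture.  Column
#' names are prefixed with `"D"` (e.g. `Rn-N` becomes `DRn-N`), marking them
#' as mixture-level quantities.
#'
#' @param rule_id Mixing rule, see [mixing_rules()]; default 9.
#' @param compound_descriptors Numeric data.frame of descriptors, one row per
#'   compound, row names (or an `index` column) identifying compounds.
#' @param mixtures Data.frame with columns `component_a`, `component_b`,
#'   `x_a`, `x_b` (as from [load_mixture_table()] or [simulate_study()]), and
#'   optionally `mixture_no` for output row names.
#' @return Numeric data.frame, one row per mixture, columns `D<name>`.
#' @examples
#' desc <- data.frame(A = c(1, 3), row.names = c("1", "2"))
#' mixes <- data.frame(component_a = 1, component_b = 2, x_a = 0.5, x_b = 0.5)
#' build_mixture_descriptor_table(4, desc, mixes)  # DA = 2
#' @export
build_mixture_descriptor_table <- function(rule_id = 9L, compound_descriptors, mixtures) {
  stopifnot(is.data.frame(compound_descriptors), is.data.frame(mixtures))
  ids <- if ("index" %in% names(compound_descriptors)) {
    idx <- as.character(compound_descriptors$index)
    compound_descriptors <- compound_descriptors[setdiff(names(compound_descriptors), "index")]
    idx
  } else rownames(compound_descriptors)
  if (!all(vapply(compound_descriptors, is.numeric, logical(1))))
    stop("compound_descriptors must be all-numeric (apart from an optional index column)")
  ia <- match(as.character(mixtures$component_a), ids)
  ib <- match(as.character(mixtures$component_b), ids)
  if (anyNA(ia) || anyNA(ib)) {
    miss <- which(is.na(ia) | is.na(ib))
    stop("mixture(s) ", paste(utils::head(miss, 5L), collapse = ", "),
         " reference compounds missing from the descriptor table")
  }
  out <- as.data.frame(lapply(compound_descriptors, function(col)
    apply_rule(rule_id, col[ia], col[ib], mixtures$x_a, mixtures$x_b)))
  names(out) <- paste0("D", names(compound_descriptors))
  rownames(out) <- if ("mixture_no" %in% names(mixtures))
    as.character(mixtures$mixture_no) else NULL
  out
}

#' Compare the eleven mixing rules by preliminary OLS modelling
#'
#' For each mixing rule, builds the mixture descriptor table, fits an
#' ordinary-least-squares model of the mixture response on all descriptors
#' over the training mixtures, and reports R-squared, adjusted R-squared, the
#' correlation-form F statistic and leave-one-out Q2.  This is the
#' preliminary-modelling screen used to pick a mixing rule before final model
#' development.
#'
#' Rules whose descriptor table yields a rank-deficient design (or whose
#' formula is undefined for the given descriptor values) are flagged
#' `degenerate` and carry `NA` statistics; the remaining rules are still
#' reported.
#'
#' @param compound_descriptors Per-compound descriptor data.frame (see
#'   [build_mixture_descriptor_table()]).
#' @param mixtures Mixture composition data.frame; if it has a `split`
#'   column only `split == "train"` rows are used for fitting.
#' @param responses Numeric vector of mixture responses (pEC50mix), aligned
#'   with `mixtures` rows.
#' @return Data.frame with one row per rule: `rule_id`, `label`, `n`,
#'   `r2`, `r2_adj`, `f`, `q2_loo`, `degenerate`.
#' @export
compare_rules <- function(compound_descriptors, mixtures, responses) {
  stopifnot(length(responses) == nrow(mixtures))
  keep <- if ("split" %in% names(mixtures)) mixtures$split == "train" else rep(TRUE, nrow(mixtures))
  n_min <- ncol(compound_descriptors) - ("index" %in% names(compound_descriptors)) + 2L
  if (sum(keep) < n_min)
    stop("need at least ", n_min, " training mixtures to fit the preliminary models")
  out <- mixing_rules()
  out$n <- sum(keep)
  out$r2 <- out$r2_adj <- out$f <- out$q2_loo <- NA_real_
  out$degenerate <- FALSE
  for (r in 1:11) {
    stats_r <- tryCatch({
      dm <- build_mixture_descriptor_table(r, compound_descriptors, mixtures)[keep, , drop = FALSE]
      y <- responses[keep]
      X <- as.matrix(dm)
      if (qr(cbind(1, X))$rank < ncol(X) + 1L) stop("rank-deficient design")
      fit <- fit_ols(dm, y)
      p <- length(fit$coefficients)
      r2 <- r_squared(y, fit$fitted)
      pr <- press_ols(dm, y)
      list(r2 = r2,
           r2_adj = 1 - (1 - r2) * (length(y) - 1) / (length(y) - p - 1),
           f = f_from_r2(r2, length(y)),
           q2 = pr$q2)
    }, error = function(e) NULL)
    if (is.null(stats_r)) {
      out$degenerate[r] <- TRUE
    } else {
      out$r2[r] <- stats_r$r2
      out$r2_adj[r] <- stats_r$r2_adj
      out$f[r] <- stats_r$f
      out$q2_loo[r] <- stats_r$q2
    }
  }
  out[c("rule_id", "label", "n", "r2", "r2_adj", "f", "q2_loo", "degenerate")]
}
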