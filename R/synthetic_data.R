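#' Reference inter-correlation matrix of the five selected descriptors
#'
#' The pairwise Pearson correlations among the five descriptors used by the
#' packaged QSAR models -- relative number of N atoms (`Rn-N`), HOMO energy
#' (`HOMO`), total point-charge dipole component (`Tot-pc`), minimum atomic
#' state energy for carbon (`Min-C`) and maximum electron-nuclear attraction
#' for a C-H bond (`Max-C-H`).  All off-diagonal magnitudes are below 0.8,
#' the usual chance-correlation screen, the largest being
#' `|r(Tot-pc, Min-C)| = 0.696`.  This matrix is the default correlation
#' target of the synthetic-data generator.
#'
#' @return A symmetric positive-definite 5 x 5 correlation matrix with
#'   descriptor dimnames.
#' @export
reference_descriptor_correlation <- function() {
  nm <- c("Rn-N", "HOMO", "Tot-pc", "Min-C", "Max-C-H")
  m <- matrix(c(1, -0.297, 0.217, -0.049, -0.423,
                -0.297, 1, 0.630, -0.622, 0.311,
                0.217, 0.630, 1, -0.696, 0.197,
                -0.049, -0.622, -0.696, 1, -0.145,
                -0.423, 0.311, 0.197, -0.145, 1),
              5, 5, dimnames = list(nm, nm))
  m
}

# default mixture-law coefficients: signs follow the published mixture model
# (positive Rn-N and HOMO, negative Tot-pc, Min-C, Max-C-H); the overall
# scale is calibrated so that rule-9 equimolar mixtures of unit-variance
# descriptors carry a signal variance of ~0.65, i.e. a training R2 near
# 0.73 at the default response noise of 0.49
.default_mix_coefficients <- function() {
  0.4283502 * c("Rn-N" = 0.5, "HOMO" = 0.3, "Tot-pc" = -0.3,
                "Min-C" = -0.4, "Max-C-H" = -0.2)
}

#' Configuration for the synthetic study-mimic generator
#'
#' Bundles and validates the knobs of [simulate_descriptors()] and
#' [simulate_study()].  The defaults emulate the design of the packaged
#' study system: 35 compounds and 79 binary mixtures with a 62/17
#' train/test split, five descriptors with the reference correlation
#' structure, a linear mixture-toxicity law through rule-9 mixture
#' descriptors, and response noise of 0.49 pEC50 units (the training-RMS
#' level of the packaged linear mixture model).
#'
#' @param n_compounds Number of compounds (default 35).
#' @param n_descriptors Number of descriptors (default 5).
#' @param target_correlation Target descriptor correlation matrix; default
#'   [reference_descriptor_correlation()] when `n_descriptors == 5`, the
#'   identity otherwise.  Must be symmetric positive definite.
#' @param response_model `"linear"` or `"rbf"`.
#' @param coefficients Named linear-law coefficients on the mixture
#'   descriptors (default: calibrated study-mimic values, see Details).
#' @param intercept Response intercept (default 3.5, a mid-scale pEC50).
#' @param compound_gain Multiplier applied to `coefficients` for the
#'   individual-compound linear law (default 5, placing the compound-model
#'   R2 near the individual-model regime at the shared noise level).
#' @param rbf For `response_model = "rbf"`: list with `n_centers` (3),
#'   `width` (1.6) and `weight_sd` (2); an optional `weights` vector plants
#'   fixed hidden-unit weights instead of drawing them, which keeps every
#'   planted centre identifiable in recovery studies.
#' @param noise_sd Gaussian response noise SD, pEC50 units (default 0.49).
#' @param r2_target_mixtures,r2_target_compounds In linear mode, the
#'   signal-to-noise regime to pin: the linear predictor is rescaled, per
#'   realization, to the signal SD `noise_sd * sqrt(r2 / (1 - r2))` implied
#'   by the target R2 and the noise level.  Without this, the heavy tails of
#'   cubic mixture descriptors make the realized R2 of a 62-mixture draw
#'   swing far around its population value.  Defaults 0.727 and 0.887 (the
#'   packaged models' training regimes); set to `NULL` (or use
#'   `noise_sd = 0`) to disable rescaling.  The rescaled ("effective")
#'   coefficients are returned by [simulate_study()].
#' @param n_mixtures Number of binary mixtures (default 79).
#' @param ratio_scheme `"equimolar"` (all ratios `"1\\1"`) or `"log_spread"`
#'   (toxic-unit ratios spanning several orders of magnitude, as the
#'   packaged table's `"13396\\1"` ... `"1\\116"` do).
#' @param mixing_rule The "true" rule generating mixture descriptors
#'   (default 9).
#' @param train_frac Fraction of mixtures in the training split
#'   (default 62/79).
#' @param seed Integer seed making every draw reproducible.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_compounds = 35L, n_descriptors = 5L,
                       target_correlation = NULL,
                       response_model = c("linear", "rbf"),
                       coefficients = NULL, intercept = 3.5,
                       compound_gain = 5,
                       rbf = list(n_centers = 3L, width = 1.6, weight_sd = 2),
                       noise_sd = 0.49, n_mixtures = 79L,
                       r2_target_mixtures = 0.727, r2_target_compounds = 0.887,
                       ratio_scheme = c("equimolar", "log_spread"),
                       mixing_rule = 9L, train_frac = 62 / 79,
                       seed = 20220927L) {
  response_model <- match.arg(response_model)
  ratio_scheme <- match.arg(ratio_scheme)
  if (is.null(target_correlation))
    target_correlation <- if (n_descriptors == 5L) reference_descriptor_correlation()
                          else diag(n_descriptors)
  if (!isTRUE(all.equal(target_correlation, t(target_correlation))) ||
      nrow(target_correlation) != n_descriptors)
    stop("target_correlation must be a symmetric ", n_descriptors, " x ",
         n_descriptors, " matrix")
  if (min(eigen(target_correlation, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("target_correlation must be positive definite")
  if (is.null(coefficients)) {
    coefficients <- if (n_descriptors == 5L) .default_mix_coefficients()
                    else stats::setNames(rep(0.2, n_descriptors),
                                         paste0("d", seq_len(n_descriptors)))
  }
  if (length(coefficients) != n_descriptors)
    stop("coefficients must have one entry per descriptor")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_mixtures < 1L || n_compounds < 2L) stop("need >= 2 compounds and >= 1 mixture")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_descriptors = as.integer(n_descriptors),
                 target_correlation = target_correlation,
                 response_model = response_model,
                 coefficients = coefficients, intercept = intercept,
                 compound_gain = compound_gain, rbf = rbf,
                 noise_sd = noise_sd,
                 r2_target_mixtures = r2_target_mixtures,
                 r2_target_compounds = r2_target_compounds,
                 n_mixtures = as.integer(n_mixtures),
                 ratio_scheme = ratio_scheme, mixing_rule = as.integer(mixing_rule),
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "sim_config")
}

.descriptor_names <- function(config) {
  nm <- colnames(config$target_correlation)
  if (is.null(nm)) nm <- names(config$coefficients)
  if (is.null(nm)) nm <- paste0("d", seq_len(config$n_descriptors))
  nm
}

.draw_descriptors <- function(config, n) {
  X <- MASS::mvrnorm(n, mu = rep(0, config$n_descriptors),
                     Sigma = config$target_correlation)
  colnames(X) <- .descriptor_names(config)
  as.data.frame(X)
}

#' Simulate a correlated descriptor table
#'
#' Draws `n_compounds` rows of multivariate-normal descriptors with the
#' configured target correlation; sample correlations converge to the
#' target as n grows.  Deterministic for a given seed.
#'
#' @param config A [sim_config()].
#' @return Descriptor data.frame (`n_compounds` x `n_descriptors`).
#' @export
simulate_descriptors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  .draw_descriptors(config, config$n_compounds)
}

.draw_ratio_text <- function(n, scheme) {
  if (scheme == "equimolar") return(rep("1\\1", n))
  e <- stats::runif(n, -2.1, 4.15)  # log10(a/b) spanning the packaged range
  ifelse(e >= 0,
         sprintf("%d\\1", pmax(1L, as.integer(round(10^e)))),
         sprintf("1\\%d", pmax(1L, as.integer(round(10^-e)))))
}

.rbf_surface <- function(X, centers, width, weights, bias) {
  drop(bias + .rbf_act(as.matrix(X), as.matrix(centers), width) %*% weights)
}

#' Simulate a full synthetic mixture-toxicity study
#'
#' Generates, under one seed, everything the modelling pipeline consumes:
#' a compound descriptor table with the configured correlation structure,
#' individual-compound responses, a binary-mixture composition table with
#' toxic-unit ratios, mixture descriptors built under the configured "true"
#' mixing rule, mixture responses from the configured response law plus
#' Gaussian noise, train/test splits mirroring the 28/7 and 62/17 designs,
#' and cyclic five-fold cross-validation blocks for the mixtures.
#'
#' For `response_model = "linear"`, compound responses follow
#' `intercept + X %*% (compound_gain * coefficients)` and mixture responses
#' `intercept + DMIX %*% coefficients`; for `"rbf"`, both follow a common
#' Gaussian-RBF surface with `rbf$n_centers` centres drawn from the
#' compound rows.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `compounds` (descriptor data.frame),
#'   `y_compounds`, `compound_split`, `mixtures` (composition data.frame
#'   with `mixture_no`, `component_a`, `component_b`, `ratio_text`, `x_a`,
#'   `x_b`, `split`, `cv_block`), `mixture_descriptors`, `y_mixtures`, and
#'   (RBF mode) `rbf_truth`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  X <- .draw_descriptors(config, config$n_compounds)
  rownames(X) <- as.character(seq_len(config$n_compounds))

  pairs <- t(replicate(config$n_mixtures,
                       sample.int(config$n_compounds, 2L, replace = FALSE)))
  mixtures <- data.frame(mixture_no = seq_len(config$n_mixtures),
                         component_a = pairs[, 1], component_b = pairs[, 2],
                         ratio_text = .draw_ratio_text(config$n_mixtures,
                                                       config$ratio_scheme))
  frac <- parse_toxic_unit_ratio(mixtures$ratio_text)
  mixtures$x_a <- frac$x_a; mixtures$x_b <- frac$x_b

  Dmix <- build_mixture_descriptor_table(config$mixing_rule, X, mixtures)

  rbf_truth <- NULL
  eff_mix <- eff_cmp <- NULL
  if (config$response_model == "linear") {
    beta <- unname(config$coefficients)
    eff_cmp <- .pin_signal(config$compound_gain * beta, as.matrix(X),
                           config$r2_target_compounds, config$noise_sd)
    eff_mix <- .pin_signal(beta, as.matrix(Dmix),
                           config$r2_target_mixtures, config$noise_sd)
    names(eff_cmp) <- names(config$coefficients)
    names(eff_mix) <- paste0("D", names(config$coefficients))
    mu_c <- config$intercept + drop(as.matrix(X) %*% eff_cmp)
    mu_m <- config$intercept + drop(as.matrix(Dmix) %*% eff_mix)
  } else {
    idx <- sample.int(config$n_compounds, config$rbf$n_centers)
    w <- if (!is.null(config$rbf$weights)) {
      stopifnot(length(config$rbf$weights) == config$rbf$n_centers)
      config$rbf$weights
    } else stats::rnorm(config$rbf$n_centers, sd = config$rbf$weight_sd)
    rbf_truth <- list(centers = as.matrix(X)[idx, , drop = FALSE],
                      center_idx = idx, width = config$rbf$width,
                      weights = w, bias = config$intercept)
    mu_c <- .rbf_surface(X, rbf_truth$centers, rbf_truth$width, w, rbf_truth$bias)
    mu_m <- .rbf_surface(Dmix, rbf_truth$centers, rbf_truth$width, w, rbf_truth$bias)
  }
  y_c <- mu_c + stats::rnorm(config$n_compounds, sd = config$noise_sd)
  y_m <- mu_m + stats::rnorm(config$n_mixtures, sd = config$noise_sd)

  n_tr_c <- round(config$n_compounds * 28 / 35)
  compound_split <- factor(rep("test", config$n_compounds), levels = c("train", "test"))
  compound_split[sample.int(config$n_compounds, n_tr_c)] <- "train"
  n_tr_m <- round(config$n_mixtures * config$train_frac)
  mixtures$split <- factor(rep("test", config$n_mixtures), levels = c("train", "test"))
  mixtures$split[sample.int(config$n_mixtures, n_tr_m)] <- "train"
  mixtures$cv_block <- factor(LETTERS[(mixtures$mixture_no - 1L) %% 5L + 1L],
                              levels = LETTERS[1:5])

  list(config = config, compounds = X, y_compounds = y_c,
       compound_split = compound_split, mixtures = mixtures,
       mixture_descriptors = Dmix, y_mixtures = y_m,
       effective_coefficients = eff_mix,
       effective_coefficients_compounds = eff_cmp,
       rbf_truth = rbf_truth)
}

# rescale a coefficient vector so the realized linear-predictor SD equals
# the target implied by (r2_target, noise_sd); identity when pinning is off
.pin_signal <- function(beta, X, r2_target, noise_sd) {
  s <- drop(X %*% beta)
  if (is.null(r2_target) || noise_sd <= 0 || stats::sd(s) == 0) return(beta)
  beta * noise_sd * sqrt(r2_target / (1 - r2_target)) / stats::sd(s)
}
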