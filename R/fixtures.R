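#' Packaged toxicity table of the 35 individual compounds
#'
#' Loads the packaged table of 35 individual aquatic toxicants (13 aldehydes,
#' 11 cyanides, 10 sulfonamides and trimethoprim) with their experimental
#' toxicity, the predictions of the published multiple-linear-regression (MLR)
#' and radial-basis-function-network (RBFNN) models, the corresponding
#' residuals and the train/test split used for the individual-compound models.
#' Toxicity is expressed as pEC50, the negative decadic logarithm of the molar
#' EC50; larger values mean higher toxicity.
#'
#' On load the table is checked against its structural invariants: 35 rows,
#' a 28/7 train/test split, and experimental minus predicted equal to the
#' stored residual for both model columns within the 2-decimal printing
#' precision of the source values.
#'
#' @return A `data.frame` with 35 rows and columns `index`, `name`,
#'   `chem_class` (factor: `AHS`, `CGS`, `SAS`, `TMP`), `pEC50_exp`,
#'   `pEC50_pred_mlr`, `resid_mlr`, `pEC50_pred_rbfnn`, `resid_rbfnn`, and
#'   `split` (factor: `train`, `test`).
#' @seealso [load_mixture_table()]
#' @examples
#' cmp <- load_compound_table()
#' table(cmp$split)
#' @export
load_compound_table <- function() {
  path <- system.file("extdata", "compounds_individual.csv",
                      package = "mixqsar", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  expect_cols <- c("index", "name", "chem_class", "pEC50_exp",
                   "pEC50_pred_mlr", "resid_mlr", "pEC50_pred_rbfnn",
                   "resid_rbfnn", "split")
  if (!identical(names(tab), expect_cols) || nrow(tab) != 35L)
    stop("compound fixture is corrupted: unexpected shape or column names")
  tab$chem_class <- factor(tab$chem_class, levels = c("AHS", "CGS", "SAS", "TMP"))
  tab$split <- factor(tab$split, levels = c("train", "test"))
  .check_residual_columns(tab$pEC50_exp,
                          tab[c("pEC50_pred_mlr", "pEC50_pred_rbfnn")],
                          tab[c("resid_mlr", "resid_rbfnn")],
                          "compound")
  if (sum(tab$split == "train") != 28L || sum(tab$split == "test") != 7L)
    stop("compound fixture is corrupted: split counts are not 28/7")
  tab
}

#' Packaged toxicity table of the 79 binary mixtures
#'
#' Loads the packaged table of 79 binary mixtures of the 35 individual
#' compounds: component indices, the verbatim toxic-unit ratio string
#' (e.g. `"1\\1"`, `"13396\\1"`), the experimental mixture toxicity
#' (pEC50mix), the published MLR and RBFNN predictions with residuals, the
#' 62/17 train/test split, and the five-fold cross-validation block label
#' (`A`--`E`) of each mixture.
#'
#' The toxic-unit ratio `"a\\b"` is normalised to fractional composition
#' weights `x_a = a/(a+b)`, `x_b = b/(a+b)` (see
#' [parse_toxic_unit_ratio()]); these weights play the role of the mole
#' fractions X1, X2 in the mixing rules.
#'
#' @return A `data.frame` with 79 rows and columns `mixture_no`,
#'   `component_a`, `component_b`, `ratio_text`, `x_a`, `x_b`,
#'   `pEC50mix_exp`, `pEC50mix_pred_mlr`, `resid_mlr`, `pEC50mix_pred_rbfnn`,
#'   `resid_rbfnn`, `split` (factor), `cv_block` (factor `A`--`E`).
#' @seealso [load_compound_table()], [parse_toxic_unit_ratio()]
#' @examples
#' mix <- load_mixture_table()
#' table(mix$cv_block)
#' @export
load_mixture_table <- function() {
  path <- system.file("extdata", "mixtures_binary.csv",
                      package = "mixqsar", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  expect_cols <- c("mixture_no", "component_a", "component_b", "ratio_text",
                   "pEC50mix_exp", "pEC50mix_pred_mlr", "resid_mlr",
                   "pEC50mix_pred_rbfnn", "resid_rbfnn", "split", "cv_block")
  if (!identical(names(tab), expect_cols) || nrow(tab) != 79L)
    stop("mixture fixture is corrupted: unexpected shape or column names")
  frac <- parse_toxic_unit_ratio(tab$ratio_text)
  tab$x_a <- frac$x_a
  tab$x_b <- frac$x_b
  tab <- tab[c("mixture_no", "component_a", "component_b", "ratio_text",
               "x_a", "x_b", "pEC50mix_exp", "pEC50mix_pred_mlr", "resid_mlr",
               "pEC50mix_pred_rbfnn", "resid_rbfnn", "split", "cv_block")]
  tab$split <- factor(tab$split, levels = c("train", "test"))
  tab$cv_block <- factor(tab$cv_block, levels = c("A", "B", "C", "D", "E"))
  .check_residual_columns(tab$pEC50mix_exp,
                          tab[c("pEC50mix_pred_mlr", "pEC50mix_pred_rbfnn")],
                          tab[c("resid_mlr", "resid_rbfnn")],
                          "mixture")
  if (sum(tab$split == "train") != 62L || sum(tab$split == "test") != 17L)
    stop("mixture fixture is corrupted: split counts are not 62/17")
  if (any(is.na(tab$cv_block)) || !all(tabulate(tab$cv_block, 5L) == c(16L, 16L, 16L, 16L, 15L)))
    stop("mixture fixture is corrupted: cross-validation blocks do not partition 1..79")
  tab
}

# exp - pred must equal the stored residual within 2-dp printing precision
.check_residual_columns <- function(exp_col, pred_cols, resid_cols, what) {
  for (j in seq_along(pred_cols)) {
    dev <- abs(exp_col - pred_cols[[j]] - resid_cols[[j]])
    if (any(dev > 0.011))
      stop(sprintf("%s fixture is corrupted: residual column %s inconsistent (max dev %.3f)",
                   what, names(resid_cols)[j], max(dev)))
  }
}

#' Parse a toxic-unit ratio string into fractional composition weights
#'
#' A binary mixture's composition is recorded as the toxic-unit ratio
#' `"a\\b"` of its two components.  The ratio is normalised to weights
#' `x_a = a/(a+b)` and `x_b = b/(a+b)`, which sum to one and serve as the
#' composition fractions X1, X2 of the mixing rules.
#'
#' @param ratio_text Character vector of ratio strings of the form `"a\\b"`
#'   with strictly positive numeric parts.
#' @return A `data.frame` with numeric columns `x_a` and `x_b`
#'   (`x_a + x_b == 1`), one row per input string.
#' @examples
#' parse_toxic_unit_ratio(c("1\\1", "13396\\1", "1\\116"))
#' @export
parse_toxic_unit_ratio <- function(ratio_text) {
  if (!is.character(ratio_text) || length(ratio_text) == 0L)
    stop("ratio_text must be a non-empty character vector")
  parts <- strsplit(ratio_text, "\\", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad))
    stop("malformed toxic-unit ratio: ",
         paste(unique(ratio_text[bad]), collapse = ", "))
  a <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  b <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- is.na(a) | is.na(b) | a <= 0 | b <= 0
  if (any(bad))
    stop("toxic-unit ratio parts must be positive numbers: ",
         paste(unique(ratio_text[bad]), collapse = ", "))
  data.frame(x_a = a / (a + b), x_b = b / (a + b))
}

#' Export the packaged toxicity tables to a directory
#'
#' Writes the two packaged fixtures (individual compounds and binary
#' mixtures) as UTF-8 CSV files to `dir`, so they can be inspected or fed to
#' external tools.
#'
#' @param dir Destination directory; created if absent.
#' @return Invisibly, the two file paths written.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- c(system.file("extdata", "compounds_individual.csv", package = "mixqsar", mustWork = TRUE),
           system.file("extdata", "mixtures_binary.csv", package = "mixqsar", mustWork = TRUE))
  dst <- file.path(dir, basename(src))
  ok <- file.copy(src, dst, overwrite = TRUE)
  if (!all(ok)) stop("failed to export fixtures to ", dir)
  invisible(dst)
}
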