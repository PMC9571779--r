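test_that("screening removes exact duplicates, constants and NA columns", {
  tab <- random_table(30, 3, seed = 1)
  tab$dup <- tab$d1
  tab$const <- 5
  tab$holes <- c(NA, rnorm(29))
  scr <- screen_descriptors(tab)
  expect_true(all(c("const", "holes") %in% scr$report$removed_names))
  # exactly one of the |r| = 1 pair survives
  expect_equal(sum(c("d1", "dup") %in% scr$report$retained_names), 1L)
  expect_equal(scr$report$n_input,
               scr$report$n_removed_invalid + scr$report$n_removed_correlated +
                 scr$report$n_retained)
  expect_lt(max(abs(cor(scr$table))[upper.tri(diag(ncol(scr$table)))]), 0.8)
})

test_that("the correlated-pair tie-break keeps the column nearer the response", {
  set.seed(2)
  x <- rnorm(100)
  tab <- data.frame(weak = x + rnorm(100, sd = 0.3),
                    strong = x + rnorm(100, sd = 0.05))
  y <- x
  scr <- screen_descriptors(tab, y, corr_threshold = 0.8)
  expect_equal(scr$report$retained_names, "strong")
})

test_that("an all-nonconforming pool raises an explicit error", {
  expect_error(screen_descriptors(data.frame(a = rep(1, 10), b = rep(2, 10))),
               "empty descriptor pool")
})

test_that("the five study descriptors survive screening at their reference correlations", {
  # at large n the sample correlations approach the target matrix, whose
  # largest magnitude is 0.696 < 0.8
  X <- simulate_descriptors(sim_config(n_compounds = 4000L, seed = 11L))
  scr <- screen_descriptors(X)
  expect_equal(sort(scr$report$retained_names),
               sort(colnames(reference_descriptor_correlation())))
  expect_equal(scr$report$n_removed_correlated, 0L)
})

test_that("stepwise recovers a planted two-descriptor model from ten candidates", {
  tab <- random_table(60, 10, seed = 7)
  set.seed(77)
  y <- 2 * tab$d3 - tab$d7 + rnorm(60, sd = 0.1)
  sel <- forward_stepwise_mlr(tab, y)
  expect_equal(sel$selected, c("d3", "d7"))
  # recovered coefficients within 3 standard errors of truth
  ref <- summary(lm(y ~ d3 + d7, data = tab))$coefficients
  expect_lt(abs(sel$model$coefficients[["d3"]] - 2) / ref["d3", "Std. Error"], 3)
  expect_lt(abs(sel$model$coefficients[["d7"]] + 1) / ref["d7", "Std. Error"], 3)
})

test_that("a column identical to the response is picked first with R2 = 1", {
  tab <- random_table(25, 4, seed = 8)
  sel <- forward_stepwise_mlr(tab, tab$d2, max_terms = 3)
  expect_equal(sel$selected[1], "d2")
  expect_equal(sel$steps$r2[1], 1, tolerance = 1e-12)
})

test_that("stepwise follows the greedy path of an exhaustive subset oracle", {
  tab <- random_table(40, 6, seed = 13)
  set.seed(14)
  y <- tab$d1 + 0.8 * tab$d5 - 0.5 * tab$d6 + rnorm(40, sd = 0.3)
  # oracle: enumerate all 1-subsets, then all 2-subsets containing the best 1
  rss_of <- function(cols) sum(resid(lm(y ~ ., data = tab[cols]))^2)
  one <- vapply(names(tab), function(nm) rss_of(nm), numeric(1))
  best1 <- names(which.min(one))
  two <- vapply(setdiff(names(tab), best1),
                function(nm) rss_of(c(best1, nm)), numeric(1))
  best2 <- names(which.min(two))
  sel <- forward_stepwise_mlr(tab, y, max_terms = 2)
  expect_equal(sel$selected, c(best1, best2))
})

test_that("selection is deterministic and R2 is non-decreasing over steps", {
  tab <- random_table(50, 8, seed = 21)
  set.seed(22)
  y <- tab$d2 - tab$d4 + 0.5 * tab$d8 + rnorm(50, sd = 0.4)
  s1 <- forward_stepwise_mlr(tab, y)
  s2 <- forward_stepwise_mlr(tab, y)
  expect_identical(s1$selected, s2$selected)
  expect_true(all(diff(s1$steps$r2) >= -1e-12))
})

test_that("collinear candidates are skipped with a warning", {
  tab <- random_table(30, 3, seed = 31)
  tab$d4 <- tab$d1 - tab$d2           # dependent once d1, d2 are in
  set.seed(32)
  y <- tab$d1 + tab$d2 + tab$d3 + rnorm(30, sd = 0.05)
  expect_warning(sel <- forward_stepwise_mlr(tab, y, max_terms = 4),
                 "collinear")
  # the dependent member of {d1, d2, d4} is skipped, the fit stays full rank
  expect_length(sel$skipped, 1L)
  expect_true(sel$skipped %in% c("d1", "d2", "d4"))
  expect_length(sel$selected, 3L)
  expect_true(all(is.finite(sel$model$coefficients)))
})

test_that("screening plus stepwise on the study-mimic selects all five descriptors", {
  cfg <- sim_config(n_compounds = 400L, seed = 17L)
  st <- simulate_study(cfg)
  scr <- screen_descriptors(st$compounds, st$y_compounds)
  expect_equal(scr$report$n_retained, 5L)
  sel <- forward_stepwise_mlr(scr$table, st$y_compounds)
  expect_setequal(sel$selected, colnames(reference_descriptor_correlation()))
})
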