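test_that("scalar statistics obey their closed forms", {
  obs <- c(1, 2, 3, 4)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(rms_error(c(0.3, -0.4), c(0, 0)), sqrt(mean(c(0.09, 0.16))))
  expect_equal(mae(c(0.5, -0.5), c(0, 0)), 0.5)
  expect_equal(f_from_r2(0.5, 22), 20)
  expect_equal(f_from_r2(1, 10), Inf)
  expect_equal(q2_ext(obs, obs, 2), 1)
  expect_equal(q2_ext(obs, rep(2.5, 4), 2.5), 0)
  expect_equal(k_slope(obs, obs), 1)
  expect_equal(k_slope(obs, 2 * obs), 0.5)
  expect_error(r_squared(rep(1, 5), obs[c(1, 2, 3, 4, 1)]), "constant")
  expect_error(k_slope(obs, rep(0, 4)), "undefined")
})

test_that("mae never exceeds rms", {
  set.seed(71)
  for (k in 1:20) {
    o <- rnorm(15); p <- rnorm(15)
    expect_lte(mae(o, p), rms_error(o, p))
  }
})

test_that("the correlation-form F reproduces every published (R2, n, F) triple within 2%", {
  triples <- rbind(
    c(0.887, 28, 204.660), c(0.987, 7, 374.332),   # individual MLR train/test
    c(0.864, 28, 165.309), c(0.941, 7, 79.300),    # individual RBFNN train/test
    c(0.727, 62, 159.537), c(0.721, 17, 38.773),   # mixture MLR train/test
    c(0.956, 62, 1279.919), c(0.880, 17, 110.980)) # mixture RBFNN train/test
  for (i in seq_len(nrow(triples)))
    expect_equal(f_from_r2(triples[i, 1], triples[i, 2]), triples[i, 3],
                 tolerance = 0.02)
})

test_that("the hat-matrix LOO shortcut equals brute-force refitting", {
  tab <- random_table(20, 3, seed = 72)
  set.seed(73)
  y <- tab$d1 - tab$d3 + rnorm(20, sd = 0.5)
  fast <- press_ols(tab, y)
  slow <- q2_loo(ols_trainer(), tab, y)
  expect_equal(fast$press, slow$press, tolerance = 1e-8)
  expect_equal(fast$q2, slow$q2, tolerance = 1e-8)
})

test_that("LOO Q2 is near one for noiseless linear data and non-positive for permuted data", {
  tab <- random_table(20, 2, seed = 74)
  y <- 1 + tab$d1 + 2 * tab$d2
  expect_gt(q2_loo(ols_trainer(), tab, y)$q2, 0.999)
  set.seed(75)
  expect_lte(q2_loo(ols_trainer(), tab, sample(y))$q2, 0)
})

test_that("LOO Q2 never exceeds the training R2 for OLS", {
  for (s in 1:50) {
    tab <- random_table(25, 3, seed = 1000 + s)
    set.seed(2000 + s)
    y <- tab$d1 - 0.5 * tab$d2 + rnorm(25, sd = 1)
    m <- fit_ols(tab, y)
    expect_lte(press_ols(tab, y)$q2, m$r2 + 1e-12)
  }
})

test_that("Y-randomization is seeded, reproducible and near zero under scrambling", {
  st <- simulate_study(sim_config())
  tr <- st$mixtures$split == "train"
  tab <- st$mixture_descriptors[tr, ]
  y <- st$y_mixtures[tr]
  r1 <- y_randomization(ols_trainer(), tab, y, n_reps = 10)
  r2 <- y_randomization(ols_trainer(), tab, y, n_reps = 10)
  expect_identical(r1, r2)
  expect_true(all(r1$r2 < 0.2))
  expect_true(all(r1$rms > rms_error(y, fit_ols(tab, y)$fitted)))
  expect_error(y_randomization(ols_trainer(), tab, y, n_reps = 0), "n_reps")
})

test_that("Y-randomization leaves the global RNG stream untouched", {
  tab <- random_table(20, 2, seed = 76)
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(y_randomization(ols_trainer(), tab, tab$d1, n_reps = 2))
  expect_equal(rnorm(1), before)
})

test_that("blocked k-fold gives perfect folds on noiseless data and matches LOO as singletons", {
  tab <- random_table(20, 2, seed = 77)
  y <- 2 + tab$d1 - tab$d2
  blocks <- rep(c("A", "B", "C", "D"), each = 5)
  cv <- blocked_kfold(ols_trainer(), tab, y, blocks)
  expect_equal(cv$folds$r2_test, rep(1, 4), tolerance = 1e-8)
  # singleton blocks reproduce the LOO PRESS
  set.seed(78)
  y2 <- y + rnorm(20, sd = 0.3)
  cv1 <- blocked_kfold(ols_trainer(), tab, y2, as.character(1:20))
  press_cv <- sum(cv1$folds$rms_test^2)   # each fold RMS is |residual|
  expect_equal(press_cv, press_ols(tab, y2)$press, tolerance = 1e-8)
})

test_that("blocked k-fold finds no skill in permuted responses", {
  tab <- random_table(40, 3, seed = 79)
  set.seed(80)
  y <- tab$d1 + rnorm(40, sd = 0.1)
  yp <- sample(y)
  cv <- blocked_kfold(ols_trainer(), tab, yp, rep(LETTERS[1:5], each = 8))
  expect_lt(mean(cv$folds$r2_test), 0.2)
  expect_error(blocked_kfold(ols_trainer(), tab, yp, rep(NA, 40)), "block")
})

test_that("validation_report bundles internal and external statistics", {
  set.seed(81)
  o <- rnorm(10, 4); p <- o + rnorm(10, sd = 0.2)
  rep <- validation_report(o, p, train_mean = 4)
  expect_named(rep, c("n", "r2", "rms", "f", "mae", "q2_ext", "k", "k_prime"))
  expect_equal(rep$n, 10)
  expect_equal(rep$f, f_from_r2(rep$r2, 10))
})
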