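test_that("Gaussian activations obey their closed form", {
  tab <- data.frame(x1 = c(0, 1, 0), x2 = c(0, 0, 2))
  net <- structure(list(centers = matrix(c(0, 0), 1, 2,
                                         dimnames = list(NULL, c("x1", "x2"))),
                        width = 2, weights = 1, bias = 0, n_hidden = 1L,
                        scaler = NULL, descriptor_names = c("x1", "x2")),
                   class = "rbf_network")
  a <- rbf_activations(net, tab)
  expect_equal(a[1, 1], 1)                       # input equals the centre
  expect_equal(a[3, 1], exp(-1))                 # ||x - c|| = r
  expect_equal(a[2, 1], exp(-1 / 4))
  net$width <- 1e6                               # r -> Inf limit
  expect_equal(max(abs(rbf_activations(net, tab) - 1)), 0, tolerance = 1e-10)
  net$width <- -1
  expect_error(rbf_activations(net, tab), "positive")
})

test_that("output weights solve the least-squares problem exactly", {
  # 2 rows, 1 centre, 2 unknowns: exact interpolation
  tab <- data.frame(x = c(0, 1))
  w <- fit_output_weights(matrix(0, 1, 1), width = 1, tab, y = c(3, 5))
  a2 <- exp(-1)
  expect_equal(w$bias + w$weights * c(1, a2), c(3, 5))
  # random 30x8 instance against the normal-equation oracle
  tab2 <- random_table(30, 2, seed = 51)
  centers <- as.matrix(tab2[1:8, ])
  set.seed(52)
  y <- rnorm(30)
  w2 <- fit_output_weights(centers, width = 1.5, tab2, y)
  X <- as.matrix(tab2)
  A <- exp(-as.matrix(dist(rbind(X, centers)))[1:30, 31:38]^2 / 1.5^2)
  D <- cbind(1, A)
  beta <- drop(MASS::ginv(t(D) %*% D) %*% t(D) %*% y)
  expect_equal(unname(c(w2$bias, w2$weights)), unname(beta), tolerance = 1e-6)
})

test_that("with all rows as centres and a small width the fit interpolates", {
  tab <- random_table(12, 2, seed = 53)
  set.seed(54)
  y <- rnorm(12)
  sel <- forward_subset_select_centers(tab, y, width = 0.05,
                                       max_centers = 12, criterion = "sse")
  w <- suppressWarnings(fit_output_weights(as.matrix(tab[sel, ]), 0.05,
                                           tab, y))
  A <- exp(-as.matrix(dist(as.matrix(tab)))[, sel, drop = FALSE]^2 / 0.05^2)
  fitted <- w$bias + drop(A %*% w$weights)
  expect_lt(max(abs(fitted - y)), 1e-6)
})

test_that("centre selection is deterministic and stops for a constant response", {
  tab <- random_table(20, 2, seed = 55)
  expect_length(forward_subset_select_centers(tab, rep(2, 20), width = 1), 0)
  set.seed(56)
  y <- rnorm(20)
  expect_identical(forward_subset_select_centers(tab, y, width = 1),
                   forward_subset_select_centers(tab, y, width = 1))
})

test_that("training recovers a planted three-centre surface and its width", {
  st <- simulate_study(rbf_recovery_config(seed = 1L))
  tr <- st$compound_split == "train"
  net <- train_rbfnn(st$compounds[tr, ], st$y_compounds[tr], max_centers = 10L)
  expect_lt(abs(net$width - 1.6), 0.3 + 1e-9)
  p <- predict(net, st$compounds[!tr, ])
  expect_lt(rms_error(st$y_compounds[!tr], p), 2 * 0.05)
  # every planted centre lies within the kernel width of a selected centre
  Ct <- scale(st$rbf_truth$centers, net$scaler$center, net$scaler$scale)
  for (i in seq_len(nrow(Ct))) {
    d <- sqrt(rowSums(sweep(net$centers, 2, Ct[i, ])^2))
    expect_lt(min(d), net$width)
  }
})

test_that("a singleton width grid is honoured and noise yields no LOO skill", {
  tab <- random_table(30, 3, seed = 57)
  set.seed(58)
  y <- tab$d1 + rnorm(30, sd = 0.2)
  net <- train_rbfnn(tab, y, width_grid = 2.5, max_centers = 5)
  expect_equal(net$width, 2.5)
  # no skill on pure noise: procedure-level (nested) LOO, which unlike the
  # in-sample PRESS of the selected network carries no selection optimism
  set.seed(59)
  y_noise <- rnorm(30)
  loo <- q2_loo(rbfnn_trainer(width_grid = c(0.5, 1, 2), max_centers = 4),
                tab, y_noise)
  expect_lt(loo$q2, 0.2)
  expect_error(train_rbfnn(tab, y, width_grid = numeric(0)), "empty")
})

test_that("one very wide centre degenerates towards the intercept-only model", {
  tab <- random_table(25, 2, seed = 60)
  set.seed(61)
  y <- rnorm(25, mean = 4)
  net <- suppressWarnings(train_rbfnn(tab, y, width_grid = 1e4, max_centers = 1))
  p <- suppressWarnings(predict(net, tab))
  expect_lt(sd(p), 0.05 * sd(y))
  expect_equal(mean(p), mean(y), tolerance = 1e-3)
})

test_that("training R2 is non-decreasing along the nested centre path", {
  tab <- random_table(35, 2, seed = 62)
  set.seed(63)
  y <- sin(tab$d1) + 0.5 * tab$d2 + rnorm(35, sd = 0.1)
  sel <- forward_subset_select_centers(tab, y, width = 1.5, max_centers = 8)
  r2_path <- vapply(seq_along(sel), function(k) {
    w <- fit_output_weights(as.matrix(tab[sel[1:k], , drop = FALSE]), 1.5, tab, y)
    A <- exp(-as.matrix(dist(as.matrix(tab)))[, sel[1:k], drop = FALSE]^2 / 1.5^2)
    r_squared(y, w$bias + drop(A %*% w$weights))
  }, numeric(1))
  expect_true(all(diff(r2_path) >= -1e-9))
})

test_that("predictions are invariant to the order of training rows", {
  tab <- random_table(30, 2, seed = 64)
  set.seed(65)
  y <- tab$d1^2 + rnorm(30, sd = 0.1)
  net1 <- train_rbfnn(tab, y, width_grid = c(1, 1.5), max_centers = 6)
  perm <- sample(30)
  net2 <- train_rbfnn(tab[perm, ], y[perm], width_grid = c(1, 1.5), max_centers = 6)
  grid <- random_table(10, 2, seed = 66)
  expect_equal(predict(net1, grid), predict(net2, grid), tolerance = 1e-8)
})
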