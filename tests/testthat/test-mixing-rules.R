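test_that("apply_rule reproduces hand arithmetic for the named rules", {
  expect_equal(apply_rule(9, d1 = 3, d2 = 3, x1 = 0.5, x2 = 0.5), 27)   # d^3 at symmetry
  expect_equal(apply_rule(9, d1 = 2, d2 = 1, x1 = 0.75, x2 = 0.25), 6.25)
  expect_equal(apply_rule(4, d1 = 2, d2 = 4, x1 = 0.25, x2 = 0.75), 3.5)
  expect_equal(apply_rule(2, d1 = 1, d2 = 3, x1 = 0.5, x2 = 0.5), 4)
  expect_equal(apply_rule(1, d1 = 1.5, d2 = -0.5, x1 = 0.3, x2 = 0.7), 1)
  expect_equal(apply_rule(11, d1 = 3, d2 = 4, x1 = 0.5, x2 = 0.5), sqrt(12.5))
})

test_that("every rule is symmetric under swapping the two components", {
  set.seed(101)
  for (k in 1:50) {
    d1 <- exp(rnorm(1)); d2 <- exp(rnorm(1))   # positive: all radicands valid
    x1 <- runif(1); x2 <- 1 - x1
    for (r in 1:11)
      expect_equal(apply_rule(r, d1, d2, x1, x2),
                   apply_rule(r, d2, d1, x2, x1),
                   tolerance = 1e-12)
  }
})

test_that("even-root rules refuse negative radicands, naming the rule", {
  expect_error(apply_rule(3, d1 = -5, d2 = -5, x1 = 0.5, x2 = 0.5), "rule 3")
  expect_error(apply_rule(10, d1 = -2, d2 = -2, x1 = 0.5, x2 = 0.5), "rule 10")
  expect_error(apply_rule(11, d1 = 0, d2 = 0, x1 = 0.5, x2 = 0.5), NA)  # zero radicand fine
  # rule 7's signed cube root is defined for negatives
  expect_equal(apply_rule(7, d1 = -8, d2 = -8, x1 = 0.5, x2 = 0.5),
               -(0.5^3 * 8 + 0.5^3 * 8)^(1 / 3))
})

test_that("invalid rule ids and non-normalised fractions are rejected", {
  expect_error(apply_rule(0, 1, 1, 0.5, 0.5), "rule_id")
  expect_error(apply_rule(12, 1, 1, 0.5, 0.5), "rule_id")
  expect_error(apply_rule(4, 1, 1, 0.6, 0.6), "x1 \\+ x2")
})

test_that("mixture descriptor tables match per-cell arithmetic", {
  desc <- data.frame(u = c(2, 1, 4), v = c(0.5, 2, 1),
                     row.names = as.character(1:3))
  mixes <- data.frame(mixture_no = 1:3,
                      component_a = c(1, 2, 3), component_b = c(2, 3, 1),
                      x_a = c(0.5, 0.25, 1), x_b = c(0.5, 0.75, 0))
  got <- build_mixture_descriptor_table(9, desc, mixes)
  expect_equal(names(got), c("Du", "Dv"))
  expect_equal(got$Du,
               c(0.5 * 8 + 0.5 * 1, 0.25 * 1 + 0.75 * 64, 1 * 64 + 0))
  expect_equal(got$Dv,
               c(0.5 * 0.125 + 0.5 * 8, 0.25 * 8 + 0.75 * 1, 1 * 1 + 0))
  # degenerate mixture x_a = 1 equals the component-a transform alone
  expect_equal(got$Du[3], desc$u[3]^3)
  # self-mixture under any split of x returns v^3 for rule 9
  self <- data.frame(component_a = 2, component_b = 2, x_a = 0.3, x_b = 0.7)
  expect_equal(build_mixture_descriptor_table(9, desc, self)$Dv, 2^3)
})

test_that("missing component rows are reported with the mixture number", {
  desc <- data.frame(u = 1:2, row.names = c("1", "2"))
  mixes <- data.frame(mixture_no = 1:2, component_a = c(1, 1),
                      component_b = c(2, 9), x_a = 0.5, x_b = 0.5)
  expect_error(build_mixture_descriptor_table(4, desc, mixes), "2")
})

test_that("compare_rules identifies a planted rule-4 linear law", {
  desc <- random_table(40, 3, seed = 5, prefix = "", positive = TRUE)
  names(desc) <- c("a", "b", "c"); rownames(desc) <- as.character(1:40)
  mixes <- random_mixtures(40, 70, seed = 5)
  D4 <- build_mixture_descriptor_table(4, desc, mixes)
  set.seed(6)
  y <- 2 + 1.5 * D4$Da - 1 * D4$Db + 0.8 * D4$Dc + rnorm(70, sd = 0.05)
  rep <- compare_rules(desc, mixes, y)
  expect_equal(rep$rule_id, 1:11)
  expect_false(any(rep$degenerate))
  # among the composition-weighted linear family, the generating rule wins
  sub <- rep[rep$rule_id %in% 4:7, ]
  expect_equal(sub$rule_id[which.max(sub$q2_loo)], 4L)
  expect_gt(rep$r2[4], 0.99)
})

test_that("compare_rules finds no signal in permuted responses", {
  desc <- random_table(40, 3, seed = 5, prefix = "", positive = TRUE)
  names(desc) <- c("a", "b", "c"); rownames(desc) <- as.character(1:40)
  mixes <- random_mixtures(40, 70, seed = 5)
  D4 <- build_mixture_descriptor_table(4, desc, mixes)
  set.seed(6)
  y <- 2 + 1.5 * D4$Da - 1 * D4$Db + 0.8 * D4$Dc + rnorm(70, sd = 0.05)
  set.seed(9)
  rep <- compare_rules(desc, mixes, sample(y))
  expect_true(all(rep$r2[!rep$degenerate] < 0.2))
})

test_that("duplicate descriptor columns flag every rule as degenerate", {
  desc <- random_table(20, 1, seed = 3, positive = TRUE)
  desc$d2 <- desc$d1
  rownames(desc) <- as.character(1:20)
  mixes <- random_mixtures(20, 30, seed = 3)
  set.seed(4)
  rep <- compare_rules(desc, mixes, rnorm(30))
  expect_true(all(rep$degenerate))
  expect_true(all(is.na(rep$r2)))
})
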