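test_that("ucb1 follows the standard bound with unvisited-first", {
  expect_identical(ucb1(0, 0L, 5L), Inf)
  expect_identical(ucb1(0, 1L, 1L, c_explore = sqrt(2)), 0)
  # hand arithmetic: 0.5 + 1 * sqrt(2 ln 2)
  expect_equal(ucb1(0.5, 1L, 2L, c_explore = 1), 0.5 + sqrt(2 * log(2)),
               tolerance = 1e-12)
  expect_equal(ucb1(0.5, 1L, 2L, c_explore = 1), 1.6774, tolerance = 1e-4)
  # vectorized over children
  expect_identical(ucb1(c(0.9, 0), c(3L, 0L), 3L)[2], Inf)
  expect_error(ucb1(0, -1L, 2L), "non-negative")
})

test_that("reward squashing maps into [-1, 1] monotonically", {
  lin <- reward_transform("linear_unit", 0, 1)
  expect_identical(squash(0, lin), -1)
  expect_identical(squash(1, lin), 1)
  expect_identical(squash(0.5, lin), 0)
  expect_identical(squash(2, lin), 1) # clamped
  expect_identical(squash(-Inf, lin), -1)

  th <- reward_transform("tanh_scaled", scale = 10)
  expect_identical(squash(0, th), 0)
  expect_equal(squash(5, th), tanh(0.5))
  x <- seq(-50, 50, by = 7)
  y <- squash(x, th)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= -1 & y <= 1))
  expect_error(squash(NaN, th), "non-finite")
})

test_that("transforms are picked from the declared score range", {
  expect_identical(moltree:::default_transform(score_function("qed"))$kind,
                   "linear_unit")
  expect_identical(moltree:::default_transform(score_function("plogp"))$kind,
                   "tanh_scaled")
})
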