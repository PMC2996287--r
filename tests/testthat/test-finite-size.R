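test_that("forward size-vocabulary map matches the closed form", {
  expect_equal(text_size_from_vocab(4, 0.5), 4)
  expect_equal(text_size_from_vocab(3, 2), 6)
  expect_equal(text_size_from_vocab(1, 0.7), 0)
  # continuous through the unit-exponent limit t -> N log N
  expect_equal(text_size_from_vocab(10, 1 + 1e-8), 10 * log(10), tolerance = 1e-6)
  expect_equal(text_size_from_vocab(10, 1 - 1e-8), 10 * log(10), tolerance = 1e-6)
  expect_error(text_size_from_vocab(0.5, 2), ">= 1")
  expect_error(text_size_from_vocab(10, -1), "positive")
  expect_error(text_size_from_vocab(10, 1), "Lambert")
})

test_that("inverse map round-trips the forward map", {
  for (alpha in c(0.3, 0.7, 1.3, 2.5)) {
    for (N in c(2, 10, 1e3, 1e5)) {
      t <- text_size_from_vocab(N, alpha)
      expect_equal(vocab_from_text_size(t, alpha), N, tolerance = 1e-8)
    }
  }
  expect_error(vocab_from_text_size(-1, 2), "positive")
})

test_that("unit Zipf exponent routes to the Lambert-W branch", {
  expect_equal(vocab_from_text_size(exp(1), 1), exp(1), tolerance = 1e-12)
  expect_equal(vocab_from_text_size(10 * log(10), 1), 10, tolerance = 1e-9)
  for (t in c(10, 1e3, 1e6)) {
    N <- vocab_from_text_size(t, 1)
    expect_equal(N * log(N) / t, 1, tolerance = 1e-9)
    # the generic root-finder just outside the branch threshold agrees
    for (alpha in c(1 - 1e-6, 1 + 1e-6)) {
      expect_equal(vocab_from_text_size(t, alpha), N, tolerance = 1e-3)
    }
  }
})

test_that("improved relation anchors at one and agrees with basic in slope", {
  expect_equal(vocab_from_text_size_improved(1, 0.7), 1)
  expect_equal(vocab_from_text_size_improved(1, 2.3), 1)
  # monotone in t
  Ns <- vocab_from_text_size_improved(c(10, 100, 1000, 1e4), 0.8)
  expect_true(all(diff(Ns) > 0))
  # the two variants track the same Heaps exponent (log-log slope over
  # matched vocabulary grids), even though their levels differ
  alpha <- 1.117
  size <- 101940
  slope_on <- function(tfun, M) {
    N <- seq(2, M, length.out = 400)
    fit_heaps_lsq(data.frame(t = vapply(N, tfun, numeric(1)), N = N))$lambda_hat
  }
  basic <- slope_on(function(n) text_size_from_vocab(n, alpha),
                    vocab_from_text_size(size, alpha))
  improved <- slope_on(function(n) zipfheaps:::.tsize_improved(n, alpha),
                       vocab_from_text_size_improved(size, alpha))
  expect_lt(abs(basic - improved), 0.05)
})

test_that("rank-sum always exceeds its integral approximation", {
  e <- sum_integral_error(2, 2)
  expect_equal(e$sum_value, 1.25)
  expect_equal(e$integral_value, 0.5)
  expect_equal(e$rel_error, 0.6)
  e1 <- sum_integral_error(1, 2)
  expect_equal(e1$sum_value, 1.5)
  expect_equal(e1$integral_value, log(2))
  expect_equal(e1$rel_error, (1.5 - log(2)) / 1.5, tolerance = 1e-12)
  expect_lt(sum_integral_error(0.5, 1e6)$rel_error, 0.01)
  # strict positivity, growth in alpha, decay in N
  alphas <- c(0.5, 1, 2, 3)
  Ns <- c(10, 100, 1e4)
  errs <- outer(alphas, Ns, Vectorize(function(a, n) sum_integral_error(a, n)$rel_error))
  expect_true(all(errs > 0 & errs < 1))
  expect_true(all(apply(errs, 2, diff) > 0))  # increasing in alpha
  expect_true(all(apply(errs, 1, diff) < 0))  # decreasing in N
  expect_error(sum_integral_error(2, 1), ">= 2")
})

test_that("discrete rank-sum brackets the continuous relation from above", {
  # with the same prefactor N^alpha, the summed size exceeds the
  # integral-based closed form, so the discrete curve lies right of it
  for (alpha in c(0.6, 1.4, 2.2)) {
    N <- 2:200
    t_int <- text_size_from_vocab(N, alpha)
    t_sum <- N^alpha * vapply(N, function(n) sum(seq_len(n)^(-alpha)), numeric(1))
    expect_true(all(t_sum > t_int))
  }
})

test_that("finite-size Heaps exponent grows with system size and has asymptotic limits", {
  lam <- vapply(10^(3:8), function(s) heaps_exponent_numeric(2, s), numeric(1))
  expect_true(all(diff(lam) >= 0))
  expect_true(all(lam > 0 & lam <= 1))
  expect_equal(heaps_exponent_numeric(2, 1e12), 0.5, tolerance = 0.02)
  expect_equal(heaps_exponent_numeric(0.5, 1e12), 1, tolerance = 0.02)
  expect_equal(heaps_exponent_numeric(3, 1e12), 1 / 3, tolerance = 0.02)
  # near the unit exponent the finite-size deficit persists even at 1e8
  expect_lt(heaps_exponent_numeric(1, 1e8), 1 - 0.01)
  expect_error(heaps_exponent_numeric(2, 5), ">= 10")
  expect_error(heaps_exponent_numeric(2, 1e4, grid_size = 10), ">= 50")
})

test_that("model curves are nearly power laws in log-log", {
  for (alpha in c(0.5, 1.2, 3)) {
    for (size in c(1e3, 1e5, 1e7)) {
      d <- heaps_exponent_numeric(alpha, size, details = TRUE)
      expect_gt(d$r_squared, 0.99)
    }
  }
})

test_that("accelerating exponent is the reciprocal finite-size exponent", {
  expect_equal(accelerating_exponent(2, 1e12), 2, tolerance = 0.04)
  expect_equal(accelerating_exponent(1.117, 101940),
               1 / heaps_exponent_numeric(1.117, 101940))
  expect_gte(accelerating_exponent(0.4, 1e10), 1)
})

test_that("relation_curve tabulates a monotone model curve", {
  rc <- relation_curve(1.3, 1e4, grid_size = 200)
  expect_s3_class(rc, "relation_curve")
  expect_true(all(diff(rc$N) > 0))
  expect_equal(nrow(rc), 200)
  expect_equal(max(rc$t), 1e4)
})
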