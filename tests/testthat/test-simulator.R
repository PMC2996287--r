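test_that("simulations are reproducible from the seed and internally consistent", {
  a <- simulate_zipf_stream(1.2, 500, seed = 7)
  b <- simulate_zipf_stream(1.2, 500, seed = 7)
  c <- simulate_zipf_stream(1.2, 500, seed = 8)
  expect_identical(unclass(a$stream), unclass(b$stream))
  expect_false(identical(unclass(a$stream), unclass(c$stream)))
  for (sim in list(a,
                   simulate_cutoff_stream(2.5, 20, 400, seed = 1),
                   simulate_exponential_stream(0.05, 400, seed = 1))) {
    expect_length(sim$stream, sim$config$steps)
    expect_equal(attr(sim$table, "T"), sim$config$steps)
    expect_identical(attr(sim$table, "M"), sim$curve$N[nrow(sim$curve)])
    expect_true(all(diff(sim$curve$N) %in% c(0L, 1L)))
  }
})

test_that("uniform rank choice reproduces the coupon-collector expectation", {
  # alpha = 0 makes every element equally likely each step; the expected
  # number of distinct elements after T = 10 draws from a pool of 10 is
  # 10 * (1 - 0.9^10) = 6.5132
  set.seed(1)
  N <- vapply(1:10000, function(i) {
    attr(simulate_zipf_stream(0, 10, 10)$table, "M")
  }, integer(1))
  expect_equal(mean(N), 10 * (1 - 0.9^10), tolerance = 0.05 / 6.5)
})

test_that("an overwhelming rank-1 preference locks onto a single element", {
  sim <- simulate_zipf_stream(30, 100, seed = 3)
  expect_identical(attr(sim$table, "M"), 1L)
})

test_that("bucket-index sampler agrees with the explicit re-sorting model", {
  # same process, two implementations: compare mean final vocabulary
  nrep <- 60
  N_fast <- vapply(1:nrep, function(s) {
    attr(simulate_zipf_stream(1, 300, 300, seed = s)$table, "M")
  }, integer(1))
  N_ref <- vapply(1:nrep, function(s) {
    length(unique(naive_rank_process(1, 300, 300, seed = 1000 + s)))
  }, integer(1))
  se <- sqrt(var(N_fast) / nrep + var(N_ref) / nrep)
  expect_lt(abs(mean(N_fast) - mean(N_ref)), 4 * max(se, 1))
})

test_that("the simulated rank distribution keeps a stable Zipf exponent", {
  for (alpha in c(0.7, 1.5)) {
    spread <- vapply(1:5, function(s) {
      ev <- unclass(simulate_zipf_stream(alpha, 1e5, seed = s)$stream)
      ah <- vapply(c(1e4, 33333, 1e5), function(k) {
        fit_zipf_mle(as.integer(table(ev[seq_len(k)])), z_min = "auto")$alpha_hat
      }, numeric(1))
      max(ah) - min(ah)
    }, numeric(1))
    expect_lt(median(spread), 0.1)
  }
})

test_that("removing the cutoff recovers the pure Zipf process", {
  beta <- 2.5
  lam_cut <- vapply(1:10, function(s) {
    sim_heaps_fit(simulate_cutoff_stream(beta, 1e4, 1e4, seed = s))$lambda_hat
  }, numeric(1))
  lam_zipf <- vapply(1:10, function(s) {
    sim_heaps_fit(simulate_zipf_stream(1 / (beta - 1), 1e4, seed = s))$lambda_hat
  }, numeric(1))
  expect_lt(abs(median(lam_cut) - median(lam_zipf)), 0.02)
})

test_that("strengthening the cutoff raises the Heaps exponent but keeps the law", {
  fits10 <- lapply(1:10, function(s) sim_heaps_fit(simulate_cutoff_stream(2.5, 10, 1e4, seed = s)))
  lam10 <- vapply(fits10, `[[`, numeric(1), "lambda_hat")
  lam_weak <- vapply(1:10, function(s) {
    sim_heaps_fit(simulate_cutoff_stream(2.5, 1e4, 1e4, seed = s))$lambda_hat
  }, numeric(1))
  expect_gt(median(lam10), median(lam_weak))
  expect_true(all(vapply(fits10, `[[`, numeric(1), "r_squared") > 0.98))
})

test_that("an exponential rank profile bends away from Heaps' law", {
  win <- vapply(1:10, function(s) {
    sim <- simulate_exponential_stream(0.01, 1e5, seed = s)
    c(early = fit_heaps_lsq(sim$curve, fit_range = c(1, 100))$lambda_hat,
      late = fit_heaps_lsq(sim$curve, fit_range = c(1e4, 1e5))$lambda_hat)
  }, numeric(2))
  expect_gt(median(win["early", ]), 0.8)
  expect_gt(median(win["early", ] - win["late", ]), 0.2)
})

test_that("a vanishing decay rate approaches the uniform (coupon) limit", {
  N <- vapply(1:20, function(s) {
    attr(simulate_exponential_stream(1e-9, 1000, seed = s)$table, "M")
  }, integer(1))
  coupon <- 1000 * (1 - (1 - 1 / 1000)^1000)
  expect_lt(abs(mean(N) - coupon) / coupon, 0.05)
})

test_that("fixtures are reproducible and internally consistent", {
  dir <- withr::local_tempdir()
  f1 <- make_fixture("zipf", list(alpha = 1.117, steps = 1e4), seed = 7,
                     dir = dir, prefix = "z1")
  f2 <- make_fixture("zipf", list(alpha = 1.117, steps = 1e4), seed = 7,
                     dir = dir, prefix = "z2")
  expect_identical(readLines(f1[["stream"]]), readLines(f2[["stream"]]))
  expect_identical(readLines(f1[["rankfreq"]]), readLines(f2[["rankfreq"]]))
  # re-read and re-fit recovers the generating exponent
  rf <- read_rank_frequency(f1[["rankfreq"]])
  expect_lt(abs(fit_zipf_mle(rf, z_min = "auto")$alpha_hat - 1.117), 0.1)

  fo <- make_fixture("outbreak-like", list(steps = 2000, n_regions = 40),
                     seed = 2, dir = dir)
  wide <- read_cumulative_csv(fo[["cumulative"]])
  counts <- as.matrix(wide[, -1])
  expect_true(all(apply(counts, 2, function(x) all(diff(x) >= 0))))
  s <- cumulative_counts_to_stream(wide)
  expect_length(s, 2000)

  ft <- make_fixture("text-like", list(alpha = 1, steps = 600), seed = 3, dir = dir)
  st <- read_event_stream(ft[["stream"]], kind = "tokens")
  expect_length(st, 600)
  expect_error(make_fixture("nonsense", seed = 1, dir = dir))
})
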