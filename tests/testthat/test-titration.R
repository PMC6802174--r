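test_that("inverse-intensity normalization has the fast-exchange closed forms", {
  d <- data.frame(conc = c(0, 0.5), intensity = c(100, 100 / 1.18))
  s <- invert_normalize(d)
  expect_equal(s$inv_I_rel[1], 1.0)
  # 1/I_rel = 1 + K [DNA] with K = 0.36 mM^-1 at 0.5 mM
  expect_equal(s$inv_I_rel[2], 1.18, tolerance = 1e-12)
  # halved intensity doubles the inverse
  d2 <- data.frame(conc = c(0, 1), intensity = c(80, 40))
  expect_equal(invert_normalize(d2)$inv_I_rel[2], 2.0)

  expect_error(invert_normalize(data.frame(conc = 0:1, intensity = c(1, -1))),
               "positive")
  expect_error(invert_normalize(data.frame(conc = c(0.2, 0.1),
                                           intensity = c(1, 1))),
               "increasing")
  expect_error(invert_normalize(data.frame(conc = c(0.1, 0.2),
                                           intensity = c(1, 1))), "I0")
  # explicit I0 replaces the zero-DNA point
  expect_equal(invert_normalize(data.frame(conc = c(0.1, 0.2),
                                           intensity = c(50, 25)),
                                I0 = 100)$inv_I_rel, c(2, 4))
})

test_that("noiseless two-regime data is recovered to machine precision", {
  d <- generate_titration(titration_spec(K2 = 0.36, K1 = 0.18,
                                         breakpoint = 0.5, noise_sd = 0))
  fit <- fit_two_regime(invert_normalize(d), breakpoint = 0.5)
  expect_equal(fit$K2_low, 0.36, tolerance = 1e-10)
  expect_equal(fit$K1_high, 0.18, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-20)

  # flat series: both slopes vanish
  flat <- data.frame(conc = seq(0, 1.6, 0.2), inv_I_rel = 1)
  f0 <- fit_two_regime(flat)
  expect_equal(f0$K2_low, 0)
  expect_equal(f0$K1_high, 0)

  # a regime with fewer than 2 points is a coverage error
  thin <- data.frame(conc = c(0, 0.1, 0.2, 0.6), inv_I_rel = c(1, 1, 1, 1.1))
  expect_error(fit_two_regime(thin), "regime")
})

test_that("fitted slopes are invariant to the intensity scale", {
  spec <- titration_spec(noise_sd = 0.02, seed = 42)
  d <- generate_titration(spec)
  f1 <- fit_two_regime(invert_normalize(d))
  d$intensity <- d$intensity * 7.3
  f2 <- fit_two_regime(invert_normalize(d))
  expect_equal(f1$K2_low, f2$K2_low, tolerance = 1e-12)
  expect_equal(f1$K1_high, f2$K1_high, tolerance = 1e-12)
})

test_that("profiled breakpoint recovers the generating regime boundary", {
  d <- generate_titration(titration_spec(K2 = 0.36, K1 = 0.05,
                                         breakpoint = 0.5, noise_sd = 0))
  fit <- fit_two_regime(invert_normalize(d), profile_breakpoint = TRUE)
  expect_equal(fit$breakpoint, 0.5, tolerance = 1e-10)
})

test_that("slope estimates are consistent as noise shrinks and n grows", {
  truth <- c(0.36, 0.18)
  err <- sapply(c(0.04, 0.01, 0.0025), function(ns) {
    e <- replicate(40, {
      d <- generate_titration(titration_spec(noise_sd = ns,
                                             seed = sample.int(1e6, 1)))
      f <- fit_two_regime(invert_normalize(d))
      max(abs(c(f$K2_low, f$K1_high) - truth))
    })
    mean(e)
  })
  expect_true(all(diff(err) < 0))  # mean error decreases with noise
})

test_that("bootstrap intervals are seeded, degenerate on noiseless data", {
  d0 <- generate_titration(titration_spec(noise_sd = 0))
  s0 <- invert_normalize(d0)
  ci0 <- bootstrap_ci(s0, n_boot = 200, seed = 1)
  expect_equal(diff(ci0$K2_low), 0, tolerance = 1e-10)
  expect_equal(diff(ci0$K1_high), 0, tolerance = 1e-10)

  d <- generate_titration(titration_spec(noise_sd = 0.02, seed = 3))
  s <- invert_normalize(d)
  ci1 <- bootstrap_ci(s, n_boot = 200, seed = 5)
  ci2 <- bootstrap_ci(s, n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_gt(diff(ci1$K2_low), 0)
  expect_error(bootstrap_ci(s, n_boot = 50), "n_boot")
})

test_that("titration tables round-trip through CSV", {
  d <- generate_titration(titration_spec(seed = 8))
  f <- tempfile(fileext = ".csv")
  write_titration(d, f)
  d2 <- read_titration(f)
  expect_equal(d2$conc, d$conc)
  expect_equal(d2$intensity, d$intensity, tolerance = 1e-12)
})
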