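test_that("biexponential bleach parameters are recovered from a clean trace", {
  tr <- simulate_intensity_trace(A = 0.6, tau1 = 30, tau2 = 300,
                                 response_profile = 500, n_frames = 150,
                                 dt = 2)
  m <- fit_bleach(tr)
  expect_equal(m$A, 0.6, tolerance = 1e-6)
  expect_equal(m$tau1, 30, tolerance = 1e-5)
  expect_equal(m$tau2, 300, tolerance = 1e-5)
  expect_equal(bleach_curve(m, 0), 1, tolerance = 1e-9)
})

test_that("degenerate traces reduce to the nested models", {
  # constant trace: lifetimes run to the 100 * duration bound, so BL stays
  # within exp(-1/100) of 1 over the trace — identity to ~1%
  tr <- data.frame(t_s = seq(0, 100, by = 2), I_raw = rep(250, 51))
  m <- fit_bleach(tr)
  expect_true(all(abs(bleach_curve(m, tr$t_s) - 1) < 0.011))
  # single exponential: A -> 1
  tr1 <- simulate_intensity_trace(A = 1, tau1 = 40, tau2 = 50,
                                  response_profile = 100, n_frames = 100,
                                  dt = 1)
  m1 <- fit_bleach(tr1)
  bl_fit <- bleach_curve(m1, tr1$t_s)
  expect_equal(bl_fit, exp(-tr1$t_s / 40), tolerance = 1e-6)
  expect_error(fit_bleach(data.frame(t_s = 0:9, I_raw = c(0, rep(1, 9)))),
               "non-positive")
})

test_that("intensity correction divides out bleaching and subtracts background", {
  m <- structure(list(A = 0.5, tau1 = 25, tau2 = 250, t0 = 0),
                 class = "bleach_model")
  t <- seq(0, 80, by = 1)
  BL <- bleach_curve(m, t)
  raw <- data.frame(t_s = t, I_raw = 100 * BL + 40)
  out <- correct_intensity(raw, BG = 40, m)
  expect_true(all(abs(out$I - 100) < 1e-9))

  ident <- structure(list(A = 0, tau1 = 1, tau2 = 1e12, t0 = 0),
                     class = "bleach_model")
  raw2 <- data.frame(t_s = t, I_raw = rnorm(length(t), 50, 5))
  out2 <- correct_intensity(raw2, BG = 0, ident)
  expect_equal(out2$I, raw2$I_raw, tolerance = 1e-6)
  # values below background pass through as negatives
  out3 <- correct_intensity(data.frame(t_s = 0:2, I_raw = c(5, 3, 1)),
                            BG = 10, ident)
  expect_true(all(out3$I < 0))
})

test_that("correction is scale-equivariant", {
  m <- structure(list(A = 0.4, tau1 = 20, tau2 = 200, t0 = 0),
                 class = "bleach_model")
  t <- seq(0, 50, 1)
  raw <- data.frame(t_s = t, I_raw = 80 * bleach_curve(m, t) + 15)
  a <- correct_intensity(raw, BG = 15, m)
  raw_scaled <- data.frame(t_s = t, I_raw = 3 * raw$I_raw)
  b <- correct_intensity(raw_scaled, BG = 45, m)
  expect_equal(b$I, 3 * a$I, tolerance = 1e-12)
})

test_that("normalization pins the designated reference at 100", {
  tr <- data.frame(t_s = 0:9, I = c(50, 55, 60, 65, 70, 75, 80, 85, 90, 95))
  n1 <- normalize_trace(tr, "t0")
  expect_equal(n1$I[1], 100)
  expect_equal(n1$I, tr$I * 2)
  tr2 <- data.frame(t_s = 0:3, I = c(100, 90, 80, 70))
  expect_equal(normalize_trace(tr2, "t0")$I, tr2$I)   # already at 100
  n3 <- normalize_trace(tr, "reference", ref_value = 200)
  expect_equal(n3$I, tr$I / 2)
  expect_error(normalize_trace(data.frame(t_s = 0:1, I = c(0, 0)), "t0"),
               "reference")
})

test_that("the Z-line to sarcolemma ratio is a mean-of-means ratio", {
  expect_equal(zline_sarcolemma_ratio(rep(30, 10), rep(30, 10)), 1)
  expect_equal(zline_sarcolemma_ratio(rep(20, 10), rep(40, 10)), 0.5)
  set.seed(51)
  z <- runif(10, 10, 50); s <- runif(10, 20, 60)
  expect_equal(zline_sarcolemma_ratio(z, s),
               zline_sarcolemma_ratio(sample(z), sample(s)),
               tolerance = 1e-12)
  expect_error(zline_sarcolemma_ratio(rep(1, 10), rep(0, 10)), "zero")
})

test_that("simulate -> fit -> correct round trip recovers the response profile", {
  step <- function(t) ifelse(t < 50, 100, 160)
  noise <- 1
  lesion <- simulate_intensity_trace(A = 0.4, tau1 = 40, tau2 = 600,
                                     response_profile = step, BG = 30,
                                     noise_sd = noise, n_frames = 120,
                                     dt = 1, seed = 52)
  reference <- simulate_intensity_trace(A = 0.4, tau1 = 40, tau2 = 600,
                                        response_profile = 400, BG = 0,
                                        noise_sd = noise, n_frames = 120,
                                        dt = 1, seed = 53)
  m <- fit_bleach(reference)
  out <- correct_intensity(lesion, BG = 30, m)
  rmse <- sqrt(mean((out$I - step(out$t_s))^2))
  expect_lte(rmse, 2 * noise)
})
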