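test_that("zero diffusion and zero noise give frozen molecules", {
  cfg <- sim_config(list(population(0, 1)), sigma_loc = 0, seed = 1,
                    n_molecules = 50, n_frames = 100, mean_track_len = 6)
  s <- simulate_trajectories(cfg)
  spread <- tapply(s$localizations$x_nm, s$localizations$molecule_id,
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))
  spread_y <- tapply(s$localizations$y_nm, s$localizations$molecule_id,
                     function(v) diff(range(v)))
  expect_true(all(spread_y == 0))
})

test_that("step variance matches 2 D dt per axis within 3 SE", {
  D <- 0.1; dt <- 0.03
  cfg <- sim_config(list(population(D, 1)), sigma_loc = 0, dt = dt, seed = 42,
                    n_molecules = 20000, n_frames = 40000,
                    mean_track_len = 10, fov = c(40, 40))
  s <- simulate_trajectories(cfg)
  tr <- s$truth[order(s$truth$molecule_id, s$truth$frame), ]
  same <- tr$molecule_id[-1] == tr$molecule_id[-nrow(tr)]
  dx <- diff(tr$x_um)[same]; dy <- diff(tr$y_um)[same]
  sq <- c(dx^2, dy^2)
  expect_gt(length(sq), 2e5)
  se <- sd(sq) / sqrt(length(sq))
  expect_lt(abs(mean(sq) - 2 * D * dt), 3 * se)
})

test_that("seeded simulations are bit-reproducible", {
  cfg <- sim_config(list(population(0.05, 0.5, "a"), population(0.5, 0.5, "b")),
                    seed = 7, n_molecules = 200, n_frames = 300)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))
})

test_that("trajectory length distribution has the configured mean", {
  m <- 8
  cfg <- sim_config(list(population(0.001, 1)), seed = 3, mean_track_len = m,
                    n_molecules = 5000, n_frames = 10000, fov = c(50, 50))
  s <- simulate_trajectories(cfg)
  len <- as.numeric(table(s$truth$molecule_id))
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - m), 2 * se + 0.05)
})

test_that("gradient mode sets D = D0 + Dinf at the lesion and decays with r", {
  g <- c(0.03, 3, 0.01)
  cfg <- sim_config(gradient = g, lesion_center = c(10, 10), fov = c(20, 20),
                    seed = 5, n_molecules = 2000, n_frames = 2000)
  s <- simulate_trajectories(cfg)
  tr <- s$truth[!duplicated(s$truth$molecule_id), ]
  r <- sqrt((tr$x_um - 10)^2 + (tr$y_um - 10)^2)
  # D at birth radius; non-increasing in r and bounded by the extremes
  expect_true(all(tr$D_true <= g[1] + g[3] + 1e-12))
  expect_true(all(tr$D_true >= g[3]))
  o <- order(r)
  expect_true(all(diff(tr$D_true[o]) <= 1e-12))
  expect_equal(tr$D_true, g[1] * exp(-r / g[2]) + g[3], tolerance = 1e-12)
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(list()), "empty population")
  expect_error(sim_config(list(population(0.1, 0.5))), "sum to 1")
  expect_error(sim_config(list(population(0.1, 1)), dt = 0))
  expect_error(population(-1, 1))
  expect_error(sim_config(gradient = c(0.1, 1, 0.01)), "lesion_center")
})

test_that("rendered frames contain offset-plus-shot-noise when empty and a bright emitter lands in its pixel", {
  cfg <- sim_config(list(population(0, 1)), fov = c(2, 2), pixel_size = 100,
                    seed = 1)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      frame = integer(0), intensity = numeric(0))
  st <- render_frames(empty, cfg, offset = 50, n_frames = 4, seed = 2)
  expect_equal(dim(st), c(20, 20, 4))
  expect_lt(abs(mean(st) - 50), 1)           # Poisson mean = offset
  expect_gt(stats::var(as.numeric(st)), 10)  # shot noise present

  one <- data.frame(x_nm = 1050, y_nm = 550, frame = 0L, intensity = 50000)
  st1 <- render_frames(one, cfg, offset = 10, seed = 3)
  pk <- which(st1[, , 1] == max(st1[, , 1]), arr.ind = TRUE)
  # x = 1050 nm -> 11th column, y = 550 nm -> 6th row
  expect_equal(unname(pk[1, ]), c(6, 11))
})

test_that("bleaching curve construction is normalized and reduces correctly", {
  tr <- simulate_intensity_trace(A = 1, tau1 = 20, tau2 = 99, n_frames = 50,
                                 dt = 1, response_profile = function(t) 1)
  expect_equal(attr(tr, "BL"), exp(-(0:49) / 20), tolerance = 1e-12)
  expect_equal(attr(tr, "BL")[1], 1)  # BL(0) = 1 for any parameters

  tr2 <- simulate_intensity_trace(A = 0.3, tau1 = 7, tau2 = 301,
                                  response_profile = 100, BG = 0,
                                  noise_sd = 0, n_frames = 40, dt = 0.5)
  expect_equal(tr2$I_raw, 100 * attr(tr2, "BL"), tolerance = 1e-12)
  expect_equal(attr(tr2, "BL")[1], 1)

  expect_error(simulate_intensity_trace(0.5, -1, 10, 1), "tau")
})
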