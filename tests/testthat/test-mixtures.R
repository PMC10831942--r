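test_that("histograms bin on the anchored 0.2 grid and area-normalize", {
  p <- build_pdf(rep(-2.05, 7))
  occ <- which(p$counts > 0)
  expect_equal(length(occ), 1)
  expect_equal(p$edges[occ], -2.2, tolerance = 1e-9)
  expect_equal(p$density[occ], 5)              # 1 / 0.2

  set.seed(31)
  q <- build_pdf(rnorm(1000, -1.5, 0.5))
  expect_equal(sum(q$density * q$bin_width), 1, tolerance = 1e-9)
  expect_true(all(abs(q$edges / 0.2 - round(q$edges / 0.2)) < 1e-9))

  r <- build_pdf(c(rep(-1.05, 7), rep(-0.45, 3)))
  expect_setequal(r$density[r$density > 0], c(3.5, 1.5))
  expect_error(build_pdf(numeric(0)), "no finite")
})

test_that("the mixture density evaluates to the normalized closed form", {
  m <- mixture_model(centers = -1, sigmas = 0.43, fractions = 1)
  expect_equal(eval_mixture(m, -1), 1 / (0.43 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(eval_mixture(m, -1 + 0.43), eval_mixture(m, -1 - 0.43),
               tolerance = 1e-12)

  m3 <- mixture_model(centers = c(-2.63, -1.86, -1.14), sigmas = 0.43,
                      fractions = c(0.5, 0.3, 0.2))
  int <- integrate(function(x) eval_mixture(m3, x), -Inf, Inf,
                   rel.tol = 1e-8)
  expect_equal(int$value, 1, tolerance = 1e-6)
})

test_that("a noiseless three-component curve is recovered essentially exactly", {
  cen <- c(-2.63, -1.86, -1.14); sg <- 0.43; fr <- c(0.5, 0.3, 0.2)
  truth <- mixture_model(cen, sg, fr)
  bw <- 0.2
  edges <- seq(-4.4, 0.6, by = bw)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  pdf <- structure(list(edges = edges, mids = mids,
                        counts = rep(1L, length(mids)),
                        density = eval_mixture(truth, mids),
                        n = 100000L, bin_width = bw, label = "noiseless"),
                   class = "histogram_pdf")
  fit <- fit_mixture_global(pdf, J = 3)
  expect_equal(fit$centers, cen, tolerance = 1e-3)
  expect_equal(fit$sigmas, rep(sg, 3), tolerance = 1e-3)
  expect_equal(as.numeric(fit$fractions), fr, tolerance = 1e-3)
})

test_that("global fits share centers and width across datasets", {
  set.seed(32)
  cen <- c(-2.2, -0.9); sg <- 0.4
  x1 <- c(rnorm(4000, cen[1], sg), rnorm(6000, cen[2], sg))
  x2 <- c(rnorm(7000, cen[1], sg), rnorm(3000, cen[2], sg))
  fit <- fit_mixture_global(list(build_pdf(x1, label = "before"),
                                 build_pdf(x2, label = "after")), J = 2)
  # one parameter set serves both datasets by construction
  expect_equal(length(fit$centers), 2)
  expect_equal(fit$datasets, c("before", "after"))
  expect_equal(fit$centers, cen, tolerance = 0.05)
  expect_equal(fit$fractions[1, ], c(0.4, 0.6), tolerance = 0.04)
  expect_equal(fit$fractions[2, ], c(0.7, 0.3), tolerance = 0.04)
  expect_true(all(abs(rowSums(fit$fractions) - 1) < 1e-9))
})

test_that("a single-component fit lands within 2 SE of the sample mean", {
  set.seed(33)
  x <- rnorm(5000, -1.6, 0.45)
  fit <- fit_mixture_global(build_pdf(x), J = 1)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(fit$centers[1] - mean(x)), 2 * se + 0.01)
})

test_that("fit validation guards degenerate requests", {
  p <- build_pdf(rep(-1.05, 20))
  expect_error(fit_mixture_global(p, J = 3), "occupied")
  m <- mixture_model(-1, 0.4, 1)
  m$fractions[1, 1] <- 0.5
  expect_error(eval_mixture(m, 0), "sum to 1")
})

test_that("peak diffusivity comes from bins above half maximum only", {
  set.seed(34)
  x <- rnorm(20000, -0.26, 0.3)
  p <- build_pdf(x)
  pk <- find_peak_D(p)
  expect_equal(pk$center, -0.26, tolerance = 0.03)
  expect_equal(pk$D_pk, 10^pk$center, tolerance = 1e-12)
  expect_equal(pk$D_pk, 0.55, tolerance = 0.05)
  expect_equal(pk$points_used, sum({
    q <- p$density > 0.5 * max(p$density)
    i <- which.max(p$density); lo <- i; hi <- i
    while (lo > 1 && q[lo - 1]) lo <- lo - 1
    while (hi < length(q) && q[hi + 1]) hi <- hi + 1
    hi - lo + 1
  }))
})

test_that("a bimodal histogram fits only the dominant lobe", {
  set.seed(35)
  x <- c(rnorm(15000, -2.5, 0.25), rnorm(6000, -0.5, 0.25))
  p <- build_pdf(x)
  pk <- find_peak_D(p)
  expect_equal(pk$center, -2.5, tolerance = 0.1)  # minor lobe ignored
  narrow <- build_pdf(rep(c(-1.05, -1.25), 3))
  expect_error(find_peak_D(narrow), "fewer than 3")
})

test_that("population shifts reproduce the fraction arithmetic", {
  cavin <- population_shift(c(0.87, 0.00, 0.13), c(0.57, 0.25, 0.18))
  expect_equal(round(unname(cavin$gain_pct["pop2"])), 29)
  cav3 <- population_shift(c(0.39, 0.35, 0.26), c(0.12, 0.57, 0.31))
  expect_equal(round(cav3$loss_pop1_pct), 69)
  same <- population_shift(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  expect_equal(same$loss_pop1_pct, 0)
  expect_true(all(same$gain_pct == 0))
  expect_error(population_shift(c(0, 0.5, 0.5), c(0.2, 0.4, 0.4)), "zero")
})
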