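sample_dw_windows <- function(n_sweeps = 6000, barrier = 8, seed = 9,
                              k = 300, by = 0.1) {
  run_umbrella(
    toy_system("double_well", barrier = barrier, x0 = -1.4, step_sd = 0.12),
    centers = seq(-1.4, 1.4, by = by), k = k, n_sweeps = n_sweeps,
    discard = 0.25, seed = seed, cv = "x"
  )
}

test_that("WHAM recovers a known double well from umbrella windows", {
  wins <- sample_dw_windows()
  prof <- wham(wins, bins = 60, temperature = 300)
  expect_true(attr(prof, "converged"))
  exact <- toy_potential(toy_dw(8), prof$center)
  sel <- !is.na(prof$f)
  d <- prof$f[sel] - exact[sel]
  d <- d - mean(d) # profiles are defined up to an additive constant
  expect_lt(sqrt(mean(d^2)), 0.5)
})

test_that("WHAM divides out the restraint on a flat landscape", {
  # soft springs: stitching noise scales with k, so a weak restraint makes
  # the exact-division property visible above Monte Carlo noise
  wins <- run_umbrella(
    toy_system("harmonic", k = 1e-6, x0 = -1, step_sd = 0.3),
    centers = seq(-1, 1, by = 0.1), k = 50, n_sweeps = 16000,
    seed = 4, cv = "x"
  )
  prof <- wham(wins, bins = 30)
  # flat within the restrained range (tail bins beyond the outermost
  # centers are sampled only by single window edges)
  sel <- !is.na(prof$f) & prof$center >= -1 & prof$center <= 1
  expect_lt(max(prof$f[sel]) - min(prof$f[sel]), 0.3)
})

test_that("WHAM demands at least two overlapping windows", {
  wins <- sample_dw_windows(n_sweeps = 2000)
  expect_error(wham(wins[1]), "length")
  expect_error(wham(wins[c(1, 25)]), "do not overlap")
})

test_that("WHAM is stable under bin doubling on well-sampled data", {
  wins <- sample_dw_windows(n_sweeps = 8000)
  p1 <- wham(wins, bins = 40)
  p2 <- wham(wins, bins = 80)
  f2 <- stats::approx(p2$center, p2$f, xout = p1$center)$y
  sel <- !is.na(p1$f) & !is.na(f2)
  d <- p1$f[sel] - f2[sel]
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 0.35)
})

test_that("rigid center shifts translate the recovered profile", {
  wins <- sample_dw_windows(n_sweeps = 4000)
  shifted <- lapply(wins, function(w) {
    w$center <- w$center + 0.5
    w$series <- w$series + 0.5
    w
  })
  p1 <- wham(wins, bins = 40)
  p2 <- wham(shifted, bins = 40)
  expect_equal(p2$center, p1$center + 0.5, tolerance = 1e-12)
  expect_equal(p2$f, p1$f, tolerance = 1e-9)
})

test_that("bayesian bootstrap is seeded, positive, and shrinks with data", {
  wins1 <- sample_dw_windows(n_sweeps = 3000, seed = 9)
  b1 <- bayesian_bootstrap(wins1, n_boot = 25, seed = 7, bins = 40)
  b1b <- bayesian_bootstrap(wins1, n_boot = 25, seed = 7, bins = 40)
  expect_identical(b1$sd, b1b$sd)
  expect_true(all(b1$sd >= 0, na.rm = TRUE))
  wins2 <- sample_dw_windows(n_sweeps = 12000, seed = 9)
  b2 <- bayesian_bootstrap(wins2, n_boot = 25, seed = 7, bins = 40)
  expect_lt(median(b2$sd, na.rm = TRUE), median(b1$sd, na.rm = TRUE))
  expect_error(bayesian_bootstrap(wins1, n_boot = 1), "at least 2")
})

test_that("well depth reports both energy units and flags unbound profiles", {
  flat <- tibble::tibble(center = seq(0.5, 2, 0.1), f = rep(0, 16))
  wd0 <- well_depth(flat, temperature = 300)
  expect_equal(wd0$depth_kj, 0)
  expect_false(wd0$bound)
  # monotonically decaying repulsive profile has its minimum at the largest
  # distance: no bound state
  mono <- tibble::tibble(center = seq(0.5, 2, 0.1),
    f = seq(10, 0, length.out = 16))
  expect_false(well_depth(mono, temperature = 300)$bound)
  bound <- tibble::tibble(center = seq(0.5, 2.0, 0.1),
    f = c(-5, -20, -12, -6, -3, -1, rep(0, 10)))
  wd <- well_depth(bound, temperature = 300)
  expect_equal(wd$depth_kj, 20)
  expect_equal(wd$minimum_at, 0.6)
  expect_equal(wd$depth_kbt, 20 / (kB * 300), tolerance = 1e-12)
})
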