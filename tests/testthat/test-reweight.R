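test_that("free-energy estimate inverts the bias under the WT relation", {
  b <- meta_bias("x", sigma = 0.2, height = 1, gamma = Inf, stride = 10)
  grid <- seq(-1, 1, by = 0.05)
  expect_true(all(free_energy_estimate(b, grid)$f == 0)) # empty bias
  b <- deposit(b, 0, 10)
  fe <- free_energy_estimate(b, grid)
  expect_equal(fe$x[which.min(fe$f)], 0) # minimum at the kernel center
  expect_equal(max(fe$f) - min(fe$f), 1 * (1 - exp(-1 / (2 * 0.2^2))),
    tolerance = 1e-6
  )
  # finite gamma rescales by gamma/(gamma-1)
  b10 <- meta_bias("x", sigma = 0.2, height = 1, gamma = 10, stride = 10)
  b10 <- deposit(b10, 0, 10)
  fe10 <- free_energy_estimate(b10, grid)
  v_range <- 1 - exp(-1 / (2 * 0.2^2))
  expect_equal(max(fe10$f), (10 / 9) * v_range, tolerance = 1e-6)
})

test_that("bias offset c(t) handles the degenerate limits exactly", {
  grid <- seq(-2, 2, by = 0.02)
  b0 <- meta_bias("x", sigma = 0.5, height = 1, gamma = Inf, stride = 10)
  expect_equal(c_of_t(b0, c(1, 100), grid)$c, c(0, 0)) # zero bias
  # near-constant bias kappa: c(t) = kappa
  bk <- meta_bias("x", sigma = 1e6, height = 2.5, gamma = Inf, stride = 10)
  bk <- deposit(bk, 0, 10)
  expect_equal(c_of_t(bk, 20, grid)$c, 2.5, tolerance = 1e-6)
})

test_that("c(t) grows monotonically as bias accumulates", {
  out <- run_toy_metad(n_steps = 1e4, seed = 19)
  cs <- c_of_t(out$biasB, seq(100, 1e4, length.out = 25),
    seq(-1.8, 1.8, by = 0.02)
  )
  expect_true(all(diff(cs$c) > -1e-6))
})

test_that("frame weights recover the printed limits", {
  # zero bias: exactly uniform weights
  frames <- tibble::tibble(sweep = 1:50, x = rnorm(50))
  b <- meta_bias("x", sigma = 0.3, height = 1, gamma = Inf, stride = 10)
  ens <- frame_weights(frames, b)
  expect_equal(ens$weight, rep(1 / 50, 50))
  # recomputed instantaneous bias matches the engine's record
  out <- run_toy_metad(n_steps = 5e3, seed = 23)
  ens2 <- frame_weights(out$frames, out$biasB, temperature = 300)
  expect_lt(max(abs(ens2$v_bias - out$frames$bias)), 1e-9)
  # V - c identical across frames gives uniform weights
  w <- exp((ens2$v_bias - ens2$v_bias)) # degenerate check of the guard
  expect_true(all(is.finite(ens2$weight)))
  expect_equal(sum(ens2$weight), 1)
})

test_that("weights are invariant to a shared additive constant", {
  out <- run_toy_metad(n_steps = 4e3, seed = 29)
  ens <- frame_weights(out$frames, out$biasB, temperature = 300)
  beta <- 1 / (kB * 300)
  a <- beta * (ens$v_bias - ens$c_t)
  w1 <- exp(a - max(a))
  w2 <- exp((a + 7.3) - max(a + 7.3))
  expect_equal(w1 / sum(w1), w2 / sum(w2), tolerance = 1e-12)
})

test_that("weighted averages follow the defining ratio", {
  expect_equal(weighted_average(c(1, 1, 1), c(1, 2, 6)), 3) # plain mean
  expect_equal(weighted_average(c(0, 1, 0), c(5, 7, 9)), 7) # point mass
  expect_equal(weighted_average(c(0.2, 1.7, 3), rep(1, 3)), 1) # normalization
  expect_error(weighted_average(c(0, 0), c(1, 2)), "zero")
})

test_that("reweighted helicity profiles respect run geometry", {
  p <- model_params("KAAAAAAAAK", neutralized = TRUE, w = 30)
  tr <- mc_sample(p, 3000, seed = 2, record_states = TRUE)
  hel <- reweighted_per_residue_helicity(tr)
  expect_equal(nrow(hel), 10)
  expect_true(all(hel$helicity >= 0 & hel$helicity <= 1))
  # strongly helix-favouring weights give near-total helicity
  expect_gt(mean(hel$helicity), 0.9)
  # all-helical frames give exactly 1 everywhere
  frames <- tibble::tibble(state_code = rep(2^6 - 1, 4), weight = rep(0.25, 4))
  hel2 <- reweighted_per_residue_helicity(frames, n_residues = 6)
  expect_equal(hel2$helicity, rep(1, 6))
})

test_that("biased and unbiased estimates of basin populations agree", {
  # toy double well: reweighted biased run vs a long unbiased run
  out <- run_toy_metad(n_steps = 6e4, seed = 37, barrier = 6)
  ens <- frame_weights(out$frames, out$biasB, temperature = 300)
  p_right <- sum(ens$weight[ens$x > 0])
  sys <- toy_dw(6)
  set.seed(38)
  ref <- ntdfold:::propagate_chunk(sys, list(x = -1), 300,
    n_sweeps = 1.2e5, record_stride = 10
  )
  p_ref <- mean(ref$frames$x > 0)
  expect_lt(abs(p_right - p_ref), 0.08)
})
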