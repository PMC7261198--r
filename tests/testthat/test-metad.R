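test_that("deposits and evaluation follow the Gaussian sum exactly", {
  b <- meta_bias("x", sigma = 0.2, height = 1.5, gamma = Inf, stride = 10)
  expect_equal(evaluate_bias(b, 0.3), 0) # no kernels yet
  b <- deposit(b, 0.5, time = 10)
  expect_equal(evaluate_bias(b, 0.5), 1.5) # peak equals the height
  expect_equal(evaluate_bias(b, 0.5 + 0.2), 1.5 * exp(-1 / 2)) # one sigma out
  expect_equal(evaluate_bias(b, 0.5, t = 5), 0) # before the deposit
  # fixed-height deposition stacks linearly
  b <- deposit(b, 0.5, time = 20)
  expect_equal(evaluate_bias(b, 0.5), 3.0)
})

test_that("well-tempered heights decay by the printed exponential", {
  b <- meta_bias("x", sigma = 0.2, height = 2, gamma = 50, stride = 10)
  b <- deposit(b, 0, time = 10, temperature = 300)
  expect_equal(b$kernels$height[1], 2)
  b <- deposit(b, 0, time = 20, temperature = 300)
  expect_equal(
    b$kernels$height[2],
    2 * exp(-2 / (kB * 49 * 300))
  )
  expect_error(deposit(freeze_bias(b), 0, 30), "frozen")
})

test_that("bias evaluation matches a hand-rolled kernel loop", {
  b <- meta_bias(c("s_alpha", "s_rg"), c(0.3, 0.1), 1, Inf, 10)
  set.seed(2)
  for (t in 1:25) b <- deposit(b, c(runif(1, 0, 5), runif(1, 0.4, 1)), t)
  pts <- cbind(seq(0, 5, length.out = 30), seq(0.4, 1, length.out = 30))
  ref <- sapply(seq_len(nrow(pts)), function(i) {
    sum(b$kernels$height *
      exp(-(pts[i, 1] - b$kernels$center1)^2 / (2 * 0.3^2)
        - (pts[i, 2] - b$kernels$center2)^2 / (2 * 0.1^2)))
  })
  expect_equal(evaluate_bias(b, pts), ref, tolerance = 1e-12)
  expect_error(evaluate_bias(b, c(1)), "dimension mismatch")
})

test_that("temperature ladder is exactly geometric", {
  lad <- temperature_ladder(298, 400, 8)
  expect_equal(lad[1], 298)
  expect_equal(lad[8], 400)
  expect_equal(lad[2], 298 * (400 / 298)^(1 / 7))
  ratios <- lad[-1] / lad[-8]
  expect_equal(ratios, rep((400 / 298)^(1 / 7), 7), tolerance = 1e-12)
  expect_equal(temperature_ladder(300, 450, 2), c(300, 450))
  expect_error(temperature_ladder(300, 450, 1), "at least 2")
})

test_that("exchange probability reduces to the Metropolis factor at zero bias", {
  bi <- 1 / (kB * 300)
  bj <- 1 / (kB * 330)
  expect_equal(
    exchange_probability(-50, -40, 300, 330),
    min(1, exp((bi - bj) * (-50 - (-40))))
  )
  expect_equal(exchange_probability(-50, -50, 300, 300), 1) # identical replicas
  expect_equal(exchange_probability(-10, -80, 300, 300, 3, 3, 5, 5), 1)
  # detailed balance: forward * backward factors multiply to 1 below the cap
  pf <- exchange_probability(-50, -40, 300, 330, 1, 2, 3, 4)
  pb <- exchange_probability(-40, -50, 330, 300, 3, 4, 1, 2)
  expect_equal(pf * (1 / pb), 1, tolerance = 1e-12)
})

test_that("replica exchange preserves the configuration pool and is seeded", {
  sys <- toy_system("harmonic", k = 50, x0 = 0.7, step_sd = 0.2)
  r1 <- run_tremd(sys, c(300, 400, 550), 1200,
    exchange_stride = 100, seed = 8
  )
  r2 <- run_tremd(sys, c(300, 400, 550), 1200,
    exchange_stride = 100, seed = 8
  )
  expect_identical(r1$exchange_log, r2$exchange_log)
  expect_true(all(r1$exchange_log$probability >= 0 &
    r1$exchange_log$probability <= 1))
  # identical temperatures accept every swap
  same <- run_tremd(sys, c(300, 300), 600, exchange_stride = 100, seed = 1)
  expect_true(all(same$exchange_log$accepted))
})

test_that("wider ladders exchange less", {
  sys <- toy_system("harmonic", k = 100, x0 = 0, step_sd = 0.3)
  narrow <- run_tremd(sys, c(300, 380), 6000, exchange_stride = 100, seed = 3)
  wide <- run_tremd(sys, c(300, 1500), 6000, exchange_stride = 100, seed = 3)
  expect_gt(
    mean(narrow$exchange_log$accepted),
    mean(wide$exchange_log$accepted)
  )
})

test_that("the WTE stage must precede production biasing", {
  # production driven with an unfrozen WTE bias is a protocol error
  b <- meta_bias("energy", sigma = 1, height = 1, gamma = 50, stride = 100)
  expect_false(b$frozen)
  expect_true(freeze_bias(b)$frozen)
})

test_that("a zero-height WTE stage reduces to plain parallel tempering", {
  sys <- toy_system("harmonic", k = 100, x0 = 0, step_sd = 0.3)
  lad <- c(300, 500)
  run0 <- run_ptmetad_wte(sys, lad,
    wte = list(height = 0, sigma = 1, gamma = 50, stride = 100),
    production = list(cvs = "x", height = 0, sigma = 0.2, gamma = 10,
      stride = 1e9),
    n_sweeps_wte = 400, n_sweeps = 1000, exchange_stride = 100, seed = 17
  )
  set.seed(17)
  base <- run_tremd(sys, lad, 400, exchange_stride = 100, seed = NULL)
  base2 <- run_tremd(sys, lad, 1000, exchange_stride = 100, seed = NULL)
  expect_equal(
    run0$production$exchange_log$probability,
    base2$exchange_log$probability
  )
})

test_that("umbrella windows concentrate at their centers", {
  sys <- toy_system("harmonic", k = 0.001, x0 = 0, step_sd = 0.1)
  wins <- run_umbrella(sys, centers = c(-1, 0, 1), k = 1e5,
    n_sweeps = 600, seed = 5, cv = "x"
  )
  for (w in wins) {
    expect_lt(abs(mean(w$series) - w$center), 0.02)
    expect_lt(stats::sd(w$series), 0.01)
  }
  # flat potential: means track centers at moderate stiffness too
  wins2 <- run_umbrella(sys, centers = seq(-1, 1, 0.5), k = 200,
    n_sweeps = 2000, seed = 6, cv = "x"
  )
  expect_lt(max(abs(vapply(wins2, function(w) mean(w$series), 1) -
    seq(-1, 1, 0.5))), 0.1)
  expect_warning(
    run_umbrella(sys, 0, k = 100, n_sweeps = 80, seed = 1, cv = "x"),
    "samples"
  )
})
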