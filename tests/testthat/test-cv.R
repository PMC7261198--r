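test_that("rational switch has the printed limits and monotonicity", {
  expect_equal(rational_switch(0, 8, 12), 1)
  expect_equal(rational_switch(1, 8, 12), 8 / 12)
  expect_equal(rational_switch(1e6, 8, 12), 0, tolerance = 1e-12)
  x <- seq(0, 5, by = 0.01)
  expect_true(all(diff(rational_switch(x, 8, 10)) <= 1e-12))
  # continuity through the removable singularity
  expect_equal(rational_switch(1 + 1e-7, 8, 12), 8 / 12, tolerance = 1e-5)
  expect_error(switch_params(0.1, 12, 8))
})

test_that("helicity CV scores ideal helices at the window count", {
  expect_equal(s_alpha(helix_template(11)), 6, tolerance = 1e-9)
  expect_equal(s_alpha(helix_template(6)), 1, tolerance = 1e-9)
  # fully extended chain scores essentially zero
  ext <- cbind(0.38 * (0:10), 0, 0)
  expect_lt(s_alpha(ext), 0.1)
  expect_error(s_alpha(helix_template(5)), "at least 6")
})

test_that("helicity CV decreases monotonically along a helix-to-coil morph", {
  ext <- cbind(0.38 * (0:10), 0, 0)
  tmpl <- helix_template(11)
  vals <- vapply(seq(0, 1, length.out = 10), function(a) {
    s_alpha((1 - a) * tmpl + a * ext)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("CVs are invariant under rigid rotation and translation", {
  conf <- build_coordinates(c(rep(1, 7), rep(0, 4)), seed = 5)
  moved <- rigid_move(conf$ca)
  expect_equal(s_alpha(moved), s_alpha(conf$ca), tolerance = 1e-9)
  expect_equal(s_rg(moved), s_rg(conf$ca), tolerance = 1e-9)
})

test_that("radius of gyration reproduces closed forms", {
  expect_equal(s_rg(matrix(c(3, -2, 7), 1, 3)), 0)
  expect_equal(s_rg(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(s_rg(sq), sqrt(2) / 2)
  # mass weighting: doubling one mass shifts the centre
  expect_equal(
    s_rg(rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(2, 1)),
    sqrt((2 * (1 / 3)^2 + (2 / 3)^2) / 3)
  )
})

test_that("contact CV equals the brute-force double loop", {
  rod <- make_dna_rod(20)
  p <- model_params("KAKAKAKAKA")
  conf <- build_coordinates(rep(0, 10), p, seed = 8)
  conf$charge_sites <- conf$charge_sites +
    matrix(c(1.0, 0, 0), nrow(conf$charge_sites), 3, byrow = TRUE)
  sp <- contact_switch_defaults()
  acc <- rod$sites[rod$site_central, ]
  ref <- 0
  for (i in seq_len(nrow(conf$charge_sites))) {
    for (j in seq_len(nrow(acc))) {
      r <- sqrt(sum((conf$charge_sites[i, ] - acc[j, ])^2))
      ref <- ref + rational_switch(r / sp$r0, sp$n, sp$m)
    }
  }
  expect_equal(s_cont(conf, rod), ref, tolerance = 1e-12)
})

test_that("contact CV limits: far, coincident, and at R0", {
  rod <- make_dna_rod(20)
  # the m - n = 2 rational tail decays as (r/R0)^-2, so a distant donor
  # contributes a small but non-zero count
  far <- matrix(c(10, 10, 10), 1, 3)
  expect_lt(s_cont(far, rod), 0.01)
  expect_gt(s_cont(far, rod), 0)
  # a donor exactly on an acceptor: that pair switches fully on (value 1);
  # neighbouring phosphates add their tail contributions on top
  one <- rod$sites[rod$site_central, , drop = FALSE][1, , drop = FALSE]
  expect_equal(rational_switch(0, 8, 10), 1)
  expect_gte(s_cont(one, rod), 1)
  expect_lt(s_cont(one, rod), 2)
  # a single donor at r = R0 from a single acceptor contributes n/m = 0.8
  expect_equal(rational_switch(1, 8, 10), 0.8)
  empty <- matrix(numeric(0), 0, 3)
  expect_warning(v <- s_cont(empty, rod), "empty donor")
  expect_equal(v, 0)
})

test_that("radial distance ignores the axial component", {
  rod <- make_dna_rod(20)
  onaxis <- matrix(c(0, 0, 2.5), 1, 3)
  expect_equal(radial_distance(onaxis, rod), 0)
  off <- matrix(c(1, 0, 5), 1, 3)
  expect_equal(radial_distance(off, rod), 1)
  diag2 <- matrix(c(0.6, 0.8, -3), 1, 3)
  expect_equal(radial_distance(diag2, rod), 1)
})

test_that("windowed helicity agrees between compiled and plain-R paths", {
  conf <- build_coordinates(c(rep(1, 6), 0, 0, rep(1, 4)), seed = 13)
  expect_equal(
    s_alpha(conf$ca),
    ntdfold:::s_alpha_reference(conf$ca),
    tolerance = 1e-12
  )
})
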