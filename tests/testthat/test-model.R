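test_that("chain builder realizes helices exactly and stays continuous", {
  conf <- build_coordinates(rep(1, 12))
  expect_lt(kabsch_rmsd(conf$ca, helix_template(12)), 1e-6)
  d <- sqrt(rowSums((conf$ca[-1, ] - conf$ca[-12, ])^2))
  expect_true(all(d >= 0.36 & d <= 0.40))
  # coil coordinates are reproducible under a seed
  c1 <- build_coordinates(rep(0, 12), seed = 4)
  c2 <- build_coordinates(rep(0, 12), seed = 4)
  expect_identical(c1$ca, c2$ca)
  # short h-runs (< 4) are not built on helix geometry
  c3 <- build_coordinates(c(0, 1, 1, 1, 0, 0, 0, 0), seed = 1)
  expect_gt(kabsch_rmsd(c3$ca[2:4, , drop = FALSE], helix_template(3)), 1e-4)
  c4 <- build_coordinates(c(0, 1, 1, 1, 1, 0, 0, 0), seed = 1)
  expect_lt(kabsch_rmsd(c4$ca[2:5, , drop = FALSE], helix_template(4)), 1e-9)
  expect_error(build_coordinates(integer(0)), "empty")
})

test_that("energy terms match an independent R-side evaluation", {
  p <- model_params("KAKDAK", w = 1.7, v = 0.06)
  conf <- build_coordinates(c(1, 1, 1, 1, 0, 1), p, seed = 2)
  e <- cg_energy(conf, p)
  # helix-coil bookkeeping: 5 h residues, 2 runs
  e_hc <- -kB * 300 * (5 * log(1.7) + 2 * log(0.06))
  expect_equal(e$e_hc, e_hc, tolerance = 1e-12)
  # electrostatics: explicit pair sum over charge sites
  q <- p$charge[conf$charge_residues]
  s <- conf$charge_sites
  ref <- 0
  for (i in 1:(nrow(s) - 1)) {
    for (j in (i + 1):nrow(s)) {
      r <- sqrt(sum((s[i, ] - s[j, ])^2))
      ref <- ref + p$prefactor * q[i] * q[j] * exp(-r / p$debye) / r
    }
  }
  expect_equal(e$e_elec, ref, tolerance = 1e-12)
  # point formula at r equal to the screening length
  expect_equal(p$prefactor * exp(-1) / p$debye,
    p$prefactor * exp(-p$debye / p$debye) / p$debye)
})

test_that("all-coil uncharged chains have zero energy", {
  p <- model_params("AAAA")
  conf <- build_coordinates(rep(0, 4), p, seed = 1)
  expect_equal(cg_energy(conf, p)$e_total, 0)
})

test_that("neutralization zeroes the electrostatic term", {
  h <- ntd_fixture_sequences()
  sub <- extract_basic_subregion(h$H1.0)
  states <- rep(1, 10)
  pc <- model_params(sub, neutralized = FALSE)
  pn <- model_params(sub, neutralized = TRUE)
  set.seed(3)
  lib <- coil_library_sample(10)
  cc <- build_coordinates(states, pc, lib$theta, lib$tau)
  cn <- build_coordinates(states, pn, lib$theta, lib$tau)
  expect_gt(cg_energy(cc, pc)$e_elec, 0)
  expect_equal(cg_energy(cn, pn)$e_elec, 0)
  expect_equal(cg_energy(cc, pc)$e_hc, cg_energy(cn, pn)$e_hc)
})

test_that("energy is exactly reproducible for a frozen conformation", {
  p <- model_params("KRAKEA")
  conf <- build_coordinates(c(0, 1, 1, 1, 1, 0), p, seed = 9)
  e1 <- cg_energy(conf, p)
  e2 <- cg_energy(conf, p)
  expect_identical(e1, e2)
})

test_that("sampler is deterministic under a seed", {
  p <- model_params("KAAKAA")
  t1 <- mc_sample(p, 500, seed = 42, record_states = TRUE)
  t2 <- mc_sample(p, 500, seed = 42, record_states = TRUE)
  expect_identical(tidy(t1), tidy(t2))
  expect_identical(t1$state_code, t2$state_code)
})

test_that("infinite-temperature sampling is uniform over states", {
  p <- model_params("AAAAAAAAAA", temperature = 3e7, neutralized = TRUE)
  tr <- mc_sample(p, 6000, seed = 3, record_stride = 5)
  expect_equal(mean(tr$n_h) / 10, 0.5, tolerance = 0.04)
})

test_that("sampled state frequencies match exact Boltzmann weights", {
  # detailed balance in aggregate: empirical 6-residue state distribution
  # (flips only, frozen coil geometry, charges on) vs exact enumeration
  fx <- frozen_six(seed = 21, sequence = "KAAKAA")
  tr <- mc_sample(fx$params, 4e4,
    seed = 31, init = fx$init,
    moves = c(flip = 1), record_stride = 5, record_states = TRUE
  )
  emp <- tapply(
    rep(1 / nrow(tr), nrow(tr)),
    factor(tr$state_code, levels = fx$exact$state_code), sum
  )
  emp[is.na(emp)] <- 0
  expect_lt(max(abs(as.numeric(emp) - fx$exact$prob)), 0.02)
})

test_that("transfer-matrix helicity is exact and refuses charged systems", {
  # single-residue closed form: p = w v / (1 + w v)
  p1 <- model_params("A", w = 1.5, v = 0.1)
  expect_equal(
    transfer_matrix_helicity(p1)$p_helix,
    1.5 * 0.1 / (1 + 1.5 * 0.1)
  )
  # vanishing propagation weight kills helicity everywhere
  p0 <- model_params("AAAAA", w = 1e-12, w_pro = 1e-12, w_gly = 1e-12)
  expect_true(all(transfer_matrix_helicity(p0)$p_helix < 1e-10))
  # end effects: interior exceeds termini for a homopolymer
  ph <- model_params("AAAAAAAAAAAAAAAAAAAA", w = 1.5, v = 0.05)
  hel <- transfer_matrix_helicity(ph)$p_helix
  expect_gt(hel[10], hel[1])
  expect_gt(hel[10], hel[20])
  # the oracle is invalid when charges are active
  expect_error(
    transfer_matrix_helicity(model_params("KAKA")),
    "charges off"
  )
})

test_that("MC per-residue helicity agrees with the transfer matrix", {
  p <- model_params("KAKRAKAAKK", neutralized = TRUE)
  tm <- transfer_matrix_helicity(p)
  tr <- mc_sample(p, 2e4, seed = 7, record_states = TRUE, record_stride = 5)
  mc <- colMeans(decode_states(tr$state_code, 10))
  # binomial-scale error bound with a generous correlation allowance
  expect_lt(max(abs(tm$p_helix - mc)), 0.05)
})

test_that("brute-force enumeration agrees with the transfer matrix", {
  # independent oracle for the oracle: sum over all 2^L states in R
  p <- model_params("KAPKAA", neutralized = TRUE, w = 1.8, v = 0.07)
  L <- 6
  codes <- 0:(2^L - 1)
  wts <- vapply(codes, function(code) {
    s <- as.integer(bitwAnd(bitwShiftR(code, 0:(L - 1)), 1L))
    runs <- sum(s == 1 & c(1L, diff(s)) == 1)
    prod(p$w^s) * p$v^runs
  }, numeric(1))
  pj <- vapply(seq_len(L), function(i) {
    on <- bitwAnd(bitwShiftR(codes, i - 1), 1L) == 1
    sum(wts[on]) / sum(wts)
  }, numeric(1))
  expect_equal(transfer_matrix_helicity(p)$p_helix, pj, tolerance = 1e-12)
})

test_that("DNA rod geometry and central subset follow the construction", {
  rod <- make_dna_rod(20)
  expect_equal(rod$n_bp, 20)
  expect_equal(sum(rod$bp$central), 11)
  expect_equal(nrow(rod$sites), 40)
  expect_equal(diff(rod$bp$z[1:2]), 0.34)
  expect_equal(sum(make_dna_rod(11)$bp$central), 11)
  expect_error(make_dna_rod(10), "11")
})

test_that("neutralization raises helicity for basic helix-capable peptides", {
  h <- ntd_fixture_sequences()
  sub <- extract_basic_subregion(h$H1.0)
  mean_sa <- function(neu, seed) {
    p <- model_params(sub, neutralized = neu)
    tr <- mc_sample(p, 8000, seed = seed, record_stride = 10)
    mean(tr$s_alpha[-(1:100)])
  }
  expect_gte(mean_sa(TRUE, 11), mean_sa(FALSE, 12))
})
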