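test_that("secondary-structure assignment uses the minimum-run convention", {
  expect_equal(
    assign_secondary_structure(matrix(1, 1, 6)),
    rep("helix", 6)
  )
  # an isolated helical residue is coil
  expect_equal(
    assign_secondary_structure(matrix(c(0, 0, 1, 0, 0), 1)),
    rep("coil", 5)
  )
  # a run of exactly three counts (3-10-like)
  expect_equal(
    assign_secondary_structure(matrix(c(0, 1, 1, 1, 0), 1)),
    c("coil", "helix", "helix", "helix", "coil")
  )
  # dihedral mode: ideal alpha angles over >= 3 residues
  ang <- cbind(rep(-57, 6), rep(-47, 6))
  expect_equal(assign_secondary_structure(ang, mode = "dihedral"),
    rep("helix", 6))
  ang2 <- cbind(c(-57, -57, 60, -57, -57, 60), rep(-47, 6))
  expect_equal(assign_secondary_structure(ang2, mode = "dihedral"),
    rep("coil", 6))
})

test_that("compaction baselines evaluate the printed power laws", {
  b1 <- rg_baselines(1)
  expect_equal(b1$rg_glob, 2.2)
  expect_equal(b1$rg_coil, 2.02)
  b26 <- rg_baselines(26)
  expect_equal(b26$rg_glob, 2.2 * 26^0.38)
  expect_equal(b26$rg_coil, 2.02 * 26^0.60)
  expect_equal(round(b26$rg_glob, 2), 7.59)
  expect_equal(round(b26$rg_coil, 1), 14.3)
  ns <- rg_baselines(1:60)
  expect_true(all(diff(ns$rg_glob) > 0) && all(diff(ns$rg_coil) > 0))
  expect_true(all(ns$rg_coil[-1] > ns$rg_glob[-1]))
})

test_that("rg distributions put helices below the coil baseline", {
  # helix-only ensemble of a 26-mer is compact
  hel <- tibble::tibble(s_rg = rep(s_rg(helix_template(26)), 5))
  rd <- rg_distribution(hel, n_residues = 26)
  expect_lt(attr(rd, "mean_rg"), rg_baselines(26)$rg_coil)
  # a single frame is a point mass
  one <- rg_distribution(tibble::tibble(s_rg = 1.23), n_residues = 26)
  expect_equal(attr(one, "mean_rg"), 12.3)
  expect_equal(sum(one$density > 0), 1)
})

test_that("single-linkage clustering takes the transitive closure", {
  base <- helix_template(8)
  set.seed(6)
  samecl <- replicate(4, base + matrix(rnorm(24, 0, 0.005), 8, 3),
    simplify = FALSE
  )
  cl <- single_linkage_cluster(samecl, cutoff_angstrom = 2.5)
  expect_equal(nrow(attr(cl, "populations")), 1)
  expect_equal(attr(cl, "populations")$population, 1)
  # two distinct rigid shapes far apart split
  ext <- cbind(0.38 * (0:7), 0, 0)
  cl2 <- single_linkage_cluster(list(base, ext), cutoff_angstrom = 2.5)
  expect_equal(nrow(attr(cl2, "populations")), 2)
  # chaining: consecutive frames close, ends far, still one cluster
  morph <- lapply(seq(0, 1, length.out = 12), function(a) {
    (1 - a) * base + a * ext
  })
  expect_gt(kabsch_rmsd(morph[[1]], morph[[12]]), 0.25) # ends beyond cutoff
  cl3 <- single_linkage_cluster(morph, cutoff_angstrom = 2.5)
  expect_equal(nrow(attr(cl3, "populations")), 1)
  # all-pairwise-distant frames stay singletons
  far <- lapply(1:4, function(i) {
    set.seed(100 + i)
    build_coordinates(rep(0, 8))$ca
  })
  d <- sapply(far, function(a) sapply(far, function(b) kabsch_rmsd(a, b)))
  if (all(d[upper.tri(d)] > 0.25)) {
    cl4 <- single_linkage_cluster(far, cutoff_angstrom = 2.5)
    expect_equal(nrow(attr(cl4, "populations")), 4)
  }
  # populations are invariant under frame reordering
  cl5 <- single_linkage_cluster(rev(morph), cutoff_angstrom = 2.5)
  expect_equal(
    attr(cl5, "populations")$population,
    attr(cl3, "populations")$population
  )
})

test_that("contact fractions bracket the far and pinned limits", {
  rod <- make_dna_rod(20)
  far <- cbind(0.38 * (0:5) + 8, 8, 8)
  cf <- contact_fraction(list(far), rod)
  expect_equal(sum(cf$contact_fraction), 0)
  expect_equal(attr(cf, "bound_fraction"), 0)
  pinned <- far
  pinned[3, ] <- rod$sites[5, ]
  cf2 <- contact_fraction(list(pinned, far), rod, weights = c(0.5, 0.5))
  expect_equal(cf2$contact_fraction[3], 0.5)
  expect_equal(attr(cf2, "bound_fraction"), 0.5)
})

test_that("free-energy surfaces are flat for flat sampling", {
  set.seed(9)
  frames <- tibble::tibble(x = runif(60000, 0, 1))
  f1 <- fes(frames, cvs = "x", bins = 25)
  expect_lt(max(f1$f, na.rm = TRUE) - min(f1$f, na.rm = TRUE), 0.2)
})

test_that("two-state populations map to the closed-form free-energy gap", {
  # two basins at x = 0 and x = 1 separated by a sparse barrier bin
  frames <- tibble::tibble(
    x = c(rep(0, 700), rep(0.5, 10), rep(1, 290)),
    weight = rep(1 / 1000, 1000)
  )
  f <- fes(frames, cvs = "x", bins = 3, temperature = 300)
  expect_equal(attr(f, "delta_e"), -kB * 300 * log(0.29 / 0.7),
    tolerance = 1e-9
  )
  # empty bins are masked, not imputed
  f2 <- fes(tibble::tibble(x = c(rep(0, 5), rep(1, 5))), cvs = "x", bins = 10)
  expect_true(any(is.na(f2$f)))
})

test_that("from-bias and from-weights surfaces agree on a converged run", {
  out <- run_toy_metad(n_steps = 8e4, seed = 11)
  ens <- frame_weights(out$frames, out$biasB, temperature = 300)
  fw <- fes(ens, cvs = "x", bins = 35, temperature = 300)
  grid <- fw$x
  fb <- fes(out$biasB, mode = "from-bias", grid = grid)
  sel <- !is.na(fw$f) & toy_potential(out$system, grid) < 7
  d <- fb$f[sel] - fw$f[sel]
  d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 1)
})

test_that("block-average convergence diagnoses stationarity and drift", {
  set.seed(10)
  stat <- convergence_check(rnorm(2000, 0.4, 0.05),
    block_length = 400,
    discard = 200, threshold = 0.05
  )
  expect_true(attr(stat, "converged"))
  drift <- convergence_check(seq(0, 1, length.out = 2000), block_length = 400)
  expect_false(attr(drift, "converged"))
  expect_error(convergence_check(1:10, block_length = 8), "too short")
  # block-mean spread shrinks roughly as 1/sqrt(block length)
  x <- rnorm(40000)
  sd_small <- sd(convergence_check(x, block_length = 100)$mean)
  sd_big <- sd(convergence_check(x, block_length = 1600)$mean)
  expect_gt(sd_small / sd_big, 2) # expect ~4
})

test_that("tidiers and plots expose results without side effects", {
  p <- model_params("KAAKAA", neutralized = TRUE)
  tr <- mc_sample(p, 400, seed = 1)
  expect_s3_class(tidy(tr), "tbl_df")
  g <- glance(tr)
  expect_equal(g$n_frames, nrow(tr))
  hw <- helical_wheel(extract_basic_subregion(ntd_fixture_sequences()$H1.0))
  expect_s3_class(autoplot(hw), "ggplot")
  expect_s3_class(autoplot(tr), "ggplot")
  prof <- tibble::tibble(center = seq(0.1, 0.5, 0.1), f = c(-8, -5, -2, 0, 0))
  class(prof) <- c("pmf_profile", class(prof))
  expect_s3_class(autoplot(prof), "ggplot")
})
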