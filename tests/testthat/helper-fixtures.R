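# shared helpers: small deterministic systems used across test files

kB <- 0.0083145

toy_dw <- function(barrier = 8, x0 = -1, step_sd = 0.25) {
  toy_system("double_well", barrier = barrier, x0 = x0, step_sd = step_sd)
}

# short biased run on the double well, returning frames + grown bias
run_toy_metad <- function(n_steps = 2e4, seed = 11, barrier = 8,
                          height = 0.5, gamma = 10, stride = 50,
                          record_stride = 20) {
  sys <- toy_dw(barrier)
  b <- meta_bias("x", sigma = 0.1, height = height, gamma = gamma,
    stride = stride
  )
  set.seed(seed)
  out <- ntdfold:::propagate_chunk(sys, list(x = -1), 300,
    n_sweeps = n_steps,
    record_stride = record_stride, biasB = b
  )
  out$system <- sys
  out
}

# frozen-geometry 6-residue system: enumerable ground truth
frozen_six <- function(seed = 21, sequence = "KAAKAA", ...) {
  set.seed(seed)
  p <- model_params(sequence, ...)
  lib <- coil_library_sample(nchar(sequence))
  init <- build_coordinates(rep(0L, nchar(sequence)), p,
    coil_theta = lib$theta, coil_tau = lib$tau
  )
  list(params = p, lib = lib, init = init,
    exact = enumerate_states(p, lib$theta, lib$tau)
  )
}

# rigid-rotation + translation of a coordinate matrix
rigid_move <- function(x, angle = 0.7, axis = c(1, 2, 2), shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(x %*% t(R), 2, -shift)
}
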