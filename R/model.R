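KB <- 0.0083145 # kJ/mol/K

CV_IDS <- c(
  s_alpha = 1L, s_rg = 2L, s_cont = 3L, rdist = 4L, energy = 5L, n_h = 6L
)

#' Parameters of the coarse-grained helix-coil model
#'
#' A minimal sequence-aware helix-coil Hamiltonian with three residue classes
#' (Pro, Gly, all other), a nucleation penalty, screened Debye-Hueckel
#' electrostatics between sidechain pseudo-charges (Lys/Arg +1, Asp/Glu -1,
#' His neutral), a neutralization switch that zeroes the basic charges
#' (emulating charge screening by DNA or reduced protonation), and an
#' optional attractive DNA-rod field.
#'
#' The helix-coil energy of a state vector is
#' `-kB * t_ref * (sum(log w_i over helical residues) + n_runs * log v)`,
#' so `w > 1` favours propagation and `v < 1` penalizes nucleation.
#' Default weights are calibrated so that the bundled subtype subregions
#' reproduce the qualitative neutralization-induced helicity ordering
#' (see the methods vignette).
#'
#' @param sequence Character sequence, [ntd_sequence] or [basic_subregion].
#' @param w Propagation weight of non-Pro/Gly residues (dimensionless).
#' @param w_pro,w_gly Propagation weights of Pro and Gly (helix breakers).
#' @param v Nucleation weight (dimensionless, < 1).
#' @param debye_nm Debye screening length in nm (0.78 nm for 0.15 M
#'   monovalent salt).
#' @param prefactor Screened-Coulomb prefactor in kJ/mol nm per unit charge
#'   pair (default `kB * 300 * 0.7`, the Bjerrum prefactor in water at 300 K).
#' @param dna_strength Dimensionless scale of the DNA-rod interaction.
#' @param temperature Simulation temperature in K.
#' @param t_ref Reference temperature (K) defining the helix-coil energy
#'   scale, so that propensities weaken at high simulation temperature.
#' @param neutralized Logical; if `TRUE`, Lys/Arg charges are set to zero.
#'
#' @return An object of class `hc_params`.
#' @export
#' @examples
#' p <- model_params("KAKAKAAAAK", neutralized = TRUE)
model_params <- function(sequence, w = 2.0, w_pro = 0.02, w_gly = 0.3,
                         v = 0.05, debye_nm = 0.78,
                         prefactor = KB * 300 * 0.7, dna_strength = 1.0,
                         temperature = 300, t_ref = 300,
                         neutralized = FALSE) {
  sp <- as_residue_span(sequence)
  res <- sp$residues
  stopifnot(w > 0, w_pro > 0, w_gly > 0, v > 0, debye_nm > 0, temperature > 0)
  wi <- ifelse(res == "P", w_pro, ifelse(res == "G", w_gly, w))
  q <- ifelse(res %in% c("K", "R"), if (neutralized) 0 else 1,
    ifelse(res %in% c("D", "E"), -1, 0)
  )
  structure(
    list(
      sequence = res, residue_index = sp$index, label = sp$label,
      w = wi, v = v, charge = q, debye = debye_nm, prefactor = prefactor,
      dna_strength = dna_strength, temperature = temperature, t_ref = t_ref,
      neutralized = neutralized,
      class_w = c(other = w, P = w_pro, G = w_gly)
    ),
    class = "hc_params"
  )
}

#' @export
print.hc_params <- function(x, ...) {
  cat(sprintf(
    "<hc_params> %s (%d residues)%s\n  w = %.3g (P %.3g, G %.3g), v = %.3g, T = %g K, lambda_D = %g nm\n",
    x$label, length(x$sequence),
    if (x$neutralized) " [neutralized]" else "",
    x$class_w["other"], x$class_w["P"], x$class_w["G"], x$v,
    x$temperature, x$debye
  ))
  invisible(x)
}

mspec_of <- function(p) {
  list(
    w = p$w, v = p$v, charge = p$charge, debye = p$debye,
    prefactor = p$prefactor, dna_strength = p$dna_strength, t_ref = p$t_ref
  )
}

rodspec_of <- function(rod) {
  if (is.null(rod)) {
    return(NULL)
  }
  stopifnot(inherits(rod, "dna_rod"))
  list(
    sites = rod$sites, central = rod$site_central,
    site_charge = rod$site_charge, center = rod$center
  )
}

# ---------------------------------------------------------------------------

#' Draw coil dihedral angles from the coil library
#'
#' The coil library is a broad uniform basin: virtual bond angles uniform on
#' 75-145 degrees, virtual dihedrals uniform on (-180, 180]. Only the
#' statistical compaction of the coil, not Ramachandran fidelity, is modelled.
#'
#' @param n Number of residues.
#' @return List with elements `theta` and `tau` in radians.
#' @export
coil_library_sample <- function(n) {
  list(
    theta = stats::runif(n, 75, 145) * pi / 180,
    tau = stats::runif(n, -180, 180) * pi / 180
  )
}

#' Build Calpha coordinates from a helix/coil state vector
#'
#' Maximal runs of at least 4 consecutive helical residues are built on ideal
#' alpha-helix Calpha geometry (rise 0.15 nm per residue, 100 degrees per
#' residue, virtual bond 0.38 nm); all other residues use their coil
#' dihedrals. The chain is continuous by construction.
#'
#' @param states Integer/logical vector (1 = helix, 0 = coil) or character
#'   vector of `"h"`/`"c"` labels.
#' @param params Optional [model_params()]; if supplied, charge pseudo-atoms
#'   are placed for its charged residues.
#' @param coil_theta,coil_tau Optional coil angles in radians (drawn from
#'   [coil_library_sample()] when missing).
#' @param seed Optional seed used when drawing coil angles.
#'
#' @return An object of class `cg_conformation`: list with `states`, `ca`
#'   (n x 3 matrix, nm), `charge_sites`, `charge_residues`, `coil_theta`,
#'   `coil_tau`, `shift`.
#' @export
#' @examples
#' conf <- build_coordinates(rep(1, 11))
#' s_alpha(conf)
build_coordinates <- function(states, params = NULL, coil_theta = NULL,
                              coil_tau = NULL, seed = NULL) {
  states <- normalize_states(states)
  n <- length(states)
  if (n < 1) stop("empty state vector", call. = FALSE)
  if (is.null(coil_theta) || is.null(coil_tau)) {
    if (!is.null(seed)) set.seed(seed)
    lib <- coil_library_sample(n)
    if (is.null(coil_theta)) coil_theta <- lib$theta
    if (is.null(coil_tau)) coil_tau <- lib$tau
  }
  ca <- .cpp_build_chain(states, coil_theta, coil_tau)
  charged <- if (is.null(params)) integer(0) else which(params$charge != 0)
  sites <- if (length(charged)) {
    .cpp_charge_sites(ca, charged - 1L)
  } else {
    matrix(numeric(0), 0, 3)
  }
  structure(
    list(
      states = states, ca = ca, charge_sites = sites,
      charge_residues = charged, coil_theta = coil_theta,
      coil_tau = coil_tau, shift = c(0, 0, 0)
    ),
    class = "cg_conformation"
  )
}

normalize_states <- function(states) {
  if (is.character(states)) {
    if (length(states) == 1L && nchar(states) > 1L) {
      states <- strsplit(states, "")[[1]]
    }
    states <- as.integer(states == "h")
  }
  as.integer(as.logical(as.integer(states)))
}

#' @export
print.cg_conformation <- function(x, ...) {
  cat(sprintf(
    "<cg_conformation> %d residues, %d helical, %d charge sites\n",
    length(x$states), sum(x$states), nrow(x$charge_sites)
  ))
  invisible(x)
}

#' Model energy of a conformation
#'
#' Total energy in kJ/mol: helix-coil term
#' `-kB*t_ref*(sum log w + runs * log v)`, screened electrostguatic repulsion
#' between charge pseudo-atoms, and the optional DNA-rod term. Overlapping
#' charge sites (r < 0.01 nm) return a hard-core rejection value (1e10).
#'
#' @param conf A `cg_conformation` (from [build_coordinates()]).
#' @param params A [model_params()] object for the same sequence.
#' @param rod Optional [make_dna_rod()] object (its field is applied only
#'   when supplied).
#'
#' @return One-row tibble with columns `e_hc`, `e_elec`, `e_dna`, `e_total`
#'   (kJ/mol).
#' @export
cg_energy <- function(conf, params, rod = NULL) {
  stopifnot(inherits(conf, "cg_conformation"), inherits(params, "hc_params"))
  if (length(conf$states) != length(params$sequence)) {
    stop("conformation and parameters disagree on residue count",
      call. = FALSE
    )
  }
  e <- .cpp_energy(
    mspec_of(params), rodspec_of(rod), conf$states,
    conf$coil_theta, conf$coil_tau, conf$shift
  )
  tibble::tibble(
    e_hc = e$hc, e_elec = e$elec, e_dna = e$dna, e_total = e$total
  )
}

# ---------------------------------------------------------------------------

#' Metropolis Monte Carlo sampling of the helix-coil model
#'
#' Samples the model at `params$temperature` with single-residue helix/coil
#' flips, coil-dihedral perturbations and (when a DNA rod is present)
#' rigid-body translations. Supports an active or frozen metadynamics bias,
#' a frozen or active well-tempered-ensemble bias on the potential energy,
#' and a harmonic umbrella restraint on any collective variable.
#'
#' @param params A [model_params()] object.
#' @param n_sweeps Number of MC sweeps (one sweep attempts one move per
#'   residue).
#' @param seed Integer seed (recorded in the result).
#' @param init Optional `cg_conformation` to start from (default: all-coil).
#' @param record_stride Record one frame every this many sweeps.
#' @param moves Named numeric vector of move probabilities
#'   (`flip`, `dihedral`, `rigid`); normalized internally.
#' @param rod Optional [make_dna_rod()].
#' @param bias Optional [meta_bias()] acting on conformational CVs.
#' @param wte_bias Optional [meta_bias()] on the potential energy (the
#'   well-tempered-ensemble bias), typically frozen during production.
#' @param umbrella Optional list `list(cv = "rdist", center =, k =)` adding
#'   `0.5 k (s - center)^2`.
#' @param record_states Record the helix/coil state vector per frame
#'   (as a bitmask; residue i helical contributes 2^(i-1)).
#' @param time_offset Offset added to the sweep counter (used when chaining
#'   runs, e.g. between replica-exchange attempts).
#'
#' @return A `cg_trajectory`: tibble of frames (sweep, energy terms, CVs,
#'   bias values) with attributes `params`, `seed`, `acceptance`, `final`
#'   (restart state), `bias`, `wte_bias` (updated bias objects), `rod`.
#' @export
#' @examples
#' p <- model_params("KAAAAK", neutralized = TRUE)
#' tr <- mc_sample(p, n_sweeps = 200, seed = 1)
#' mean(tr$n_h)
mc_sample <- function(params, n_sweeps, seed = NULL, init = NULL,
                      record_stride = 10,
                      moves = c(flip = 0.5, dihedral = 0.5, rigid = 0),
                      rod = NULL, bias = NULL, wte_bias = NULL,
                      umbrella = NULL, record_states = FALSE,
                      time_offset = 0) {
  stopifnot(inherits(params, "hc_params"), n_sweeps >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(params$sequence)
  if (is.null(init)) init <- build_coordinates(rep(0L, n), params)
  mv <- c(flip = 0, dihedral = 0, rigid = 0)
  mv[names(moves)] <- moves
  if (is.null(rod)) mv["rigid"] <- 0
  mv <- mv / sum(mv)
  umb <- if (is.null(umbrella)) {
    NULL
  } else {
    list(
      cv_id = CV_IDS[[umbrella$cv %||% "rdist"]],
      center = umbrella$center, k = umbrella$k
    )
  }
  res <- .cpp_cg_run(
    mspec_of(params), rodspec_of(rod), init$states, init$coil_theta,
    init$coil_tau, init$shift, params$temperature, as.integer(n_sweeps),
    as.integer(record_stride), unname(mv[c("flip", "dihedral", "rigid")]),
    bias_cpp_spec(wte_bias), bias_cpp_spec(bias), umb,
    record_states, time_offset
  )
  frames <- tibble::as_tibble(res$frames)
  if (record_states) frames$state_code <- res$state_codes
  final <- build_like(init, res)
  structure(
    frames,
    class = c("cg_trajectory", class(frames)),
    params = params, seed = seed, acceptance = res$acceptance,
    final = final, rod = rod,
    bias = update_bias_kernels(bias, res$kernelsB),
    wte_bias = update_bias_kernels(wte_bias, res$kernelsA)
  )
}

build_like <- function(init, res) {
  structure(
    list(
      states = as.integer(res$states),
      ca = NULL, charge_sites = NULL, charge_residues = init$charge_residues,
      coil_theta = as.numeric(res$coil_theta),
      coil_tau = as.numeric(res$coil_tau),
      shift = as.numeric(res$shift)
    ),
    class = "cg_conformation"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d frames, acceptance %.2f, seed %s\n",
    nrow(x), attr(x, "acceptance"),
    format(attr(x, "seed") %||% NA)
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------

#' Exact per-residue helicity by transfer matrix
#'
#' Computes the exact equilibrium probability that each residue is helical
#' under the pure helix-coil part of the Hamiltonian (statistical weight
#' `prod(w_i over h) * v^runs`), by a forward-backward pass over the
#' two-state transfer matrix. This is the independent oracle for the MC
#' sampler and is only valid when the configurational energy does not couple
#' residues beyond nearest-neighbour run bookkeeping, i.e. with all charges
#' off and no DNA field.
#'
#' @param params A [model_params()] whose effective charges are all zero
#'   (neutralized, or a sequence without charged residues). Charged
#'   parameters are refused.
#' @return Tibble with columns `residue`, `p_helix`.
#' @export
#' @examples
#' transfer_matrix_helicity(model_params("AAAA", neutralized = TRUE))
transfer_matrix_helicity <- function(params) {
  fb <- tm_forward_backward(params)
  L <- length(params$sequence)
  p <- vapply(seq_len(L), function(i) {
    fb$f[i, 2] * fb$b[i, 2] / fb$Z
  }, numeric(1))
  tibble::tibble(residue = params$residue_index, p_helix = p)
}

#' Exact expected count of fully helical six-residue windows
#'
#' The geometric helicity CV of this model is, to high accuracy, the number
#' of six-residue windows whose residues are all helical (such windows sit on
#' ideal helix geometry and contribute 1; all other windows contribute
#' essentially 0 under the tight switching function). This function computes
#' its exact equilibrium expectation by transfer matrix, and is the oracle
#' used to calibrate and test subtype helicity orderings.
#'
#' @inheritParams transfer_matrix_helicity
#' @param normalized If `TRUE`, divide by the number of windows (L - 5).
#' @return A single number.
#' @export
transfer_matrix_salpha <- function(params, normalized = FALSE) {
  fb <- tm_forward_backward(params)
  L <- length(params$sequence)
  if (L < 6) stop("need at least 6 residues", call. = FALSE)
  wi <- params$w
  v <- params$v
  tot <- 0
  for (i in 1:(L - 5)) {
    pref <- if (i == 1) {
      wi[1] * v * prod(wi[2:6])
    } else {
      (fb$f[i - 1, 1] * v + fb$f[i - 1, 2]) * prod(wi[i:(i + 5)])
    }
    tot <- tot + pref * fb$b6[i + 5] / fb$Z
  }
  if (normalized) tot / (L - 5) else tot
}

tm_forward_backward <- function(params) {
  stopifnot(inherits(params, "hc_params"))
  if (any(params$charge != 0)) {
    stop(
      "transfer-matrix oracle is only valid with charges off ",
      "(use neutralized = TRUE or an uncharged sequence)",
      call. = FALSE
    )
  }
  wi <- params$w
  v <- params$v
  L <- length(wi)
  f <- matrix(0, L, 2) # column 1: coil, column 2: helix
  f[1, ] <- c(1, wi[1] * v)
  if (L > 1) {
    for (i in 2:L) {
      f[i, 1] <- f[i - 1, 1] + f[i - 1, 2]
      f[i, 2] <- wi[i] * (v * f[i - 1, 1] + f[i - 1, 2])
    }
  }
  b <- matrix(0, L, 2)
  b[L, ] <- c(1, 1)
  if (L > 1) {
    for (i in (L - 1):1) {
      b[i, 1] <- b[i + 1, 1] + wi[i + 1] * v * b[i + 1, 2]
      b[i, 2] <- b[i + 1, 1] + wi[i + 1] * b[i + 1, 2]
    }
  }
  list(f = f, b = b, b6 = b[, 2], Z = f[L, 1] + f[L, 2])
}

#' Exact Boltzmann state probabilities for small chains
#'
#' Enumerates all `2^L` helix/coil state vectors of a chain with frozen coil
#' geometry and returns their exact Boltzmann probabilities at the model
#' temperature, including the electrostatic and DNA terms evaluated on the
#' frozen geometry. Feasible for L up to ~16; used as the ground truth in
#' detailed-balance and reweighting tests.
#'
#' @param params A [model_params()] object.
#' @param coil_theta,coil_tau Frozen coil angles (radians).
#' @param rod Optional [make_dna_rod()].
#' @return Tibble with `state_code` (bitmask), `energy`, `prob`.
#' @export
enumerate_states <- function(params, coil_theta, coil_tau, rod = NULL) {
  L <- length(params$sequence)
  if (L > 16) stop("enumeration is limited to L <= 16", call. = FALSE)
  codes <- 0:(2^L - 1)
  en <- vapply(codes, function(code) {
    states <- as.integer(bitwAnd(bitwShiftR(code, 0:(L - 1)), 1L))
    e <- .cpp_energy(
      mspec_of(params), rodspec_of(rod), states, coil_theta, coil_tau,
      c(0, 0, 0)
    )
    e$total
  }, numeric(1))
  beta <- 1 / (KB * params$temperature)
  wts <- exp(-beta * (en - min(en)))
  tibble::tibble(state_code = codes, energy = en, prob = wts / sum(wts))
}
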