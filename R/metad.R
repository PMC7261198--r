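#' Create an empty metadynamics bias
#'
#' The bias is a sum of Gaussians deposited along one or two collective
#' variables. With a finite bias factor `gamma` the deposit height decays as
#' `W * exp(-V(s,t) / (kB * dT))` with `dT = (gamma - 1) * T` (well-tempered
#' metadynamics); `gamma = Inf` reproduces fixed-height deposition.
#'
#' @param cv_names Character vector (length 1 or 2) naming the CVs, from
#'   `"s_alpha"`, `"s_rg"`, `"s_cont"`, `"rdist"`, `"energy"`, `"n_h"`,
#'   `"x"` (toy systems use `"x"`).
#' @param sigma Gaussian width per CV (CV units).
#' @param height Base deposit height W in kJ/mol.
#' @param gamma Bias factor (> 1, or `Inf` for non-well-tempered).
#' @param stride Deposition interval in sweeps.
#' @param frozen If `TRUE` the bias is evaluated but no longer grown.
#'
#' @return Object of class `meta_bias`.
#' @export
#' @examples
#' b <- meta_bias("x", sigma = 0.1, height = 1, gamma = 10)
meta_bias <- function(cv_names, sigma, height = 1.0, gamma = Inf,
                      stride = 500L, frozen = FALSE) {
  stopifnot(
    length(cv_names) %in% 1:2, all(sigma > 0),
    length(sigma) == length(cv_names), height >= 0, gamma > 1
  )
  kernels <- tibble::tibble(
    time = numeric(), center1 = numeric(), center2 = numeric(),
    sigma1 = numeric(), sigma2 = numeric(), height = numeric()
  )
  structure(
    list(
      cv_names = cv_names, sigma = sigma, height = height, gamma = gamma,
      stride = as.integer(stride), frozen = frozen, kernels = kernels
    ),
    class = "meta_bias"
  )
}

#' @export
print.meta_bias <- function(x, ...) {
  cat(sprintf(
    "<meta_bias> on (%s): %d kernels, W = %g kJ/mol, sigma = (%s), gamma = %s%s\n",
    paste(x$cv_names, collapse = ", "), nrow(x$kernels), x$height,
    paste(signif(x$sigma, 3), collapse = ", "), format(x$gamma),
    if (x$frozen) " [frozen]" else ""
  ))
  invisible(x)
}

n_kernels <- function(bias) nrow(bias$kernels)

bias_cpp_spec <- function(bias) {
  if (is.null(bias)) {
    return(NULL)
  }
  stopifnot(inherits(bias, "meta_bias"))
  toy <- bias$cv_names == "x"
  ids <- ifelse(toy, 1L, CV_IDS[bias$cv_names])
  k <- as.matrix(bias$kernels[, c("time", "center1", "center2", "height")])
  list(
    cv_ids = as.integer(ids), sigma = bias$sigma, height = bias$height,
    gamma = bias$gamma, stride = bias$stride, frozen = bias$frozen,
    kernels = k
  )
}

update_bias_kernels <- function(bias, kmat) {
  if (is.null(bias)) {
    return(NULL)
  }
  d <- length(bias$cv_names)
  bias$kernels <- tibble::tibble(
    time = kmat[, 1], center1 = kmat[, 2], center2 = kmat[, 3],
    sigma1 = bias$sigma[1],
    sigma2 = if (d == 2) bias$sigma[2] else 0,
    height = kmat[, 4]
  )
  bias
}

#' Evaluate a metadynamics bias
#'
#' Sums all kernels deposited at or before time `t` (two-dimensional kernels
#' are products of per-CV Gaussians).
#'
#' @param bias A [meta_bias()].
#' @param s Numeric vector (one CV point) or a matrix/data frame of points,
#'   one column per CV.
#' @param t Evaluate the bias as of this time (default `Inf`: all kernels).
#' @return Bias value(s) in kJ/mol.
#' @export
evaluate_bias <- function(bias, s, t = Inf) {
  stopifnot(inherits(bias, "meta_bias"))
  d <- length(bias$cv_names)
  pts <- if (is.null(dim(s))) {
    if (d == 1) {
      matrix(s, ncol = 1)
    } else {
      if (length(s) != d) {
        stop(sprintf(
          "CV dimension mismatch: bias is on %d CV(s) (%s), point has %d",
          d, paste(bias$cv_names, collapse = ", "), length(s)
        ), call. = FALSE)
      }
      matrix(s, nrow = 1)
    }
  } else {
    as.matrix(s)
  }
  if (ncol(pts) != d) {
    stop(sprintf(
      "CV dimension mismatch: bias is on %d CV(s) (%s), points have %d",
      d, paste(bias$cv_names, collapse = ", "), ncol(pts)
    ), call. = FALSE)
  }
  k <- bias$kernels[bias$kernels$time <= t, , drop = FALSE]
  if (nrow(k) == 0) {
    return(rep(0, nrow(pts)))
  }
  .cpp_bias_grid(
    as.matrix(k[, c("time", "center1", "center2", "height")]),
    pts, bias$sigma, t
  )
}

#' Deposit one Gaussian kernel
#'
#' Appends a kernel at `s` with well-tempered height
#' `W * exp(-V(s, t) / (kB * (gamma - 1) * temperature))`; with
#' `gamma = Inf` the height is the fixed base height.
#'
#' @param bias A [meta_bias()] (must not be frozen).
#' @param s CV value(s) at the deposit point.
#' @param time Deposit time (sweeps).
#' @param temperature Replica temperature in K (used by the well-tempered
#'   decay).
#' @return The updated [meta_bias()].
#' @export
deposit <- function(bias, s, time, temperature = 300) {
  stopifnot(inherits(bias, "meta_bias"))
  if (bias$frozen) stop("cannot deposit into a frozen bias", call. = FALSE)
  d <- length(bias$cv_names)
  stopifnot(length(s) == d)
  h <- bias$height
  if (is.finite(bias$gamma)) {
    dT <- (bias$gamma - 1) * temperature
    h <- bias$height * exp(-evaluate_bias(bias, s, time) / (KB * dT))
  }
  bias$kernels <- dplyr::bind_rows(
    bias$kernels,
    tibble::tibble(
      time = time, center1 = s[1], center2 = if (d == 2) s[2] else 0,
      sigma1 = bias$sigma[1], sigma2 = if (d == 2) bias$sigma[2] else 0,
      height = h
    )
  )
  bias
}

#' Freeze a bias (stop deposition, keep evaluation)
#' @param bias A [meta_bias()].
#' @return The frozen bias.
#' @export
freeze_bias <- function(bias) {
  bias$frozen <- TRUE
  bias
}

# ---------------------------------------------------------------------------

#' Geometric temperature ladder
#'
#' `T_i = T_min * (T_max / T_min)^((i - 1) / (N - 1))`, the standard
#' geometric distribution of replica temperatures.
#'
#' @param t_min,t_max Temperature range in K (`t_max > t_min > 0`).
#' @param n Number of replicas (>= 2).
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
#' @examples
#' temperature_ladder(298, 400, 8)
temperature_ladder <- function(t_min, t_max, n) {
  if (n < 2) stop("a ladder needs at least 2 replicas", call. = FALSE)
  stopifnot(t_min > 0, t_max > t_min)
  t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
}

#' Replica-exchange acceptance probability
#'
#' The bias-aware Metropolis acceptance for swapping configurations between
#' replicas i and j:
#' `P = min(1, exp((bi - bj)(Ui - Uj) + bi (Vi(Si) - Vi(Sj)) + bj (Vj(Sj) - Vj(Si))))`
#' with `b = 1 / (kB T)`. With all bias terms zero this reduces to the
#' standard temperature-replica-exchange factor.
#'
#' @param u_i,u_j Potential energies (kJ/mol) of the configurations at
#'   replicas i and j.
#' @param t_i,t_j Replica temperatures (K).
#' @param vi_si,vi_sj Bias of replica i evaluated at its own and at
#'   replica j's CV value (kJ/mol).
#' @param vj_sj,vj_si Bias of replica j evaluated at its own and at
#'   replica i's CV value (kJ/mol).
#' @return Acceptance probability in [0, 1].
#' @export
#' @examples
#' exchange_probability(u_i = -10, u_j = -5, t_i = 300, t_j = 320)
exchange_probability <- function(u_i, u_j, t_i, t_j, vi_si = 0, vi_sj = 0,
                                 vj_sj = 0, vj_si = 0) {
  bi <- 1 / (KB * t_i)
  bj <- 1 / (KB * t_j)
  arg <- (bi - bj) * (u_i - u_j) + bi * (vi_si - vi_sj) + bj * (vj_sj - vj_si)
  min(1, exp(arg))
}

# ---------------------------------------------------------------------------
# systems: a CG peptide or a 1D toy particle in an analytic potential

#' Define a coarse-grained peptide system
#'
#' Bundles model parameters, an optional DNA rod and an optional initial
#' conformation into the system object consumed by the replica and umbrella
#' drivers.
#'
#' @param params A [model_params()].
#' @param rod Optional [make_dna_rod()].
#' @param init Optional initial `cg_conformation`.
#' @param moves Move-probability vector as in [mc_sample()].
#' @return Object of class `cg_system`.
#' @export
cg_system <- function(params, rod = NULL, init = NULL,
                      moves = c(flip = 0.5, dihedral = 0.5, rigid = 0)) {
  stopifnot(inherits(params, "hc_params"))
  structure(list(
    kind = "cg", params = params, rod = rod, init = init,
    moves = moves
  ), class = "cg_system")
}

#' Define a one-dimensional toy system
#'
#' A single particle in an analytic potential, used to validate the bias
#' engines against exact results. `"double_well"` is
#' `U(x) = barrier * (x^2 - 1)^2` (minima at x = +-1);
#' `"harmonic"` is `U(x) = 0.5 * k * x^2`.
#'
#' @param potential `"double_well"` or `"harmonic"`.
#' @param barrier Barrier height (kJ/mol) of the double well.
#' @param k Spring constant (kJ/mol) of the harmonic well.
#' @param x0 Initial position.
#' @param step_sd Proposal standard deviation.
#' @return Object of class `toy_system`.
#' @export
toy_system <- function(potential = c("double_well", "harmonic"),
                       barrier = 10, k = 1, x0 = -1, step_sd = 0.25) {
  potential <- match.arg(potential)
  structure(
    list(
      kind = "toy", potential = potential,
      pot_id = if (potential == "double_well") 1L else 2L,
      pot_params = if (potential == "double_well") barrier else k,
      x0 = x0, step_sd = step_sd
    ),
    class = "toy_system"
  )
}

#' Analytic potential of a toy system
#' @param system A [toy_system()].
#' @param x Positions.
#' @return Potential energy values (kJ/mol).
#' @export
toy_potential <- function(system, x) {
  if (system$potential == "double_well") {
    system$pot_params[1] * (x^2 - 1)^2
  } else {
    0.5 * system$pot_params[1] * x^2
  }
}

# one propagation chunk; state is system-specific
propagate_chunk <- function(system, state, temperature, n_sweeps,
                            record_stride, biasA = NULL, biasB = NULL,
                            umbrella = NULL, time_offset = 0) {
  if (system$kind == "cg") {
    p <- system$params
    p$temperature <- temperature
    umb <- if (is.null(umbrella)) {
      NULL
    } else {
      list(
        cv_id = CV_IDS[[umbrella$cv %||% "rdist"]],
        center = umbrella$center, k = umbrella$k
      )
    }
    mv <- c(flip = 0, dihedral = 0, rigid = 0)
    mv[names(system$moves)] <- system$moves
    if (is.null(system$rod)) mv["rigid"] <- 0
    mv <- mv / sum(mv)
    res <- .cpp_cg_run(
      mspec_of(p), rodspec_of(system$rod), state$states, state$coil_theta,
      state$coil_tau, state$shift, temperature, as.integer(n_sweeps),
      as.integer(record_stride), unname(mv[c("flip", "dihedral", "rigid")]),
      bias_cpp_spec(biasA), bias_cpp_spec(biasB), umb, FALSE, time_offset
    )
    newstate <- build_like(state, res)
    list(
      frames = tibble::as_tibble(res$frames), state = newstate,
      energy = res$energy, acceptance = res$acceptance,
      biasA = update_bias_kernels(biasA, res$kernelsA),
      biasB = update_bias_kernels(biasB, res$kernelsB)
    )
  } else {
    umb <- if (is.null(umbrella)) {
      NULL
    } else {
      list(center = umbrella$center, k = umbrella$k)
    }
    res <- .cpp_toy_run(
      system$pot_id, system$pot_params, state$x, system$step_sd, temperature,
      as.integer(n_sweeps), as.integer(record_stride), bias_cpp_spec(biasA),
      bias_cpp_spec(biasB), umb, time_offset
    )
    list(
      frames = tibble::as_tibble(res$frames), state = list(x = res$x),
      energy = res$energy, acceptance = res$acceptance,
      biasA = update_bias_kernels(biasA, res$kernelsA),
      biasB = update_bias_kernels(biasB, res$kernelsB)
    )
  }
}

init_state <- function(system, seed_draw = TRUE) {
  if (system$kind == "cg") {
    n <- length(system$params$sequence)
    init <- system$init %||% build_coordinates(rep(0L, n), system$params)
    list(
      states = init$states, coil_theta = init$coil_theta,
      coil_tau = init$coil_tau, shift = init$shift
    )
  } else {
    list(x = system$x0)
  }
}

# CV values of the current state, for exchange bookkeeping
state_cvs <- function(system, state, cv_names, energy) {
  if (length(cv_names) == 0) {
    return(numeric(0))
  }
  if (system$kind == "toy") {
    vapply(cv_names, function(nm) {
      if (nm == "energy") energy else state$x
    }, numeric(1))
  } else {
    conf <- build_coordinates(
      state$states,
      params = system$params,
      coil_theta = state$coil_theta, coil_tau = state$coil_tau
    )
    conf$ca <- conf$ca + matrix(state$shift, nrow(conf$ca), 3, byrow = TRUE)
    if (nrow(conf$charge_sites) > 0) {
      conf$charge_sites <- conf$charge_sites +
        matrix(state$shift, nrow(conf$charge_sites), 3, byrow = TRUE)
    }
    vapply(cv_names, function(nm) {
      switch(nm,
        s_alpha = s_alpha(conf),
        s_rg = s_rg(conf),
        s_cont = s_cont(conf, system$rod,
          charges = system$params$charge[conf$charge_residues]
        ),
        rdist = radial_distance(conf, system$rod),
        energy = energy,
        n_h = sum(state$states)
      )
    }, numeric(1))
  }
}

# ---------------------------------------------------------------------------

#' Temperature replica-exchange driver
#'
#' Alternates chunks of Metropolis propagation with exchange attempts
#' between adjacent temperatures (even/odd pair alternation per attempt
#' cycle). Optionally carries per-replica metadynamics biases, in which case
#' exchanges use the bias-aware acceptance of [exchange_probability()].
#' Configuration swaps are bookkept as swaps of the configurations between
#' temperature slots; biases stay with their temperature.
#'
#' @param system A [cg_system()] or [toy_system()].
#' @param temperatures Temperature ladder (see [temperature_ladder()]).
#' @param n_sweeps Total sweeps per replica.
#' @param exchange_stride Sweeps between exchange-attempt cycles.
#' @param seed Integer seed.
#' @param record_stride Frame recording stride.
#' @param biases Optional list of per-replica [meta_bias()] objects
#'   (evolved independently).
#' @param wte_biases Optional list of per-replica frozen WTE biases folded
#'   into the effective potential energy.
#' @param umbrella Optional umbrella restraint (applied at all replicas).
#'
#' @return Object of class `remd_run`: list with `trajectories` (one tibble
#'   per temperature), `exchange_log` (tibble: attempt, pair, i, j,
#'   probability, accepted), `acceptance_by_pair`, `temperatures`, `biases`,
#'   `wte_biases`, `seed`.
#' @export
run_tremd <- function(system, temperatures, n_sweeps, exchange_stride = 100,
                      seed = NULL, record_stride = 10, biases = NULL,
                      wte_biases = NULL, umbrella = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_rep <- length(temperatures)
  stopifnot(n_rep >= 2, n_sweeps >= exchange_stride)
  states <- replicate(n_rep, init_state(system), simplify = FALSE)
  energies <- rep(NA_real_, n_rep)
  trajs <- replicate(n_rep, list(), simplify = FALSE)
  n_chunks <- floor(n_sweeps / exchange_stride)
  log_rows <- list()
  attempt <- 0L
  for (chunk in seq_len(n_chunks)) {
    for (r in seq_len(n_rep)) {
      out <- propagate_chunk(
        system, states[[r]], temperatures[r], exchange_stride, record_stride,
        biasA = wte_biases[[r]], biasB = biases[[r]], umbrella = umbrella,
        time_offset = (chunk - 1) * exchange_stride
      )
      states[[r]] <- out$state
      energies[r] <- out$energy
      trajs[[r]][[chunk]] <- out$frames
      if (!is.null(biases)) biases[[r]] <- out$biasB
      if (!is.null(wte_biases)) wte_biases[[r]] <- out$biasA
    }
    attempt <- attempt + 1L
    first <- if (attempt %% 2 == 1) 1L else 2L
    pairs <- if (first <= n_rep - 1) seq(first, n_rep - 1, by = 2) else integer(0)
    for (i in pairs) {
      j <- i + 1L
      pr <- replica_swap_probability(
        system, states, energies, temperatures, biases, wte_biases, i, j
      )
      acc <- stats::runif(1) < pr
      if (acc) {
        tmp <- states[[i]]
        states[[i]] <- states[[j]]
        states[[j]] <- tmp
        te <- energies[i]
        energies[i] <- energies[j]
        energies[j] <- te
      }
      log_rows[[length(log_rows) + 1]] <- tibble::tibble(
        attempt = attempt, i = i, j = j, probability = pr, accepted = acc
      )
    }
  }
  exchange_log <- dplyr::bind_rows(log_rows)
  acc_pair <- exchange_log |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(
      attempts = dplyr::n(), rate = mean(.data$accepted), .groups = "drop"
    )
  structure(
    list(
      trajectories = lapply(trajs, dplyr::bind_rows),
      exchange_log = exchange_log, acceptance_by_pair = acc_pair,
      temperatures = temperatures, biases = biases, wte_biases = wte_biases,
      states = states, seed = seed
    ),
    class = "remd_run"
  )
}

# general bias-aware swap probability; reduces to exchange_probability()
# when no biases are present
replica_swap_probability <- function(system, states, energies, temperatures,
                                     biases, wte_biases, i, j) {
  u_i <- energies[i]
  u_j <- energies[j]
  # frozen WTE bias (a function of U) folds into the effective potential
  eff <- function(r, u) {
    if (is.null(wte_biases) || is.null(wte_biases[[r]])) {
      u
    } else {
      u + evaluate_bias(wte_biases[[r]], u)
    }
  }
  bi <- 1 / (KB * temperatures[i])
  bj <- 1 / (KB * temperatures[j])
  arg <- bi * (eff(i, u_i) - eff(i, u_j)) + bj * (eff(j, u_j) - eff(j, u_i))
  if (!is.null(biases) && !is.null(biases[[i]])) {
    cvn <- biases[[i]]$cv_names
    s_i <- state_cvs(system, states[[i]], cvn, u_i)
    s_j <- state_cvs(system, states[[j]], cvn, u_j)
    arg <- arg + bi * (evaluate_bias(biases[[i]], s_i) -
      evaluate_bias(biases[[i]], s_j))
    cvn_j <- biases[[j]]$cv_names
    s_i2 <- state_cvs(system, states[[i]], cvn_j, u_i)
    s_j2 <- state_cvs(system, states[[j]], cvn_j, u_j)
    arg <- arg + bj * (evaluate_bias(biases[[j]], s_j2) -
      evaluate_bias(biases[[j]], s_i2))
  }
  min(1, exp(arg))
}

#' Parallel-tempered metadynamics in the well-tempered ensemble
#'
#' Two-stage protocol. Stage 1 (WTE): each replica runs well-tempered
#' metadynamics on its potential energy (height 2.5 kJ/mol, bias factor 50,
#' deposition every 250 sweeps by default), which broadens the energy
#' fluctuations and thus the overlap between adjacent replicas. Stage 2
#' (production): the WTE bias is frozen and each replica grows an
#' independent well-tempered bias on the conformational CVs (default
#' `s_alpha`, `s_rg`); exchanges account for both biases.
#'
#' @inheritParams run_tremd
#' @param wte List of WTE-stage settings: `height`, `sigma` (kJ/mol; default
#'   is estimated from a short unbiased run when `NULL`), `gamma`, `stride`.
#' @param production List of production settings: `cvs`, `height`, `sigma`,
#'   `gamma`, `stride`.
#' @param n_sweeps_wte Sweeps per replica of the WTE stage.
#' @param n_sweeps Sweeps per replica of the production stage.
#'
#' @return Object of class `ptmetad_run`: list with `wte` (the stage-1
#'   `remd_run`), `production` (the stage-2 `remd_run`), `wte_biases`
#'   (frozen), `biases` (production), `temperatures`, `seed`.
#' @export
run_ptmetad_wte <- function(system, temperatures,
                            wte = list(
                              height = 2.5, sigma = NULL, gamma = 50,
                              stride = 250
                            ),
                            production = list(
                              cvs = c("s_alpha", "s_rg"), height = 1.0,
                              sigma = c(0.1, 0.1), gamma = 10, stride = 500
                            ),
                            n_sweeps_wte, n_sweeps, exchange_stride = 100,
                            seed = NULL, record_stride = 10) {
  if (!is.null(seed)) set.seed(seed)
  n_rep <- length(temperatures)
  if (is.null(wte$sigma)) {
    # calibrate the kernel width to the unbiased energy fluctuations
    pilot <- propagate_chunk(
      system, init_state(system), temperatures[1],
      n_sweeps = max(200, exchange_stride), record_stride = 1
    )
    wte$sigma <- max(stats::sd(pilot$frames$e_total), 1e-3)
  }
  wte_biases <- replicate(
    n_rep,
    meta_bias("energy",
      sigma = wte$sigma, height = wte$height,
      gamma = wte$gamma, stride = wte$stride %||% 250L
    ),
    simplify = FALSE
  )
  stage1 <- run_tremd(
    system, temperatures, n_sweeps_wte, exchange_stride,
    seed = NULL, record_stride = record_stride, biases = wte_biases
  )
  frozen <- lapply(stage1$biases, freeze_bias)
  prod_biases <- replicate(
    n_rep,
    meta_bias(production$cvs,
      sigma = production$sigma, height = production$height,
      gamma = production$gamma, stride = production$stride %||% 500L
    ),
    simplify = FALSE
  )
  stage2 <- run_tremd(
    system, temperatures, n_sweeps, exchange_stride,
    seed = NULL, record_stride = record_stride, biases = prod_biases,
    wte_biases = frozen
  )
  structure(
    list(
      wte = stage1, production = stage2, wte_biases = frozen,
      biases = stage2$biases, temperatures = temperatures, seed = seed
    ),
    class = "ptmetad_run"
  )
}

# ---------------------------------------------------------------------------

#' Umbrella-sampling driver
#'
#' Runs one restrained simulation per window center, adding
#' `0.5 k (s - s0)^2` to the model energy, discarding an initial
#' equilibration fraction, and seeding each window from the final state of
#' the previous one (stepwise dragging along the reaction coordinate).
#'
#' @param system A [cg_system()] (with a rod, for `cv = "rdist"`) or
#'   [toy_system()] (`cv = "x"`).
#' @param centers Sorted window centers (nm, or CV units).
#' @param k Restraint force constant (kJ/mol per CV unit squared;
#'   default 750).
#' @param n_sweeps Sweeps per window.
#' @param discard Fraction of each window discarded as equilibration
#'   (default 0.25).
#' @param seed Integer seed.
#' @param cv Restrained collective variable (default `"rdist"`).
#' @param temperature Temperature in K.
#' @param record_stride Frame recording stride.
#' @param window_init `"chain"` (each window starts from the previous
#'   window's final state, the stepwise-dragging protocol) or `"center"`
#'   (each window starts fresh at its own center, which avoids hysteresis
#'   when the bound state is sticky).
#'
#' @return List of `umbrella_window` objects: each holds `center`, `k`,
#'   `cv`, `series` (retained CV samples), `n_total`, `n_discarded`,
#'   `temperature`.
#' @export
run_umbrella <- function(system, centers, k = 750, n_sweeps = 2000,
                         discard = 0.25, seed = NULL, cv = "rdist",
                         temperature = 300, record_stride = 1,
                         window_init = c("chain", "center")) {
  if (!is.null(seed)) set.seed(seed)
  window_init <- match.arg(window_init)
  stopifnot(!is.unsorted(centers), k > 0, discard >= 0, discard < 1)
  state <- init_state(system)
  windows <- vector("list", length(centers))
  for (w in seq_along(centers)) {
    if (window_init == "center") {
      state <- init_state(system)
      if (system$kind == "cg" && cv == "rdist") {
        state$shift <- c(centers[w], 0, 0)
      } else if (system$kind == "toy") {
        state$x <- centers[w]
      }
    }
    out <- propagate_chunk(
      system, state, temperature, n_sweeps, record_stride,
      umbrella = list(cv = cv, center = centers[w], k = k)
    )
    state <- out$state
    cvcol <- if (system$kind == "toy") "x" else cv
    series <- out$frames[[cvcol]]
    n_disc <- floor(discard * length(series))
    retained <- series[(n_disc + 1):length(series)]
    if (length(retained) < 100) {
      warning(sprintf(
        "window %d (center %.3g) retains only %d samples",
        w, centers[w], length(retained)
      ), call. = FALSE)
    }
    windows[[w]] <- structure(
      list(
        center = centers[w], k = k, cv = cv, series = retained,
        n_total = length(series), n_discarded = n_disc,
        temperature = temperature
      ),
      class = "umbrella_window"
    )
  }
  windows
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "<umbrella_window> center %.3g, k = %g, %d samples (mean %.3g)\n",
    x$center, x$k, length(x$series), mean(x$series)
  ))
  invisible(x)
}
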