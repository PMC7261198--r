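#' Free-energy estimate from a metadynamics bias
#'
#' Under the well-tempered convention the free energy along the biased CVs
#' is `F(s) = -(gamma / (gamma - 1)) * V(s, t)` (with `gamma = Inf`,
#' `F = -V`), shifted so its minimum is zero.
#'
#' @param bias A [meta_bias()].
#' @param grid Numeric vector (1D bias) or list of two numeric vectors
#'   (2D bias) of CV grid points.
#' @param t Use kernels deposited up to this time (default all).
#' @return Tibble with one column per CV and a column `f` (kJ/mol).
#' @export
free_energy_estimate <- function(bias, grid, t = Inf) {
  stopifnot(inherits(bias, "meta_bias"))
  d <- length(bias$cv_names)
  pts <- grid_points(grid, d, bias$cv_names)
  v <- evaluate_bias(bias, as.matrix(pts[, seq_len(d)]), t)
  fac <- if (is.finite(bias$gamma)) bias$gamma / (bias$gamma - 1) else 1
  f <- -fac * v
  pts$f <- f - min(f)
  pts
}

grid_points <- function(grid, d, cv_names) {
  if (d == 1) {
    if (is.list(grid)) grid <- grid[[1]]
    out <- tibble::tibble(s = as.numeric(grid))
    names(out) <- cv_names[1]
  } else {
    stopifnot(is.list(grid), length(grid) == 2)
    eg <- expand.grid(s1 = grid[[1]], s2 = grid[[2]], KEEP.OUT.ATTRS = FALSE)
    out <- tibble::as_tibble(eg)
    names(out) <- cv_names
  }
  out
}

# trapezoid quadrature weights of a sorted grid vector
trap_weights <- function(x) {
  n <- length(x)
  if (n == 1) {
    return(1)
  }
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Time-dependent bias offset c(t)
#'
#' Computes `c(t) = (1/beta) * log( int exp(-beta F(s)) ds /
#' int exp(-beta (F(s) + V(s, t))) ds )` by trapezoidal quadrature on a
#' fixed CV grid, with `F(s)` taken from the bias at the same time via the
#' well-tempered relation (the standard realization of time-dependent
#' metadynamics reweighting). A zero bias gives c(t) = 0; a constant bias
#' kappa gives c(t) = kappa.
#'
#' @param bias A [meta_bias()].
#' @param times Times at which to evaluate c(t).
#' @param grid CV grid as in [free_energy_estimate()]; it must cover the
#'   sampled CV range.
#' @param temperature Temperature in K.
#' @return Tibble with columns `time` and `c`.
#' @export
c_of_t <- function(bias, times, grid, temperature = 300) {
  stopifnot(inherits(bias, "meta_bias"))
  d <- length(bias$cv_names)
  beta <- 1 / (KB * temperature)
  pts <- grid_points(grid, d, bias$cv_names)
  qw <- if (d == 1) {
    trap_weights(pts[[1]])
  } else {
    g1 <- sort(unique(pts[[1]]))
    g2 <- sort(unique(pts[[2]]))
    w1 <- trap_weights(g1)[match(pts[[1]], g1)]
    w2 <- trap_weights(g2)[match(pts[[2]], g2)]
    w1 * w2
  }
  fac <- if (is.finite(bias$gamma)) bias$gamma / (bias$gamma - 1) else 1
  cvals <- vapply(times, function(t) {
    v <- evaluate_bias(bias, as.matrix(pts[, seq_len(d)]), t)
    f <- -fac * v
    f <- f - min(f)
    lognum <- log_sum_exp(-beta * f, qw)
    logden <- log_sum_exp(-beta * (f + v), qw)
    (lognum - logden) / beta
  }, numeric(1))
  tibble::tibble(time = as.numeric(times), c = cvals)
}

log_sum_exp <- function(a, w) {
  m <- max(a)
  m + log(sum(w * exp(a - m)))
}

#' Tiwary-Parrinello frame weights
#'
#' Assigns each frame of a biased trajectory the unbiasing weight
#' `w(t) proportional to exp(beta * (V(s(t), t) - c(t)))`, normalized to sum
#' to one. The instantaneous bias `V(s(t), t)` is recomputed from the kernel
#' history; `c(t)` is computed by [c_of_t()] on a fixed grid and linearly
#' interpolated to the frame times.
#'
#' @param frames Trajectory tibble containing a time column (`sweep`) and
#'   the bias CV columns (e.g. `s_alpha`, `s_rg`, or `x`).
#' @param bias The [meta_bias()] that generated the trajectory.
#' @param temperature Temperature in K.
#' @param grid CV grid for [c_of_t()]; when `NULL`, an evenly spaced grid
#'   (201 points per CV) spanning the sampled range extended by 3 sigma.
#' @param n_c_times Number of time points at which c(t) is evaluated before
#'   interpolation (default 100).
#'
#' @return A `weighted_ensemble`: the frames tibble with columns `v_bias`,
#'   `c_t` and `weight` appended; attributes `c_series`, `temperature`,
#'   `bias`.
#' @export
frame_weights <- function(frames, bias, temperature = 300, grid = NULL,
                          n_c_times = 100) {
  stopifnot(inherits(bias, "meta_bias"))
  tcol <- if ("sweep" %in% names(frames)) "sweep" else "time"
  d <- length(bias$cv_names)
  cvcols <- vapply(bias$cv_names, function(nm) {
    if (nm %in% names(frames)) {
      nm
    } else if (nm == "x" && "x" %in% names(frames)) {
      "x"
    } else {
      stop("frames lack CV column '", nm, "'", call. = FALSE)
    }
  }, character(1))
  s <- as.matrix(frames[, cvcols, drop = FALSE])
  times <- frames[[tcol]]
  if (n_kernels(bias) == 0) {
    w <- rep(1 / nrow(frames), nrow(frames))
    out <- dplyr::mutate(frames, v_bias = 0, c_t = 0, weight = w)
    return(structure(out,
      class = c("weighted_ensemble", class(out)),
      c_series = tibble::tibble(time = range(times), c = c(0, 0)),
      temperature = temperature, bias = bias
    ))
  }
  if (is.null(grid)) {
    grid <- lapply(seq_len(d), function(i) {
      r <- range(s[, i])
      seq(r[1] - 3 * bias$sigma[i], r[2] + 3 * bias$sigma[i], length.out = 201)
    })
    if (d == 1) grid <- grid[[1]]
  }
  ct_times <- unique(stats::quantile(times, probs = seq(0, 1, length.out = n_c_times),
    names = FALSE, type = 1
  ))
  cs <- c_of_t(bias, ct_times, grid, temperature)
  c_t <- stats::approx(cs$time, cs$c, xout = times, rule = 2)$y
  v <- vapply(seq_len(nrow(frames)), function(i) {
    evaluate_bias(bias, s[i, ], t = times[i])
  }, numeric(1))
  beta <- 1 / (KB * temperature)
  a <- beta * (v - c_t)
  w <- exp(a - max(a)) # overflow guard; normalization removes the shift
  w <- w / sum(w)
  out <- dplyr::mutate(frames, v_bias = v, c_t = c_t, weight = w)
  structure(out,
    class = c("weighted_ensemble", class(out)),
    c_series = cs, temperature = temperature, bias = bias
  )
}

#' Weighted ensemble average
#'
#' `sum(w_i * O_i) / sum(w_i)`, the reweighted equilibrium average of a
#' per-frame observable.
#'
#' @param x A `weighted_ensemble` (from [frame_weights()]), or a numeric
#'   vector of weights.
#' @param observable Column name (for an ensemble) or numeric vector of
#'   per-frame values.
#' @return A single number.
#' @export
#' @examples
#' weighted_average(c(1, 1, 2), c(0, 3, 3))
weighted_average <- function(x, observable) {
  if (inherits(x, "weighted_ensemble")) {
    w <- x$weight
    o <- if (is.character(observable)) x[[observable]] else observable
  } else {
    w <- as.numeric(x)
    o <- observable
  }
  stopifnot(length(w) == length(o))
  if (all(w == 0)) stop("all weights are zero", call. = FALSE)
  sum(w * o) / sum(w)
}

#' Reweighted per-residue helicity
#'
#' Applies the weighted average residue-wise to the 0/1 helix indicator of
#' each frame (a residue counts as helical when it belongs to a run of at
#' least three helical residues, the alpha/3-10 convention of
#' [assign_secondary_structure()]).
#'
#' @param ens A `weighted_ensemble` whose frames carry a `state_code`
#'   column (run [mc_sample()] with `record_states = TRUE`), or any frames
#'   tibble plus explicit `weights`.
#' @param n_residues Number of residues (defaults to the trajectory
#'   parameters when available).
#' @param weights Optional explicit weights (default: the ensemble's).
#' @return Tibble with columns `residue`, `helicity`.
#' @export
reweighted_per_residue_helicity <- function(ens, n_residues = NULL,
                                            weights = NULL) {
  if (!"state_code" %in% names(ens)) {
    stop("frames lack recorded states; run mc_sample(record_states = TRUE)",
      call. = FALSE
    )
  }
  p <- attr(ens, "params")
  if (is.null(n_residues)) {
    if (is.null(p)) stop("supply n_residues", call. = FALSE)
    n_residues <- length(p$sequence)
  }
  w <- weights %||% ens[["weight"]]
  if (is.null(w)) w <- rep(1 / nrow(ens), nrow(ens))
  states <- decode_states(ens$state_code, n_residues)
  hel <- helix_indicator(states)
  res_idx <- if (!is.null(p)) p$residue_index else seq_len(n_residues)
  tibble::tibble(
    residue = res_idx,
    helicity = as.numeric(crossprod(hel, w) / sum(w))
  )
}

#' Decode recorded state bitmasks
#'
#' @param codes Numeric vector of state codes (residue i helical adds
#'   2^(i-1)).
#' @param n_residues Chain length.
#' @return frames x residues 0/1 matrix.
#' @export
decode_states <- function(codes, n_residues) {
  out <- matrix(0L, length(codes), n_residues)
  for (i in seq_len(n_residues)) {
    out[, i] <- as.integer(floor(codes / 2^(i - 1)) %% 2)
  }
  out
}

# 0/1 helix membership: helical residues in runs of length >= 3
helix_indicator <- function(states) {
  states <- as.matrix(states)
  t(apply(states, 1, function(s) {
    r <- rle(s)
    keep <- r$values == 1 & r$lengths >= 3
    rep(ifelse(keep, 1L, 0L), r$lengths)
  }))
}
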