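#' Potential of mean force by WHAM
#'
#' Combines umbrella-sampling windows into a potential of mean force with
#' the standard weighted-histogram self-consistent iteration: bin
#' probabilities `p_b = sum_k n_kb / sum_k N_k exp(-beta (w_kb - f_k))` and
#' window constants `exp(-beta f_k) = sum_b p_b exp(-beta w_kb)`, iterated
#' until the largest change in any `f_k` is below `tol`. The profile is
#' shifted so that the free energy at large distances is zero (the mean of
#' the outermost two bins).
#'
#' @param windows List of `umbrella_window` objects (see [run_umbrella()]).
#' @param bins Number of bins spanning the sampled range (default 50).
#' @param tol Convergence tolerance on the window constants (kJ/mol,
#'   default 1e-6).
#' @param max_iter Maximum iterations (default 1e5).
#' @param temperature Temperature in K (default: the windows' temperature).
#' @param window_weights Optional per-window multiplicative weights
#'   (used by the Bayesian bootstrap); default 1.
#'
#' @return Object of class `pmf_profile`: tibble (`center`, `f`) with
#'   attributes `temperature`, `iterations`, `converged`, `bins`.
#' @export
wham <- function(windows, bins = 50, tol = 1e-6, max_iter = 1e5,
                 temperature = NULL, window_weights = NULL) {
  stopifnot(length(windows) >= 2)
  temperature <- temperature %||% windows[[1]]$temperature %||% 300
  beta <- 1 / (KB * temperature)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ks <- vapply(windows, `[[`, numeric(1), "k")
  series <- lapply(windows, `[[`, "series")
  gw <- window_weights %||% rep(1, length(windows))

  rng <- range(unlist(series))
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  mid <- (brk[-1] + brk[-length(brk)]) / 2

  # overlap diagnostics: adjacent windows must share sampled bins
  occupied <- lapply(series, function(s) {
    unique(findInterval(s, brk, rightmost.closed = TRUE, all.inside = TRUE))
  })
  for (i in seq_len(length(windows) - 1)) {
    shared_bins <- intersect(occupied[[i]], occupied[[i + 1]])
    if (length(shared_bins) == 0) {
      stop(sprintf(
        "umbrella windows %d (center %.3g) and %d (center %.3g) do not overlap",
        i, centers[i], i + 1, centers[i + 1]
      ), call. = FALSE)
    }
    n_shared <- sum(findInterval(series[[i]], brk,
      rightmost.closed = TRUE, all.inside = TRUE
    ) %in% shared_bins)
    if (n_shared < 10) {
      warning(sprintf(
        "windows %d and %d share fewer than 10 samples", i, i + 1
      ), call. = FALSE)
    }
  }

  counts <- vapply(series, function(s) {
    tabulate(findInterval(s, brk, rightmost.closed = TRUE, all.inside = TRUE),
      nbins = bins
    )
  }, numeric(bins))
  counts <- sweep(counts, 2, gw, `*`) # bins x windows
  n_k <- colSums(counts)
  # bias of window k at bin b
  wkb <- vapply(seq_along(windows), function(k) {
    0.5 * ks[k] * (mid - centers[k])^2
  }, numeric(bins))
  expw <- exp(-beta * wkb)

  fk <- rep(0, length(windows))
  converged <- FALSE
  iter <- 0L
  num <- rowSums(counts)
  for (iter in seq_len(max_iter)) {
    den <- as.numeric(expw %*% (n_k * exp(beta * fk)))
    p <- ifelse(den > 0, num / den, 0)
    fk_new <- -log(as.numeric(crossprod(expw, p))) / beta
    fk_new <- fk_new - fk_new[1]
    delta <- max(abs(fk_new - fk))
    fk <- fk_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  f <- ifelse(p > 0, -log(p) / beta, NA_real_)
  sampled <- which(!is.na(f))
  outer2 <- utils::tail(sampled, 2)
  f <- f - mean(f[outer2])
  structure(
    tibble::tibble(center = mid, f = f),
    class = c("pmf_profile", class(tibble::tibble())),
    temperature = temperature, iterations = iter, converged = converged,
    bins = bins, breaks = brk
  )
}

#' Bayesian-bootstrap uncertainties for a WHAM profile
#'
#' Re-runs WHAM `n_boot` times with random unit-mean Dirichlet-style weights
#' assigned to complete windows (the trajectory is the resampling unit) and
#' returns the per-bin standard deviation of the profiles.
#'
#' @param windows List of `umbrella_window` objects.
#' @param n_boot Number of bootstrap replicates (at least 2; default 100).
#' @param seed Integer seed.
#' @param ... Passed on to [wham()] (`bins`, `tol`, ...).
#' @return The [wham()] profile of the full data with an `sd` column added
#'   and attributes `n_boot`.
#' @export
bayesian_bootstrap <- function(windows, n_boot = 100, seed = NULL, ...) {
  if (n_boot < 2) {
    stop("n_boot must be at least 2 (a single replicate has no spread)",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  full <- wham(windows, ...)
  nw <- length(windows)
  profs <- vapply(seq_len(n_boot), function(b) {
    g <- stats::rexp(nw)
    g <- g / mean(g) # unit-mean weights over complete windows
    suppressWarnings(wham(windows, window_weights = g, ...)$f)
  }, numeric(nrow(full)))
  full$sd <- apply(profs, 1, stats::sd, na.rm = TRUE)
  attr(full, "n_boot") <- n_boot
  full
}

#' Binding well depth of a PMF profile
#'
#' Depth of the bound-state minimum under the large-distance-zero
#' convention, in kJ/mol and in kB*T units (also rounded to the nearest
#' integer, the conventional shorthand). A profile whose minimum lies in
#' the outer shift region (no interior minimum below zero) is reported as
#' having no bound state.
#'
#' @param profile A `pmf_profile` (or any tibble with `center` and `f`).
#' @param temperature Temperature in K (default: the profile's, else 300).
#' @return One-row tibble: `depth_kj`, `depth_kbt`, `depth_kbt_rounded`,
#'   `minimum_at`, `bound` (logical).
#' @export
#' @examples
#' p <- tibble::tibble(center = 1:5 / 10, f = c(-20, -12, -4, -1, 0))
#' well_depth(p, temperature = 300)
well_depth <- function(profile, temperature = NULL) {
  temperature <- temperature %||% attr(profile, "temperature") %||% 300
  f <- profile$f
  ok <- !is.na(f)
  fmin <- min(f[ok])
  at <- profile$center[ok][which.min(f[ok])]
  depth <- 0 - fmin
  bound <- depth > 0 && at < max(profile$center[ok])
  if (!bound) depth <- 0
  kbt <- depth / (KB * temperature)
  tibble::tibble(
    depth_kj = depth, depth_kbt = kbt,
    depth_kbt_rounded = round(kbt), minimum_at = if (bound) at else NA_real_,
    bound = bound
  )
}
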