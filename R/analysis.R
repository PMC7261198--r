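#' Secondary-structure assignment
#'
#' CG mode (state vectors): a residue is labelled `helix` when it belongs to
#' a run of at least three consecutive helical residues (runs of exactly 3
#' are the 3-10-like motif, runs of 4+ the alpha-like motif; both count
#' toward helicity, matching the usual alpha + 3-10 convention). Everything
#' else is `coil`. Atomistic mode (phi/psi angles): a residue is `helix`
#' when phi is within -57 +- 30 degrees and psi within -47 +- 30 degrees
#' over at least three consecutive residues.
#'
#' @param x A frames x residues 0/1 state matrix, a trajectory with a
#'   `state_code` column, or a two-column matrix/data frame of phi/psi
#'   angles in degrees (single frame, atomistic mode).
#' @param n_residues Chain length (required for `state_code` input without
#'   parameter attributes).
#' @param mode `"cg"` or `"dihedral"`.
#' @return A frames x residues character matrix of labels (`"helix"` /
#'   `"coil"`), or a vector for a single frame.
#' @export
assign_secondary_structure <- function(x, n_residues = NULL,
                                       mode = c("cg", "dihedral")) {
  mode <- match.arg(mode)
  if (mode == "dihedral") {
    ang <- as.matrix(x)
    stopifnot(ncol(ang) == 2)
    ok <- abs(ang[, 1] - (-57)) <= 30 & abs(ang[, 2] - (-47)) <= 30
    ok[is.na(ok)] <- FALSE
    hel <- helix_indicator(matrix(as.integer(ok), nrow = 1))
    return(ifelse(drop(hel) == 1, "helix", "coil"))
  }
  if (is.data.frame(x) && "state_code" %in% names(x)) {
    p <- attr(x, "params")
    if (is.null(n_residues)) {
      if (is.null(p)) stop("supply n_residues", call. = FALSE)
      n_residues <- length(p$sequence)
    }
    x <- decode_states(x$state_code, n_residues)
  }
  states <- as.matrix(x)
  hel <- helix_indicator(states)
  lab <- ifelse(hel == 1, "helix", "coil")
  if (nrow(lab) == 1) drop(lab) else lab
}

#' Radius-of-gyration baselines for globular and random-coil proteins
#'
#' Empirical power laws for the mean radius of gyration (in Angstrom) of a
#' chain of N residues: globular `2.2 * N^0.38` and thermally denatured
#' random coil `2.02 * N^0.60`.
#'
#' @param n Residue count(s).
#' @return Tibble with columns `n`, `rg_glob`, `rg_coil` (Angstrom).
#' @export
#' @examples
#' rg_baselines(26)
rg_baselines <- function(n) {
  stopifnot(all(n >= 1))
  tibble::tibble(
    n = n,
    rg_glob = 2.2 * n^0.38,
    rg_coil = 2.02 * n^0.60
  )
}

#' Weighted radius-of-gyration distribution
#'
#' Weighted histogram of the per-frame radius of gyration with the
#' globular/random-coil baselines overlaid. The model works in nm; the
#' baselines are defined in Angstrom, so values are converted (x 10).
#'
#' @param frames Trajectory or ensemble tibble with an `s_rg` column (nm).
#' @param n_residues Chain length for the baselines.
#' @param weights Optional weights (default: `weight` column, else uniform).
#' @param breaks Number of histogram bins (default 30).
#' @return Object of class `rg_distribution`: tibble (`rg` in Angstrom,
#'   `density`) with attributes `baselines`, `frac_above_glob`,
#'   `frac_above_coil`, `mean_rg`.
#' @export
rg_distribution <- function(frames, n_residues, weights = NULL, breaks = 30) {
  rg <- frames$s_rg * 10 # nm -> Angstrom
  w <- weights %||% frames[["weight"]] %||% rep(1, length(rg))
  w <- w / sum(w)
  bl <- rg_baselines(n_residues)
  h <- graphics::hist(rg, breaks = breaks, plot = FALSE)
  dens <- vapply(seq_len(length(h$breaks) - 1), function(i) {
    sel <- rg >= h$breaks[i] & rg < h$breaks[i + 1]
    sum(w[sel]) / (h$breaks[i + 1] - h$breaks[i])
  }, numeric(1))
  out <- tibble::tibble(rg = h$mids, density = dens)
  structure(out,
    class = c("rg_distribution", class(out)),
    baselines = bl,
    frac_above_glob = sum(w[rg > bl$rg_glob[1]]),
    frac_above_coil = sum(w[rg > bl$rg_coil[1]]),
    mean_rg = sum(w * rg)
  )
}

#' Single-linkage clustering of conformations
#'
#' Clusters frames by the transitive closure of the relation "best-fit
#' Calpha RMSD below the cutoff" (single linkage). Cluster populations are
#' normalized sums of the frame weights; the representative of a cluster is
#' its highest-weight frame.
#'
#' @param coords List of n x 3 Calpha matrices (nm), one per frame.
#' @param cutoff_angstrom RMSD cutoff in Angstrom (default 2.5; coordinates
#'   in nm are converted internally).
#' @param weights Optional frame weights (default uniform).
#' @param max_frames Frames are strided down to at most this many before the
#'   O(n^2) RMSD matrix is computed (default 2000); the stride is recorded.
#' @return Object of class `cluster_set`: tibble (`frame`, `cluster`,
#'   `weight`) with attributes `populations` (tibble: cluster, population,
#'   representative), `cutoff_angstrom`, `stride`.
#' @export
single_linkage_cluster <- function(coords, cutoff_angstrom = 2.5,
                                   weights = NULL, max_frames = 2000) {
  n_all <- length(coords)
  stopifnot(n_all >= 1)
  stride <- ceiling(n_all / max_frames)
  keep <- seq(1, n_all, by = stride)
  coords <- coords[keep]
  w <- (weights %||% rep(1, n_all))[keep]
  w <- w / sum(w)
  n <- length(coords)
  cutoff_nm <- cutoff_angstrom / 10
  if (n == 1) {
    assign <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- kabsch_rmsd(coords[[i]], coords[[j]])
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    # merges strictly below the cutoff join clusters ("< cutoff" relation)
    assign <- stats::cutree(hc, h = cutoff_nm * (1 - 1e-12))
  }
  # relabel clusters by decreasing population
  pop <- tapply(w, assign, sum)
  ord <- order(-pop)
  relabel <- match(assign, as.integer(names(pop))[ord])
  pops <- tibble::tibble(
    cluster = seq_along(ord),
    population = as.numeric(pop[ord]),
    representative = vapply(seq_along(ord), function(k) {
      members <- which(relabel == k)
      as.integer(keep[members[which.max(w[members])]])
    }, integer(1))
  )
  out <- tibble::tibble(frame = keep, cluster = relabel, weight = w)
  structure(out,
    class = c("cluster_set", class(out)),
    populations = pops, cutoff_angstrom = cutoff_angstrom, stride = stride
  )
}

#' Per-residue DNA-contact fractions
#'
#' Fraction of frames in which each residue is in contact with the rod
#' (any of its sites within the cutoff of any rod site), plus the global
#' bound fraction (any residue in contact).
#'
#' @param coords List of per-frame conformations (`cg_conformation`) or
#'   Calpha matrices (nm).
#' @param rod A [make_dna_rod()].
#' @param cutoff_angstrom Contact cutoff in Angstrom (default 3.2).
#' @param weights Optional frame weights.
#' @return Tibble (`residue`, `contact_fraction`) with attribute
#'   `bound_fraction`.
#' @export
contact_fraction <- function(coords, rod, cutoff_angstrom = 3.2,
                             weights = NULL) {
  stopifnot(inherits(rod, "dna_rod"))
  cutoff_nm <- cutoff_angstrom / 10
  n_frames <- length(coords)
  w <- weights %||% rep(1, n_frames)
  w <- w / sum(w)
  get_ca <- function(x) if (inherits(x, "cg_conformation")) x$ca else x
  L <- nrow(get_ca(coords[[1]]))
  frac <- numeric(L)
  bound <- 0
  for (f in seq_len(n_frames)) {
    ca <- get_ca(coords[[f]])
    incontact <- vapply(seq_len(L), function(i) {
      dd <- sqrt(colSums((t(rod$sites) - ca[i, ])^2))
      any(dd < cutoff_nm)
    }, logical(1))
    frac <- frac + w[f] * incontact
    if (any(incontact)) bound <- bound + w[f]
  }
  structure(
    tibble::tibble(residue = seq_len(L), contact_fraction = frac),
    bound_fraction = bound
  )
}

#' Free-energy surface over collective variables
#'
#' Either from the deposited bias (`-gamma/(gamma-1) * V`, see
#' [free_energy_estimate()]) or from reweighted frame histograms
#' (`-kT * log` of the weighted density). The global minimum is shifted to
#' zero; empty bins are masked (NA), never imputed; local minima are
#' located on the grid and the free-energy difference between the two
#' lowest minima is reported.
#'
#' @param x A `weighted_ensemble`/trajectory tibble (mode `"from-weights"`)
#'   or a [meta_bias()] (mode `"from-bias"`).
#' @param cvs CV column name(s) (1 or 2), e.g. `"s_alpha"` or
#'   `c("s_alpha", "s_rg")`. Ignored for `"from-bias"`.
#' @param mode `"from-weights"` or `"from-bias"`.
#' @param bins Number of bins per CV (default 40), or a list of explicit
#'   break vectors.
#' @param temperature Temperature (K) for `-kT log`.
#' @param grid Grid for `"from-bias"` (as in [free_energy_estimate()]).
#' @return Object of class `fes`: tibble (CV columns, `f`) with attributes
#'   `minima` (tibble) and `delta_e` (kJ/mol between the two lowest minima,
#'   NA if fewer than two).
#' @export
fes <- function(x, cvs = NULL, mode = c("from-weights", "from-bias"),
                bins = 40, temperature = 300, grid = NULL) {
  mode <- match.arg(mode)
  if (mode == "from-bias") {
    stopifnot(inherits(x, "meta_bias"))
    if (is.null(grid)) stop("supply a grid for mode = 'from-bias'", call. = FALSE)
    surf <- free_energy_estimate(x, grid)
    cvs <- x$cv_names
  } else {
    stopifnot(!is.null(cvs), length(cvs) %in% 1:2)
    w <- x[["weight"]] %||% rep(1 / nrow(x), nrow(x))
    vals <- lapply(cvs, function(cc) x[[cc]])
    brk <- if (is.list(bins)) bins else {
      lapply(vals, function(v) {
        r <- range(v)
        if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
        seq(r[1], r[2], length.out = bins + 1)
      })
    }
    mid <- lapply(brk, function(b) (b[-1] + b[-length(b)]) / 2)
    idx <- lapply(seq_along(cvs), function(k) {
      findInterval(vals[[k]], brk[[k]], rightmost.closed = TRUE,
        all.inside = TRUE
      )
    })
    if (length(cvs) == 1) {
      mass <- tapply(w, factor(idx[[1]], levels = seq_along(mid[[1]])), sum)
      mass[is.na(mass)] <- 0
      surf <- tibble::tibble(s = mid[[1]], p = as.numeric(mass))
      names(surf)[1] <- cvs
    } else {
      key <- factor(
        paste(idx[[1]], idx[[2]]),
        levels = as.vector(outer(
          seq_along(mid[[1]]), seq_along(mid[[2]]), paste
        ))
      )
      mass <- tapply(w, key, sum)
      mass[is.na(mass)] <- 0
      eg <- expand.grid(i = seq_along(mid[[1]]), j = seq_along(mid[[2]]))
      surf <- tibble::tibble(
        s1 = mid[[1]][eg$i], s2 = mid[[2]][eg$j], p = as.numeric(mass)
      )
      names(surf)[1:2] <- cvs
    }
    kt <- KB * temperature
    surf$f <- ifelse(surf$p > 0, -kt * log(surf$p), NA_real_)
    surf$f <- surf$f - min(surf$f, na.rm = TRUE)
    surf$p <- NULL
  }
  minima <- locate_minima(surf, cvs)
  delta_e <- if (nrow(minima) >= 2) minima$f[2] - minima$f[1] else NA_real_
  structure(surf,
    class = c("fes", class(surf)),
    minima = minima, delta_e = delta_e, cvs = cvs,
    temperature = temperature, mode = mode
  )
}

# grid local minima (1D: lower than both neighbours; 2D: lower than the
# 4-neighbourhood), NA bins excluded
locate_minima <- function(surf, cvs) {
  if (length(cvs) == 1) {
    s <- surf[[cvs]]
    f <- surf$f
    o <- order(s)
    s <- s[o]
    f <- f[o]
    n <- length(f)
    is_min <- vapply(seq_len(n), function(i) {
      if (is.na(f[i])) {
        return(FALSE)
      }
      # unsampled (masked) neighbours do not certify a minimum
      left <- if (i > 1) f[i - 1] else Inf
      right <- if (i < n) f[i + 1] else Inf
      if (all(is.na(c(left, right)))) {
        return(FALSE)
      }
      f[i] <= min(left, right, na.rm = TRUE)
    }, logical(1))
    out <- tibble::tibble(s = s[is_min], f = f[is_min])
    names(out)[1] <- cvs
  } else {
    g1 <- sort(unique(surf[[cvs[1]]]))
    g2 <- sort(unique(surf[[cvs[2]]]))
    fm <- matrix(NA_real_, length(g1), length(g2))
    fm[cbind(match(surf[[cvs[1]]], g1), match(surf[[cvs[2]]], g2))] <- surf$f
    rows <- list()
    for (i in seq_along(g1)) {
      for (j in seq_along(g2)) {
        fc <- fm[i, j]
        if (is.na(fc)) next
        nb <- c(
          if (i > 1) fm[i - 1, j] else Inf,
          if (i < length(g1)) fm[i + 1, j] else Inf,
          if (j > 1) fm[i, j - 1] else Inf,
          if (j < length(g2)) fm[i, j + 1] else Inf
        )
        if (fc <= min(nb, na.rm = TRUE)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            s1 = g1[i], s2 = g2[j], f = fc
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) > 0) names(out)[1:2] <- cvs
  }
  dplyr::arrange(out, .data$f)
}

#' Block-average convergence check
#'
#' Splits a per-frame observable series into consecutive blocks after
#' discarding an initial stretch, and reports per-block means together with
#' a stability verdict (maximum drift between consecutive block means below
#' a threshold).
#'
#' @param x Numeric observable series (e.g. helical content per frame).
#' @param block_length Frames per block.
#' @param discard Initial frames to discard.
#' @param threshold Maximum allowed |difference| between consecutive block
#'   means (default 0.1 in observable units).
#' @return Tibble (`block`, `mean`) with attributes `converged` (logical)
#'   and `max_drift`.
#' @export
convergence_check <- function(x, block_length, discard = 0, threshold = 0.1) {
  x <- x[(discard + 1):length(x)]
  n_blocks <- floor(length(x) / block_length)
  if (n_blocks < 2) {
    stop("series too short: need at least 2 blocks after discard",
      call. = FALSE
    )
  }
  bm <- vapply(seq_len(n_blocks), function(b) {
    mean(x[((b - 1) * block_length + 1):(b * block_length)])
  }, numeric(1))
  drift <- max(abs(diff(bm)))
  structure(
    tibble::tibble(block = seq_len(n_blocks), mean = bm),
    converged = drift < threshold, max_drift = drift
  )
}
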