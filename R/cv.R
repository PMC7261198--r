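#' Rigid DNA rod
#'
#' A straight, rigid B-DNA stand-in: one phosphate site per base pair per
#' strand on a helix of radius 0.9 nm, twist 36 degrees per bp and rise
#' 0.34 nm per bp, centred at the origin with its axis along z. The central
#' 11 bp are flagged; they define the acceptor set of the electrostatic
#' contact CV. No groove geometry is modelled.
#'
#' @param n_bp Number of base pairs (at least 11, so the central 11-bp
#'   subset is defined). Default 20.
#' @param rise_nm Rise per bp in nm (default 0.34).
#' @param site_charge Charge per phosphate site in e units (default -1).
#'
#' @return Object of class `dna_rod` with fields `n_bp`, `axis`, `center`,
#'   `bp` (tibble: bp, z, central), `sites` (2 n_bp x 3 matrix), `site_bp`,
#'   `site_central`, `site_charge`.
#' @export
#' @examples
#' rod <- make_dna_rod(20)
#' sum(rod$bp$central)
make_dna_rod <- function(n_bp = 20, rise_nm = 0.34, site_charge = -1) {
  if (n_bp < 11) {
    stop("n_bp must be >= 11 so the central 11-bp subset is defined",
      call. = FALSE
    )
  }
  radius <- 0.9
  twist <- 36 * pi / 180
  i <- seq_len(n_bp)
  z <- (i - (n_bp + 1) / 2) * rise_nm
  c_start <- floor((n_bp - 11) / 2) + 1L
  central <- i >= c_start & i <= c_start + 10L
  ang1 <- (i - 1) * twist
  ang2 <- ang1 + pi
  sites <- rbind(
    cbind(radius * cos(ang1), radius * sin(ang1), z),
    cbind(radius * cos(ang2), radius * sin(ang2), z)
  )
  structure(
    list(
      n_bp = as.integer(n_bp), rise = rise_nm,
      axis = c(0, 0, 1), center = c(0, 0, 0),
      bp = tibble::tibble(bp = i, z = z, central = central),
      sites = sites, site_bp = c(i, i), site_central = c(central, central),
      site_charge = site_charge
    ),
    class = "dna_rod"
  )
}

#' @export
print.dna_rod <- function(x, ...) {
  cat(sprintf(
    "<dna_rod> %d bp (%d central), %d phosphate sites, charge %g e/site\n",
    x$n_bp, sum(x$bp$central), nrow(x$sites), x$site_charge
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Rational switching function
#'
#' `(1 - x^n) / (1 - x^m)` for a dimensionless ratio `x = r / R0`, the
#' standard smooth counting function of biased-MD collective variables.
#' The removable singularity at `x = 1` is evaluated as `n/m` (guard band
#' |x - 1| < 1e-9). Continuous and monotonically decreasing on [0, Inf);
#' equals 1 at x = 0 and tends to 0 as x grows (for m > n).
#'
#' @param x Non-negative ratio(s).
#' @param n,m Integer exponents with `m > n > 0`.
#' @return Numeric vector of switch values.
#' @export
#' @examples
#' rational_switch(c(0, 1, 10), n = 8, m = 12)
rational_switch <- function(x, n, m) {
  stopifnot(m > n, n > 0, all(x >= 0))
  out <- numeric(length(x))
  sing <- abs(x - 1) < 1e-9
  out[sing] <- n / m
  out[!sing] <- (1 - x[!sing]^n) / (1 - x[!sing]^m)
  out
}

#' Switching-function parameters
#'
#' @param r0 Reference distance in nm.
#' @param n,m Integer exponents, `m > n > 0`.
#' @return A `switch_params` list.
#' @export
switch_params <- function(r0, n, m) {
  stopifnot(r0 > 0, m > n, n > 0)
  structure(list(r0 = r0, n = n, m = m), class = "switch_params")
}

#' Default switching parameters of the helicity CV (R0 = 0.08 nm, n = 8,
#' m = 12)
#' @return A [switch_params()] object.
#' @export
alpha_switch_defaults <- function() switch_params(0.08, 8, 12)

#' Default switching parameters of the contact CV (R0 = 0.2 nm, n = 8,
#' m = 10)
#' @return A [switch_params()] object.
#' @export
contact_switch_defaults <- function() switch_params(0.2, 8, 10)

ca_of <- function(conf) {
  if (inherits(conf, "cg_conformation")) {
    if (is.null(conf$ca)) {
      conf <- build_coordinates(conf$states,
        coil_theta = conf$coil_theta, coil_tau = conf$coil_tau
      )
      conf$ca
    } else {
      conf$ca
    }
  } else if (is.matrix(conf)) {
    stopifnot(ncol(conf) == 3)
    conf
  } else {
    stop("expected a cg_conformation or an n x 3 coordinate matrix",
      call. = FALSE
    )
  }
}

#' Ideal alpha-helix Calpha template
#'
#' @param n Number of residues.
#' @return n x 3 matrix of coordinates (nm).
#' @export
helix_template <- function(n = 6) .cpp_helix_template(as.integer(n))

#' Helical-content collective variable
#'
#' Sum over all contiguous six-residue windows of the rational switch of
#' `RMSD / R0`, where RMSD is the best-fit (Kabsch) Calpha RMSD of the
#' window to an ideal six-residue alpha helix. An ideal helix of length L
#' scores L - 5; a fully extended chain scores ~0.
#'
#' @param conf A `cg_conformation` or n x 3 Calpha matrix (nm), n >= 6.
#' @param sp Switching parameters (default [alpha_switch_defaults()]).
#' @return A single number in [0, L - 5].
#' @export
#' @examples
#' s_alpha(helix_template(11))
s_alpha <- function(conf, sp = alpha_switch_defaults()) {
  ca <- ca_of(conf)
  if (nrow(ca) < 6) stop("s_alpha needs at least 6 residues", call. = FALSE)
  .cpp_salpha(ca, helix_template(6), sp$r0, sp$n, sp$m)
}

# naive reference used in cross-checks (windowed loop in plain R)
s_alpha_reference <- function(ca, sp = alpha_switch_defaults()) {
  tmpl <- helix_template(6)
  tot <- 0
  for (i in 1:(nrow(ca) - 5)) {
    r <- kabsch_rmsd(ca[i:(i + 5), , drop = FALSE], tmpl)
    tot <- tot + rational_switch(r / sp$r0, sp$n, sp$m)
  }
  tot
}

#' Best-fit RMSD after Kabsch superposition
#'
#' @param a,b n x 3 coordinate matrices.
#' @return RMSD in the coordinate units.
#' @export
kabsch_rmsd <- function(a, b) .cpp_kabsch_rmsd(a, b)

#' Radius-of-gyration collective variable
#'
#' Mass-weighted root-mean-square distance of the Calpha atoms from their
#' centre of mass. With equal masses (the default; all Calpha are identical)
#' this is the usual radius of gyration.
#'
#' @param conf A `cg_conformation` or n x 3 Calpha matrix (nm).
#' @param masses Optional per-atom masses.
#' @return Radius of gyration in nm.
#' @export
#' @examples
#' s_rg(rbind(c(0, 0, 0), c(1, 0, 0)))
s_rg <- function(conf, masses = NULL) {
  ca <- ca_of(conf)
  m <- if (is.null(masses)) rep(1, nrow(ca)) else masses
  stopifnot(length(m) == nrow(ca))
  com <- colSums(ca * m) / sum(m)
  sqrt(sum(m * rowSums((ca - matrix(com, nrow(ca), 3, byrow = TRUE))^2)) /
    sum(m))
}

#' Protein-DNA electrostatic-contact collective variable
#'
#' Smooth count of contacts between the positive sidechain pseudo-atoms of
#' Lys/Arg (donors) and the phosphate sites of the central 11 bp of the rod
#' (acceptors): the double sum of the rational switch of `r / R0` with
#' R0 = 0.2 nm, n = 8, m = 10.
#'
#' @param conf A `cg_conformation` with charge sites (build with `params`).
#' @param rod A [make_dna_rod()] object.
#' @param sp Switching parameters (default [contact_switch_defaults()]).
#' @param charges Optional per-site charges of the conformation's charge
#'   sites; positive sites form the donor set. Defaults to +1 for all sites.
#' @return A single non-negative number.
#' @export
s_cont <- function(conf, rod, sp = contact_switch_defaults(),
                   charges = NULL) {
  stopifnot(inherits(rod, "dna_rod"))
  don <- if (inherits(conf, "cg_conformation")) conf$charge_sites else conf
  if (is.null(don) || nrow(don) == 0) {
    warning("empty donor set; s_cont = 0")
    return(0)
  }
  q <- if (is.null(charges)) rep(1, nrow(don)) else charges
  don <- don[q > 0, , drop = FALSE]
  if (nrow(don) == 0) {
    warning("empty donor set; s_cont = 0")
    return(0)
  }
  acc <- rod$sites[rod$site_central, , drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(don))) {
    r <- sqrt(rowSums((acc - matrix(don[i, ], nrow(acc), 3, byrow = TRUE))^2))
    tot <- tot + sum(rational_switch(r / sp$r0, sp$n, sp$m))
  }
  tot
}

#' Radial peptide-DNA distance
#'
#' Distance, in the plane normal to the rod axis, between the rod's central
#' base-pair reference point and the centroid of the peptide Calpha atoms.
#' The rod is re-aligned internally so its axis defines the normal plane;
#' displacement along the axis is ignored.
#'
#' @param conf A `cg_conformation` or Calpha matrix.
#' @param rod A [make_dna_rod()] object.
#' @return Distance in nm.
#' @export
radial_distance <- function(conf, rod) {
  stopifnot(inherits(rod, "dna_rod"))
  ca <- ca_of(conf)
  cen <- colMeans(ca) - rod$center
  ax <- rod$axis / sqrt(sum(rod$axis^2))
  par <- sum(cen * ax)
  sqrt(max(0, sum(cen^2) - par^2))
}
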