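#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang .data
NULL

#' Tidy a metadynamics bias
#'
#' One row per deposited kernel.
#'
#' @param x A [meta_bias()].
#' @param ... Unused.
#' @return Tibble of kernels with CV-named center columns.
#' @export
tidy.meta_bias <- function(x, ...) {
  k <- x$kernels
  d <- length(x$cv_names)
  out <- tibble::tibble(time = k$time)
  out[[paste0("center_", x$cv_names[1])]] <- k$center1
  if (d == 2) out[[paste0("center_", x$cv_names[2])]] <- k$center2
  out$height <- k$height
  out
}

#' @rdname tidy.meta_bias
#' @export
glance.meta_bias <- function(x, ...) {
  tibble::tibble(
    n_kernels = nrow(x$kernels),
    cvs = paste(x$cv_names, collapse = ","),
    height = x$height, gamma = x$gamma, stride = x$stride,
    frozen = x$frozen,
    total_height = sum(x$kernels$height)
  )
}

#' Tidy a trajectory
#'
#' @param x A `cg_trajectory`.
#' @param ... Unused.
#' @return The frames as a plain tibble.
#' @export
tidy.cg_trajectory <- function(x, ...) {
  tibble::as_tibble(unclass_frames(x))
}

unclass_frames <- function(x) {
  class(x) <- setdiff(class(x), c("cg_trajectory", "weighted_ensemble"))
  x
}

#' @rdname tidy.cg_trajectory
#' @export
glance.cg_trajectory <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x),
    acceptance = attr(x, "acceptance"),
    mean_s_alpha = mean(x$s_alpha),
    mean_s_rg = mean(x$s_rg),
    mean_energy = mean(x$e_total),
    seed = attr(x, "seed") %||% NA_integer_
  )
}

#' Tidy a free-energy surface
#'
#' @param x An `fes`.
#' @param ... Unused.
#' @return The grid tibble.
#' @export
tidy.fes <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.fes
#' @export
glance.fes <- function(x, ...) {
  m <- attr(x, "minima")
  tibble::tibble(
    n_minima = nrow(m),
    delta_e = attr(x, "delta_e"),
    mode = attr(x, "mode"),
    temperature = attr(x, "temperature")
  )
}

#' Tidy a PMF profile
#'
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @return The bin tibble.
#' @export
tidy.pmf_profile <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.pmf_profile
#' @export
glance.pmf_profile <- function(x, ...) {
  dplyr::bind_cols(
    well_depth(x),
    tibble::tibble(
      iterations = attr(x, "iterations"),
      converged = attr(x, "converged"),
      n_boot = attr(x, "n_boot") %||% NA_integer_
    )
  )
}

#' Tidy a cluster set
#'
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return Frame-to-cluster assignment tibble.
#' @export
tidy.cluster_set <- function(x, ...) tibble::as_tibble(unclass(x))

#' @rdname tidy.cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  p <- attr(x, "populations")
  tibble::tibble(
    n_clusters = nrow(p),
    top_population = p$population[1],
    cutoff_angstrom = attr(x, "cutoff_angstrom"),
    stride = attr(x, "stride")
  )
}

#' Tidy a replica-exchange run
#'
#' @param x An `remd_run`.
#' @param ... Unused.
#' @return The exchange log tibble.
#' @export
tidy.remd_run <- function(x, ...) x$exchange_log

#' @rdname tidy.remd_run
#' @export
glance.remd_run <- function(x, ...) {
  tibble::tibble(
    n_replicas = length(x$temperatures),
    t_min = min(x$temperatures), t_max = max(x$temperatures),
    n_attempts = nrow(x$exchange_log),
    mean_acceptance = mean(x$exchange_log$accepted)
  )
}
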