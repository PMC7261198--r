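#' Read NTD sequences from a FASTA file
#'
#' The record id (first word of the header) becomes the subtype id.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Named list of [ntd_sequence] objects in file order.
#' @export
read_ntd_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA input: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  out <- lapply(seq_along(aa), function(i) {
    ntd_sequence(ids[i], as.character(aa[[i]]))
  })
  names(out) <- ids
  out
}

#' Write NTD sequences to a FASTA file
#'
#' @param seqs List of [ntd_sequence] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ntd_fasta <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) {
    s <- as_ntd_sequence(s)
    c(paste0(">", s$subtype_id), paste(s$residues, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- whitespace tables with a "#! FIELDS" header --------------------------

#' Write a CV time-series table
#'
#' Whitespace-delimited table with a `#! FIELDS` header line naming the
#' columns, the common convention of biased-MD post-processing tools.
#'
#' @param df Data frame of numeric columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  utils::write.table(
    format(as.data.frame(df), digits = 17, trim = TRUE, scientific = NA),
    con,
    quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a CV time-series table
#'
#' @param path Path to a table written by [write_timeseries()].
#' @return A tibble with the columns named in the `#! FIELDS` header.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#! FIELDS")) {
    stop("missing '#! FIELDS' header in ", path, call. = FALSE)
  }
  fields <- strsplit(sub("^#! FIELDS\\s+", "", header), "\\s+")[[1]]
  dat <- utils::read.table(path, comment.char = "#")
  if (ncol(dat) != length(fields)) {
    stop(sprintf(
      "field count mismatch in %s: header names %d columns, data has %d",
      path, length(fields), ncol(dat)
    ), call. = FALSE)
  }
  names(dat) <- fields
  tibble::as_tibble(dat)
}

#' Write metadynamics kernels to a HILLS-like file
#'
#' One row per deposited Gaussian: time, center per CV, sigma per CV,
#' height, bias factor.
#'
#' @param bias A [meta_bias] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hills <- function(bias, path) {
  k <- bias$kernels
  d <- length(bias$cv_names)
  df <- data.frame(time = k$time)
  for (i in seq_len(d)) df[[bias$cv_names[i]]] <- k[[paste0("center", i)]]
  for (i in seq_len(d)) {
    df[[paste0("sigma_", bias$cv_names[i])]] <- k[[paste0("sigma", i)]]
  }
  df$height <- k$height
  df$biasf <- rep(bias$gamma, nrow(k))
  write_timeseries(df, path)
}

#' Read metadynamics kernels from a HILLS-like file
#'
#' @param path Path to a file written by [write_hills()].
#' @return A [meta_bias] object.
#' @export
read_hills <- function(path) {
  df <- read_timeseries(path)
  nm <- names(df)
  sig_idx <- grep("^sigma_", nm)
  cvs <- sub("^sigma_", "", nm[sig_idx])
  if (!all(c("time", "height", "biasf", cvs) %in% nm)) {
    stop("not a HILLS-like table: ", path, call. = FALSE)
  }
  if (is.unsorted(df$time)) {
    stop("kernel times are not sorted in ", path, call. = FALSE)
  }
  gamma <- if (nrow(df) > 0) df$biasf[1] else Inf
  bias <- meta_bias(
    cv_names = cvs,
    sigma = if (nrow(df) > 0) {
      as.numeric(df[1, sig_idx])
    } else {
      rep(0.1, length(cvs))
    },
    height = if (nrow(df) > 0) max(df$height) else 1,
    gamma = gamma
  )
  k <- tibble::tibble(time = df$time)
  for (i in seq_along(cvs)) k[[paste0("center", i)]] <- df[[cvs[i]]]
  for (i in seq_along(cvs)) k[[paste0("sigma", i)]] <- df[[sig_idx[i]]]
  k$height <- df$height
  bias$kernels <- k
  bias
}

# ---- key-value run configuration ------------------------------------------

#' Write a run configuration as key-value text
#'
#' Scalars and numeric vectors are written in full precision
#' (`key = v1 v2 ...`), so a configuration round-trips losslessly.
#'
#' @param config Named list of scalars or atomic vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt1 <- function(v) {
    if (is.numeric(v)) {
      paste(vapply(v, function(x) sprintf("%.17g", x), character(1)),
        collapse = " "
      )
    } else {
      paste(as.character(v), collapse = " ")
    }
  }
  lines <- vapply(names(config), function(k) {
    paste(k, "=", fmt1(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a key-value run configuration
#'
#' @param path Path written by [write_run_config()].
#' @return Named list; values parse as numeric/logical where possible.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    vals <- strsplit(trimws(kv[2]), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(num)) {
      num
    } else if (all(vals %in% c("TRUE", "FALSE"))) {
      as.logical(vals)
    } else {
      vals
    }
  }
  out
}

# ---- PDB traces -----------------------------------------------------------

#' Write conformations as a multi-model Calpha PDB trace
#'
#' One `MODEL`/`ENDMDL` block per conformation, Calpha atoms plus one `CB`
#' pseudo-atom per charged residue. Coordinates are stored in Angstrom (the
#' PDB unit); the model works in nm and the conversion is applied here.
#'
#' @param confs A conformation or list of conformations (see
#'   [build_coordinates()]).
#' @param path Output path.
#' @param sequence Optional character vector of one-letter codes used for
#'   residue names.
#' @return `path`, invisibly.
#' @export
write_pdb_trace <- function(confs, path, sequence = NULL) {
  if (inherits(confs, "cg_conformation")) confs <- list(confs)
  aa3 <- c(
    A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
    E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
    M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
    Y = "TYR", V = "VAL"
  )
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(confs)) {
    cf <- confs[[m]]
    n <- nrow(cf$ca)
    res3 <- if (is.null(sequence)) {
      rep("ALA", n)
    } else {
      unname(aa3[sequence])
    }
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 1L
    for (i in seq_len(n)) {
      writeLines(sprintf(
        "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, res3[i], i, 10 * cf$ca[i, 1], 10 * cf$ca[i, 2],
        10 * cf$ca[i, 3]
      ), con)
      serial <- serial + 1L
    }
    if (!is.null(cf$charge_sites) && nrow(cf$charge_sites) > 0) {
      for (j in seq_len(nrow(cf$charge_sites))) {
        i <- cf$charge_residues[j]
        writeLines(sprintf(
          "ATOM  %5d  CB  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, res3[i], i, 10 * cf$charge_sites[j, 1],
          10 * cf$charge_sites[j, 2], 10 * cf$charge_sites[j, 3]
        ), con)
        serial <- serial + 1L
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model Calpha PDB trace
#'
#' Uses bio3d to parse the file and returns the Calpha coordinates of each
#' model in nm.
#'
#' @param path Path to a PDB file.
#' @return List of n x 3 Calpha coordinate matrices (nm), one per model.
#' @export
read_pdb_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  nmod <- dim(pdb$xyz)[1]
  lapply(seq_len(nmod), function(m) {
    xyz <- pdb$xyz[m, sel$xyz]
    matrix(xyz, ncol = 3, byrow = TRUE) / 10
  })
}
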