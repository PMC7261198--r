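#' Construct an NTD peptide sequence
#'
#' Represents the N-terminal domain (NTD) of a linker-histone subtype as an
#' ordered vector of one-letter amino-acid codes with an explicit residue
#' numbering origin, so that residue labels such as "K14" refer to positions
#' in the full-length protein.
#'
#' @param subtype_id Short label for the subtype, e.g. `"H1.0"`.
#' @param residues Character scalar (e.g. `"MTENST..."`) or character vector
#'   of one-letter codes. Only the 20 standard amino acids are accepted.
#' @param first_index Integer residue number of the first residue (default 1).
#'
#' @return An object of class `ntd_sequence`.
#' @export
#' @examples
#' ntd_sequence("toy", "KAK")
ntd_sequence <- function(subtype_id, residues, first_index = 1L) {
  if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(as.character(residues))
  if (length(residues) < 1L) {
    stop("an NTD sequence must contain at least one residue", call. = FALSE)
  }
  bad <- setdiff(unique(residues), AA_STANDARD)
  if (length(bad) > 0L) {
    stop("non-standard amino-acid codes: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      subtype_id = as.character(subtype_id),
      residues = residues,
      first_index = as.integer(first_index)
    ),
    class = "ntd_sequence"
  )
}

AA_STANDARD <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' @export
print.ntd_sequence <- function(x, ...) {
  cat(sprintf(
    "<ntd_sequence> %s: %d residues (%d-%d)\n  %s\n",
    x$subtype_id, length(x$residues), x$first_index,
    x$first_index + length(x$residues) - 1L,
    paste(x$residues, collapse = "")
  ))
  invisible(x)
}

#' @export
length.ntd_sequence <- function(x) length(x$residues)

#' @export
as.character.ntd_sequence <- function(x, ...) paste(x$residues, collapse = "")

residue_indices <- function(seq) {
  seq$first_index + seq_along(seq$residues) - 1L
}

as_ntd_sequence <- function(x, subtype_id = "seq") {
  if (inherits(x, "ntd_sequence")) x else ntd_sequence(subtype_id, x)
}

#' Bundled H1 NTD subtype sequences
#'
#' Returns the three human H1 NTD subtype sequences bundled with the package
#' (H1.0, H1.1, H1.2). The H1.0 entry is the canonical 26-residue NTD. The
#' H1.1 and H1.2 entries are synthetic reconstructions: the exact published
#' sequences are not reproducible from the available text, so these are built
#' to match the published basic-subregion composition exactly (see the
#' methods vignette).
#'
#' @return A named list of [ntd_sequence] objects, ordered by subtype id.
#' @export
#' @examples
#' names(ntd_fixture_sequences())
ntd_fixture_sequences <- function() {
  path <- system.file("extdata", "ntd_subtypes_synthetic.fasta",
    package = "ntdfold"
  )
  read_ntd_fasta(path)
}

#' Extract the basic subregion of an NTD
#'
#' The basic subregion is the Lys/Arg-rich segment of the NTD adjoining the
#' globular domain. Two definitions coexist in the field and both are
#' supported: `"span-first-to-last-basic"` takes the inclusive span between
#' the first and last Arg/Lys of the NTD (used for composition tables);
#' `"three-before-first-lys"` starts three residues (one helical turn) before
#' the first Lys and runs to the end of the NTD (used to design simulation
#' constructs).
#'
#' @param seq An [ntd_sequence] (or a character sequence).
#' @param variant Subregion definition, see Details.
#'
#' @return An object of class `basic_subregion` with fields `parent`,
#'   `start_index`, `end_index`, `definition_variant`.
#' @export
#' @examples
#' h1 <- ntd_fixture_sequences()
#' extract_basic_subregion(h1$H1.0)
extract_basic_subregion <- function(seq,
                                    variant = c(
                                      "span-first-to-last-basic",
                                      "three-before-first-lys"
                                    )) {
  seq <- as_ntd_sequence(seq)
  variant <- match.arg(variant)
  idx <- residue_indices(seq)
  basic <- idx[seq$residues %in% c("K", "R")]
  if (length(basic) == 0L) {
    stop("no basic residues (K/R) in sequence '", seq$subtype_id, "'",
      call. = FALSE
    )
  }
  if (variant == "span-first-to-last-basic") {
    start <- basic[1]
    end <- basic[length(basic)]
  } else {
    lys <- idx[seq$residues == "K"]
    if (length(lys) == 0L) {
      stop("no Lys residue in sequence '", seq$subtype_id,
        "'; the three-before-first-lys definition requires one",
        call. = FALSE
      )
    }
    start <- max(lys[1] - 3L, idx[1])
    end <- idx[length(idx)]
  }
  structure(
    list(
      parent = seq, start_index = as.integer(start),
      end_index = as.integer(end), definition_variant = variant
    ),
    class = "basic_subregion"
  )
}

#' @export
print.basic_subregion <- function(x, ...) {
  cat(sprintf(
    "<basic_subregion> %s %d-%d (%s)\n  %s\n",
    x$parent$subtype_id, x$start_index, x$end_index, x$definition_variant,
    paste(subregion_residues(x), collapse = "")
  ))
  invisible(x)
}

subregion_residues <- function(sub) {
  idx <- residue_indices(sub$parent)
  sub$parent$residues[idx >= sub$start_index & idx <= sub$end_index]
}

as_residue_span <- function(x) {
  # normalizes sequence-like inputs to (residues, residue numbers, label)
  if (inherits(x, "basic_subregion")) {
    list(
      residues = subregion_residues(x),
      index = x$start_index:x$end_index,
      label = x$parent$subtype_id
    )
  } else {
    s <- as_ntd_sequence(x)
    list(
      residues = s$residues, index = residue_indices(s),
      label = s$subtype_id
    )
  }
}

#' Composition statistics of a sequence span
#'
#' Counts basic (Lys/Arg) and helix-breaking (Pro/Gly) residues. The basic
#' percentage is truncated (not rounded) to one decimal, matching the
#' convention of published composition tables (9/21 prints as 42.8).
#'
#' @param sub A [basic_subregion], [ntd_sequence], or character sequence.
#'
#' @return A one-row tibble with columns `length`, `n_basic`, `pct_basic`,
#'   `n_breaker`.
#' @export
#' @examples
#' composition_stats("KAK")
composition_stats <- function(sub) {
  sp <- as_residue_span(sub)
  n <- length(sp$residues)
  n_basic <- sum(sp$residues %in% c("K", "R"))
  n_breaker <- sum(sp$residues %in% c("P", "G"))
  tibble::tibble(
    length = n,
    n_basic = n_basic,
    pct_basic = trunc(1000 * n_basic / n) / 10,
    n_breaker = n_breaker
  )
}

#' Helical-wheel projection and basic-face detection
#'
#' Projects a sequence onto the cross-section of an ideal alpha helix (3.6
#' residues per turn, so 100 degrees between consecutive residues): residue
#' `i` of the span receives azimuthal angle `((i - start) * 100) mod 360`.
#' The basic "face" is the contiguous angular arc of width `face_width_deg`
#' that maximizes the number of Lys/Arg residues; arc start angles are
#' scanned in 1-degree steps and ties are broken by the smallest start angle.
#' His is classed as neutral.
#'
#' @param x A [basic_subregion], [ntd_sequence], or character sequence with
#'   at least two residues.
#' @param face_width_deg Width of the face arc in degrees (default 180).
#'
#' @return An object of class `wheel_projection`: a tibble with columns
#'   `residue`, `aa`, `angle_deg`, `charge_class`, `in_face`, and attributes
#'   `face_start_deg`, `face_width_deg`, `basic_face_members`.
#' @export
#' @examples
#' hw <- helical_wheel(extract_basic_subregion(ntd_fixture_sequences()$H1.0))
#' attr(hw, "basic_face_members")
helical_wheel <- function(x, face_width_deg = 180) {
  sp <- as_residue_span(x)
  if (length(sp$residues) < 2L) {
    stop("helical wheel needs at least 2 residues", call. = FALSE)
  }
  stopifnot(face_width_deg > 0, face_width_deg <= 360)
  angle <- ((sp$index - sp$index[1]) * 100) %% 360
  charge_class <- ifelse(sp$residues %in% c("K", "R"), "basic",
    ifelse(sp$residues %in% c("D", "E"), "acidic", "neutral")
  )
  basic_angle <- angle[charge_class == "basic"]
  starts <- 0:359
  counts <- vapply(starts, function(s) {
    sum(((basic_angle - s) %% 360) < face_width_deg)
  }, integer(1))
  face_start <- starts[which.max(counts)]
  in_face <- ((angle - face_start) %% 360) < face_width_deg
  out <- tibble::tibble(
    residue = sp$index, aa = sp$residues, angle_deg = angle,
    charge_class = charge_class, in_face = in_face
  )
  structure(out,
    class = c("wheel_projection", class(out)),
    face_start_deg = face_start,
    face_width_deg = face_width_deg,
    basic_face_members = sp$index[in_face & charge_class == "basic"],
    label = sp$label
  )
}

#' Tabular report over NTD subtypes
#'
#' One row per subtype with basic-subregion composition statistics and a
#' summary of the helical-wheel basic face, ordered deterministically by
#' subtype id.
#'
#' @param seqs List of [ntd_sequence] objects (e.g. [ntd_fixture_sequences()]).
#' @param variant Basic-subregion definition passed to
#'   [extract_basic_subregion()].
#' @param face_width_deg Face width passed to [helical_wheel()].
#'
#' @return A tibble with columns `subtype_id`, `length`, `n_basic`,
#'   `pct_basic`, `n_breaker`, `face_start_deg`, `n_face_basic`,
#'   `face_members` (comma-separated residue labels such as "K14").
#' @export
#' @examples
#' subtype_report(ntd_fixture_sequences())
subtype_report <- function(seqs, variant = "span-first-to-last-basic",
                           face_width_deg = 180) {
  if (length(seqs) == 0L) {
    return(tibble::tibble(
      subtype_id = character(), length = integer(), n_basic = integer(),
      pct_basic = numeric(), n_breaker = integer(),
      face_start_deg = numeric(), n_face_basic = integer(),
      face_members = character()
    ))
  }
  ids <- vapply(seqs, function(s) as_ntd_sequence(s)$subtype_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate subtype ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  rows <- lapply(seqs[order(ids)], function(s) {
    s <- as_ntd_sequence(s)
    sub <- extract_basic_subregion(s, variant)
    st <- composition_stats(sub)
    hw <- helical_wheel(sub, face_width_deg)
    members <- attr(hw, "basic_face_members")
    aa <- hw$aa[match(members, hw$residue)]
    st |>
      dplyr::mutate(subtype_id = s$subtype_id, .before = 1) |>
      dplyr::mutate(
        face_start_deg = attr(hw, "face_start_deg"),
        n_face_basic = length(members),
        face_members = paste0(aa, members, collapse = ",")
      )
  })
  dplyr::bind_rows(rows)
}
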