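#' Write a backbone model as a PDB file
#'
#' Poly-alanine backbone, single chain A, 1-based residue numbering; the
#' repeat index is stored in the B-factor column so it survives a round
#' trip. Coordinates are written at the format's 3-decimal precision.
#'
#' @param model A `backbone_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "backbone_model"))
  a <- model$atoms
  lines <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    lines[i] <- sprintf(
      "ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, a$atom[i], "ALA", "A", a$res_id[i], a$x[i], a$y[i], a$z[i],
      1.00, as.numeric(a$repeat_index[i]), substr(a$atom[i], 1, 1)
    )
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a backbone model from a PDB file
#'
#' Parses standard fixed-width ATOM records. When a [repeat_topology()] is
#' supplied, segment annotations (helix/loop) and per-repeat numbering are
#' reconstructed from it; otherwise the repeat index is taken from the
#' B-factor column (as written by [write_pdb()]) and segments are left
#' unannotated.
#'
#' @param path PDB file.
#' @param topology Optional [repeat_topology()] used to reannotate segments.
#' @return A `backbone_model`.
#' @export
read_pdb <- function(path, topology = NULL) {
  lines <- readLines(path)
  at <- grep("^ATOM  |^HETATM", lines)
  if (length(at) == 0) stop("no ATOM records found: empty model.")
  parse_field <- function(ln, from, to, what, lineno) {
    out <- suppressWarnings(as.numeric(substr(ln, from, to)))
    if (any(is.na(out))) {
      bad <- lineno[which(is.na(out))[1]]
      stop(sprintf("malformed ATOM record at line %d (field %s)", bad, what))
    }
    out
  }
  ln <- lines[at]
  atom <- trimws(substr(ln, 13, 16))
  resno <- as.integer(parse_field(ln, 23, 26, "resSeq", at))
  x <- parse_field(ln, 31, 38, "x", at)
  y <- parse_field(ln, 39, 46, "y", at)
  z <- parse_field(ln, 47, 54, "z", at)
  bfac <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
  rep_idx <- if (all(!is.na(bfac)) && all(bfac >= 1)) as.integer(round(bfac)) else 1L

  if (!is.null(topology)) {
    rpr <- topology$residues_per_repeat
    rep_idx <- (resno - 1L) %/% rpr + 1L
    rir <- (resno - 1L) %% rpr + 1L
    h1 <- topology$helix_lengths[1]; l1 <- topology$loop_lengths[1]
    h2 <- topology$helix_lengths[2]
    segment <- ifelse(rir <= h1, "H1",
               ifelse(rir <= h1 + l1, "L1",
               ifelse(rir <= h1 + l1 + h2, "H2", "L2")))
  } else {
    n_rep <- max(rep_idx)
    segment <- rep(NA_character_, length(resno))
    topology <- repeat_topology("imported", c(16L, 16L), c(1L, 1L),
                                n_repeats = n_rep)
    topology$residues_per_repeat <- max(1L, length(unique(resno)) %/% n_rep)
  }
  atoms <- tibble::tibble(
    res_id = resno,
    repeat_index = rep_idx,
    res_in_repeat = (resno - 1L) %% topology$residues_per_repeat + 1L,
    segment = segment,
    atom = atom,
    x = x, y = y, z = z
  )
  structure(
    list(atoms = atoms, topology = topology,
         params = helical_params(d_rep = 10)),
    class = "backbone_model"
  )
}

#' Write a surface array as CSV
#'
#' Columns: `repeat_index`, `slot`, `x`, `y`, `z`, `residue`, `charge`.
#' @param array A `surface_array`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_array_csv <- function(array, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(array)), path)
  invisible(path)
}

#' Read a surface array from CSV
#' @param path CSV file written by [write_array_csv()] (or with the same
#'   columns).
#' @param name Array label.
#' @return A `surface_array`.
#' @export
read_array_csv <- function(path, name = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  surface_array(tbl, name = name %||% basename(path))
}

#' Write a slab as an XYZ file
#'
#' Standard XYZ: atom count, comment, then `species x y z` per line.
#' Carbonate carbon/oxygen are written as C and O.
#'
#' @param slab A `surface_slab`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(slab, path) {
  stopifnot(inherits(slab, "surface_slab"))
  elem <- c(Ca = "Ca", C_carbonate = "C", O_carbonate = "O")[slab$species]
  hdr <- c(as.character(nrow(slab)),
           sprintf("%s (%s) slab", attr(slab, "cell_name"),
                   paste(attr(slab, "plane"), collapse = "")))
  body <- sprintf("%-2s %12.6f %12.6f %12.6f", elem, slab$x, slab$y, slab$z)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an analysis/docking report as JSON with provenance
#'
#' Reports embed the seed and a hash of the settings so repeated runs are
#' identifiable.
#'
#' @param x A list of results (must be JSON-serializable).
#' @param path Output file.
#' @param seed Seed used for the computation.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path, seed = NA_integer_) {
  payload <- list(
    results = x,
    provenance = list(
      seed = seed,
      config_hash = rlang::hash(x),
      package = "calcitile",
      version = as.character(utils::packageVersion("calcitile"))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
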