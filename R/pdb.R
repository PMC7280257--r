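# PDB coordinate-file handling: fixed-column parsing into a structure model,
# alt-loc resolution, and a writer used for round-trip checks and synthetic
# fixtures.

#' The 20 standard amino-acid residue codes
#'
#' Only these residues are ever eligible as "active" residues on the protein
#' side of a contact search; waters, ions, glycans and other heterogroups are
#' never selected.
#' @keywords internal
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# two-letter element symbols that occur in PDB atom names starting at column 13
TWO_LETTER_ELEMENTS <- c(
  "BR", "CL", "FE", "MG", "MN", "NA", "ZN", "CA", "CU", "NI", "CO", "SE", "CD"
)

#' Parse PDB-format text into a structure model
#'
#' Reads fixed-column `ATOM`/`HETATM` records. Only the first model of a
#' multi-model file is kept; alternate locations are resolved to the highest
#' occupancy (ties broken by file order). Element symbols are taken from
#' columns 77-78 when present and inferred from the atom name otherwise.
#'
#' @param text PDB-format text: a single string or a character vector of lines.
#' @param source_id identifier recorded on the model (e.g. a PDB ID).
#' @return An object of class `structure_model`: a list with `atoms` (a
#'   data.frame with one row per atom: `serial`, `name`, `alt_loc`,
#'   `res_name`, `chain`, `res_seq`, `i_code`, `x`, `y`, `z`, `occupancy`,
#'   `element`, `record`) and `source_id`.
#' @examples
#' txt <- make_toy_structure(n_residues = 2,
#'                           planted_min_distances = c(2.5, 3.2), seed = 1)
#' mod <- parse_structure(txt, source_id = "toy")
#' table(mod$atoms$record)
#' @export
parse_structure <- function(text, source_id = "unknown") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rec6 <- substr(lines, 1, 6)
  is_atom <- rec6 %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 5) == "ATOM " # tolerate short-padded records

  # first model only: drop everything after the first ENDMDL
  endmdl <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(endmdl) > 0) {
    is_atom[seq_along(lines) > endmdl[1]] <- FALSE
  }
  idx <- which(is_atom)
  if (length(idx) == 0) {
    stop("parse error: no ATOM or HETATM coordinate records found", call. = FALSE)
  }

  num_field <- function(lns, from, to, what, line_no, required = TRUE) {
    raw <- trimws(substr(lns, from, to))
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & (required | nzchar(raw)))
    if (length(bad) > 0) {
      stop(sprintf("parse error: malformed %s field ('%s') at line %d",
                   what, raw[bad[1]], line_no[bad[1]]), call. = FALSE)
    }
    val
  }

  lns <- lines[idx]
  atoms <- data.frame(
    serial    = num_field(lns, 7, 11, "serial", idx),
    name      = trimws(substr(lns, 13, 16)),
    alt_loc   = substr(lns, 17, 17),
    res_name  = trimws(substr(lns, 18, 20)),
    chain     = substr(lns, 22, 22),
    res_seq   = num_field(lns, 23, 26, "residue number", idx),
    i_code    = trimws(substr(lns, 27, 27)),
    x         = num_field(lns, 31, 38, "x coordinate", idx),
    y         = num_field(lns, 39, 46, "y coordinate", idx),
    z         = num_field(lns, 47, 54, "z coordinate", idx),
    occupancy = num_field(lns, 55, 60, "occupancy", idx, required = FALSE),
    record    = ifelse(substr(lns, 1, 6) == "HETATM", "HETATM", "ATOM"),
    stringsAsFactors = FALSE
  )
  atoms$alt_loc[atoms$alt_loc == " "] <- ""
  atoms$occupancy[is.na(atoms$occupancy)] <- 1.0
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("parse error: non-finite coordinates", call. = FALSE)
  }

  # element: columns 77-78 when present, otherwise inferred from the atom name
  elem <- trimws(substr(lns, 77, 78))
  infer <- !nzchar(elem)
  if (any(infer)) {
    elem[infer] <- infer_element(substr(lns[infer], 13, 16))
  }
  atoms$element <- toupper(elem)

  atoms <- resolve_alt_locs(atoms)
  structure(list(atoms = atoms, source_id = source_id),
            class = "structure_model")
}

# Infer an element symbol from the 4-character PDB atom-name field.
# A name starting in column 13 with a recognised two-letter symbol (CL, FE,
# ...) is a two-letter element; otherwise the first alphabetic character wins.
infer_element <- function(name4) {
  vapply(name4, function(nm) {
    two <- toupper(substr(nm, 1, 2))
    if (substr(nm, 1, 1) != " " && two %in% TWO_LETTER_ELEMENTS) return(two)
    ch <- regmatches(nm, regexpr("[A-Za-z]", nm))
    if (length(ch) == 0) "" else toupper(ch)
  }, character(1), USE.NAMES = FALSE)
}

# Keep one atom per (chain, res_seq, i_code, res_name, name): the highest
# occupancy wins, first-listed on ties.
resolve_alt_locs <- function(atoms) {
  key <- paste(atoms$chain, atoms$res_seq, atoms$i_code,
               atoms$res_name, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  keep <- ord[!duplicated(key[ord])]
  atoms <- atoms[sort(keep), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Write a structure model as PDB-format text
#'
#' Emits fixed-column `ATOM`/`HETATM` records followed by `END`. Used for
#' round-trip testing and by the synthetic-structure generator.
#'
#' @param model a `structure_model`.
#' @param path optional file path; when `NULL` the text is returned invisibly.
#' @return The PDB text as a single string (invisibly when written to file).
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  # atom names of <4 chars conventionally start in column 14
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$record, a$serial, nm,
                   ifelse(nzchar(a$alt_loc), a$alt_loc, " "),
                   a$res_name, a$chain, a$res_seq,
                   ifelse(nzchar(a$i_code), a$i_code, " "),
                   a$x, a$y, a$z, a$occupancy, 0, a$element)
  txt <- paste(c(lines, "END", ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(sub("\n$", "", txt), path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("structure_model '%s': %d atoms (%d polymer, %d hetero), %d residues\n",
              x$source_id, nrow(a), sum(a$record == "ATOM"),
              sum(a$record == "HETATM"),
              length(unique(paste(a$chain, a$res_seq, a$i_code)))))
  invisible(x)
}
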